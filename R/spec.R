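#' Describe a planted group effect for the synthetic cohort generator
#'
#' An effect is an additive shift applied to the mean node curve (or to the
#' expected fiber count for `variable = "Fib"`) of a specific tract instance
#' in a specific patient subset. Positive effect sizes place the affected
#' patients above the control baseline; the study's typical directions are a
#' positive shift for MD and negative shifts for FA, Vol and Fib.
#'
#' @param tract One of [tract_names()].
#' @param variable One of [afq_variables()].
#' @param effect_size Signed shift in the variable's units (FA unitless, MD
#'   1e-3 mm^2/s, Vol mm^3/node, Fib expected streamline count).
#' @param scope `"global"` (whole tract) or an integer segment index 1..5
#'   (one 20-node block). `Fib` admits only `"global"`.
#' @param laterality `"ipsi"`, `"contra"` (relative to each patient's ictal
#'   onset zone) or `"midline"`; CFMe admits only `"midline"`.
#' @param target_group `"FLE"`, `"TLE"` or `"both"` patient groups.
#' @param timepoint `"pre"`, `"post"` or `"both"`.
#' @param outcome Restrict to `"seizure-free"` (Engel I) or `"recurrence"`
#'   (Engel II-IV) patients, or `"any"`.
#'
#' @return An object of class `effect_spec`.
#' @seealso [cohort_spec()], [plant_effect()]
#' @export
#' @examples
#' effect_spec("CH", "MD", +0.40, scope = "global", laterality = "ipsi",
#'             target_group = "TLE")
effect_spec <- function(tract, variable, effect_size,
                        scope = "global",
                        laterality = c("ipsi", "contra", "midline"),
                        target_group = c("both", "FLE", "TLE"),
                        timepoint = c("both", "pre", "post"),
                        outcome = c("any", "seizure-free", "recurrence")) {
  tract <- match.arg(tract, tract_names())
  variable <- match.arg(variable, afq_variables())
  laterality <- match.arg(laterality)
  target_group <- match.arg(target_group)
  timepoint <- match.arg(timepoint)
  outcome <- match.arg(outcome)
  if (!is.numeric(effect_size) || length(effect_size) != 1 || !is.finite(effect_size)) {
    abort("`effect_size` must be a single finite number.")
  }
  if (!identical(scope, "global")) {
    if (!is.numeric(scope) || length(scope) != 1 || scope != as.integer(scope) ||
        scope < 1 || scope > 5) {
      abort("`scope` must be \"global\" or an integer segment index in 1..5.")
    }
    scope <- as.integer(scope)
  }
  if (tract == "CFMe" && laterality != "midline") {
    abort("CFMe is a midline tract: `laterality` must be \"midline\".")
  }
  if (tract != "CFMe" && laterality == "midline") {
    abort(paste0(tract, " is bilateral: `laterality` must be \"ipsi\" or \"contra\"."))
  }
  if (variable == "Fib" && !identical(scope, "global")) {
    abort("Fib is a whole-tract count: `scope` must be \"global\".")
  }
  structure(
    list(tract = tract, variable = variable, effect_size = effect_size,
         scope = scope, laterality = laterality, target_group = target_group,
         timepoint = timepoint, outcome = outcome),
    class = "effect_spec"
  )
}

#' @export
print.effect_spec <- function(x, ...) {
  scope <- if (identical(x$scope, "global")) "global" else paste0("segment ", x$scope)
  cat(sprintf("<effect_spec> %+g on %s %s %s (%s), %s/%s/%s\n",
              x$effect_size, x$laterality, x$tract, x$variable, scope,
              x$target_group, x$timepoint, x$outcome))
  invisible(x)
}

check_field <- function(ok, field, what) {
  if (!isTRUE(ok)) abort(paste0("Invalid cohort_spec field `", field, "`: ", what))
}

#' Configure a synthetic epilepsy-surgery cohort
#'
#' Defines the study design emulated by [simulate_cohort()]: group sizes for
#' healthy controls and frontal/temporal lobe epilepsy (FLE/TLE) patients,
#' how many patients are operated and the fraction of operated patients who
#' are seizure free (Engel Class I) one year after surgery, demographics,
#' the noise model for node curves, and a list of planted effects. Defaults
#' reproduce the study design: 19 controls, 8 FLE (7 operated, 1/7 seizure
#' free) and 12 TLE (10 operated, 6/10 seizure free).
#'
#' Node curves for FA, MD and Vol are generated as a smooth tract-specific
#' mean curve plus a subject-level random shift (`between_subject_sd`) plus
#' node-level Gaussian noise with exponential autocorrelation over the node
#' index (`node_noise_sd`, `node_correlation_length`). Fib is drawn from a
#' negative binomial with mean `fib_mean` and size `fib_size`.
#'
#' @param n_controls,n_fle,n_tle Group sizes (each at least 2).
#' @param n_operated_fle,n_operated_tle Operated patients per group;
#'   operated patients have both `pre` and `post` timepoints.
#' @param seizure_free_fraction Named numeric `c(FLE = , TLE = )`, the
#'   fraction of operated patients classed Engel I.
#' @param ioz_side_policy Side of the ictal onset zone for patients:
#'   `"random"`, `"all-left"` or `"all-right"`.
#' @param age_mean,age_sd Named numeric vectors over
#'   `c("control","FLE","TLE")`, years.
#' @param effects List of [effect_spec()] objects to plant.
#' @param between_subject_sd,node_noise_sd Named numeric over
#'   `c("FA","MD","Vol")`; non-negative.
#' @param node_correlation_length Exponential correlation length of the node
#'   noise, in nodes (0 means independent node noise).
#' @param fib_mean,fib_size Negative-binomial parameters for fiber counts.
#' @param dropout_prob Probability that a tract instance could not be
#'   measured and is flagged invalid (discarded downstream).
#' @param voxel_size Acquisition voxel size in mm (used for volume in the
#'   streamline-bundle output mode).
#' @param n_nodes,n_segments Profile resolution; `n_nodes` must be divisible
#'   by `n_segments`.
#' @param seed Integer seed controlling all randomness of the generator.
#'
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(seed = 1)
#' cohort <- simulate_cohort(spec)
#' dplyr::count(cohort$subjects, group)
cohort_spec <- function(n_controls = 19L, n_fle = 8L, n_tle = 12L,
                        n_operated_fle = 7L, n_operated_tle = 10L,
                        seizure_free_fraction = c(FLE = 1 / 7, TLE = 6 / 10),
                        ioz_side_policy = c("random", "all-left", "all-right"),
                        age_mean = c(control = 30, FLE = 22, TLE = 33.6),
                        age_sd = c(control = 8, FLE = 5, TLE = 13.8),
                        effects = list(),
                        between_subject_sd = c(FA = 0.02, MD = 0.03, Vol = 1.5),
                        node_noise_sd = c(FA = 0.02, MD = 0.03, Vol = 1.5),
                        node_correlation_length = 10,
                        fib_mean = 80, fib_size = 20,
                        dropout_prob = 0,
                        voxel_size = 2,
                        n_nodes = 100L, n_segments = 5L,
                        seed = 1L) {
  ioz_side_policy <- match.arg(ioz_side_policy)
  int1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == as.integer(x)
  check_field(int1(n_controls) && n_controls >= 2, "n_controls", "need an integer >= 2")
  check_field(int1(n_fle) && n_fle >= 2, "n_fle", "need an integer >= 2")
  check_field(int1(n_tle) && n_tle >= 2, "n_tle", "need an integer >= 2")
  check_field(int1(n_operated_fle) && n_operated_fle >= 0 && n_operated_fle <= n_fle,
              "n_operated_fle", "need an integer in 0..n_fle")
  check_field(int1(n_operated_tle) && n_operated_tle >= 0 && n_operated_tle <= n_tle,
              "n_operated_tle", "need an integer in 0..n_tle")
  check_field(all(c("FLE", "TLE") %in% names(seizure_free_fraction)) &&
                all(seizure_free_fraction >= 0 & seizure_free_fraction <= 1),
              "seizure_free_fraction", "need proportions in [0,1] named FLE and TLE")
  for (nm in c("control", "FLE", "TLE")) {
    check_field(nm %in% names(age_mean) && age_mean[[nm]] > 0, "age_mean",
                paste0("missing or non-positive entry for ", nm))
    check_field(nm %in% names(age_sd) && age_sd[[nm]] >= 0, "age_sd",
                paste0("missing or negative entry for ", nm))
  }
  check_field(is.list(effects) && all(map_lgl(effects, inherits, "effect_spec")),
              "effects", "need a list of effect_spec objects")
  for (nm in nodewise_variables()) {
    check_field(nm %in% names(between_subject_sd) && between_subject_sd[[nm]] >= 0,
                "between_subject_sd", paste0("missing or negative sd for ", nm))
    check_field(nm %in% names(node_noise_sd) && node_noise_sd[[nm]] >= 0,
                "node_noise_sd", paste0("missing or negative sd for ", nm))
  }
  check_field(is.numeric(node_correlation_length) && node_correlation_length >= 0,
              "node_correlation_length", "need a non-negative length in nodes")
  check_field(is.numeric(fib_mean) && fib_mean > 0, "fib_mean", "need a positive mean")
  check_field(is.numeric(fib_size) && fib_size > 0, "fib_size", "need a positive size")
  check_field(is.numeric(dropout_prob) && dropout_prob >= 0 && dropout_prob <= 1,
              "dropout_prob", "need a proportion in [0,1]")
  check_field(is.numeric(voxel_size) && voxel_size > 0, "voxel_size", "need a positive size in mm")
  check_field(int1(n_nodes) && n_nodes >= 10, "n_nodes", "need an integer >= 10")
  check_field(int1(n_segments) && n_segments >= 1 && n_nodes %% n_segments == 0,
              "n_segments", "need a divisor of n_nodes")
  check_field(int1(seed), "seed", "need a single integer")

  structure(
    list(n_controls = as.integer(n_controls), n_fle = as.integer(n_fle),
         n_tle = as.integer(n_tle),
         n_operated_fle = as.integer(n_operated_fle),
         n_operated_tle = as.integer(n_operated_tle),
         seizure_free_fraction = seizure_free_fraction,
         ioz_side_policy = ioz_side_policy,
         age_mean = age_mean, age_sd = age_sd,
         effects = effects,
         between_subject_sd = between_subject_sd,
         node_noise_sd = node_noise_sd,
         node_correlation_length = node_correlation_length,
         fib_mean = fib_mean, fib_size = fib_size,
         dropout_prob = dropout_prob, voxel_size = voxel_size,
         n_nodes = as.integer(n_nodes), n_segments = as.integer(n_segments),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d controls, %d FLE (%d operated), %d TLE (%d operated); %d nodes / %d segments; %d planted effect(s); seed %d\n",
    x$n_controls, x$n_fle, x$n_operated_fle, x$n_tle, x$n_operated_tle,
    x$n_nodes, x$n_segments, length(x$effects), x$seed))
  invisible(x)
}
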
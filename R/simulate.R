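# smooth tract-specific mean node curve; phase varies by tract so bundles
# are distinguishable but every curve has bounded first differences
mean_node_curve <- function(tract, variable, n_nodes) {
  base <- c(FA = 0.45, MD = 0.80, Vol = 15)[[variable]]
  amp <- c(FA = 0.03, MD = 0.04, Vol = 2)[[variable]]
  phase <- (match(tract, tract_names()) - 1) * pi / 3
  base + amp * sin(2 * pi * seq_len(n_nodes) / n_nodes + phase)
}

# lower-triangular factor of the exponential node-correlation matrix
node_corr_chol <- function(n_nodes, corr_length) {
  if (corr_length <= 0) return(diag(n_nodes))
  d <- abs(outer(seq_len(n_nodes), seq_len(n_nodes), "-"))
  t(chol(exp(-d / corr_length)))
}

# deterministic per-subject, per-timepoint RNG substream (independent of the
# draw order of other subjects, so the scheme survives reordering)
substream_seed <- function(seed, subject_index, timepoint) {
  tp <- if (timepoint == "post") 13L else 0L
  as.integer((abs(as.numeric(seed)) %% 1e6 * 1009 + subject_index * 101 + tp) %%
               2147483647)
}

# negative-binomial fiber counts; size = Inf is the noise-free limit and
# yields the (rounded) expected count deterministically
draw_fib <- function(n, mu, size) {
  if (is.infinite(size)) return(as.integer(round(mu)) + integer(n))
  rnbinom(n, mu = mu, size = size)
}

clamp_variable <- function(x, variable) {
  switch(variable,
    FA = pmin(pmax(x, 0), 1),
    MD = pmax(x, 1e-6),
    Vol = pmax(x, 0),
    x
  )
}

#' Apply a planted effect to a node curve
#'
#' Adds the effect size to all nodes (global scope) or only to the 20-node
#' block of the targeted segment, leaving every other node untouched.
#'
#' @param base_curve Numeric vector of node values (length divisible by 5
#'   when a segmental scope is used).
#' @param effect An [effect_spec()] (only its `scope` and `effect_size` are
#'   used here).
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' plant_effect(rep(0.5, 100), effect_spec("CH", "FA", -0.1, laterality = "ipsi"))[1]
plant_effect <- function(base_curve, effect) {
  stopifnot(inherits(effect, "effect_spec"))
  if (identical(effect$scope, "global")) {
    return(base_curve + effect$effect_size)
  }
  k <- effect$scope
  if (k < 1 || k > 5) abort("segment index must lie in 1..5")
  if (length(base_curve) %% 5 != 0) {
    abort("segmental effects need a node count divisible by 5")
  }
  len <- length(base_curve) / 5
  idx <- seq.int((k - 1) * len + 1, k * len)
  out <- base_curve
  out[idx] <- out[idx] + effect$effect_size
  out
}

# does `effect` apply to this subject at this timepoint and tract side?
effect_matches <- function(effect, subject, timepoint, tract, side) {
  if (effect$tract != tract) return(FALSE)
  if (subject$group == "control") return(FALSE)
  if (!(effect$target_group %in% c("both", subject$group))) return(FALSE)
  if (!(effect$timepoint %in% c("both", timepoint))) return(FALSE)
  if (effect$outcome != "any") {
    status <- if (identical(subject$engel_class, "I")) "seizure-free"
              else if (subject$engel_class %in% c("II", "III", "IV")) "recurrence"
              else "none"
    if (status != effect$outcome) return(FALSE)
  }
  if (tract == "CFMe") return(effect$laterality == "midline")
  eff_side <- if (effect$laterality == "ipsi") subject$ioz_side
              else setdiff(c("left", "right"), subject$ioz_side)
  identical(side, eff_side)
}

simulate_subjects <- function(spec) {
  groups <- c(rep("control", spec$n_controls), rep("FLE", spec$n_fle),
              rep("TLE", spec$n_tle))
  ids <- c(sprintf("C%03d", seq_len(spec$n_controls)),
           sprintf("F%03d", seq_len(spec$n_fle)),
           sprintf("T%03d", seq_len(spec$n_tle)))
  n <- length(groups)
  age <- pmax(10, rnorm(n, spec$age_mean[groups], spec$age_sd[groups]))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  dur_mean <- c(control = 0, FLE = 13.4, TLE = 17.6)[groups]
  dur_sd <- c(control = 0, FLE = 8.3, TLE = 9.7)[groups]
  duration <- pmax(1, rnorm(n, dur_mean, dur_sd))
  duration[groups == "control"] <- NA_real_
  ioz <- switch(spec$ioz_side_policy,
    "all-left" = rep("left", n),
    "all-right" = rep("right", n),
    "random" = sample(c("left", "right"), n, replace = TRUE)
  )
  ioz[groups == "control"] <- "none"

  operated <- rep(FALSE, n)
  engel <- rep("none", n)
  for (g in c("FLE", "TLE")) {
    idx <- which(groups == g)
    n_op <- if (g == "FLE") spec$n_operated_fle else spec$n_operated_tle
    op_idx <- idx[seq_len(n_op)]
    operated[op_idx] <- TRUE
    n_free <- round(spec$seizure_free_fraction[[g]] * n_op)
    free_idx <- op_idx[seq_len(n_free)]
    rec_idx <- setdiff(op_idx, free_idx)
    engel[free_idx] <- "I"
    if (length(rec_idx) > 0) {
      engel[rec_idx] <- sample(c("II", "III", "IV"), length(rec_idx), replace = TRUE)
    }
  }

  tibble(
    subject_id = ids, group = groups, operated = operated, ioz_side = ioz,
    engel_class = engel, age = age, sex = sex, duration = duration,
    has_pre = TRUE, has_post = operated
  )
}

subject_timepoints <- function(subject) {
  if (isTRUE(subject$has_post)) c("pre", "post") else "pre"
}

instance_table <- function() {
  bind_rows(
    expand_grid(tract = bilateral_tracts(), side = c("left", "right")),
    tibble(tract = "CFMe", side = "midline")
  )
}

#' Simulate a synthetic epilepsy-surgery cohort
#'
#' Generates subjects (controls, FLE and TLE patients with operated status,
#' ictal-onset-zone side and Engel outcome) together with per-subject tract
#' data: either ready-made 100-node tract profiles (`output = "profiles"`)
#' or raw streamline bundles with per-point FA/MD samples
#' (`output = "bundles"`) to be run through [profile_bundles()].
#'
#' Controls are measured once; their profiles carry timepoint `"pre"` and
#' serve as the reference arm of both pre- and postsurgical comparisons.
#' Operated patients are measured pre and post. Planted effects from
#' `spec$effects` are added to the matching subjects' mean curves before
#' noise clamping; all randomness derives from `spec$seed` through a fixed
#' per-subject substream scheme, so equal specs give identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @param output `"profiles"` (default) or `"bundles"`.
#' @return A list with elements `subjects` (tibble) and either `profiles`
#'   (a tract-profile tibble: subject_id, timepoint, tract, side, node, FA,
#'   MD, Vol, Fib, valid) or `bundles` (a tibble of streamline points:
#'   subject_id, timepoint, tract, side, fiber, x, y, z, FA, MD, with the
#'   voxel size as an attribute).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(seed = 7))
#' dplyr::count(cohort$profiles, timepoint)
simulate_cohort <- function(spec, output = c("profiles", "bundles")) {
  stopifnot(inherits(spec, "cohort_spec"))
  output <- match.arg(output)
  set.seed(spec$seed)
  subjects <- simulate_subjects(spec)
  L <- node_corr_chol(spec$n_nodes, spec$node_correlation_length)
  inst <- instance_table()

  curves <- precompute_mean_curves(spec$n_nodes)
  rows <- vector("list", nrow(subjects) * 2)
  r <- 0L
  for (i in seq_len(nrow(subjects))) {
    subj <- as.list(subjects[i, ])
    for (tp in subject_timepoints(subj)) {
      set.seed(substream_seed(spec$seed, i, tp))
      r <- r + 1L
      rows[[r]] <- if (output == "profiles") {
        simulate_profiles_one(spec, subj, tp, inst, L, curves)
      } else {
        simulate_bundles_one(spec, subj, tp, inst)
      }
    }
  }
  dat <- list_rbind(rows[seq_len(r)])
  if (output == "profiles") {
    list(subjects = subjects, profiles = as_tract_profiles(dat))
  } else {
    attr(dat, "voxel_size") <- spec$voxel_size
    list(subjects = subjects, bundles = dat)
  }
}

precompute_mean_curves <- function(n_nodes) {
  out <- list()
  for (tr in tract_names()) {
    for (v in nodewise_variables()) {
      out[[paste0(tr, ".", v)]] <- mean_node_curve(tr, v, n_nodes)
    }
  }
  out
}

# node-curve generation for one subject/timepoint; returns profile rows.
# All instance noise is drawn in one batch so the hot loop only applies
# planted effects and clamping.
simulate_profiles_one <- function(spec, subj, tp, inst, L, curves) {
  n <- spec$n_nodes
  vars <- nodewise_variables()
  m <- nrow(inst)
  node_sd <- unlist(spec$node_noise_sd[vars])
  btw_sd <- unlist(spec$between_subject_sd[vars])

  dropped <- if (spec$dropout_prob > 0) runif(m) < spec$dropout_prob else rep(FALSE, m)
  b <- matrix(rnorm(m * 3), m, 3) * rep(btw_sd, each = m)
  eps <- L %*% matrix(rnorm(n * m * 3), n, m * 3)  # columns: (instance, variable)

  vals <- matrix(NA_real_, n * m, 3, dimnames = list(NULL, vars))
  fib_mu <- rep(spec$fib_mean, m)
  is_patient <- subj$group != "control"
  for (j in seq_len(m)) {
    tract <- inst$tract[j]
    side <- inst$side[j]
    rows_j <- ((j - 1) * n + 1):(j * n)
    for (v in seq_along(vars)) {
      curve <- curves[[paste0(tract, ".", vars[v])]] + b[j, v] +
        eps[, (j - 1) * 3 + v] * node_sd[v]
      if (is_patient) {
        for (e in spec$effects) {
          if (e$variable == vars[v] && effect_matches(e, subj, tp, tract, side)) {
            curve <- plant_effect(curve, e)
          }
        }
      }
      vals[rows_j, v] <- clamp_variable(curve, vars[v])
    }
    if (is_patient) {
      for (e in spec$effects) {
        if (e$variable == "Fib" && effect_matches(e, subj, tp, tract, side)) {
          fib_mu[j] <- fib_mu[j] + e$effect_size
        }
      }
    }
  }
  fib <- draw_fib(m, pmax(fib_mu, 0.1), spec$fib_size)
  new_tibble(list(
    subject_id = rep(subj$subject_id, n * m),
    timepoint = rep(tp, n * m),
    tract = rep(inst$tract, each = n),
    side = rep(inst$side, each = n),
    node = rep(seq_len(n), m),
    FA = vals[, "FA"], MD = vals[, "MD"], Vol = vals[, "Vol"],
    Fib = rep(as.integer(fib), each = n),
    valid = rep(!dropped, each = n)
  ), nrow = n * m)
}

# streamline-bundle generation: fibers follow a smooth 3D centerline with
# per-fiber lateral offsets; FA/MD are sampled from the subject's node
# curves at each point's arc-length fraction. Vol and Fib emerge downstream
# from voxel occupancy and the fiber count, so planted Vol effects apply
# only in profile output mode.
simulate_bundles_one <- function(spec, subj, tp, inst) {
  n <- spec$n_nodes
  vars <- c("FA", "MD")
  out <- vector("list", nrow(inst))
  for (j in seq_len(nrow(inst))) {
    tract <- inst$tract[j]
    side <- inst$side[j]
    phase <- (match(tract, tract_names()) - 1) * pi / 3
    curves <- list()
    b <- rnorm(2) * unlist(spec$between_subject_sd[vars])
    for (v in seq_along(vars)) {
      curve <- mean_node_curve(tract, vars[v], n) + b[v]
      for (e in spec$effects) {
        if (e$variable == vars[v] && effect_matches(e, subj, tp, tract, side)) {
          curve <- plant_effect(curve, e)
        }
      }
      curves[[vars[v]]] <- clamp_variable(curve, vars[v])
    }
    fib_mu <- spec$fib_mean
    for (e in spec$effects) {
      if (e$variable == "Fib" && effect_matches(e, subj, tp, tract, side)) {
        fib_mu <- fib_mu + e$effect_size
      }
    }
    n_fib <- max(2L, draw_fib(1, max(fib_mu, 0.1), spec$fib_size))
    x_sign <- if (side == "right") 1 else if (side == "left") -1 else 0
    fibers <- vector("list", n_fib)
    for (f in seq_len(n_fib)) {
      n_pts <- sample(60:120, 1)
      tt <- seq(0, 1, length.out = n_pts)
      off <- rnorm(2) * 1.5
      x <- x_sign * 25 + 12 * sin(pi * tt + phase) + off[1] + rnorm(n_pts, sd = 0.1)
      y <- 100 * tt + rnorm(n_pts, sd = 0.1)
      z <- 8 * cos(0.5 * pi * tt + phase) + off[2] + rnorm(n_pts, sd = 0.1)
      # arc-length fraction of each point along its own fiber
      s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2 + diff(z)^2)))
      frac <- s / s[n_pts]
      node_frac <- (seq_len(n) - 1) / (n - 1)
      fa <- approx(node_frac, curves$FA, xout = frac)$y + rnorm(n_pts, sd = 0.005)
      md <- approx(node_frac, curves$MD, xout = frac)$y + rnorm(n_pts, sd = 0.005)
      fibers[[f]] <- tibble(
        subject_id = subj$subject_id, timepoint = tp, tract = tract,
        side = side, fiber = f, point = seq_len(n_pts), x = x, y = y, z = z,
        FA = pmin(pmax(fa, 0), 1), MD = pmax(md, 1e-6)
      )
    }
    out[[j]] <- list_rbind(fibers)
  }
  list_rbind(out)
}

as_tract_profiles <- function(x) {
  class(x) <- unique(c("tract_profiles", class(x)))
  x
}
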
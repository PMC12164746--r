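# pull the LSD contrast for the unordered pair {a, b}, oriented a - b
extract_pair <- function(fit, a, b) {
  pw <- fit$pairwise
  i <- which((pw$group_a == a & pw$group_b == b) | (pw$group_a == b & pw$group_b == a))
  d <- pw$diff[i]
  if (pw$group_a[i] != a) d <- -d
  list(group_a = a, group_b = b, diff = d, se = pw$se[i], df = pw$df[i],
       p_value = pw$p_value[i])
}

grid_scopes <- function(n_segments = 5L) {
  bind_rows(
    tibble(variable = afq_variables(), scope = "global"),
    expand_grid(variable = nodewise_variables(), scope = segment_labels(n_segments))
  )
}

#' Group-comparison grid over tracts, variables and scopes
#'
#' Runs the ANOVA/ANCOVA + Fisher LSD machinery over every analysis cell:
#' 11 tract instances (ipsi/contra for the five bilateral families plus the
#' midline CFMe) x 4 variables at global scope x FA/MD/Vol at each of the
#' 5 segments, i.e. 19 comparisons per instance and 209 rows per group
#' pair. Three groupings are available:
#'
#' * `"diagnosis"`: a 3-level model (control, FLE, TLE); the emitted pairs
#'   are each patient group against controls, with p-values from the LSD
#'   contrast inside the 3-level fit (pooled error variance).
#' * `"combined"`: all patients against controls in a 2-level model.
#' * `"outcome"`: operated patients only, seizure freedom (Engel I) versus
#'   seizure recurrence (Engel II-IV); controls are not involved.
#'
#' Patients contribute the requested `timepoint`; controls are measured
#' once and always contribute their single (presurgical) measurement. A
#' tract instance with any invalid (discarded) profile among the compared
#' subjects is emitted with `skipped = TRUE` and `NA` statistics rather
#' than silently dropped. Cells in which every compared group is constant
#' (zero within-group variance, the exact noise-free limit) are resolved by
#' the means alone: p = 1 when the group means coincide, p = 0 when they
#' differ.
#'
#' @param summaries Output of [summarize_profiles()].
#' @param subjects Subject table.
#' @param grouping `"diagnosis"`, `"combined"` or `"outcome"`.
#' @param timepoint `"pre"` or `"post"` (patients' side of the comparison).
#' @param alpha Significance level for the `significant` flag.
#' @param covariates Optional character subset of `c("age", "sex")` entered
#'   as ANCOVA covariates.
#' @param control_policy How control hemispheres are combined
#'   (see [combine_control_sides()]).
#' @param multiplicity `"none"` (the study's raw P < 0.05 with LSD) or
#'   `"BH"` for Benjamini-Hochberg adjustment within each group pair.
#' @param n_segments Number of segments (default 5).
#' @return A tibble of class `tract_grid`: cohort_scope, tract, laterality,
#'   timepoint, variable, scope, group_a, group_b, n_a, n_b, mean_a,
#'   mean_b, p_value, p_adjusted, direction (sign of mean_a - mean_b),
#'   significant, skipped. Attributes carry alpha and a config fingerprint.
#' @export
comparison_grid <- function(summaries, subjects,
                            grouping = c("diagnosis", "combined", "outcome"),
                            timepoint = c("pre", "post"),
                            alpha = 0.05,
                            covariates = NULL,
                            control_policy = c("pool", "subject-mean"),
                            multiplicity = c("none", "BH"),
                            n_segments = 5L) {
  grouping <- match.arg(grouping)
  timepoint <- match.arg(timepoint)
  control_policy <- match.arg(control_policy)
  multiplicity <- match.arg(multiplicity)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie strictly between 0 and 1.")
  }
  if (!is.null(covariates)) {
    covariates <- match.arg(covariates, c("age", "sex"), several.ok = TRUE)
  }

  asum <- analysis_summaries(summaries, subjects, control_policy)
  info <- subjects |>
    select("subject_id", "group", "operated", "engel_class", "age", "sex")
  asum <- asum |> left_join(info, by = "subject_id")

  asum <- asum |>
    filter((.data$group == "control" & .data$timepoint == "pre") |
             (.data$group != "control" & .data$timepoint == .env$timepoint))

  if (grouping == "diagnosis") {
    asum$glabel <- asum$group
    patient_groups <- intersect(c("FLE", "TLE"), unique(asum$glabel))
    if (length(patient_groups) == 0 || !"control" %in% asum$glabel) {
      abort("data error: diagnosis grouping needs controls and at least one patient group.")
    }
    pairs <- map(patient_groups, ~ c(.x, "control"))
  } else if (grouping == "combined") {
    asum$glabel <- ifelse(asum$group == "control", "control", "patients")
    if (length(unique(asum$glabel)) < 2) {
      abort("data error: combined grouping needs controls and patients.")
    }
    pairs <- list(c("patients", "control"))
  } else {
    asum <- asum |> filter(.data$group != "control", .data$operated)
    asum$glabel <- ifelse(asum$engel_class == "I", "seizure-free", "recurrence")
    if (!all(c("seizure-free", "recurrence") %in% unique(asum$glabel))) {
      abort("data error: outcome grouping needs operated patients in both Engel classes.")
    }
    pairs <- list(c("seizure-free", "recurrence"))
  }

  instances <- tract_instances()
  cells <- grid_scopes(n_segments)
  n_rows <- nrow(instances) * nrow(cells) * length(pairs)
  acc <- list(
    cohort_scope = character(n_rows), tract = character(n_rows),
    laterality = character(n_rows), variable = character(n_rows),
    scope = character(n_rows), group_a = character(n_rows),
    group_b = character(n_rows), n_a = integer(n_rows), n_b = integer(n_rows),
    mean_a = rep(NA_real_, n_rows), mean_b = rep(NA_real_, n_rows),
    p_value = rep(NA_real_, n_rows), direction = rep(NA_real_, n_rows),
    skipped = logical(n_rows)
  )
  pair_groups <- unique(unlist(pairs))
  r <- 0L

  for (j in seq_len(nrow(instances))) {
    tr <- instances$tract[j]
    lat <- instances$laterality[j]
    inst <- asum[asum$tract == tr &
                   (asum$laterality == lat |
                      (lat != "midline" & asum$laterality == "pooled-control")), ]
    skipped_inst <- any(!inst$valid)
    cell_rows <- split(seq_len(nrow(inst)), paste(inst$variable, inst$scope))
    glabel <- inst$glabel
    value <- inst$value
    for (cidx in seq_len(nrow(cells))) {
      v <- cells$variable[cidx]
      sc <- cells$scope[cidx]
      idx <- cell_rows[[paste(v, sc)]]
      g_cell <- glabel[idx]
      fit <- NULL
      degenerate <- FALSE
      if (!skipped_inst && length(idx) > 0 &&
          all(tabulate(factor(g_cell, levels = pair_groups)) >= 2)) {
        covs <- if (length(covariates)) inst[idx, covariates, drop = FALSE] else NULL
        fit <- tryCatch(
          lsd_anova(value[idx], g_cell, covariates = covs),
          error = function(e) {
            if (!grepl("degenerate-variance", conditionMessage(e))) stop(e)
            NULL
          }
        )
        if (is.null(fit)) {
          # exact noise-free limit: every group is constant, so the contrast
          # is decided by the means alone (equal -> p = 1, different -> p = 0)
          degenerate <- TRUE
          gm <- tapply(value[idx], g_cell, mean)
          fit <- list(means = list(group = names(gm), mean = as.numeric(gm)))
        }
      }
      for (p in pairs) {
        a <- p[1]; b <- p[2]
        r <- r + 1L
        acc$cohort_scope[r] <- paste0(a, "-vs-", b)
        acc$tract[r] <- tr
        acc$laterality[r] <- lat
        acc$variable[r] <- v
        acc$scope[r] <- sc
        acc$group_a[r] <- a
        acc$group_b[r] <- b
        acc$n_a[r] <- sum(g_cell == a)
        acc$n_b[r] <- sum(g_cell == b)
        if (is.null(fit)) {
          acc$skipped[r] <- TRUE
          next
        }
        m_a <- fit$means$mean[fit$means$group == a]
        m_b <- fit$means$mean[fit$means$group == b]
        acc$mean_a[r] <- m_a
        acc$mean_b[r] <- m_b
        if (degenerate) {
          same <- abs(m_a - m_b) <= 1e-8 * max(1, abs(m_a), abs(m_b))
          acc$p_value[r] <- as.numeric(same)
          acc$direction[r] <- if (same) 0 else sign(m_a - m_b)
        } else {
          acc$p_value[r] <- extract_pair(fit, a, b)$p_value
          acc$direction[r] <- sign(m_a - m_b)
        }
      }
    }
  }

  grid <- new_tibble(acc, nrow = n_rows) |>
    mutate(timepoint = .env$timepoint, .after = "laterality")
  grid <- grid |>
    group_by(.data$cohort_scope) |>
    mutate(p_adjusted = if (multiplicity == "BH") p.adjust(.data$p_value, "BH")
           else .data$p_value) |>
    ungroup() |>
    mutate(significant = ifelse(.data$skipped, NA, .data$p_adjusted < alpha)) |>
    arrange(.data$cohort_scope,
            factor(.data$tract, levels = tract_names()), .data$laterality,
            factor(.data$variable, levels = afq_variables()),
            factor(.data$scope, levels = scope_levels(n_segments)))

  attr(grid, "alpha") <- alpha
  attr(grid, "grouping") <- grouping
  attr(grid, "config_fingerprint") <- hash(list(
    alpha = alpha, grouping = grouping, timepoint = timepoint,
    covariates = covariates, control_policy = control_policy,
    multiplicity = multiplicity, n_segments = n_segments
  ))
  class(grid) <- unique(c("tract_grid", class(grid)))
  grid
}

#' Write a comparison grid as TSV with a JSON sidecar
#'
#' The TSV carries the grid rows plus the configuration fingerprint and
#' package version as columns; the sidecar (`<path>.json`) records the
#' analysis configuration and row/significance counts machine-readably.
#'
#' @param grid A `tract_grid` from [comparison_grid()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_grid <- function(grid, path) {
  out <- grid |>
    mutate(config_fingerprint = attr(grid, "config_fingerprint") %||% NA_character_,
           software_version = as.character(packageVersion("epitract")))
  write_tsv(out, path)
  sidecar <- list(
    alpha = attr(grid, "alpha"), grouping = attr(grid, "grouping"),
    config_fingerprint = attr(grid, "config_fingerprint"),
    software_version = as.character(packageVersion("epitract")),
    n_rows = nrow(grid), n_skipped = sum(grid$skipped),
    n_significant = sum(grid$significant, na.rm = TRUE)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
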
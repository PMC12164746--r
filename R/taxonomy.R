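format_vars <- function(vars) {
  paste(intersect(afq_variables(), vars), collapse = ",")
}

format_dirs <- function(vars, dirs) {
  ord <- intersect(afq_variables(), vars)
  if (length(ord) == 0) return("")
  d <- dirs[match(ord, vars)]
  paste0(ord, ifelse(d > 0, "+", ifelse(d < 0, "-", "0")), collapse = ",")
}

label_row <- function(results, category, timepoint, vars, dirs, segments = integer()) {
  tibble(
    cohort_scope = results$cohort_scope[1], tract = results$tract[1],
    laterality = results$laterality[1], category = category,
    timepoint = timepoint,
    variables = format_vars(vars),
    n_variables = length(vars),
    segments = paste(sort(segments), collapse = ","),
    n_segments = length(segments),
    directions = format_dirs(vars, dirs)
  )
}

check_rows <- function(results, scope_kind, n_segments = 5L) {
  if (scope_kind == "global") {
    g <- results[results$scope == "global", , drop = FALSE]
    if (!setequal(g$variable, afq_variables()) || nrow(g) != 4) {
      abort("incomplete grid: need the 4 global-scope rows (FA, MD, Vol, Fib) for the tract instance.")
    }
    g
  } else {
    s <- results[results$scope != "global", , drop = FALSE]
    if (nrow(s) != 3 * n_segments ||
        !setequal(s$variable, nodewise_variables()) ||
        !setequal(s$scope, segment_labels(n_segments))) {
      abort("incomplete grid: need FA, MD and Vol rows for every segment of the tract instance.")
    }
    s
  }
}

#' Rule-based abnormality labels for one tract instance
#'
#' `classify_global()` implements the consistent-global rule: a tract whose
#' whole-length comparison reaches significance on three or four of the
#' four variables (FA, MD, Vol, Fib) versus the reference group.
#' `classify_segmental()` implements the consistent-segmental rule: a
#' segment is abnormal when at least two of its three segmental variables
#' (FA, MD, Vol) are significant, and the tract is labelled when one to
#' four of the five segments are abnormal. A tract abnormal in all five
#' segments is flagged `whole-length-segmental` instead, since it is no
#' longer a segment-confined finding.
#'
#' @param results Comparison-grid rows for one tract instance, one
#'   timepoint and one group pair (global rows for `classify_global`,
#'   segmental rows for `classify_segmental`; extra rows are ignored).
#'   Rows must be evaluable (`skipped = FALSE`).
#' @param n_segments Number of segments (default 5).
#' @return A one-row label tibble, or `NULL` when the rule does not fire.
#' @export
classify_global <- function(results) {
  g <- check_rows(results, "global")
  if (any(is.na(g$significant))) {
    abort("tract instance not evaluable: skipped rows in the global grid.")
  }
  sig <- g$significant
  if (!sum(sig) %in% c(3L, 4L)) return(NULL)
  label_row(g, "consistent-global", g$timepoint[1],
            g$variable[sig], g$direction[sig])
}

#' @rdname classify_global
#' @export
classify_segmental <- function(results, n_segments = 5L) {
  s <- check_rows(results, "segmental", n_segments)
  if (any(is.na(s$significant))) {
    abort("tract instance not evaluable: skipped rows in the segmental grid.")
  }
  seg_idx <- match(s$scope, segment_labels(n_segments))
  var_idx <- match(s$variable, nodewise_variables())
  sig <- matrix(FALSE, 3, n_segments)
  sig[cbind(var_idx, seg_idx)] <- s$significant
  dirm <- matrix(NA_real_, 3, n_segments)
  dirm[cbind(var_idx, seg_idx)] <- s$direction
  abnormal <- colSums(sig) >= 2
  n_abn <- sum(abnormal)
  if (n_abn == 0) return(NULL)
  vars_mask <- rowSums(sig[, abnormal, drop = FALSE]) > 0
  vars <- nodewise_variables()[vars_mask]
  dirs <- map_dbl(which(vars_mask), function(v) {
    d <- dirm[v, abnormal & sig[v, ]]
    if (length(d) == 0) 0 else sign(sum(sign(d)))
  })
  category <- if (n_abn <= 4) "consistent-segmental" else "whole-length-segmental"
  label_row(s, category, s$timepoint[1], vars, dirs, which(abnormal))
}

#' Longitudinal (pre vs post) abnormality labels for one tract instance
#'
#' Implements the de novo and reinforcement rules. Globally: a tract gains
#' a `de-novo-global` label when three or four variables are significant
#' after surgery among the variables that were *not* significant before,
#' and a `reinforced-global` label when three or four variables are
#' significant at both timepoints with the same direction. Segmentally the
#' same idea applies to (variable, segment) pairs: a segment is de novo
#' abnormal when at least two of its variables are newly significant, and
#' reinforced when at least two persist with the same direction; one to
#' four such segments yield the corresponding label. A tract may carry
#' de novo and reinforced labels simultaneously on disjoint variable sets;
#' pre-only significance (resolution) yields no label.
#'
#' @param pre_results,post_results Comparison-grid rows (19 each) for the
#'   same tract instance and group pair at the two timepoints.
#' @param n_segments Number of segments (default 5).
#' @return A label tibble with 0 to 4 rows, all `timepoint = "post"`.
#' @export
classify_longitudinal <- function(pre_results, post_results, n_segments = 5L) {
  out <- list()

  g_pre <- check_rows(pre_results, "global")
  g_post <- check_rows(post_results, "global")
  if (any(is.na(g_pre$significant)) || any(is.na(g_post$significant))) {
    abort("tract instance not evaluable at one timepoint: no longitudinal label.")
  }
  ord <- match(afq_variables(), g_pre$variable)
  sp <- g_pre$significant[ord]
  dp <- g_pre$direction[ord]
  ordq <- match(afq_variables(), g_post$variable)
  sq <- g_post$significant[ordq]
  dq <- g_post$direction[ordq]

  newv <- sq & !sp
  if (sum(newv) %in% c(3L, 4L)) {
    out <- c(out, list(label_row(g_post, "de-novo-global", "post",
                                 afq_variables()[newv], dq[newv])))
  }
  reinf <- sp & sq & (sign(dp) == sign(dq))
  if (sum(reinf) %in% c(3L, 4L)) {
    out <- c(out, list(label_row(g_post, "reinforced-global", "post",
                                 afq_variables()[reinf], dq[reinf])))
  }

  s_pre <- check_rows(pre_results, "segmental", n_segments)
  s_post <- check_rows(post_results, "segmental", n_segments)
  if (any(is.na(s_pre$significant)) || any(is.na(s_post$significant))) {
    abort("tract instance not evaluable at one timepoint: no longitudinal label.")
  }
  msig <- function(s) {
    m <- matrix(FALSE, 3, n_segments)
    m[cbind(match(s$variable, nodewise_variables()),
            match(s$scope, segment_labels(n_segments)))] <- s$significant
    m
  }
  mdir <- function(s) {
    m <- matrix(NA_real_, 3, n_segments)
    m[cbind(match(s$variable, nodewise_variables()),
            match(s$scope, segment_labels(n_segments)))] <- s$direction
    m
  }
  Sp <- msig(s_pre); Sq <- msig(s_post)
  Dp <- mdir(s_pre); Dq <- mdir(s_post)

  seg_label <- function(pairs, category) {
    abnormal <- colSums(pairs) >= 2
    n_abn <- sum(abnormal)
    if (n_abn < 1 || n_abn > 4) return(NULL)
    vars_mask <- rowSums(pairs[, abnormal, drop = FALSE]) > 0
    vars <- nodewise_variables()[vars_mask]
    dirs <- map_dbl(which(vars_mask), function(v) {
      d <- Dq[v, abnormal & pairs[v, ]]
      if (length(d) == 0) 0 else sign(sum(sign(d)))
    })
    label_row(s_post, category, "post", vars, dirs, which(abnormal))
  }
  lab <- seg_label(Sq & !Sp, "de-novo-segmental")
  if (!is.null(lab)) out <- c(out, list(lab))
  lab <- seg_label(Sp & Sq & (sign(Dp) == sign(Dq)) & !is.na(Dp) & !is.na(Dq),
                   "reinforced-segmental")
  if (!is.null(lab)) out <- c(out, list(lab))

  if (length(out) == 0) return(NULL)
  list_rbind(out)
}

#' Classify abnormalities over a full comparison grid
#'
#' Applies [classify_global()] and [classify_segmental()] to every tract
#' instance and group pair of a presurgical grid and, when a postsurgical
#' grid is supplied, also to the post grid plus [classify_longitudinal()].
#' Tract instances with skipped cells at a timepoint are excluded from that
#' timepoint's labels (and from longitudinal labels when either timepoint
#' is affected); they are listed in the `not_evaluable` attribute rather
#' than treated as free of abnormality.
#'
#' @param grid_pre A `tract_grid` at timepoint `"pre"`.
#' @param grid_post Optional `tract_grid` at timepoint `"post"` with the
#'   same cohort pairs.
#' @param n_segments Number of segments (default 5).
#' @return A label tibble of class `abnormality_labels` (possibly 0 rows):
#'   cohort_scope, tract, laterality, category, timepoint, variables,
#'   n_variables, segments, n_segments, directions.
#' @export
classify_abnormalities <- function(grid_pre, grid_post = NULL, n_segments = 5L) {
  split_cells <- function(grid) {
    if (is.null(grid)) return(NULL)
    split(as_tibble(grid),
          paste(grid$cohort_scope, grid$tract, grid$laterality, sep = "\r"))
  }
  pre_cells <- split_cells(grid_pre)
  post_cells <- split_cells(grid_post)

  labels <- list()
  not_eval <- list()
  consistent <- function(cell, tp) {
    if (any(cell$skipped)) {
      not_eval[[length(not_eval) + 1]] <<- cell[1, c("cohort_scope", "tract", "laterality")] |>
        mutate(timepoint = tp)
      return(NULL)
    }
    bind_rows(classify_global(cell), classify_segmental(cell, n_segments))
  }
  for (key in names(pre_cells)) {
    labels <- c(labels, list(consistent(pre_cells[[key]], "pre")))
  }
  if (!is.null(post_cells)) {
    for (key in names(post_cells)) {
      labels <- c(labels, list(consistent(post_cells[[key]], "post")))
    }
    for (key in intersect(names(pre_cells), names(post_cells))) {
      pre <- pre_cells[[key]]
      post <- post_cells[[key]]
      if (any(pre$skipped) || any(post$skipped)) next
      labels <- c(labels, list(classify_longitudinal(pre, post, n_segments)))
    }
  }
  out <- list_rbind(keep(labels, ~ !is.null(.x)))
  if (nrow(out) == 0) {
    out <- tibble(cohort_scope = character(), tract = character(),
                  laterality = character(), category = character(),
                  timepoint = character(), variables = character(),
                  n_variables = integer(), segments = character(),
                  n_segments = integer(), directions = character())
  }
  out <- out |>
    arrange(.data$cohort_scope,
            factor(.data$tract, levels = tract_names()), .data$laterality,
            factor(.data$category, levels = categories_taxonomy()))
  attr(out, "not_evaluable") <- list_rbind(not_eval)
  class(out) <- unique(c("abnormality_labels", class(out)))
  out
}

#' Tally abnormality labels
#'
#' Counts labels by category (zero-filled over all categories) within
#' grouping columns, and optionally per involved variable.
#'
#' @param labels An `abnormality_labels` tibble.
#' @param by Grouping columns present in `labels` (default cohort_scope and
#'   laterality); use `character()` for overall counts.
#' @param per_variable If `TRUE`, split each label into its involved
#'   variables and count label-variable participations instead.
#' @return A tibble of deterministic ordering with an `n` count column.
#' @export
taxonomy_report <- function(labels, by = c("cohort_scope", "laterality"),
                            per_variable = FALSE) {
  cats <- categories_taxonomy()
  if (nrow(labels) == 0) {
    out <- if (per_variable) {
      expand_grid(category = cats, variable = afq_variables())
    } else {
      tibble(category = cats)
    }
    out$n <- 0L
    return(out)
  }
  by <- intersect(by, names(labels))
  dat <- as_tibble(labels)
  if (per_variable) {
    dat <- dat |>
      separate_rows("variables", sep = ",") |>
      rename(variable = "variables")
    out <- dat |> count(across(all_of(c(by, "category", "variable"))))
    out <- out |>
      complete(!!!rlang::syms(by),
               category = cats, variable = afq_variables(),
               fill = list(n = 0L))
  } else {
    out <- dat |> count(across(all_of(c(by, "category"))))
    out <- out |> complete(!!!rlang::syms(by), category = cats, fill = list(n = 0L))
  }
  out |>
    mutate(n = as.integer(.data$n)) |>
    arrange(across(all_of(by)), factor(.data$category, levels = cats))
}
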
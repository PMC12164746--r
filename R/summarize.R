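#' Summarise tract profiles into global and segment means
#'
#' Partitions each 100-node profile into `n_segments` equal blocks of
#' consecutive nodes (segment 1 = nodes 1-20, ..., segment 5 = nodes 81-100
#' at the defaults) and averages FA, MD and Vol within each block; the
#' global mean is computed as the mean of the segment means, which for
#' equal-sized segments is identical to the mean over all nodes (and makes
#' the aggregation identity exact in floating point). Fib is a whole-tract
#' count and appears with global scope only. Instances flagged
#' `valid = FALSE` are carried through with `NA` values so that downstream
#' comparisons can mark the affected cells as skipped instead of silently
#' dropping them.
#'
#' @param profiles A tract-profile tibble (see [simulate_cohort()] /
#'   [profile_bundles()] / [read_tract_profiles()]).
#' @param n_segments Number of segments; must divide the node count.
#' @return A long tibble: subject_id, timepoint, tract, side, variable,
#'   scope (`"global"`, `"seg1"`..`"segK"`), value, valid.
#' @export
summarize_profiles <- function(profiles, n_segments = 5L) {
  need <- c("subject_id", "timepoint", "tract", "side", "node",
            "FA", "MD", "Vol", "Fib", "valid")
  miss <- setdiff(need, names(profiles))
  if (length(miss) > 0) {
    abort(paste0("profiles table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  n_nodes <- max(profiles$node)
  if (n_nodes %% n_segments != 0) {
    abort(sprintf("configuration error: %d nodes are not divisible into %d segments",
                  n_nodes, n_segments))
  }
  seg_len <- n_nodes %/% n_segments
  segs <- segment_labels(n_segments)

  # segment means via one rowsum over (instance, segment) keys; the global
  # mean is the mean of the segment means (identical to the all-node mean
  # for equal segments, and exact by construction)
  ord <- order(profiles$subject_id, profiles$timepoint, profiles$tract,
               profiles$side, profiles$node)
  p <- profiles[ord, ]
  seg_of <- (p$node - 1L) %/% seg_len + 1L
  inst_key <- paste(p$subject_id, p$timepoint, p$tract, p$side, sep = "\r")
  seg_key <- paste(inst_key, sprintf("%03d", seg_of), sep = "\r")
  V <- rowsum(cbind(FA = p$FA, MD = p$MD, Vol = p$Vol), seg_key, reorder = TRUE) /
    seg_len

  keys <- matrix(unlist(strsplit(rownames(V), "\r", fixed = TRUE)),
                 ncol = 5, byrow = TRUE)
  seg_inst <- paste(keys[, 1], keys[, 2], keys[, 3], keys[, 4], sep = "\r")
  # global mean = mean() of the segment means, so that recomputing the
  # aggregation identity with mean() reproduces it bit for bit
  G <- vapply(colnames(V), function(cn) {
    apply(matrix(V[, cn], nrow = n_segments), 2, mean)
  }, numeric(nrow(V) / n_segments))
  if (is.null(dim(G))) G <- matrix(G, nrow = 1, dimnames = list(NULL, colnames(V)))
  rownames(G) <- seg_inst[seq(1, nrow(V), by = n_segments)]

  meta <- p[p$node == 1L, c("subject_id", "timepoint", "tract", "side",
                            "Fib", "valid")]
  meta_key <- paste(meta$subject_id, meta$timepoint, meta$tract, meta$side,
                    sep = "\r")
  seg_meta <- meta[match(seg_inst, meta_key), ]
  glob_meta <- meta[match(rownames(G), meta_key), ]

  mk <- function(md, variable, scope, value) {
    new_tibble(list(
      subject_id = md$subject_id, timepoint = md$timepoint, tract = md$tract,
      side = md$side, variable = rep(variable, nrow(md)), scope = scope,
      value = ifelse(md$valid, value, NA_real_), valid = md$valid
    ), nrow = nrow(md))
  }
  out <- list(
    mk(glob_meta, "FA", rep("global", nrow(G)), G[, "FA"]),
    mk(glob_meta, "MD", rep("global", nrow(G)), G[, "MD"]),
    mk(glob_meta, "Vol", rep("global", nrow(G)), G[, "Vol"]),
    mk(glob_meta, "Fib", rep("global", nrow(G)), as.numeric(glob_meta$Fib)),
    mk(seg_meta, "FA", segs[as.integer(keys[, 5])], V[, "FA"]),
    mk(seg_meta, "MD", segs[as.integer(keys[, 5])], V[, "MD"]),
    mk(seg_meta, "Vol", segs[as.integer(keys[, 5])], V[, "Vol"])
  )
  bind_rows(out) |>
    arrange(.data$subject_id, .data$timepoint,
            factor(.data$tract, levels = tract_names()), .data$side,
            factor(.data$variable, levels = afq_variables()),
            factor(.data$scope, levels = scope_levels(n_segments)))
}

recoded_laterality_levels <- function() c("ipsi", "contra", "midline", "pooled-control")

#' Recode tract sides relative to the ictal onset zone
#'
#' For patients, a tract on the same side as the ictal onset zone (IOZ)
#' becomes `ipsi` and the opposite side `contra`; the midline CFMe stays
#' `midline`. Controls (no IOZ) keep their anatomical side until
#' [combine_control_sides()] pools them. Applying the recode to an already
#' recoded table is a no-op, and no numeric field is touched.
#'
#' @param summaries Output of [summarize_profiles()] (or a profiles table
#'   with a `side` column).
#' @param subjects Subject table with `subject_id`, `group`, `ioz_side`.
#' @return The input with `side` replaced by a `laterality` column.
#' @export
recode_laterality <- function(summaries, subjects) {
  side_col <- if ("laterality" %in% names(summaries)) "laterality" else "side"
  already <- summaries[[side_col]] %in% recoded_laterality_levels()
  info <- subjects |> select("subject_id", "group", "ioz_side")
  out <- summaries |> left_join(info, by = "subject_id")
  if (anyNA(out$group)) {
    abort("data error: summaries reference subjects missing from the subject table")
  }
  bad <- out$group != "control" & !(out$ioz_side %in% c("left", "right")) & !already
  if (any(bad)) {
    abort(paste0("data error: patient(s) without an ictal-onset-zone side: ",
                 paste(unique(out$subject_id[bad]), collapse = ", ")))
  }
  side <- out[[side_col]]
  lat <- side
  pat <- out$group != "control" & !already
  lat[pat & side == "midline"] <- "midline"
  lat[pat & side == out$ioz_side] <- "ipsi"
  lat[pat & side != out$ioz_side & side != "midline"] <- "contra"
  out$laterality <- lat
  out[[setdiff(c("side", "laterality"), "laterality")]] <- NULL
  out |> select(-"group", -"ioz_side") |> relocate("laterality", .after = "tract")
}

#' Combine the two hemispheres of control subjects
#'
#' The study's control arm is side-agnostic: left and right tract
#' characteristics are combined. Under `policy = "pool"` both sides enter
#' the analysis as separate observations relabelled `pooled-control`;
#' under `policy = "subject-mean"` each control contributes one observation
#' per tract, the side average. CFMe passes through once per subject under
#' either policy.
#'
#' @param summaries Summaries of control subjects only (long format of
#'   [summarize_profiles()], before or after [recode_laterality()]).
#' @param subjects Subject table (used to verify the inputs are controls).
#' @param policy `"pool"` or `"subject-mean"`.
#' @return Summaries with a `laterality` column (`pooled-control` or
#'   `midline`) and, under pooling, an `obs_id` distinguishing the two
#'   hemispheric observations of a subject.
#' @export
combine_control_sides <- function(summaries, subjects,
                                  policy = c("pool", "subject-mean")) {
  policy <- match.arg(policy)
  side_col <- if ("laterality" %in% names(summaries)) "laterality" else "side"
  grp <- setNames(subjects$group, subjects$subject_id)
  if (any(grp[unique(summaries$subject_id)] != "control")) {
    abort("data error: combine_control_sides() received non-control subjects")
  }
  side <- summaries[[side_col]]
  if (policy == "pool") {
    out <- summaries
    out$obs_id <- paste0(out$subject_id, ifelse(side == "midline", "", paste0(".", side)))
    out$laterality <- ifelse(side == "midline", "midline", "pooled-control")
    out[[setdiff(c("side", "laterality"), "laterality")]] <- NULL
  } else {
    out <- summaries |>
      mutate(.side = .data[[side_col]]) |>
      group_by(.data$subject_id, .data$timepoint, .data$tract,
               .data$variable, .data$scope) |>
      summarise(
        value = if (all(is.na(.data$value))) NA_real_ else mean(.data$value, na.rm = TRUE),
        valid = any(.data$valid),
        laterality = if (all(.data$.side == "midline")) "midline" else "pooled-control",
        .groups = "drop"
      )
    out$obs_id <- out$subject_id
  }
  out |> relocate("laterality", .after = "tract")
}

# analysis-ready summaries: patients laterality-recoded, controls combined,
# one obs_id per analysis observation
analysis_summaries <- function(summaries, subjects,
                               control_policy = c("pool", "subject-mean")) {
  control_policy <- match.arg(control_policy)
  grp <- setNames(subjects$group, subjects$subject_id)
  is_control <- grp[summaries$subject_id] == "control"
  pats <- recode_laterality(summaries[!is_control, , drop = FALSE], subjects)
  pats$obs_id <- pats$subject_id
  ctrl <- combine_control_sides(summaries[is_control, , drop = FALSE],
                                subjects, control_policy)
  bind_rows(pats, ctrl)
}
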
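#' Resample a streamline at equally spaced arc-length nodes
#'
#' Places `n_nodes` points on the piecewise-linear curve through the input
#' points at equal arc-length spacing, preserving both endpoints exactly.
#' Scalar samples attached to the points (e.g. FA, MD) are interpolated
#' linearly along the same arc-length parameterisation.
#'
#' @param points A data frame / tibble with numeric columns `x`, `y`, `z`
#'   and optionally scalar columns, or a numeric matrix with 3 columns.
#' @param n_nodes Number of output nodes (>= 2).
#' @param scalars Character vector of scalar column names to interpolate
#'   (defaults to all non-coordinate numeric columns when `points` is a
#'   data frame).
#' @return A tibble with `n_nodes` rows and columns `x`, `y`, `z` plus the
#'   interpolated scalar columns.
#' @export
#' @examples
#' fib <- tibble::tibble(x = 0, y = 0, z = c(0, 99))
#' resample_fiber(fib, 100)$z[1:3]
resample_fiber <- function(points, n_nodes = 100L, scalars = NULL) {
  if (is.matrix(points)) {
    points <- as_tibble(points, .name_repair = "minimal")
    names(points)[1:3] <- c("x", "y", "z")
  }
  if (!all(c("x", "y", "z") %in% names(points))) {
    abort("`points` must have columns x, y, z.")
  }
  if (n_nodes < 2) abort("`n_nodes` must be at least 2.")
  if (nrow(points) < 2) abort("degenerate fiber: fewer than 2 points.")
  xyz <- as.matrix(points[, c("x", "y", "z")])
  seg <- sqrt(rowSums(diff(xyz)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) abort("degenerate fiber: zero total arc length.")
  # collapse zero-length steps so approx() sees strictly increasing knots
  keep <- c(TRUE, seg > 0)
  s_k <- s[keep]
  target <- seq(0, total, length.out = n_nodes)
  if (is.null(scalars)) {
    scalars <- setdiff(names(points)[map_lgl(points, is.numeric)], c("x", "y", "z"))
  }
  cols <- c("x", "y", "z", scalars)
  out <- map(cols, function(cl) {
    v <- approx(s_k, points[[cl]][keep], xout = target)$y
    # endpoints exactly
    v[1] <- points[[cl]][1]
    v[n_nodes] <- points[[cl]][nrow(points)]
    v
  })
  names(out) <- cols
  as_tibble(out)
}

# voxel-occupancy volume at one node: number of distinct voxel cells (at
# voxel_size) containing any fiber's k-th resampled point, times voxel_size^3
node_voxel_volume <- function(xyz, voxel_size) {
  cells <- unique(floor(xyz / voxel_size))
  nrow(cells) * voxel_size^3
}

#' Build a tract profile from one streamline bundle
#'
#' Resamples every fiber to `n_nodes` equally spaced arc-length nodes and
#' aggregates: FA/MD at node k are the unweighted means over fibers of the
#' fiber-wise interpolated scalars; Vol at node k is the volume of the
#' distinct voxel cells (edge `voxel_size` mm) containing any fiber's k-th
#' node; Fib is the fiber count. A bundle with fewer than `min_fibers`
#' fibers yields `valid = FALSE` rather than an error, mirroring the
#' discard rule for tracts whose variables could not be measured.
#'
#' @param bundle Tibble of streamline points with columns `fiber`, `x`, `y`,
#'   `z`, `FA`, `MD` (one tract instance of one subject/timepoint; metadata
#'   columns `subject_id`, `timepoint`, `tract`, `side` are carried through
#'   if present).
#' @param n_nodes Profile resolution (default 100).
#' @param min_fibers Minimum fiber count for a measurable tract (default 5).
#' @param voxel_size Voxel edge in mm for the volume computation.
#' @return A tract-profile tibble with `n_nodes` rows: node, FA, MD, Vol,
#'   Fib, valid (+ metadata columns).
#' @export
profile_bundle <- function(bundle, n_nodes = 100L, min_fibers = 5L, voxel_size = 2) {
  stopifnot(is.data.frame(bundle), "fiber" %in% names(bundle))
  fibers <- split(bundle, bundle$fiber)
  res <- map(fibers, resample_fiber, n_nodes = n_nodes, scalars = c("FA", "MD"))
  fa <- rowMeans(do.call(cbind, map(res, "FA")))
  md <- rowMeans(do.call(cbind, map(res, "MD")))
  vol <- map_dbl(seq_len(n_nodes), function(k) {
    xyz <- do.call(rbind, map(res, ~ as.matrix(.x[k, c("x", "y", "z")])))
    node_voxel_volume(xyz, voxel_size)
  })
  meta <- bundle[1, intersect(c("subject_id", "timepoint", "tract", "side"),
                              names(bundle)), drop = FALSE]
  out <- tibble(
    node = seq_len(n_nodes), FA = fa, MD = md, Vol = vol,
    Fib = length(fibers), valid = length(fibers) >= min_fibers
  )
  as_tract_profiles(bind_cols(meta[rep(1, n_nodes), , drop = FALSE], out))
}

#' Profile every bundle of a cohort
#'
#' Applies [profile_bundle()] to each (subject, timepoint, tract, side)
#' instance of a long streamline-point tibble, as produced by
#' [simulate_cohort()] with `output = "bundles"`.
#'
#' @inheritParams profile_bundle
#' @param bundles Long tibble of streamline points for many tract instances.
#' @return A tract-profile tibble covering all instances.
#' @export
profile_bundles <- function(bundles, n_nodes = 100L, min_fibers = 5L,
                            voxel_size = attr(bundles, "voxel_size") %||% 2) {
  key <- paste(bundles$subject_id, bundles$timepoint, bundles$tract,
               bundles$side, sep = "\r")
  parts <- split(bundles, key)
  as_tract_profiles(list_rbind(map(
    parts, profile_bundle,
    n_nodes = n_nodes, min_fibers = min_fibers, voxel_size = voxel_size
  )))
}
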
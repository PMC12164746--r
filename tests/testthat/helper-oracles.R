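# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementations they check.

# Kruskal-Wallis H with tie correction, straight from the rank-sum formula
kw_oracle <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  gs <- split(r, groups)
  h <- 12 / (N * (N + 1)) * sum(vapply(gs, function(z) sum(z)^2 / length(z),
                                       0)) - 3 * (N + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h <- h / corr
  list(H = h, p = stats::pchisq(h, length(gs) - 1, lower.tail = FALSE))
}

# one-way ANOVA + Fisher LSD from the explicit sums-of-squares decomposition
anova_lsd_oracle <- function(values, groups) {
  gs <- split(values, groups)
  k <- length(gs)
  N <- length(values)
  m <- vapply(gs, mean, 0)
  n <- vapply(gs, length, 0L)
  grand <- mean(values)
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum(vapply(seq_len(k), function(i) sum((gs[[i]] - m[i])^2), 0))
  mse <- ssw / (N - k)
  f <- (ssb / (k - 1)) / mse
  pairs <- utils::combn(names(gs), 2)
  pw <- apply(pairs, 2, function(p) {
    a <- p[1]; b <- p[2]
    t <- (m[a] - m[b]) / sqrt(mse * (1 / n[a] + 1 / n[b]))
    2 * stats::pt(-abs(t), N - k)
  })
  names(pw) <- paste(pairs[1, ], pairs[2, ], sep = "|")
  list(F = f, p = stats::pf(f, k - 1, N - k, lower.tail = FALSE), pairwise = pw)
}

# brute-force evaluators of the abnormality rules on significance patterns
global_rule_oracle <- function(sig4) {
  sum(sig4) == 3 || sum(sig4) == 4
}

segmental_rule_oracle <- function(sig_mat) {
  # sig_mat: 3 variables x 5 segments
  abn <- integer(0)
  for (s in 1:5) {
    n <- 0
    for (v in 1:3) if (sig_mat[v, s]) n <- n + 1
    if (n >= 2) abn <- c(abn, s)
  }
  if (length(abn) >= 1 && length(abn) <= 4) {
    list(fires = TRUE, whole = FALSE, segments = abn)
  } else if (length(abn) == 5) {
    list(fires = FALSE, whole = TRUE, segments = abn)
  } else {
    list(fires = FALSE, whole = FALSE, segments = abn)
  }
}

# arc-length coordinate of a point known to lie on a polyline
arc_position <- function(xyz, pt) {
  s <- c(0, cumsum(sqrt(rowSums(diff(xyz)^2))))
  best <- Inf
  pos <- NA_real_
  for (j in seq_len(nrow(xyz) - 1)) {
    d <- xyz[j + 1, ] - xyz[j, ]
    len2 <- sum(d^2)
    if (len2 == 0) next
    t <- sum((pt - xyz[j, ]) * d) / len2
    t <- min(max(t, 0), 1)
    perp <- sqrt(sum((xyz[j, ] + t * d - pt)^2))
    if (perp < best) {
      best <- perp
      pos <- s[j] + t * sqrt(len2)
    }
  }
  pos
}

# dense brute-force equal-arc-length resampler for polylines
resample_oracle <- function(xyz, n_nodes, densify = 200L) {
  # densify each segment linearly, then walk the cumulative arc length
  pts <- list()
  for (i in seq_len(nrow(xyz) - 1)) {
    tt <- seq(0, 1, length.out = densify + 1)[-(densify + 1)]
    pts[[i]] <- outer(1 - tt, xyz[i, ]) + outer(tt, xyz[i + 1, ])
  }
  dense <- rbind(do.call(rbind, pts), xyz[nrow(xyz), ])
  s <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  target <- seq(0, s[length(s)], length.out = n_nodes)
  idx <- vapply(target, function(t) which.min(abs(s - t)), 0L)
  dense[idx, , drop = FALSE]
}

# grid-row scaffolding for taxonomy tests: one tract instance, all 19 cells
make_instance_grid <- function(sig_global = rep(FALSE, 4),
                               sig_seg = matrix(FALSE, 3, 5),
                               dir_global = rep(1, 4),
                               dir_seg = matrix(1, 3, 5),
                               timepoint = "pre") {
  g <- tibble::tibble(
    cohort_scope = "patients-vs-control", tract = "CH", laterality = "ipsi",
    timepoint = timepoint, variable = afq_variables(), scope = "global",
    significant = sig_global, direction = dir_global, skipped = FALSE
  )
  s <- tidyr::expand_grid(variable = nodewise_variables(),
                          scope = paste0("seg", 1:5))
  s$cohort_scope <- "patients-vs-control"
  s$tract <- "CH"; s$laterality <- "ipsi"; s$timepoint <- timepoint
  vi <- match(s$variable, nodewise_variables())
  si <- as.integer(sub("seg", "", s$scope))
  s$significant <- sig_seg[cbind(vi, si)]
  s$direction <- dir_seg[cbind(vi, si)]
  s$skipped <- FALSE
  dplyr::bind_rows(g, s)
}

# a small cohort spec used across tests (cheap but structurally complete)
small_spec <- function(seed = 1, ...) {
  cohort_spec(n_controls = 6, n_fle = 2, n_tle = 4,
              n_operated_fle = 2, n_operated_tle = 3,
              seizure_free_fraction = c(FLE = 0.5, TLE = 2 / 3),
              seed = seed, ...)
}
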
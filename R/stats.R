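#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference distribution
#' on (number of groups - 1) degrees of freedom, as used for the
#' demographic comparisons (age, epilepsy duration) between patient groups.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values`.
#' @return A one-row tibble: `H`, `df`, `p_value`.
#' @export
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("A", "B"), each = 3))
kruskal_wallis <- function(values, groups) {
  if (length(values) != length(groups)) {
    abort("`values` and `groups` must have the same length.")
  }
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(as.character(groups[keep]))
  if (nlevels(groups) < 2) abort("data error: need at least 2 non-empty groups.")
  if (any(table(groups) == 0)) abort("data error: empty group.")
  kt <- kruskal.test(values, groups)
  tibble(H = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value)
}

#' Kruskal-Wallis tests of demographics between patient groups
#'
#' Convenience wrapper running [kruskal_wallis()] on age and epilepsy
#' duration between the FLE and TLE groups of a subject table.
#'
#' @param subjects Subject table.
#' @param variables Columns of `subjects` to test.
#' @return A tibble with one row per variable: variable, H, df, p_value.
#' @export
compare_demographics <- function(subjects, variables = c("age", "duration")) {
  pats <- subjects |> filter(.data$group != "control")
  list_rbind(map(variables, function(v) {
    kruskal_wallis(pats[[v]], pats$group) |> mutate(variable = v, .before = 1)
  }))
}

#' One-way ANOVA / ANCOVA with Fisher LSD pairwise contrasts
#'
#' Fits the general linear model of a continuous response on a group factor
#' (optionally adjusting for covariates entered linearly) and computes
#' Fisher's least-significant-difference post-hoc contrasts: two-sided
#' pairwise t tests built on the pooled error mean square and its residual
#' degrees of freedom, with no multiplicity adjustment. With two groups and
#' no covariates the LSD contrast is algebraically the pooled-variance
#' two-sample t test.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length as `values`.
#' @param covariates Optional data frame of per-observation covariates
#'   (numeric or factor), e.g. age and sex. `NULL` or zero columns gives
#'   the plain one-way ANOVA.
#' @return An object of class `lsd_anova` with elements `omnibus` (F test
#'   for the group term), `pairwise` (one row per unordered group pair:
#'   diff = mean_a - mean_b, se, df, statistic, p_value), `means` (per-group
#'   n and raw mean) and `mse`. [tidy()] returns the pairwise table,
#'   [glance()] the omnibus row.
#' @export
#' @examples
#' fit <- lsd_anova(c(1, 2, 3, 4, 5, 7), rep(c("a", "b", "c"), each = 2))
#' tidy(fit)
lsd_anova <- function(values, groups, covariates = NULL) {
  if (length(values) != length(groups)) {
    abort("`values` and `groups` must have the same length.")
  }
  g <- factor(as.character(groups))
  if (nlevels(g) < 2) abort("data error: need at least 2 groups.")
  n_g <- tabulate(g)
  if (any(n_g < 2)) abort("data error: every group needs at least 2 observations.")
  has_cov <- !is.null(covariates) && NCOL(covariates) > 0
  N <- length(values)
  k <- nlevels(g)

  gmeans <- as.numeric(rowsum(values, g) / n_g)
  means <- new_tibble(list(group = levels(g), n = n_g, mean = gmeans), nrow = k)

  # constant-within-every-group data give no error variance; detect this on
  # the value range (robust to 1-ulp summation noise in the group means)
  rng <- as.numeric(tapply(values, g, function(z) diff(range(z))))
  if (all(rng <= 1e-12 * max(1, abs(values)))) {
    abort("degenerate-variance error: zero within-group variance.")
  }

  if (!has_cov) {
    if (N - k < 1) abort("data error: no residual degrees of freedom.")
    ssw <- sum((values - gmeans[as.integer(g)])^2)
    if (ssw <= 0) abort("degenerate-variance error: zero within-group variance.")
    grand <- mean(values)
    ssb <- sum(n_g * (gmeans - grand)^2)
    df1 <- k - 1
    df2 <- N - k
    mse <- ssw / df2
    f <- (ssb / df1) / mse
    omnibus <- new_tibble(list(statistic = f, df1 = df1, df2 = df2,
                               p_value = pf(f, df1, df2, lower.tail = FALSE)),
                          nrow = 1L)
    pairs <- utils::combn(k, 2)
    diff <- gmeans[pairs[1, ]] - gmeans[pairs[2, ]]
    se <- sqrt(mse * (1 / n_g[pairs[1, ]] + 1 / n_g[pairs[2, ]]))
    tval <- diff / se
    np <- ncol(pairs)
    pairwise <- new_tibble(list(
      group_a = levels(g)[pairs[1, ]], group_b = levels(g)[pairs[2, ]],
      diff = diff, se = se, df = rep(df2, np), statistic = tval,
      p_value = 2 * pt(-abs(tval), df2)
    ), nrow = np)
  } else {
    covariates <- as.data.frame(covariates)
    dat <- data.frame(.y = values, .g = g, covariates)
    if (any(!complete.cases(dat))) abort("data error: missing covariate values.")
    form <- stats::as.formula(paste(".y ~", paste(names(covariates), collapse = " + "),
                                    "+ .g"))
    fit <- lm(form, data = dat)
    df2 <- df.residual(fit)
    if (df2 < 1) abort("data error: no residual degrees of freedom.")
    mse <- sum(fit$residuals^2) / df2
    if (mse <= 0) abort("degenerate-variance error: zero residual variance.")
    atab <- anova(fit)  # sequential; group entered last = adjusted for covariates
    grow <- which(rownames(atab) == ".g")
    omnibus <- tibble(statistic = atab$`F value`[grow], df1 = atab$Df[grow],
                      df2 = df2, p_value = atab$`Pr(>F)`[grow])
    # LSD contrasts on the adjusted group effects (treatment coding:
    # coefficient of level a minus coefficient of level b)
    beta <- stats::coef(fit)
    V <- vcov(fit)
    coef_of <- function(level) {
      nm <- paste0(".g", level)
      if (nm %in% names(beta)) nm else NA_character_
    }
    pairs <- utils::combn(levels(g), 2)
    pw <- map2(pairs[1, ], pairs[2, ], function(a, b) {
      ca <- coef_of(a); cb <- coef_of(b)
      est <- (if (is.na(ca)) 0 else beta[[ca]]) - (if (is.na(cb)) 0 else beta[[cb]])
      va <- if (is.na(ca)) 0 else V[ca, ca]
      vb <- if (is.na(cb)) 0 else V[cb, cb]
      vab <- if (is.na(ca) || is.na(cb)) 0 else V[ca, cb]
      se <- sqrt(va + vb - 2 * vab)
      tval <- est / se
      tibble(group_a = a, group_b = b, diff = est, se = se, df = df2,
             statistic = tval, p_value = 2 * pt(-abs(tval), df2))
    })
    pairwise <- list_rbind(pw)
  }

  structure(list(omnibus = omnibus, pairwise = pairwise, means = means,
                 mse = mse, covariates = if (has_cov) names(covariates) else character()),
            class = "lsd_anova")
}

#' @export
print.lsd_anova <- function(x, ...) {
  cat(sprintf("<lsd_anova> F(%d, %d) = %.4g, p = %.4g; %d group(s)%s\n",
              x$omnibus$df1, x$omnibus$df2, x$omnibus$statistic,
              x$omnibus$p_value, nrow(x$means),
              if (length(x$covariates)) paste0("; covariates: ",
                                               paste(x$covariates, collapse = ", "))
              else ""))
  print(x$pairwise)
  invisible(x)
}

#' @rdname lsd_anova
#' @param x An `lsd_anova` object.
#' @param ... Unused.
#' @export
tidy.lsd_anova <- function(x, ...) x$pairwise

#' @rdname lsd_anova
#' @export
glance.lsd_anova <- function(x, ...) x$omnibus

#' @export
generics::tidy

#' @export
generics::glance
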
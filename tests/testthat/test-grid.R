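test_that("the grid has 19 comparisons per tract instance and 209 per pair", {
  ch <- simulate_cohort(small_spec(seed = 31))
  s <- summarize_profiles(ch$profiles)
  g <- comparison_grid(s, ch$subjects, grouping = "diagnosis", timepoint = "pre")
  expect_equal(nrow(g), 2 * 11 * 19)
  per_pair <- dplyr::count(g, cohort_scope)
  expect_true(all(per_pair$n == 209))
  per_inst <- dplyr::count(g, cohort_scope, tract, laterality)
  expect_true(all(per_inst$n == 19))
  # Fib never appears with a segment scope
  expect_true(all(g$scope[g$variable == "Fib"] == "global"))
  # significance flag is consistent with alpha
  ok <- !is.na(g$significant)
  expect_identical(g$significant[ok], g$p_adjusted[ok] < 0.05)

  comb <- comparison_grid(s, ch$subjects, grouping = "combined", timepoint = "pre")
  expect_equal(nrow(comb), 209)
  expect_true(all(comb$group_a == "patients"))
})

test_that("grid p-values equal a direct LSD fit of the same cell", {
  ch <- simulate_cohort(small_spec(seed = 32))
  s <- summarize_profiles(ch$profiles)
  g <- comparison_grid(s, ch$subjects, grouping = "diagnosis", timepoint = "pre")
  cell <- g[g$cohort_scope == "TLE-vs-control" & g$tract == "CFMe" &
              g$variable == "MD" & g$scope == "seg2", ]
  # rebuild the cell by hand: patients' seg2 MD + pooled control sides
  pats <- ch$subjects$subject_id[ch$subjects$group != "control"]
  x <- s[s$tract == "CFMe" & s$variable == "MD" & s$scope == "seg2" &
           s$timepoint == "pre", ]
  grp <- ch$subjects$group[match(x$subject_id, ch$subjects$subject_id)]
  fit <- lsd_anova(x$value, grp)
  want <- tidy(fit)
  i <- which(want$group_a == "TLE" | want$group_b == "TLE")
  i <- i[want$group_a[i] == "control" | want$group_b[i] == "control"]
  expect_equal(cell$p_value, want$p_value[i], tolerance = 1e-12)
  expect_equal(cell$mean_a,
               mean(x$value[grp == "TLE"]), tolerance = 1e-12)
})

test_that("planted MD increase is detected with a positive direction", {
  eff <- list(effect_spec("CH", "MD", +0.40, "global", "ipsi",
                          target_group = "TLE"))
  spec <- cohort_spec(n_controls = 19, n_fle = 2, n_tle = 12,
                      n_operated_fle = 0, n_operated_tle = 0,
                      ioz_side_policy = "all-left", effects = eff, seed = 33)
  ch <- simulate_cohort(spec)
  g <- comparison_grid(summarize_profiles(ch$profiles), ch$subjects,
                       grouping = "diagnosis", timepoint = "pre")
  row <- g[g$cohort_scope == "TLE-vs-control" & g$tract == "CH" &
             g$laterality == "ipsi" & g$variable == "MD" & g$scope == "global", ]
  expect_true(row$significant)
  expect_equal(row$direction, 1)  # patients above controls: increased MD
  expect_equal(row$n_a, 12)
  expect_equal(row$n_b, 38)  # 19 controls, both hemispheres pooled
})

test_that("invalid profiles mark whole tract instances as skipped", {
  ch <- simulate_cohort(small_spec(seed = 34))
  prof <- ch$profiles
  prof$valid[prof$subject_id == "C001" & prof$tract == "ILF" &
               prof$side == "left"] <- FALSE
  g <- comparison_grid(summarize_profiles(prof), ch$subjects,
                       grouping = "diagnosis", timepoint = "pre")
  skipped <- g[g$skipped, ]
  expect_setequal(unique(skipped$tract), "ILF")
  expect_equal(nrow(skipped), 2 * 2 * 19)  # both lateralities, both pairs
  expect_true(all(is.na(skipped$p_value)))
  expect_equal(nrow(g), 418)  # still emitted, not dropped
})

test_that("outcome grouping compares Engel I with II-IV and validates inputs", {
  ch <- simulate_cohort(small_spec(seed = 35))
  s <- summarize_profiles(ch$profiles)
  g <- comparison_grid(s, ch$subjects, grouping = "outcome", timepoint = "post")
  expect_equal(nrow(g), 209)
  expect_true(all(g$group_a == "seizure-free" & g$group_b == "recurrence"))
  n_free <- sum(ch$subjects$engel_class == "I")
  expect_true(all(g$n_a == n_free))

  all_free <- ch$subjects
  all_free$engel_class[all_free$operated] <- "I"
  expect_error(comparison_grid(s, all_free, grouping = "outcome",
                               timepoint = "post"), "data error")
})

test_that("covariate adjustment and BH multiplicity change the grid as configured", {
  ch <- simulate_cohort(small_spec(seed = 36))
  s <- summarize_profiles(ch$profiles)
  plain <- comparison_grid(s, ch$subjects, grouping = "combined", timepoint = "pre")
  adj <- comparison_grid(s, ch$subjects, grouping = "combined", timepoint = "pre",
                         covariates = c("age", "sex"))
  expect_false(isTRUE(all.equal(plain$p_value, adj$p_value)))
  bh <- comparison_grid(s, ch$subjects, grouping = "combined", timepoint = "pre",
                        multiplicity = "BH")
  expect_identical(bh$p_value, plain$p_value)
  keep <- !is.na(bh$p_value)
  expect_identical(bh$p_adjusted[keep], p.adjust(bh$p_value[keep], "BH"))
  expect_true(all(bh$p_adjusted[keep] >= bh$p_value[keep]))
})
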
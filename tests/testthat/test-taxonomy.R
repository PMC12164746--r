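test_that("classify_global applies the 3-4 variable rule", {
  # FA .01, MD .04, Vol .03 significant; Fib .20 not
  g <- make_instance_grid(sig_global = c(TRUE, TRUE, TRUE, FALSE),
                          dir_global = c(-1, 1, -1, -1))
  lab <- classify_global(g)
  expect_equal(lab$category, "consistent-global")
  expect_equal(lab$variables, "FA,MD,Vol")
  expect_equal(lab$directions, "FA-,MD+,Vol-")

  expect_null(classify_global(make_instance_grid(
    sig_global = c(TRUE, TRUE, FALSE, FALSE))))

  all4 <- classify_global(make_instance_grid(sig_global = rep(TRUE, 4)))
  expect_equal(all4$n_variables, 4)

  expect_error(classify_global(make_instance_grid()[-1, ]), "incomplete")
})

test_that("classify_segmental applies the 2-3 variables / 1-4 segments rule", {
  sig <- matrix(FALSE, 3, 5)
  sig[1:2, 1:2] <- TRUE  # FA and MD in segments 1 and 2
  lab <- classify_segmental(make_instance_grid(sig_seg = sig))
  expect_equal(lab$category, "consistent-segmental")
  expect_equal(lab$segments, "1,2")
  expect_equal(lab$variables, "FA,MD")

  # all five segments abnormal: flagged whole-length, not consistent-segmental
  whole <- classify_segmental(make_instance_grid(sig_seg = matrix(TRUE, 3, 5)))
  expect_equal(whole$category, "whole-length-segmental")

  # a single significant variable in one segment is not enough
  one <- matrix(FALSE, 3, 5); one[1, 3] <- TRUE
  expect_null(classify_segmental(make_instance_grid(sig_seg = one)))
})

test_that("classifiers equal the brute-force rule evaluators on sampled patterns", {
  # exhaustive enumeration runs in the acceptance suite; spot-check here
  set.seed(60)
  for (i in 1:60) {
    sig4 <- runif(4) < 0.5
    lab <- classify_global(make_instance_grid(sig_global = sig4))
    expect_equal(!is.null(lab), global_rule_oracle(sig4))
    sigm <- matrix(runif(15) < 0.4, 3, 5)
    lab <- classify_segmental(make_instance_grid(sig_seg = sigm))
    want <- segmental_rule_oracle(sigm)
    expect_equal(!is.null(lab) && lab$category == "consistent-segmental",
                 want$fires)
    if (want$fires) {
      expect_equal(lab$segments, paste(want$segments, collapse = ","))
    }
  }
})

test_that("longitudinal rules label de novo and reinforced abnormalities", {
  pre0 <- make_instance_grid(timepoint = "pre")  # nothing significant
  post <- make_instance_grid(sig_global = c(FALSE, TRUE, TRUE, TRUE),
                             dir_global = c(1, 1, -1, -1), timepoint = "post")
  labs <- classify_longitudinal(pre0, post)
  expect_equal(labs$category, "de-novo-global")
  expect_equal(labs$variables, "MD,Vol,Fib")

  # same three variables significant pre and post with equal directions
  pre <- make_instance_grid(sig_global = c(TRUE, FALSE, TRUE, TRUE),
                            dir_global = c(-1, 1, -1, -1), timepoint = "pre")
  post2 <- make_instance_grid(sig_global = c(TRUE, FALSE, TRUE, TRUE),
                              dir_global = c(-1, 1, -1, -1), timepoint = "post")
  labs2 <- classify_longitudinal(pre, post2)
  expect_equal(labs2$category, "reinforced-global")
  expect_equal(labs2$variables, "FA,Vol,Fib")

  # direction flip breaks reinforcement
  flip <- make_instance_grid(sig_global = c(TRUE, FALSE, TRUE, TRUE),
                             dir_global = c(1, 1, -1, -1), timepoint = "post")
  expect_null(classify_longitudinal(pre, flip))

  # resolution (pre significant, post not) yields no label
  expect_null(classify_longitudinal(pre, pre0))

  # segmental de novo: two variables newly significant in segment 4
  sd <- matrix(FALSE, 3, 5); sd[2:3, 4] <- TRUE
  post3 <- make_instance_grid(sig_seg = sd, timepoint = "post")
  labs3 <- classify_longitudinal(pre0, post3)
  expect_equal(labs3$category, "de-novo-segmental")
  expect_equal(labs3$segments, "4")
})

test_that("identical pre and post grids reinforce and never create de novo labels", {
  set.seed(61)
  for (i in 1:20) {
    sig4 <- runif(4) < 0.5
    sigm <- matrix(runif(15) < 0.4, 3, 5)
    pre <- make_instance_grid(sig_global = sig4, sig_seg = sigm, timepoint = "pre")
    post <- make_instance_grid(sig_global = sig4, sig_seg = sigm, timepoint = "post")
    labs <- classify_longitudinal(pre, post)
    if (!is.null(labs)) {
      expect_false(any(grepl("de-novo", labs$category)))
      rg <- labs[labs$category == "reinforced-global", ]
      if (nrow(rg) == 1) {
        pre_lab <- classify_global(pre)
        expect_equal(rg$variables, pre_lab$variables)
      }
    }
  }
})

test_that("classify_abnormalities excludes skipped instances and lists them", {
  ch <- simulate_cohort(small_spec(seed = 62))
  prof <- ch$profiles
  prof$valid[prof$tract == "Un" & prof$side == "right"] <- FALSE
  s <- summarize_profiles(prof)
  g_pre <- comparison_grid(s, ch$subjects, "combined", "pre")
  g_post <- comparison_grid(s, ch$subjects, "combined", "post")
  labs <- classify_abnormalities(g_pre, g_post)
  ne <- attr(labs, "not_evaluable")
  expect_true("Un" %in% ne$tract)
  expect_false(any(labs$tract == "Un" & labs$laterality %in% c("ipsi", "contra")))
})

test_that("taxonomy_report tallies labels with zero-filled categories", {
  empty <- classify_abnormalities(
    comparison_grid(summarize_profiles(simulate_cohort(small_spec(63))$profiles),
                    simulate_cohort(small_spec(63))$subjects, "combined", "pre"))
  rep0 <- taxonomy_report(empty[0, ])
  expect_true(all(rep0$n == 0))
  expect_setequal(rep0$category, categories_taxonomy())

  labs <- tibble::tibble(
    cohort_scope = "patients-vs-control", tract = c("CH", "ILF"),
    laterality = "ipsi",
    category = c("consistent-global", "de-novo-segmental"),
    timepoint = c("pre", "post"), variables = c("FA,MD,Vol", "MD,Vol"),
    n_variables = c(3L, 2L), segments = c("", "2"), n_segments = c(0L, 1L),
    directions = c("FA-,MD+,Vol-", "MD+,Vol-")
  )
  rep1 <- taxonomy_report(labs)
  expect_equal(sum(rep1$n), 2L)
  expect_equal(rep1$n[rep1$category == "consistent-global"], 1L)
  pv <- taxonomy_report(labs, per_variable = TRUE)
  expect_equal(sum(pv$n[pv$category == "de-novo-segmental"]), 2L)
  expect_equal(sum(pv$n), 5L)
  # independent recount
  expect_equal(sum(rep1$n), nrow(labs))
})
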
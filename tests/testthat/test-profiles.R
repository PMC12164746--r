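test_that("resample_fiber places nodes at equal arc length", {
  straight <- tibble::tibble(x = 0, y = 0, z = c(0, 99))
  out <- resample_fiber(straight, 100)
  expect_equal(out$z, 0:99)
  expect_equal(out$x, rep(0, 100))

  # already equally spaced collinear points come back unchanged
  collinear <- tibble::tibble(x = seq(0, 9), y = 2 * seq(0, 9), z = 0)
  expect_equal(as.data.frame(resample_fiber(collinear, 10)),
               as.data.frame(collinear))

  # equal-spacing property: the nodes sit at equally spaced arc-length
  # coordinates of the input polyline
  set.seed(1)
  for (i in 1:10) {
    poly <- tibble::tibble(x = cumsum(runif(20)), y = cumsum(runif(20)),
                           z = cumsum(runif(20)))
    rs <- resample_fiber(poly, 37)
    xyz <- as.matrix(poly)
    pos <- apply(as.matrix(rs[, c("x", "y", "z")]), 1, arc_position, xyz = xyz)
    d <- diff(pos)
    expect_lt(diff(range(d)) / mean(d), 1e-9)
    expect_equal(unlist(rs[1, c("x", "y", "z")]),
                 unlist(poly[1, c("x", "y", "z")]), ignore_attr = TRUE)
    expect_equal(unlist(rs[37, c("x", "y", "z")]),
                 unlist(poly[20, c("x", "y", "z")]), ignore_attr = TRUE)
  }
})

test_that("resample_fiber matches a dense brute-force resampler on a quarter circle", {
  theta <- seq(0, pi / 2, length.out = 1000)
  qc <- cbind(x = 10 * cos(theta), y = 10 * sin(theta), z = 0)
  got <- resample_fiber(qc, 5)
  want <- resample_oracle(qc, 5)
  err <- sqrt(rowSums((as.matrix(got[, c("x", "y", "z")]) - want)^2))
  expect_lt(max(err), 0.01)
})

test_that("resample_fiber rejects degenerate fibers", {
  expect_error(resample_fiber(tibble::tibble(x = 1, y = 1, z = 1), 10),
               "degenerate")
  expect_error(resample_fiber(tibble::tibble(x = c(1, 1), y = 1, z = 1), 10),
               "degenerate")
})

test_that("profile_bundle aggregates fibers and counts voxels", {
  fib1 <- tibble::tibble(fiber = 1, x = 0.1, y = 0.1, z = seq(0, 99, length.out = 50),
                         FA = 0.5, MD = 0.8)
  bundle <- dplyr::bind_rows(fib1, dplyr::mutate(fib1, fiber = 2),
                             dplyr::mutate(fib1, fiber = 3))
  prof <- profile_bundle(bundle, n_nodes = 100, min_fibers = 2, voxel_size = 2)
  expect_equal(prof$FA, rep(0.5, 100))
  expect_equal(prof$MD, rep(0.8, 100))
  expect_true(all(prof$Fib == 3L))
  expect_true(all(prof$valid))

  # a single straight fiber crossing 100 distinct 2 mm voxels
  one <- tibble::tibble(fiber = 1, x = 0.1, y = 0.1, z = c(1, 199),
                        FA = 0.5, MD = 0.8)
  prof1 <- profile_bundle(one, n_nodes = 100, min_fibers = 1, voxel_size = 2)
  expect_equal(sum(prof1$Vol), 100 * 8)

  # below min_fibers: valid = FALSE, no error
  two <- dplyr::bind_rows(one, dplyr::mutate(one, fiber = 2, x = 0.3))
  prof2 <- profile_bundle(two, n_nodes = 100, min_fibers = 5)
  expect_false(any(prof2$valid))
})

test_that("profile_bundle is invariant to fiber ordering", {
  set.seed(4)
  mk <- function(id) tibble::tibble(
    fiber = id, x = cumsum(runif(30)), y = cumsum(runif(30)), z = cumsum(runif(30)),
    FA = runif(30, 0.3, 0.6), MD = runif(30, 0.6, 1))
  bundle <- dplyr::bind_rows(mk(1), mk(2), mk(3))
  shuffled <- bundle[sample(nrow(bundle)), ]
  shuffled <- dplyr::arrange(shuffled, fiber, x)  # restore within-fiber order
  a <- profile_bundle(dplyr::arrange(bundle, fiber, x), 20, 1)
  b <- profile_bundle(shuffled, 20, 1)
  expect_equal(a, b)
})

test_that("summarize_profiles computes segment and global means", {
  prof <- tibble::tibble(
    subject_id = "s1", timepoint = "pre", tract = "CH", side = "left",
    node = 1:100, FA = (1:100) / 200, MD = 1:100, Vol = 0.8,
    Fib = 42L, valid = TRUE
  )
  s <- summarize_profiles(prof)
  md <- s[s$variable == "MD", ]
  expect_equal(md$value[md$scope != "global"], c(10.5, 30.5, 50.5, 70.5, 90.5))
  expect_equal(md$value[md$scope == "global"], 50.5)
  vol <- s[s$variable == "Vol", ]
  expect_equal(vol$value, rep(0.8, nrow(vol)))
  expect_equal(s$value[s$variable == "Fib"], 42)
  expect_equal(sum(s$variable == "Fib"), 1)  # global only

  # mean of segment means equals the global mean exactly, for any profile
  ch <- simulate_cohort(small_spec(seed = 2))
  ss <- summarize_profiles(ch$profiles)
  wide <- ss |>
    dplyr::filter(variable != "Fib") |>
    dplyr::group_by(subject_id, timepoint, tract, side, variable) |>
    dplyr::summarise(glob = value[scope == "global"],
                     segmean = mean(value[scope != "global"]), .groups = "drop")
  expect_identical(wide$glob, wide$segmean)
})

test_that("summarize_profiles rejects non-divisible segmentations", {
  ch <- simulate_cohort(small_spec(seed = 2))
  expect_error(summarize_profiles(ch$profiles, n_segments = 3), "divisible")
})

test_that("laterality recoding follows the ictal onset zone and is idempotent", {
  ch <- simulate_cohort(small_spec(seed = 9, ioz_side_policy = "all-left"))
  s <- summarize_profiles(ch$profiles)
  pats <- ch$subjects$subject_id[ch$subjects$group != "control"]
  rec <- recode_laterality(s[s$subject_id %in% pats, ], ch$subjects)
  expect_setequal(unique(rec$laterality), c("ipsi", "contra", "midline"))
  expect_true(all(rec$laterality[rec$tract == "CFMe"] == "midline"))
  # left tracts of left-IOZ patients are ipsilateral, right ones contralateral
  sub <- s[s$subject_id %in% pats, ]
  expect_true(all(rec$laterality[sub$side == "left" & sub$tract != "CFMe"] == "ipsi"))
  expect_true(all(rec$laterality[sub$side == "right"] == "contra"))
  # numeric fields untouched; applying twice is a no-op
  expect_identical(rec$value, sub$value)
  rec2 <- recode_laterality(rec, ch$subjects)
  expect_identical(rec2$laterality, rec$laterality)
  expect_identical(rec2$value, rec$value)
})

test_that("recoding fails for patients without an IOZ side", {
  ch <- simulate_cohort(small_spec(seed = 9))
  subj <- ch$subjects
  subj$ioz_side[subj$group == "TLE"] <- "none"
  s <- summarize_profiles(ch$profiles)
  pats <- subj$subject_id[subj$group != "control"]
  expect_error(recode_laterality(s[s$subject_id %in% pats, ], subj), "data error")
})

test_that("control sides combine by pooling or subject means", {
  ch <- simulate_cohort(cohort_spec(n_controls = 19, n_fle = 2, n_tle = 2,
                                    n_operated_fle = 0, n_operated_tle = 0,
                                    seed = 10))
  s <- summarize_profiles(ch$profiles)
  ctrl <- s[s$subject_id %in% ch$subjects$subject_id[ch$subjects$group == "control"], ]

  pooled <- combine_control_sides(ctrl, ch$subjects, "pool")
  ilf_glob <- pooled[pooled$tract == "ILF" & pooled$variable == "FA" &
                       pooled$scope == "global", ]
  expect_equal(nrow(ilf_glob), 38)  # 19 controls x 2 sides
  expect_true(all(ilf_glob$laterality == "pooled-control"))

  avg <- combine_control_sides(ctrl, ch$subjects, "subject-mean")
  ilf_avg <- avg[avg$tract == "ILF" & avg$variable == "FA" & avg$scope == "global", ]
  expect_equal(nrow(ilf_avg), 19)
  one <- ctrl[ctrl$subject_id == "C001" & ctrl$tract == "ILF" &
                ctrl$variable == "FA" & ctrl$scope == "global", ]
  expect_equal(ilf_avg$value[ilf_avg$subject_id == "C001"], mean(one$value))

  # CFMe: exactly one observation per control under either policy
  for (res in list(pooled, avg)) {
    cf <- res[res$tract == "CFMe" & res$variable == "FA" & res$scope == "global", ]
    expect_equal(nrow(cf), 19)
    expect_true(all(cf$laterality == "midline"))
  }

  expect_error(combine_control_sides(s, ch$subjects, "pool"), "data error")
})

test_that("profile tables round-trip through CSV and validate on read", {
  ch <- simulate_cohort(small_spec(seed = 12))
  nodes_csv <- withr::local_tempfile(fileext = ".csv")
  tracts_csv <- withr::local_tempfile(fileext = ".csv")
  write_tract_profiles(ch$profiles, nodes_csv, tracts_csv)
  back <- read_tract_profiles(nodes_csv, tracts_csv)
  orig <- dplyr::arrange(ch$profiles, subject_id, timepoint,
                         factor(tract, levels = tract_names()), side, node)
  expect_equal(as.data.frame(back), as.data.frame(orig), tolerance = 1e-12)

  # a 99-node tract is reported with subject and tract named
  broken <- ch$profiles[!(ch$profiles$subject_id == "C001" &
                            ch$profiles$tract == "ILF" &
                            ch$profiles$side == "left" &
                            ch$profiles$node == 50), ]
  write_tract_profiles(broken, nodes_csv, tracts_csv)
  expect_error(read_tract_profiles(nodes_csv, tracts_csv), "C001/ILF")

  # FA out of range is rejected
  bad <- ch$profiles
  bad$FA[5] <- 1.7
  write_tract_profiles(bad, nodes_csv, tracts_csv)
  expect_error(read_tract_profiles(nodes_csv, tracts_csv), "FA outside")

  # header-only files give an empty table, not an error
  writeLines("subject_id,timepoint,tract,side,node,FA,MD,VOL", nodes_csv)
  writeLines("subject_id,timepoint,tract,side,FIB,valid", tracts_csv)
  empty <- read_tract_profiles(nodes_csv, tracts_csv)
  expect_equal(nrow(empty), 0)
})

test_that("bundles round-trip through JSON lines and profile correctly", {
  spec <- cohort_spec(n_controls = 2, n_fle = 2, n_tle = 2,
                      n_operated_fle = 0, n_operated_tle = 0, seed = 21,
                      fib_mean = 8, fib_size = 5)
  ch <- simulate_cohort(spec, output = "bundles")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_bundles_jsonl(ch$bundles, path)
  back <- read_bundles_jsonl(path)
  expect_equal(nrow(back), nrow(ch$bundles))
  expect_equal(back$FA, ch$bundles$FA)

  profs <- profile_bundles(ch$bundles, n_nodes = 100, min_fibers = 2,
                           voxel_size = 2)
  counts <- dplyr::count(profs, subject_id, timepoint, tract, side)
  expect_true(all(counts$n == 100))
  expect_true(all(profs$FA >= 0 & profs$FA <= 1))
  expect_true(all(profs$MD > 0))
  expect_true(all(profs$Vol >= 0))
})
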
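# Synthetic cohort generator: dose calibration, outcome model, gland
# phantoms, reproducibility.

test_that("dose draws hit the cohort quartile targets and bounds", {
  set.seed(41)
  par <- generate_doses(10000, list(median = 29.2, q1 = 14.6, q3 = 34.9))
  q <- quantile(par, c(0.25, 0.5, 0.75), names = FALSE)
  expect_lt(abs(q[2] - 29.2), 1.0)
  expect_lt(abs(q[1] - 14.6), 1.5)
  expect_lt(abs(q[3] - 34.9), 1.5)
  expect_true(all(par >= 0 & par <= 70))

  smg <- generate_doses(10000, list(median = 56.4, q1 = 47.2, q3 = 59.5))
  expect_lt(abs(median(smg) - 56.4), 1.0)
  expect_true(all(smg >= 0 & smg <= 70))
})

test_that("quantile calibration is exact at the anchor probabilities", {
  d <- calibrate_dose_distribution(29.2, 14.6, 34.9)
  expect_equal(d$quantile_fn(c(0.25, 0.5, 0.75)), c(14.6, 29.2, 34.9))
  expect_true(all(diff(d$quantile_fn(seq(0, 1, 0.01))) >= 0))
  expect_error(calibrate_dose_distribution(29.2, 34.9, 14.6))
})

test_that("the generative outcome model is calibrated and null-consistent", {
  set.seed(42)
  n <- 10000
  dose <- generate_doses(n, list(median = 29.2, q1 = 14.6, q3 = 34.9))
  tex <- rnorm(n)
  base <- generate_baseline_grades(n)
  out <- generate_outcomes(dose, tex, base,
                           list(b_dose = 0.08, b_texture = 0.6,
                                b_baseline = 0.5, prevalence = 0.48))
  expect_lt(abs(mean(out$indicator) - 0.48), 0.05)
  expect_equal(mean(out$prob), 0.48, tolerance = 1e-6)

  # all coefficients zero with a fixed zero intercept: a fair coin
  out0 <- generate_outcomes(dose, tex, base,
                            list(b_dose = 0, b_texture = 0,
                                 b_baseline = 0, prevalence = 0.5),
                            intercept = 0)
  expect_equal(unique(out0$prob), 0.5)
  expect_lt(abs(mean(out0$indicator) - 0.5), 0.02)
})

test_that("baseline grades match the moderate-to-severe target rate", {
  set.seed(43)
  g <- generate_baseline_grades(20000)
  expect_true(all(g %in% 1:4))
  expect_lt(abs(mean(g >= 3) - 0.06), 0.01)
})

test_that("cohort records are reproducible and internally consistent", {
  spec <- cohort_spec(n_patients = 200, seed = 99)
  rec <- generate_cohort_records(spec)
  tdir <- withr::local_tempdir()
  f1 <- file.path(tdir, "a.csv"); f2 <- file.path(tdir, "b.csv")
  write.csv(rec, f1, row.names = FALSE)
  write.csv(generate_cohort_records(spec), f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # endpoint indicator is the grade >= 3 rule
  expect_equal(rec$xer12m, as.integer(rec$xer_grade_12m >= 3))
  expect_equal(rec$ss12m, as.integer(rec$ss_grade_12m >= 3))
  expect_true(all(rec$mean_dose_cl_parotid_gy >= 0))
  # patients without any intact SMG carry no SMG features
  none <- !rec$smg_left_intact & !rec$smg_right_intact
  expect_true(all(is.na(rec$smg_maxhu[none])))
})

test_that("artifact and resection rates follow the spec knobs", {
  spec <- cohort_spec(n_patients = 109, seed = 7)
  rec <- generate_cohort_records(spec)
  truth <- attr(rec, "truth")
  expect_lt(abs(mean(truth$has_artifact) - 0.95), 0.07)  # binomial at n=109
  spec0 <- cohort_spec(n_patients = 60, seed = 8, smg_resection_prob = 0,
                       ipsi_parotid_resection_prob = 0)
  rec0 <- generate_cohort_records(spec0)
  expect_true(all(rec0$smg_left_intact & rec0$smg_right_intact &
                  rec0$ipsi_parotid_intact))
})

test_that("prevalence calibration holds at large n", {
  rec <- generate_cohort_records(cohort_spec(n_patients = 10000, seed = 11))
  expect_lt(abs(mean(rec$xer12m) - 0.48), 0.05)
  expect_lt(abs(mean(rec$ss12m) - 0.33), 0.05)
})

test_that("gland phantoms respect geometry and the texture knob", {
  expect_error(generate_gland_volume(dims = c(10L, 10L, 4L),
                                     semi_axes_mm = c(30, 30, 30)),
               "does not fit")
  # correlation-length limits: white noise is fine-textured, long
  # correlation near-homogeneous
  g_fine <- generate_gland_volume(corr_len = 0.1, seed = 12)
  g_smooth <- generate_gland_volume(corr_len = 3.5, seed = 12)
  sre_of <- function(g) {
    sel <- exclude_artifact_slices(g$volume, g$mask)
    texture_2d(discretise(g$volume, g$mask, sel), "sre")
  }
  s_fine <- sre_of(g_fine); s_smooth <- sre_of(g_smooth)
  expect_gt(s_fine, 0.55)
  expect_lt(s_smooth, 0.35)
  expect_gt(s_fine, s_smooth)
})

test_that("mean SRE decreases monotonically in correlation length", {
  grid <- c(0.3, 0.8, 1.6, 3.2)
  means <- sapply(seq_along(grid), function(i) {
    mean(sapply(1:6, function(r) {
      g <- generate_gland_volume(corr_len = grid[i], seed = 1000 * i + r)
      sel <- exclude_artifact_slices(g$volume, g$mask)
      texture_2d(discretise(g$volume, g$mask, sel), "sre")
    }))
  })
  expect_true(all(diff(means) < 0))
})

test_that("planted artifact slices round-trip through exclusion", {
  g <- generate_gland_volume(dims = c(30L, 30L, 10L),
                             semi_axes_mm = c(11, 11, 12),
                             artifact_slices = c(4L, 6L), seed = 13)
  sel <- exclude_artifact_slices(g$volume, g$mask)
  bearing <- mask_bearing_slices(g$mask)
  expect_identical(setdiff(bearing, sel$retained),
                   intersect(g$truth$artifact_slices, bearing))
})

test_that("imaging cohorts share the tabular generative core", {
  spec <- cohort_spec(n_patients = 4, seed = 14)
  coh <- generate_cohort(spec)
  rec <- generate_cohort_records(spec)
  shared <- c("patient_id", "mean_dose_cl_parotid_gy", "xer12m", "ss12m",
              "baseline_xer_grade", "smg_left_intact")
  expect_identical(coh$records[shared], rec[shared])
  # resected glands have no mask
  for (i in seq_len(4)) {
    expect_identical(is.null(coh$patients[[i]]$masks$smg_left),
                     !coh$records$smg_left_intact[i])
  }
  # artifact truth slices are really hot, and only those slices are
  for (i in seq_len(4)) {
    p <- coh$patients[[i]]
    hot <- which(apply(p$volume$voxels, 3, function(s) any(s > 2000)))
    expect_identical(hot, p$truth$artifact_slices)
  }
})
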
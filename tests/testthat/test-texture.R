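# GLCM/GLRLM construction, SRE and inverse difference moment, aggregation,
# 3D mode, and the per-patient feature vector.

test_that("hand-enumerated matrices on a 1x3 row of labels [1,1,2]", {
  roi <- roi_from_matrix(matrix(c(1L, 1L, 2L), 3, 1))
  g <- build_glcm(roi, 1L, c(1L, 0L))
  expect_equal(g$counts[1, 1], 2)
  expect_equal(g$counts[1, 2], 1)
  expect_equal(g$counts[2, 1], 1)
  expect_equal(glcm_probabilities(g)[1, 1], 0.5)
  r <- build_glrlm(roi, 1L, c(1L, 0L))
  expect_equal(r$counts[1, 2], 1)
  expect_equal(r$counts[2, 1], 1)
  expect_equal(r$n_runs, 2L)
  expect_equal(sre(r), (1 / 4 + 1) / 2)
})

test_that("homogeneous slices attain the analytic limits", {
  w <- 5L; h <- 4L
  roi <- roi_from_matrix(matrix(3L, w, h))
  g <- build_glcm(roi, 1L, c(1L, 0L))
  p <- glcm_probabilities(g)
  expect_equal(p[3, 3], 1)
  expect_equal(inverse_difference_moment(g), 1)
  r <- build_glrlm(roi, 1L, c(1L, 0L))
  expect_equal(sre(r), 1 / w^2)           # h identical runs of length w
  expect_equal(r$counts[3, w], h)
  expect_equal(r$n_runs, h)
  r2 <- build_glrlm(roi, 1L, c(0L, 1L))   # across: w runs of length h
  expect_equal(sre(r2), 1 / h^2)
})

test_that("alternating labels give SRE = 1 along the alternating axes", {
  cb <- (outer(1:6, 1:6, "+") %% 2L) + 1L
  roi <- roi_from_matrix(cb)
  expect_equal(sre(build_glrlm(roi, 1L, c(1L, 0L))), 1)
  expect_equal(sre(build_glrlm(roi, 1L, c(0L, 1L))), 1)
})

test_that("two-cell off-diagonal mass gives IDM = 0.5", {
  roi <- roi_from_matrix(matrix(c(1L, 2L), 2, 1))
  g <- build_glcm(roi, 1L, c(1L, 0L))
  p <- glcm_probabilities(g)
  expect_equal(p[1, 2], 0.5)
  expect_equal(p[2, 1], 0.5)
  expect_equal(inverse_difference_moment(g), 0.5)
})

test_that("degenerate slices yield flagged empty matrices", {
  one <- matrix(NA_integer_, 3, 3); one[2, 2] <- 5L
  roi <- roi_from_matrix(one)
  for (d in directions_2d()) {
    expect_equal(build_glcm(roi, 1L, d)$n_pairs, 0L)
    expect_equal(build_glrlm(roi, 1L, d)$n_runs, 0L)
    expect_true(is.na(sre(build_glrlm(roi, 1L, d))))
    expect_true(is.na(inverse_difference_moment(build_glcm(roi, 1L, d))))
  }
  expect_error(build_glcm(roi, 2L, c(1L, 0L)), "not retained")
  expect_error(build_glcm(roi, 1L, c(2L, 0L)), "direction")
})

test_that("matrices and features match brute-force oracles on random slices", {
  set.seed(101)
  for (rep in 1:30) {
    lab <- random_masked_slice()
    roi <- roi_from_matrix(lab)
    for (d in directions_2d()) {
      og <- oracle_glcm(lab, d)
      g <- build_glcm(roi, 1L, d)
      expect_equal(unname(g$counts), og)
      or <- oracle_glrlm(lab, d)
      r <- build_glrlm(roi, 1L, d)
      if (sum(og) > 0) {
        # adjacency exists: full run structure must match the scanner
        expect_same_counts(r$counts, or)
        expect_equal(sre(r), oracle_sre(or), tolerance = 1e-14)
        expect_equal(inverse_difference_moment(g), oracle_idm(og),
                     tolerance = 1e-14)
      } else {
        expect_equal(r$n_runs, 0L)   # degenerate direction, flagged empty
      }
    }
  }
})

test_that("every labelled voxel is covered exactly once by runs", {
  set.seed(55)
  for (rep in 1:10) {
    lab <- random_masked_slice()
    roi <- roi_from_matrix(lab)
    n_lab <- sum(!is.na(lab))
    if (n_lab < 2) next
    for (d in directions_2d()) {
      r <- build_glrlm(roi, 1L, d)
      if (r$n_runs == 0L) next
      covered <- sum(sweep(r$counts, 2L, seq_len(ncol(r$counts)), "*"))
      expect_equal(covered, n_lab)
    }
  }
})

test_that("run structure is invariant under label permutation", {
  set.seed(77)
  lab <- random_masked_slice(n_levels = 4L)
  perm <- sample(4L)
  lab_p <- lab
  lab_p[!is.na(lab)] <- perm[lab[!is.na(lab)]]
  for (d in directions_2d()) {
    a <- build_glrlm(roi_from_matrix(lab), 1L, d)
    b <- build_glrlm(roi_from_matrix(lab_p), 1L, d)
    expect_equal(sre(a), sre(b))
    nc <- max(ncol(a$counts), ncol(b$counts))
    expect_equal(colSums(pad_cols(a$counts, nc)),
                 colSums(pad_cols(b$counts, nc)))
  }
})

test_that("refining texture never decreases SRE", {
  rows <- list(rep(1L, 8), c(rep(1L, 4), rep(2L, 4)),
               rep(c(1L, 1L, 2L, 2L), 2), rep(c(1L, 2L), 4))
  vals <- vapply(rows, function(rr)
    sre(build_glrlm(roi_from_matrix(matrix(rr, 8, 1)), 1L, c(1L, 0L))),
    numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_equal(vals[1], 1 / 64)
  expect_equal(vals[4], 1)
})

test_that("aggregation averages non-empty fragments only", {
  expect_equal(aggregate_2d(c(0.7, 0.7, 0.7)), 0.7)
  expect_equal(aggregate_2d(c(0.2, 0.4, NA)), 0.3)
  expect_true(is.na(aggregate_2d(c(NA_real_, NA_real_))))
})

test_that("maxHU respects the mask and the slice exclusion", {
  vox <- array(40, c(4, 4, 2))
  vol <- ct_volume(vox)
  msk <- roi_mask(array(TRUE, c(4, 4, 2)))
  sel <- exclude_artifact_slices(vol, msk)
  expect_equal(max_hu(vol, msk, sel), 40)

  vox[2, 2, 1] <- 183
  vox[3, 3, 2] <- 3000          # artifact on slice 2 -> slice excluded
  vol2 <- ct_volume(vox)
  sel2 <- exclude_artifact_slices(vol2, msk)
  expect_equal(sel2$retained, 1L)
  expect_equal(max_hu(vol2, msk, sel2), 183)

  # oracle: list-scan over recorded in-mask retained voxels
  flags <- msk$flags; flags[, , 2] <- FALSE
  expect_equal(max_hu(vol2, msk, sel2), max(vox[flags]))
})

test_that("a single-slice gland reduces 3D to the in-plane average", {
  set.seed(9)
  lab <- random_masked_slice(n = 10L, p_mask = 0.9)
  roi2 <- roi_from_matrix(lab)
  roi3 <- roi_from_array(array(lab, c(dim(lab), 1L)))
  for (f in c("sre", "idm"))
    expect_equal(texture_3d(roi3, f), texture_2d(roi2, f), tolerance = 1e-14)
})

test_that("homogeneous cube: axial direction contributes 1/w^2", {
  w <- 5L
  a <- array(7L, c(w, w, w))
  m <- radsaliva:::.glrlm_counts(a, c(1L, 0L, 0L), 16L)
  expect_equal(sre(m), 1 / w^2)
  expect_equal(m$n_runs, w * w)
})

test_that("3D matrices match a 13-direction brute-force scanner", {
  set.seed(202)
  a <- array(sample.int(3L, 6 * 6 * 6, replace = TRUE), c(6, 6, 6))
  a[runif(length(a)) > 0.85] <- NA_integer_
  roi <- roi_from_array(a)
  sre_dirs <- numeric(0)
  for (d in directions_3d()) {
    og <- oracle_glcm(a, d)
    g <- radsaliva:::.glcm_counts(a, d, 16L)
    expect_equal(unname(g$counts), og)
    or <- oracle_glrlm(a, d)
    r <- radsaliva:::.glrlm_counts(a, d, 16L)
    if (sum(og) > 0) {
      expect_same_counts(r$counts, or)
      sre_dirs <- c(sre_dirs, oracle_sre(or))
    } else {
      expect_equal(r$n_runs, 0L)
      sre_dirs <- c(sre_dirs, NA_real_)
    }
  }
  expect_equal(texture_3d(roi, "sre"), mean(sre_dirs, na.rm = TRUE),
               tolerance = 1e-14)
  expect_length(directions_3d(), 13L)
})

test_that("feature vector flags missingness and computes 3D when clean", {
  g <- generate_gland_volume(dims = c(24L, 24L, 8L),
                             semi_axes_mm = c(9, 9, 7), corr_len = 1,
                             seed = 21)
  row <- feature_vector(g$volume, list(cl_parotid = g$mask), id = "p1")
  expect_false(is.na(row$cl_parotid_sre_2d))
  expect_false(is.na(row$cl_parotid_sre_3d))   # artifact-free
  expect_equal(row$cl_parotid_excluded_fraction, 0)

  # artifact every mask-bearing slice: features missing, not zero
  vox <- g$volume$voxels
  for (k in mask_bearing_slices(g$mask)) vox[1, 1, k] <- 3000
  row2 <- feature_vector(ct_volume(vox, g$volume$spacing),
                         list(cl_parotid = g$mask), id = "p1")
  expect_true(is.na(row2$cl_parotid_sre_2d))
  expect_true(is.na(row2$cl_parotid_maxhu))
  expect_equal(row2$cl_parotid_excluded_fraction, 1)

  # absent (resected) gland
  row3 <- feature_vector(g$volume,
                         list(cl_parotid = g$mask, smg_left = NULL),
                         id = "p1")
  expect_true(is.na(row3$smg_left_sre_2d))
  expect_false(is.na(row3$cl_parotid_sre_2d))
})
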
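# Synthetic cohort generator: CT volumes with textured ellipsoidal salivary
# glands and planted metal-artifact streaks, dose metrics matching the study
# cohort's marginals, baseline and 12-month toxicity with a known logistic
# generative model. Every stage records its ground truth so the whole
# pipeline is testable without any clinical download.

# -- dose distribution -------------------------------------------------------
# Mean gland doses in the emulated cohort are strongly left-skewed (sparing
# tail): the population quartiles are matched exactly by construction, via a
# monotone quantile function anchored at the target quartiles.

#' Calibrate a quantile-matched dose distribution
#'
#' Builds a smooth, bounded dose distribution whose population quartiles
#' equal the requested median and inter-quartile bounds exactly: a monotone
#' (Hyman) cubic interpolant of the quantile function through the anchor
#' points (0, lower tail), (0.25, q1), (0.5, median), (0.75, q3),
#' (1, upper tail), with tails extended by three inter-quartile ranges and
#' clipped to `[lower, upper]` Gy. Sample quartiles converge to the targets
#' as n grows, and every draw lies inside the bounds.
#'
#' @param median,q1,q3 target median and quartiles in Gy (must satisfy
#'   `q1 < median < q3`).
#' @param lower,upper support bounds in Gy.
#' @return list with `quantile_fn` (function of p in \[0, 1\]), `lower`,
#'   `upper` and the anchor points.
#' @export
calibrate_dose_distribution <- function(median, q1, q3,
                                        lower = 0, upper = 70) {
  stopifnot(q1 < median, median < q3, lower < q1, q3 < upper)
  iqr <- q3 - q1
  knots_p <- c(0, 0.25, 0.5, 0.75, 1)
  knots_q <- c(max(lower, q1 - 3 * iqr), q1, median, q3,
               min(upper, q3 + 3 * iqr))
  qf <- stats::splinefun(knots_p, knots_q, method = "hyman")
  list(quantile_fn = function(p) pmin(pmax(qf(p), lower), upper),
       lower = lower, upper = upper,
       knots_p = knots_p, knots_q = knots_q)
}

#' Draw mean gland doses
#'
#' Samples from the quantile-matched dose distribution by inverse CDF, so
#' the sample median and quartiles approach the targets as n grows and every
#' draw lies inside the support bounds.
#'
#' @param n number of draws.
#' @param targets list with `median`, `q1`, `q3` and optional `lower`,
#'   `upper` (Gy).
#' @return numeric vector of doses in Gy.
#' @export
generate_doses <- function(n, targets) {
  d <- calibrate_dose_distribution(targets$median, targets$q1, targets$q3,
                                   lower = if (is.null(targets$lower)) 0
                                           else targets$lower,
                                   upper = if (is.null(targets$upper)) 70
                                           else targets$upper)
  d$quantile_fn(stats::runif(n))
}

# -- cohort specification ----------------------------------------------------

#' Synthetic cohort specification
#'
#' Full parameterisation of the generator. Defaults emulate the study
#' conditions: 109 head-and-neck patients, contra-lateral parotid mean dose
#' median 29.2 Gy (IQR 14.6-34.9), bilateral submandibular mean dose median
#' 56.4 Gy (IQR 47.2-59.5), 12-month endpoint prevalences ~48 % (xerostomia)
#' and ~33 % (sticky saliva), ~6 % moderate-to-severe baseline symptoms,
#' metal-artifact slices in ~95 % of patients, and 1.074 x 1.074 x 3.0 mm
#' voxels.
#'
#' @param n_patients cohort size.
#' @param seed master seed; all randomness (including per-patient volume
#'   seeds) derives from it.
#' @param parotid_dose,smg_dose target dose quantiles (Gy), see
#'   [generate_doses()].
#' @param artifact_prob_patient probability a patient carries any dental
#'   implant slice.
#' @param artifact_prob_slice per-slice artifact probability among
#'   gland-bearing slices of an affected patient.
#' @param smg_resection_prob per-gland probability a submandibular gland is
#'   absent (resected).
#' @param ipsi_parotid_resection_prob probability the ipsilateral parotid is
#'   absent (the contra-lateral parotid is an inclusion criterion and is
#'   always present).
#' @param baseline_grade_probs probabilities of baseline EORTC grades 1-4
#'   (defaults give ~6 % moderate-to-severe, grade >= 3).
#' @param xer_coefs,ss_coefs generative logistic coefficients: `b_dose`
#'   (per Gy), `b_texture` (per SD of the latent texture score),
#'   `b_baseline` (per baseline grade), `prevalence` (target endpoint rate
#'   used to calibrate the intercept).
#' @param texture_link parameters of the monotone map from the standard
#'   normal latent texture score to the in-plane correlation length (voxels):
#'   `log_mid`, `slope`, `min`, `max`. Higher score, shorter correlation,
#'   higher SRE.
#' @param measurement_noise sd of the noise added to simulated (tabular)
#'   feature measurements, on the latent scale.
#' @param spacing voxel size in mm.
#' @param volume_dim CT grid size per patient (voxels).
#' @return object of class `cohort_spec` (a named list).
#' @export
cohort_spec <- function(n_patients = 109,
                        seed = 1L,
                        parotid_dose = list(median = 29.2, q1 = 14.6,
                                            q3 = 34.9, lower = 0, upper = 70),
                        smg_dose = list(median = 56.4, q1 = 47.2,
                                        q3 = 59.5, lower = 0, upper = 70),
                        artifact_prob_patient = 0.95,
                        artifact_prob_slice = 0.35,
                        smg_resection_prob = 0.12,
                        ipsi_parotid_resection_prob = 0.04,
                        baseline_grade_probs = c(0.72, 0.22, 0.05, 0.01),
                        xer_coefs = list(b_dose = 0.08, b_texture = 0.6,
                                         b_baseline = 0.5, prevalence = 0.48),
                        ss_coefs = list(b_dose = 0.08, b_texture = 0.6,
                                        b_baseline = 0.5, prevalence = 0.33),
                        texture_link = list(log_mid = 0.35, slope = 0.4,
                                            min = 0.2, max = 4),
                        measurement_noise = 0.3,
                        spacing = c(1.074, 1.074, 3.0),
                        volume_dim = c(56L, 56L, 16L)) {
  stopifnot(n_patients >= 2,
            artifact_prob_patient >= 0, artifact_prob_patient <= 1,
            artifact_prob_slice >= 0, artifact_prob_slice <= 1,
            smg_resection_prob >= 0, smg_resection_prob <= 1,
            all(spacing > 0),
            abs(sum(baseline_grade_probs) - 1) < 1e-8)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Draw baseline EORTC grades
#' @param n number of patients.
#' @param probs probabilities of grades 1-4.
#' @return integer grades in 1..4.
#' @export
generate_baseline_grades <- function(n, probs = c(0.72, 0.22, 0.05, 0.01)) {
  sample.int(4L, n, replace = TRUE, prob = probs)
}

#' Calibrate a generative intercept to a target prevalence
#'
#' Finds `b0` so that `mean(plogis(b0 + lp))` equals the target endpoint
#' prevalence over the supplied linear-predictor sample.
#'
#' @param lp numeric linear predictor without intercept.
#' @param target target prevalence in (0, 1).
#' @return the intercept (numeric scalar).
#' @export
calibrate_intercept <- function(lp, target) {
  stopifnot(target > 0, target < 1, length(lp) >= 2)
  stats::uniroot(function(b0) mean(stats::plogis(b0 + lp)) - target,
                 c(-50, 50), tol = 1e-10)$root
}

#' Draw binary toxicity endpoints from the generative logistic model
#'
#' `P(endpoint) = plogis(b0 + b_dose * dose + b_texture * texture_z +
#' b_baseline * baseline)`. When `intercept` is `NULL` it is calibrated on
#' the realised linear predictors so the cohort prevalence matches
#' `coefs$prevalence` in expectation.
#'
#' @param dose mean gland dose (Gy).
#' @param texture_z latent texture score (standard-normal scale).
#' @param baseline baseline grade (numeric 1-4).
#' @param coefs list `b_dose`, `b_texture`, `b_baseline`, `prevalence`.
#' @param intercept fixed intercept, or `NULL` to calibrate.
#' @return list `indicator` (0/1), `prob`, `intercept`, `lp`.
#' @export
generate_outcomes <- function(dose, texture_z, baseline, coefs,
                              intercept = NULL) {
  stopifnot(all(is.finite(c(coefs$b_dose, coefs$b_texture, coefs$b_baseline))))
  lp <- coefs$b_dose * dose + coefs$b_texture * texture_z +
        coefs$b_baseline * baseline
  b0 <- if (is.null(intercept)) calibrate_intercept(lp, coefs$prevalence)
        else intercept
  prob <- stats::plogis(b0 + lp)
  list(indicator = stats::rbinom(length(prob), 1L, prob),
       prob = prob, intercept = b0, lp = lp)
}

.texture_corr_len <- function(texture_z, link) {
  pmin(pmax(exp(link$log_mid - link$slope * texture_z), link$min), link$max)
}

# endpoint indicator -> a 12-month grade consistent with grade >= 3
.grade_from_indicator <- function(ind) {
  ifelse(ind == 1L,
         2L + stats::rbinom(length(ind), 1L, 0.25) + 1L,  # 3 or 4
         1L + stats::rbinom(length(ind), 1L, 0.4))        # 1 or 2
}

# -- correlated Gaussian texture field ---------------------------------------

.gaussian_kernel <- function(sigma) {
  if (sigma <= 0.05) return(1)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

# 1D convolution along one axis of a 3D array, edge-renormalised.
.conv1 <- function(a, k, axis) {
  if (length(k) == 1L) return(a)
  r <- (length(k) - 1L) / 2L
  dims <- dim(a)
  out <- array(0, dims)
  wt <- array(0, dims)
  n <- dims[axis]
  for (o in -r:r) {
    w <- k[o + r + 1L]
    src <- seq_len(n)
    src <- src[src + o >= 1L & src + o <= n]
    dst <- src + o
    ia_src <- ia_dst <- rep(list(quote(expr = )), 3L)
    ia_src[[axis]] <- src
    ia_dst[[axis]] <- dst
    slab <- do.call(`[`, c(list(a), ia_src, list(drop = FALSE)))
    tmp <- do.call(`[`, c(list(out), ia_dst, list(drop = FALSE))) + w * slab
    out <- do.call(`[<-`, c(list(out), ia_dst, list(value = tmp)))
    wslab <- do.call(`[`, c(list(wt), ia_dst, list(drop = FALSE))) + w
    wt <- do.call(`[<-`, c(list(wt), ia_dst, list(value = wslab)))
  }
  out / wt
}

# Stationary correlated Gaussian field: white noise smoothed with a
# separable Gaussian kernel (sd = corr_len voxels in-plane; the axial sd is
# scaled by the spacing ratio so correlation is near-isotropic in mm), then
# standardised to zero mean, unit sd.
.correlated_field <- function(dims, corr_len, spacing) {
  f <- array(stats::rnorm(prod(dims)), dims)
  sz <- corr_len * spacing[1] / spacing[3]
  f <- .conv1(f, .gaussian_kernel(corr_len), 1L)
  f <- .conv1(f, .gaussian_kernel(corr_len), 2L)
  f <- .conv1(f, .gaussian_kernel(sz), 3L)
  (f - mean(f)) / stats::sd(f)
}

.ellipsoid_mask <- function(dims, spacing, center_mm, semi_axes_mm) {
  xs <- (seq_len(dims[1]) - 0.5) * spacing[1]
  ys <- (seq_len(dims[2]) - 0.5) * spacing[2]
  zs <- (seq_len(dims[3]) - 0.5) * spacing[3]
  dx2 <- ((xs - center_mm[1]) / semi_axes_mm[1])^2
  dy2 <- ((ys - center_mm[2]) / semi_axes_mm[2])^2
  dz2 <- ((zs - center_mm[3]) / semi_axes_mm[3])^2
  q <- outer(outer(dx2, dy2, "+"), dz2, "+")
  q <= 1
}

#' Generate a single textured gland phantom
#'
#' An ellipsoidal gland in a soft-tissue background volume. In-gland HU are
#' drawn from a stationary correlated Gaussian field (mean `mean_hu`, sd
#' `sd_hu`) whose in-plane correlation length (in voxels) controls the
#' run-length structure -- short correlation gives fine texture (high SRE),
#' long correlation a near-homogeneous gland (low SRE). Metal-artifact
#' slices, if requested, overwrite an in-plane streak with 3000 HU on the
#' recorded slice set.
#'
#' @param dims volume grid size (voxels).
#' @param spacing voxel size in mm.
#' @param center_mm gland centre in mm (default: volume centre).
#' @param semi_axes_mm ellipsoid semi-axes in mm (default 14, 11, 12: a
#'   ~20-30 mm gland).
#' @param mean_hu,sd_hu in-gland intensity mean and sd (HU).
#' @param corr_len in-plane correlation length in voxels.
#' @param artifact_slices axial indices to artifact (default none).
#' @param gland gland label for the mask.
#' @param seed optional seed (`set.seed` is called when non-NULL).
#' @return list `volume` (`ct_volume`), `mask` (`roi_mask`), `truth` (list
#'   `artifact_slices`, `corr_len`).
#' @export
generate_gland_volume <- function(dims = c(40L, 40L, 14L),
                                  spacing = c(1.074, 1.074, 3.0),
                                  center_mm = NULL,
                                  semi_axes_mm = c(14, 11, 12),
                                  mean_hu = 30, sd_hu = 20,
                                  corr_len = 1.5,
                                  artifact_slices = integer(0),
                                  gland = "cl_parotid",
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  extent_mm <- dims * spacing
  if (is.null(center_mm)) center_mm <- extent_mm / 2
  if (any(center_mm - semi_axes_mm < 0) ||
      any(center_mm + semi_axes_mm > extent_mm))
    stop("gland does not fit in volume", call. = FALSE)
  flags <- .ellipsoid_mask(dims, spacing, center_mm, semi_axes_mm)
  vox <- array(stats::rnorm(prod(dims), 0, 5), dims)
  field <- .correlated_field(dims, corr_len, spacing)
  vox[flags] <- mean_hu + sd_hu * field[flags]
  for (k in artifact_slices) vox[, ceiling(dims[2] / 2), k] <- 3000
  vox <- pmin(pmax(vox, -1024), 3071)
  list(volume = ct_volume(vox, spacing),
       mask = roi_mask(flags, gland = gland),
       truth = list(artifact_slices = as.integer(artifact_slices),
                    corr_len = corr_len))
}

# One patient's CT: contra-lateral parotid plus (optionally) two SMGs, with
# artifacts planted on a recorded slice set drawn from the gland-bearing
# slices.
.simulate_patient_volume <- function(spec, seed, t_parotid, t_smg_texture,
                                     m_smg, has_artifact,
                                     smg_left_present, smg_right_present) {
  set.seed(seed)
  dims <- spec$volume_dim
  spacing <- spec$spacing
  link <- spec$texture_link
  vox <- array(stats::rnorm(prod(dims), 0, 5), dims)

  glands <- list()
  geo <- list(
    cl_parotid = list(center_vox = c(16, 38, 9),
                      semi = c(stats::runif(1, 11, 16),
                               stats::runif(1, 9, 13),
                               stats::runif(1, 9, 15)),
                      mean_hu = 30,
                      corr = .texture_corr_len(t_parotid, link)),
    smg_left = list(center_vox = c(38, 16, 6),
                    semi = c(stats::runif(1, 8, 12),
                             stats::runif(1, 8, 11),
                             stats::runif(1, 5, 8)),
                    mean_hu = 30 + 8 * m_smg,
                    corr = .texture_corr_len(t_smg_texture, link)),
    smg_right = list(center_vox = c(38, 42, 6),
                     semi = c(stats::runif(1, 8, 12),
                              stats::runif(1, 8, 11),
                              stats::runif(1, 5, 8)),
                     mean_hu = 30 + 8 * m_smg,
                     corr = .texture_corr_len(t_smg_texture, link))
  )
  present <- c(cl_parotid = TRUE, smg_left = smg_left_present,
               smg_right = smg_right_present)
  masks <- list()
  for (g in names(geo)) {
    if (!present[[g]]) { masks[g] <- list(NULL); next }
    gg <- geo[[g]]
    center_mm <- gg$center_vox * spacing
    flags <- .ellipsoid_mask(dims, spacing, center_mm, gg$semi)
    field <- .correlated_field(dims, gg$corr, spacing)
    vox[flags] <- gg$mean_hu + 20 * field[flags]
    masks[[g]] <- roi_mask(flags, gland = g)
  }
  bearing <- sort(unique(unlist(lapply(masks[!vapply(masks, is.null,
                                                     logical(1))],
                                       mask_bearing_slices))))
  artifact_slices <- integer(0)
  if (has_artifact && length(bearing)) {
    hit <- bearing[stats::runif(length(bearing)) < spec$artifact_prob_slice]
    if (length(hit) == 0L) hit <- sample(bearing, 1L)
    artifact_slices <- sort(hit)
    for (k in artifact_slices)
      vox[, ceiling(dims[2] / 2) + (-1:0), k] <- 3000
  }
  vox <- pmin(pmax(vox, -1024), 3071)
  list(volume = ct_volume(vox, spacing), masks = masks,
       truth = list(artifact_slices = artifact_slices,
                    corr_len_parotid = geo$cl_parotid$corr,
                    corr_len_smg = geo$smg_left$corr))
}

# Shared tabular generative core. A single set.seed(spec$seed) drives every
# draw in a fixed order, so records and imaging cohorts built from the same
# spec share doses, baselines, latents and outcomes.
.generate_base <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  set.seed(spec$seed)
  patient_id <- sprintf("pt%04d", seq_len(n))
  dose_parotid <- generate_doses(n, spec$parotid_dose)
  dose_smg <- generate_doses(n, spec$smg_dose)
  baseline_xer <- generate_baseline_grades(n, spec$baseline_grade_probs)
  baseline_ss <- generate_baseline_grades(n, spec$baseline_grade_probs)
  t_parotid <- stats::rnorm(n)       # latent parotid texture score
  t_smg_texture <- stats::rnorm(n)   # latent SMG texture score
  m_smg <- stats::rnorm(n)           # latent SMG peak-intensity score
  has_artifact <- stats::rbinom(n, 1L, spec$artifact_prob_patient) == 1L
  smg_left_intact <- stats::rbinom(n, 1L, 1 - spec$smg_resection_prob) == 1L
  smg_right_intact <- stats::rbinom(n, 1L, 1 - spec$smg_resection_prob) == 1L
  ipsi_parotid_intact <-
    stats::rbinom(n, 1L, 1 - spec$ipsi_parotid_resection_prob) == 1L
  prescription_gy <- sample(c(50, 55, 60, 65, 70), n, replace = TRUE,
                            prob = c(1, 1, 24, 80, 3) / 109)
  n_fractions <- c(`50` = 20L, `55` = 20L, `60` = 30L, `65` = 30L,
                   `70` = 35L)[as.character(prescription_gy)]
  xer <- generate_outcomes(dose_parotid, t_parotid, baseline_xer,
                           spec$xer_coefs)
  ss <- generate_outcomes(dose_smg, m_smg, baseline_ss, spec$ss_coefs)
  xer_grade_12m <- .grade_from_indicator(xer$indicator)
  ss_grade_12m <- .grade_from_indicator(ss$indicator)
  # tabular stand-ins for measured features (imaging mode overwrites these
  # with values extracted from the phantom volumes)
  noise <- spec$measurement_noise
  meas <- data.frame(
    cl_parotid_sre_2d = 0.55 + 0.06 * (t_parotid + stats::rnorm(n, 0, noise)),
    cl_parotid_idm_2d = 0.55 - 0.05 * (t_parotid + stats::rnorm(n, 0, noise)),
    cl_parotid_maxhu = 85 + 8 * t_parotid + stats::rnorm(n, 0, 6),
    smg_sre_2d = 0.55 + 0.06 * (t_smg_texture + stats::rnorm(n, 0, noise)),
    smg_maxhu = 95 + 14 * m_smg + stats::rnorm(n, 0, 14 * noise)
  )
  meas$smg_sre_2d[!smg_left_intact & !smg_right_intact] <- NA_real_
  meas$smg_maxhu[!smg_left_intact & !smg_right_intact] <- NA_real_
  n_parotid_slices <- sample(9:12, n, replace = TRUE)
  n_excluded <- ifelse(has_artifact,
                       pmax(1L, stats::rbinom(n, n_parotid_slices,
                                              spec$artifact_prob_slice)),
                       0L)
  meas$cl_parotid_excluded_fraction <- n_excluded / n_parotid_slices
  meas$cl_parotid_sre_3d <- ifelse(n_excluded == 0L,
                                   meas$cl_parotid_sre_2d +
                                     stats::rnorm(n, 0, 0.01),
                                   NA_real_)
  patient_seeds <- sample.int(.Machine$integer.max - 1L, n)
  records <- data.frame(
    patient_id = patient_id,
    prescription_gy = prescription_gy,
    n_fractions = n_fractions,
    mean_dose_cl_parotid_gy = dose_parotid,
    mean_dose_bilateral_smg_gy = dose_smg,
    baseline_xer_grade = baseline_xer,
    baseline_ss_grade = baseline_ss,
    xer_grade_12m = xer_grade_12m,
    ss_grade_12m = ss_grade_12m,
    xer12m = xer$indicator,
    ss12m = ss$indicator,
    smg_left_intact = smg_left_intact,
    smg_right_intact = smg_right_intact,
    ipsi_parotid_intact = ipsi_parotid_intact,
    stringsAsFactors = FALSE
  )
  truth <- list(
    t_parotid = t_parotid, t_smg_texture = t_smg_texture, m_smg = m_smg,
    has_artifact = has_artifact,
    xer_prob = xer$prob, ss_prob = ss$prob,
    xer_intercept = xer$intercept, ss_intercept = ss$intercept,
    patient_seeds = patient_seeds
  )
  list(records = records, measurements = meas, truth = truth)
}

#' Generate synthetic patient records (tabular mode)
#'
#' The clinical table plus simulated feature measurements, without building
#' CT volumes -- the fast path for statistical calibration studies (null
#' rejection rates, parameter recovery, prevalence checks) where the imaging
#' chain is not under test. Feature stand-ins are noisy monotone transforms
#' of the same latent scores that drive the outcomes, so effect sizes carry
#' through exactly as in imaging mode.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame of one row per patient; ground truth in
#'   `attr(, "truth")`.
#' @export
generate_cohort_records <- function(spec) {
  base <- .generate_base(spec)
  out <- cbind(base$records, base$measurements)
  attr(out, "truth") <- base$truth
  out
}

#' Generate a complete synthetic cohort with CT volumes
#'
#' Builds every patient's CT volume with textured gland masks and planted
#' artifact streaks, alongside the clinical records. Fully reproducible
#' under the spec's seed: each patient's volume is generated from a derived
#' per-patient seed.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `synthetic_cohort`: `records` (clinical
#'   data.frame, no feature columns -- those come from extraction),
#'   `patients` (named list of `volume`, `masks`, `truth`), `truth`
#'   (cohort-level ground truth), `spec`.
#' @export
generate_cohort <- function(spec) {
  base <- .generate_base(spec)
  n <- spec$n_patients
  patients <- vector("list", n)
  names(patients) <- base$records$patient_id
  for (i in seq_len(n)) {
    patients[[i]] <- .simulate_patient_volume(
      spec, base$truth$patient_seeds[i],
      t_parotid = base$truth$t_parotid[i],
      t_smg_texture = base$truth$t_smg_texture[i],
      m_smg = base$truth$m_smg[i],
      has_artifact = base$truth$has_artifact[i],
      smg_left_present = base$records$smg_left_intact[i],
      smg_right_present = base$records$smg_right_intact[i])
  }
  structure(list(records = base$records, patients = patients,
                 truth = base$truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, seed %d\n",
              nrow(x$records), x$spec$seed))
  invisible(x)
}

#' Write a synthetic cohort in the pipeline's input formats
#'
#' NIfTI-1 volume and mask files per patient, the clinical CSV, and a
#' ground-truth JSON (for tests only, not consumed by the analysis).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pid in names(cohort$patients)) {
    p <- cohort$patients[[pid]]
    write_nifti_volume(p$volume, file.path(dir, paste0(pid, "_ct.nii.gz")))
    for (g in names(p$masks)) {
      if (is.null(p$masks[[g]])) next
      write_nifti_volume(p$masks[[g]],
                         file.path(dir, paste0(pid, "_mask_", g, ".nii.gz")),
                         spacing = p$volume$spacing)
    }
  }
  utils::write.csv(cohort$records, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  truth <- cohort$truth
  truth$per_patient_artifact_slices <-
    lapply(cohort$patients, function(p) p$truth$artifact_slices)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding `clinical.csv` and per-patient NIfTI files.
#' @return object of class `synthetic_cohort` (without generator ground
#'   truth).
#' @export
read_cohort <- function(dir) {
  records <- utils::read.csv(file.path(dir, "clinical.csv"),
                             stringsAsFactors = FALSE)
  patients <- list()
  for (pid in records$patient_id) {
    vol <- read_ct_volume(file.path(dir, paste0(pid, "_ct.nii.gz")))
    masks <- list()
    for (g in c("cl_parotid", "smg_left", "smg_right")) {
      path <- file.path(dir, paste0(pid, "_mask_", g, ".nii.gz"))
      m <- if (file.exists(path)) read_roi_mask(path, gland = g) else NULL
      masks[g] <- list(m)
    }
    patients[[pid]] <- list(volume = vol, masks = masks, truth = NULL)
  }
  structure(list(records = records, patients = patients, truth = NULL,
                 spec = NULL),
            class = "synthetic_cohort")
}
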
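# Grey-level co-occurrence and run-length matrices on masked, discretised
# regions; Short Run Emphasis and inverse difference moment; 2D slice-wise
# computation with averaging over all (slice, direction) fragments, and a
# reference 3D 13-direction mode for artifact-free glands.
#
# Directions are integer lattice offsets. Runs and co-occurrence pairs never
# cross the mask boundary or an excluded slice: unlabelled (NA) voxels break
# them.

#' In-plane GLCM/GLRLM directions
#'
#' The four unique 2D offsets (0°, 45°, 90°, 135°) as (dx, dy) pairs.
#' @return list of integer length-2 vectors.
#' @export
directions_2d <- function() {
  list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))
}

#' 3D GLCM/GLRLM directions
#'
#' The 13 unique offsets (up to sign) of the 26-connected neighbourhood.
#' @return list of integer length-3 vectors.
#' @export
directions_3d <- function() {
  dirs <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    d <- c(dx, dy, dz)
    if (all(d == 0L)) next
    # keep one representative per +/- pair: first non-zero component positive
    nz <- d[d != 0L][1]
    if (nz > 0L) dirs[[length(dirs) + 1L]] <- as.integer(d)
  }
  dirs
}

# -- matrix builders ---------------------------------------------------------

# one axial slice as a 2D matrix (degenerate extents preserved)
.slice_matrix <- function(roi, k) {
  array(roi$labels[, , k], dim(roi$labels)[1:2])
}

# Symmetric co-occurrence counts of labelled voxels at offset d, over a 2D
# matrix or 3D array of labels (NA = unlabelled). Both orderings of each pair
# are accumulated (IBSI symmetric convention).
.glcm_counts <- function(lab, d, n_bins) {
  dims <- dim(lab)
  pos <- which(!is.na(lab))
  if (length(pos) < 2L)
    return(structure(list(counts = matrix(0, n_bins, n_bins), n_pairs = 0L,
                          n_bins = n_bins), class = "glcm_matrix"))
  co <- arrayInd(pos, dims)
  nb <- sweep(co, 2L, as.integer(d), "+")
  ok <- rep(TRUE, nrow(nb))
  for (a in seq_along(dims)) ok <- ok & nb[, a] >= 1L & nb[, a] <= dims[a]
  if (!any(ok))
    return(structure(list(counts = matrix(0, n_bins, n_bins), n_pairs = 0L,
                          n_bins = n_bins), class = "glcm_matrix"))
  co <- co[ok, , drop = FALSE]
  nb <- nb[ok, , drop = FALSE]
  mult <- c(1, cumprod(dims)[-length(dims)])
  nb_lin <- as.vector((nb - 1L) %*% mult) + 1L
  i <- lab[pos[ok]]
  j <- lab[nb_lin]
  keep <- !is.na(j)
  i <- i[keep]; j <- j[keep]
  cnt <- matrix(tabulate((j - 1L) * n_bins + i, nbins = n_bins * n_bins),
                n_bins, n_bins)
  cnt <- cnt + t(cnt)
  structure(list(counts = cnt, n_pairs = sum(cnt), n_bins = n_bins),
            class = "glcm_matrix")
}

# Run-length counts along offset d. A run is a maximal collinear sequence of
# equal labels; broken by NA voxels, the mask/grid boundary, or label change.
.glrlm_counts <- function(lab, d, n_bins) {
  dims <- dim(lab)
  pos <- which(!is.na(lab))
  empty <- structure(list(counts = matrix(0, n_bins, 1L), n_runs = 0L,
                          n_bins = n_bins), class = "glrlm_matrix")
  if (length(pos) < 2L) return(empty)
  co <- arrayInd(pos, dims)
  labs <- lab[pos]
  a <- which(d != 0L)[1]
  t <- co[, a] / d[a]                   # advances by +1 per step along d
  start <- co - outer(t, as.integer(d)) # constant along each lattice line
  ord <- do.call(order, c(lapply(seq_len(ncol(start)), function(k) start[, k]),
                          list(t)))
  st <- start[ord, , drop = FALSE]
  tt <- t[ord]
  ll <- labs[ord]
  n <- length(ll)
  same_line <- rowSums(abs(st[-1, , drop = FALSE] -
                           st[-n, , drop = FALSE])) == 0
  contiguous <- diff(tt) == 1
  # degenerate direction: no two labelled voxels are collinear-adjacent, so
  # every run would be a trivial singleton; flag empty so aggregation skips
  if (!any(same_line & contiguous)) return(empty)
  same_label <- diff(ll) == 0
  new_run <- c(TRUE, !(same_line & contiguous & same_label))
  run_id <- cumsum(new_run)
  len <- tabulate(run_id)
  run_lab <- ll[new_run]
  l_max <- max(len)
  cnt <- matrix(tabulate((len - 1L) * n_bins + run_lab, nbins = n_bins * l_max),
                n_bins, l_max)
  structure(list(counts = cnt, n_runs = sum(cnt), n_bins = n_bins),
            class = "glrlm_matrix")
}

#' Grey-level co-occurrence matrix of one slice
#'
#' Counts ordered pairs of labelled voxels separated by the in-plane offset
#' `direction`, accumulated symmetrically (both orderings). Pairs that cross
#' the mask boundary are skipped. A slice with fewer than two labelled voxels
#' yields an empty matrix (`n_pairs = 0`) so aggregation can skip it.
#'
#' @param roi a `discretised_roi`.
#' @param slice_index axial slice index; must be in `roi$retained`.
#' @param direction one of [directions_2d()].
#' @return A `glcm_matrix`: `counts` (n_bins x n_bins), `n_pairs`, `n_bins`.
#' @export
build_glcm <- function(roi, slice_index, direction) {
  stopifnot(inherits(roi, "discretised_roi"))
  if (!slice_index %in% roi$retained)
    stop("slice ", slice_index, " is not retained", call. = FALSE)
  .check_direction_2d(direction)
  .glcm_counts(.slice_matrix(roi, slice_index), direction, roi$n_bins)
}

#' Grey-level run-length matrix of one slice
#'
#' A run is a maximal collinear sequence of equal labels along `direction`;
#' runs are broken by the mask boundary, the slice boundary, and label
#' changes, so every labelled voxel belongs to exactly one run per direction.
#' A slice in which no two labelled voxels are collinear-adjacent along the
#' direction carries no run-length information and yields an empty, flagged
#' matrix (this is what reduces the 3D mode to its in-plane directions on a
#' single-slice region).
#'
#' @inheritParams build_glcm
#' @return A `glrlm_matrix`: `counts` (n_bins x Lmax), `n_runs`, `n_bins`.
#' @export
build_glrlm <- function(roi, slice_index, direction) {
  stopifnot(inherits(roi, "discretised_roi"))
  if (!slice_index %in% roi$retained)
    stop("slice ", slice_index, " is not retained", call. = FALSE)
  .check_direction_2d(direction)
  .glrlm_counts(.slice_matrix(roi, slice_index), direction, roi$n_bins)
}

.check_direction_2d <- function(direction) {
  ok <- any(vapply(directions_2d(), identical, logical(1),
                   as.integer(direction)))
  if (!ok) stop("direction must be one of (1,0), (1,1), (0,1), (-1,1)",
                call. = FALSE)
}

#' Normalised co-occurrence probabilities
#' @param m a `glcm_matrix`.
#' @return matrix p(i, j) summing to 1, or all-zero if the matrix is empty.
#' @export
glcm_probabilities <- function(m) {
  stopifnot(inherits(m, "glcm_matrix"))
  if (m$n_pairs == 0L) return(m$counts)
  m$counts / sum(m$counts)
}

# -- scalar features ---------------------------------------------------------

#' Short Run Emphasis
#'
#' `SRE = (1 / Nr) * sum_{i,j} r(i, j) / j^2` over a run-length matrix with
#' `Nr` runs. Lies in (0, 1]; equals 1 iff every run has length 1 (fine
#' texture); a homogeneous region of width w in the run direction gives
#' 1 / w^2.
#'
#' @param m a `glrlm_matrix`.
#' @return numeric SRE, or `NA_real_` for an empty matrix.
#' @export
sre <- function(m) {
  stopifnot(inherits(m, "glrlm_matrix"))
  if (m$n_runs == 0L) return(NA_real_)
  lens <- seq_len(ncol(m$counts))
  sum(colSums(m$counts) / lens^2) / m$n_runs
}

#' Inverse difference moment
#'
#' `IDM = sum_{i,j} p(i, j) / (1 + (i - j)^2)` over normalised co-occurrence
#' probabilities. Lies in (0, 1]; equals 1 for a homogeneous region (all
#' mass on the diagonal). This is the co-occurrence homogeneity measure in
#' the IBSI nomenclature.
#'
#' @param m a `glcm_matrix`.
#' @return numeric IDM, or `NA_real_` for an empty matrix.
#' @export
inverse_difference_moment <- function(m) {
  stopifnot(inherits(m, "glcm_matrix"))
  if (m$n_pairs == 0L) return(NA_real_)
  p <- glcm_probabilities(m)
  idx <- seq_len(m$n_bins)
  w <- 1 / (1 + outer(idx, idx, "-")^2)
  sum(p * w)
}

#' Maximum CT intensity over the retained region of interest
#'
#' Maximum raw (unclamped) HU over in-mask voxels on retained slices.
#' Excluded slices never contribute.
#'
#' @param volume a `ct_volume`.
#' @param mask an `roi_mask`.
#' @param selection a `slice_selection`.
#' @return maximum HU (numeric).
#' @export
max_hu <- function(volume, mask, selection) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "roi_mask"),
            inherits(selection, "slice_selection"))
  if (length(selection$retained) == 0L)
    stop("empty slice selection", call. = FALSE)
  flags <- mask$flags
  drop <- setdiff(seq_len(dim(flags)[3]), selection$retained)
  if (length(drop)) flags[, , drop] <- FALSE
  if (!any(flags)) stop("no in-mask voxels on retained slices", call. = FALSE)
  max(volume$voxels[flags])
}

#' Average feature fragments over (slice, direction) pairs
#'
#' Unweighted arithmetic mean over all non-empty fragments; empty fragments
#' (`NA`) are excluded from both numerator and denominator. This is the
#' slice-then-direction averaging used for 2D texture aggregation.
#'
#' @param values numeric vector of per-(slice, direction) feature values,
#'   `NA` marking empty fragments.
#' @return the mean, or `NA_real_` when every fragment is empty (feature
#'   undefined for that patient/gland).
#' @export
aggregate_2d <- function(values) {
  if (all(is.na(values))) return(NA_real_)
  mean(values, na.rm = TRUE)
}

#' Feature registry
#'
#' Named descriptors of the texture features the package computes; each entry
#' pairs a matrix builder with a scalar summary so new features can be added
#' without touching the extraction loop.
#' @return named list with elements `matrix` ("glrlm"/"glcm") and `fn`.
#' @export
feature_registry <- function() {
  list(
    sre = list(matrix = "glrlm", fn = sre),
    idm = list(matrix = "glcm", fn = inverse_difference_moment)
  )
}

#' 2D slice-wise texture feature
#'
#' Computes the requested matrix feature on every retained slice in each of
#' the four in-plane directions and averages over all non-empty
#' (slice, direction) fragments.
#'
#' @param roi a `discretised_roi`.
#' @param feature `"sre"` or `"idm"` (or any [feature_registry()] key).
#' @param return_fragments if `TRUE`, also return the per-fragment values.
#' @return the aggregated value (numeric), or, with `return_fragments`, a
#'   list `value`, `fragments` (data.frame slice/direction/value).
#' @export
texture_2d <- function(roi, feature = c("sre", "idm"),
                       return_fragments = FALSE) {
  stopifnot(inherits(roi, "discretised_roi"))
  feature <- match.arg(feature, names(feature_registry()))
  reg <- feature_registry()[[feature]]
  dirs <- directions_2d()
  vals <- numeric(0)
  frag <- list()
  for (k in roi$retained) {
    slab <- .slice_matrix(roi, k)
    for (di in seq_along(dirs)) {
      m <- if (reg$matrix == "glrlm")
        .glrlm_counts(slab, dirs[[di]], roi$n_bins)
      else
        .glcm_counts(slab, dirs[[di]], roi$n_bins)
      v <- reg$fn(m)
      vals <- c(vals, v)
      if (return_fragments)
        frag[[length(frag) + 1L]] <- data.frame(slice = k, direction = di,
                                                value = v)
    }
  }
  out <- aggregate_2d(vals)
  if (return_fragments)
    list(value = out, fragments = do.call(rbind, frag))
  else out
}

#' 3D texture feature over the full gland
#'
#' Reference mode for artifact-free glands: one matrix per 3D direction is
#' accumulated over the whole labelled volume (13 unique directions of the
#' 26-connected neighbourhood), the scalar feature is evaluated per
#' direction, and directions are averaged with the same skip-empty rule as
#' the 2D mode. A single-slice gland reduces to the four in-plane
#' directions; the nine out-of-plane directions are empty and skipped.
#'
#' @param roi a `discretised_roi` built with every mask-bearing slice
#'   retained (no exclusion: 3D runs must not jump artifacted gaps).
#' @param feature `"sre"` or `"idm"`.
#' @return the direction-averaged value (numeric), `NA_real_` if all
#'   directions are empty.
#' @export
texture_3d <- function(roi, feature = c("sre", "idm")) {
  stopifnot(inherits(roi, "discretised_roi"))
  feature <- match.arg(feature, names(feature_registry()))
  reg <- feature_registry()[[feature]]
  vals <- vapply(directions_3d(), function(d) {
    m <- if (reg$matrix == "glrlm") .glrlm_counts(roi$labels, d, roi$n_bins)
         else .glcm_counts(roi$labels, d, roi$n_bins)
    reg$fn(m)
  }, numeric(1))
  aggregate_2d(vals)
}

#' Per-patient radiomics feature vector
#'
#' Applies artifact exclusion, discretisation and feature computation to each
#' available gland mask and returns one row of the feature table. For each
#' gland the 2D-averaged SRE and inverse difference moment and the raw-HU
#' maximum are emitted; glands with no artifacted slice additionally get the
#' 3D SRE. A gland whose slices are all artifacted (or whose mask is absent,
#' e.g. resected) yields `NA` features -- missing, never zero-filled.
#'
#' @param volume a `ct_volume`.
#' @param masks named list of `roi_mask` objects (absent glands: `NULL`).
#' @param hu_threshold artifact threshold passed to
#'   [exclude_artifact_slices()].
#' @param id optional patient id stored in the row.
#' @return one-row data.frame with, per gland `<g>`: `<g>_sre_2d`,
#'   `<g>_idm_2d`, `<g>_maxhu`, `<g>_excluded_fraction`, and `<g>_sre_3d`
#'   (parotid, artifact-free only).
#' @export
feature_vector <- function(volume, masks, hu_threshold = 2000, id = NULL) {
  row <- list(patient_id = if (is.null(id)) NA_character_ else id)
  for (g in names(masks)) {
    msk <- masks[[g]]
    cols <- paste0(g, c("_sre_2d", "_idm_2d", "_maxhu", "_sre_3d",
                        "_excluded_fraction"))
    if (is.null(msk)) {
      row[cols] <- list(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_)
      next
    }
    sel <- tryCatch(exclude_artifact_slices(volume, msk, hu_threshold),
                    radsaliva_empty_roi = function(e) NULL)
    if (is.null(sel)) {
      row[cols] <- list(NA_real_, NA_real_, NA_real_, NA_real_, 1)
      next
    }
    droi <- discretise(volume, msk, sel)
    row[[cols[1]]] <- texture_2d(droi, "sre")
    row[[cols[2]]] <- texture_2d(droi, "idm")
    row[[cols[3]]] <- max_hu(volume, msk, sel)
    row[[cols[5]]] <- sel$excluded_fraction
    if (sel$excluded_fraction == 0) {
      full <- structure(list(retained = mask_bearing_slices(msk),
                             excluded_fraction = 0,
                             n_bearing = sel$n_bearing),
                        class = "slice_selection")
      droi3 <- discretise(volume, msk, full)
      row[[cols[4]]] <- texture_3d(droi3, "sre")
    } else {
      row[[cols[4]]] <- NA_real_
    }
  }
  as.data.frame(row, stringsAsFactors = FALSE)
}
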
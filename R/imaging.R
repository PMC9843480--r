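# Volume/mask containers, artifact slice exclusion, intensity discretisation.
# Conventions: arrays are indexed [x, y, z]; the third array axis is axial
# (superior-inferior); volumes and masks live on the same voxel grid (no
# resampling).

#' CT volume container
#'
#' Wraps a 3D grid of Hounsfield units together with its physical voxel
#' spacing. The third array axis is the axial (slice) axis.
#'
#' @param voxels 3D numeric array of Hounsfield units, in \[-1024, 3071\].
#' @param spacing numeric length-3, voxel size in mm along (x, y, z); all > 0.
#' @return An object of class `ct_volume` with elements `voxels` and
#'   `spacing`.
#' @examples
#' vol <- ct_volume(array(0, c(4, 4, 3)))
#' dim(vol$voxels)
#' @export
ct_volume <- function(voxels, spacing = c(1.074, 1.074, 3.0)) {
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel sizes in mm", call. = FALSE)
  rng <- range(voxels, na.rm = TRUE)
  if (rng[1] < -1024 || rng[2] > 3071)
    stop("Hounsfield units must lie in [-1024, 3071]; got range [",
         rng[1], ", ", rng[2], "]", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3f x %.3f x %.3f mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Region-of-interest mask for a salivary gland
#'
#' A binary mask on the same voxel grid as its `ct_volume`.
#'
#' @param flags 3D logical (or 0/1) array; must contain at least one `TRUE`.
#' @param gland gland label, e.g. `"cl_parotid"`, `"smg_left"`, `"smg_right"`.
#' @param volume optional `ct_volume` to validate the shape against.
#' @return An object of class `roi_mask` with elements `flags` and `gland`.
#' @export
roi_mask <- function(flags, gland = "cl_parotid", volume = NULL) {
  if (length(dim(flags)) != 3L)
    stop("`flags` must be a 3D array", call. = FALSE)
  flags <- array(as.logical(flags), dim(flags))
  if (anyNA(flags)) stop("mask flags must be 0/1 without NA", call. = FALSE)
  if (!any(flags)) stop("mask contains no voxels", call. = FALSE)
  if (!is.null(volume) && !identical(dim(flags), dim(volume$voxels)))
    stop("mask shape does not match its volume", call. = FALSE)
  structure(list(flags = flags, gland = gland), class = "roi_mask")
}

#' Axial slices carrying at least one mask voxel
#'
#' @param mask an `roi_mask`.
#' @return Integer vector of slice indices (third-axis indices) on which the
#'   mask has at least one `TRUE` voxel.
#' @export
mask_bearing_slices <- function(mask) {
  which(apply(mask$flags, 3L, any))
}

#' Exclude axial slices affected by metal artifacts
#'
#' A slice is excluded when any voxel on it -- anywhere in-plane, not only
#' inside the mask -- exceeds `hu_threshold`. Dental implants produce streaks
#' far above bone density, so a threshold well above bone (default 2000 HU)
#' flags implant slices while leaving calcifications untouched. Only
#' mask-bearing slices enter the retained set and the excluded fraction.
#'
#' @param volume a `ct_volume`.
#' @param mask an `roi_mask` on the same grid.
#' @param hu_threshold HU above which a voxel marks its slice as artifacted;
#'   must be > 200 (above the discretisation range).
#' @return An object of class `slice_selection`: `retained` (integer slice
#'   indices), `excluded_fraction` (share of mask-bearing slices removed),
#'   `n_bearing`.
#' @section Errors: if every mask-bearing slice is artifacted a condition of
#'   class `radsaliva_empty_roi` is signalled; callers drop the patient from
#'   the affected feature computation.
#' @examples
#' vox <- array(0, c(4, 4, 3)); vox[2, 2, 2] <- 3000
#' m <- array(FALSE, c(4, 4, 3)); m[2:3, 2:3, 1:3] <- TRUE
#' sel <- exclude_artifact_slices(ct_volume(vox), roi_mask(m))
#' sel$retained            # slice 2 dropped
#' @export
exclude_artifact_slices <- function(volume, mask, hu_threshold = 2000) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(mask$flags), dim(volume$voxels)))
    stop("mask shape does not match its volume", call. = FALSE)
  if (hu_threshold <= 200)
    stop("`hu_threshold` must exceed 200 HU", call. = FALSE)
  bearing <- mask_bearing_slices(mask)
  hot <- which(apply(volume$voxels, 3L, function(s) any(s > hu_threshold)))
  retained <- setdiff(bearing, hot)
  if (length(retained) == 0L)
    stop(errorCondition(
      paste0("empty ROI after exclusion: all ", length(bearing),
             " mask-bearing slices of gland '", mask$gland, "' are artifacted"),
      class = c("radsaliva_empty_roi", "error", "condition")))
  structure(list(retained = retained,
                 excluded_fraction = 1 - length(retained) / length(bearing),
                 n_bearing = length(bearing)),
            class = "slice_selection")
}

#' Discretise in-mask intensities into fixed-width HU bins
#'
#' Voxel intensities inside the mask, on retained slices only, are clamped
#' into `range` and binned at `bin_width` HU: label
#' `floor((HU - range[1]) / bin_width) + 1`, left-closed/right-open bins with
#' the top bin right-closed (HU = 200 maps to bin 16 at the defaults).
#' Out-of-range values are clamped into the boundary bins rather than
#' dropped. Out-of-mask and excluded-slice voxels carry no label (`NA`).
#'
#' @param volume a `ct_volume`.
#' @param mask an `roi_mask` on the same grid.
#' @param selection a `slice_selection` (from [exclude_artifact_slices()]).
#' @param bin_width bin width in HU (default 25).
#' @param range HU range (default c(-200, 200)); must be an integer multiple
#'   of `bin_width` wide.
#' @return An object of class `discretised_roi`: `labels` (3D integer array,
#'   `NA` off-mask/off-selection), `n_bins`, `retained`.
#' @examples
#' vox <- array(0, c(3, 3, 2))
#' m <- array(TRUE, c(3, 3, 2))
#' vol <- ct_volume(vox); msk <- roi_mask(m)
#' sel <- exclude_artifact_slices(vol, msk)
#' d <- discretise(vol, msk, sel)
#' unique(as.vector(d$labels[!is.na(d$labels)]))  # 0 HU -> bin 9
#' @export
discretise <- function(volume, mask, selection,
                       bin_width = 25, range = c(-200, 200)) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "roi_mask"),
            inherits(selection, "slice_selection"))
  if (length(selection$retained) == 0L)
    stop("empty slice selection", call. = FALSE)
  width <- range[2] - range[1]
  n_bins <- width / bin_width
  if (n_bins != round(n_bins) || n_bins < 1)
    stop("`range` must span an integer number of bins", call. = FALSE)
  n_bins <- as.integer(round(n_bins))
  sel_flags <- mask$flags
  drop <- setdiff(seq_len(dim(sel_flags)[3]), selection$retained)
  if (length(drop)) sel_flags[, , drop] <- FALSE
  labels <- array(NA_integer_, dim(sel_flags))
  hu <- pmin(pmax(volume$voxels[sel_flags], range[1]), range[2])
  labels[sel_flags] <- pmin(as.integer(floor((hu - range[1]) / bin_width)) + 1L,
                            n_bins)
  structure(list(labels = labels, n_bins = n_bins,
                 retained = selection$retained),
            class = "discretised_roi")
}

#' Per-patient slice-exclusion report
#'
#' @param selections named list (patient id) of named lists (gland) of
#'   `slice_selection` objects or `NULL` (gland fully artifacted/absent).
#' @param n_bearing named list mirroring `selections` giving the count of
#'   mask-bearing slices for glands whose selection is `NULL` (optional).
#' @return data.frame with columns `patient_id`, `gland`, `n_slices`,
#'   `n_excluded`, `excluded_fraction`.
#' @export
slice_exclusion_report <- function(selections, n_bearing = NULL) {
  rows <- list()
  for (pid in names(selections)) {
    for (gl in names(selections[[pid]])) {
      sel <- selections[[pid]][[gl]]
      if (is.null(sel)) {
        nb <- if (!is.null(n_bearing)) n_bearing[[pid]][[gl]] else NA_integer_
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid, gland = gl, n_slices = nb,
          n_excluded = nb, excluded_fraction = 1)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid, gland = gl, n_slices = sel$n_bearing,
          n_excluded = sel$n_bearing - length(sel$retained),
          excluded_fraction = sel$excluded_fraction)
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write a volume or mask to NIfTI-1
#'
#' @param x a `ct_volume` or `roi_mask`.
#' @param path output `.nii` / `.nii.gz` path.
#' @param spacing voxel spacing in mm, used for masks (volumes carry their
#'   own).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path, spacing = c(1.074, 1.074, 3.0)) {
  if (inherits(x, "ct_volume")) {
    arr <- x$voxels
    spacing <- x$spacing
  } else if (inherits(x, "roi_mask")) {
    arr <- array(as.integer(x$flags), dim(x$flags))
  } else stop("unsupported object", call. = FALSE)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a CT volume from NIfTI-1
#' @param path `.nii` / `.nii.gz` file.
#' @return a `ct_volume`.
#' @export
read_ct_volume <- function(path) {
  img <- RNifti::readNifti(path)
  ct_volume(array(as.numeric(img), dim(img)), spacing = RNifti::pixdim(img)[1:3])
}

#' Read an ROI mask from NIfTI-1
#' @param path `.nii` / `.nii.gz` file holding a 0/1 volume.
#' @param gland gland label to attach.
#' @return an `roi_mask`.
#' @export
read_roi_mask <- function(path, gland = "cl_parotid") {
  img <- RNifti::readNifti(path)
  roi_mask(array(as.numeric(img) > 0.5, dim(img)), gland = gland)
}
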
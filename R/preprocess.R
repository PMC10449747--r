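# Dataset-level MIP crop-box computation, cropping, percentile normalization.

#' Construct a crop box
#'
#' @param start integer length-3 vector of 1-based start indices.
#' @param size integer length-3 vector of extents (> 0).
#' @return An object of class `crop_box`.
#' @export
crop_box <- function(start, size) {
  start <- as.integer(start); size <- as.integer(size)
  if (length(start) != 3L || length(size) != 3L)
    stop("crop_box: start and size must have length 3")
  if (any(start < 1L)) stop("crop_box: start must be >= 1 on every axis")
  if (any(size < 1L)) stop("crop_box: size must be positive on every axis")
  structure(list(start = start, size = size), class = "crop_box")
}

#' @export
print.crop_box <- function(x, ...) {
  cat(sprintf("<crop_box> start (%s), size (%s)\n",
              paste(x$start, collapse = ", "), paste(x$size, collapse = ", ")))
  invisible(x)
}

#' Maximum intensity projection over a cohort
#'
#' Elementwise maximum across every selected channel of every case:
#' the dataset-wide MIP used to derive a single crop box that retains all
#' informative voxels for every case.
#'
#' @param cohort list of [case_bundle] objects sharing one grid shape.
#' @param channels channel names to include; default: all channels of the
#'   first case.
#' @return A [volume_grid] of the same shape.
#' @export
dataset_mip <- function(cohort, channels = NULL) {
  if (length(cohort) == 0L) stop("dataset_mip: empty cohort")
  if (is.null(channels)) channels <- names(cohort[[1L]]$channels)
  shp <- dim(cohort[[1L]]$channels[[1L]])
  acc <- array(-Inf, dim = shp)
  for (case in cohort) {
    for (ch in channels) {
      vol <- case$channels[[ch]]
      if (is.null(vol)) stop("dataset_mip: case ", case$case_id,
                             " lacks channel ", ch)
      if (!identical(dim(vol), shp))
        stop("dataset_mip: shape mismatch at case ", case$case_id)
      acc <- pmax(acc, vol$data)
    }
  }
  volume_grid(acc, cohort[[1L]]$channels[[1L]]$spacing)
}

#' Derive a crop box from a MIP volume
#'
#' Finds the tight bounding box of voxels strictly above `threshold` and,
#' when `target_size` is given, expands it symmetrically to exactly that
#' size (odd leftovers go to the lower-index side), clamped to the grid.
#'
#' @param mip a [volume_grid], typically from [dataset_mip()].
#' @param target_size optional length-3 integer extents; the BraTS-scale
#'   convention is `c(160, 216, 128)` for 240 x 240 x 155 inputs.
#' @param threshold intensity cutoff defining foreground (default 0).
#' @return A [crop_box].
#' @export
crop_box_from_mip <- function(mip, target_size = NULL, threshold = 0) {
  stopifnot(is_volume_grid(mip))
  fg <- which(mip$data > threshold, arr.ind = TRUE)
  if (nrow(fg) == 0L)
    stop("crop_box_from_mip: no voxel exceeds the threshold (empty foreground)")
  lo <- apply(fg, 2L, min)
  hi <- apply(fg, 2L, max)
  tight <- hi - lo + 1L
  shp <- dim(mip$data)
  if (is.null(target_size)) return(crop_box(lo, tight))
  target_size <- as.integer(target_size)
  if (length(target_size) != 3L) stop("crop_box_from_mip: target_size must have length 3")
  if (any(target_size > shp))
    stop("crop_box_from_mip: target_size exceeds the grid")
  if (any(tight > target_size))
    stop(sprintf("crop_box_from_mip: tight box (%s) exceeds target size (%s)",
                 paste(tight, collapse = "x"), paste(target_size, collapse = "x")))
  extra <- target_size - tight
  start <- lo - ceiling(extra / 2)          # odd leftover goes to the low side
  start <- pmax(1L, pmin(as.integer(start), shp - target_size + 1L))
  crop_box(start, target_size)
}

#' Crop a volume to a box
#'
#' @param volume a [volume_grid].
#' @param box a [crop_box] valid for the volume's shape.
#' @return A [volume_grid] of shape `box$size`; spacing unchanged.
#' @export
apply_crop <- function(volume, box) {
  stopifnot(is_volume_grid(volume), inherits(box, "crop_box"))
  shp <- dim(volume$data)
  end <- box$start + box$size - 1L
  if (any(end > shp))
    stop("apply_crop: crop box out of bounds for this volume")
  out <- volume$data[box$start[1L]:end[1L],
                     box$start[2L]:end[2L],
                     box$start[3L]:end[3L], drop = FALSE]
  volume_grid(out, volume$spacing)
}

#' Percentile intensity normalization
#'
#' Scales a volume into [0, 1] by dividing by the given percentile of its
#' strictly positive voxels and clipping: the high percentile damps
#' outlier voxels, and restricting to positive voxels keeps the
#' background (which dominates brain volumes) from dragging the divisor
#' toward zero. Quantiles use the linear-interpolation convention
#' (`stats::quantile` type 7). A volume with no positive voxel is
#' returned clipped but otherwise untouched.
#'
#' @param volume a finite [volume_grid].
#' @param probs percentile used as divisor, default 0.98.
#' @param positive_only compute the percentile over strictly positive
#'   voxels only (default TRUE).
#' @return A [volume_grid] with all values in [0, 1].
#' @export
normalize_p98 <- function(volume, probs = 0.98, positive_only = TRUE) {
  stopifnot(is_volume_grid(volume))
  v <- volume$data
  pool <- if (positive_only) v[v > 0] else as.vector(v)
  p <- if (length(pool)) stats::quantile(pool, probs, names = FALSE, type = 7) else 1
  if (!is.finite(p) || p <= 0) p <- 1
  out <- pmin(pmax(v / p, 0), 1)
  volume_grid(array(out, dim = dim(v)), volume$spacing)
}

#' Preprocess a cohort: MIP crop box, crop, normalize
#'
#' Computes one dataset-wide crop box from the cohort MIP, then crops
#' every channel and truth mask and percentile-normalizes the channels.
#' Truth masks are cropped but never normalized.
#'
#' @param cohort list of [case_bundle] objects.
#' @param target_size optional crop target extents (see
#'   [crop_box_from_mip()]); `NULL` uses the tight MIP bounding box.
#' @param threshold MIP foreground threshold.
#' @param probs normalization percentile.
#' @param channels channels used for the MIP; default all.
#' @return List with `cohort` (preprocessed bundles) and `box` (the
#'   [crop_box] applied).
#' @export
preprocess_cohort <- function(cohort, target_size = NULL, threshold = 0,
                              probs = 0.98, channels = NULL) {
  mip <- dataset_mip(cohort, channels)
  box <- crop_box_from_mip(mip, target_size = target_size, threshold = threshold)
  out <- lapply(cohort, function(case) {
    chans <- lapply(case$channels,
                    function(v) normalize_p98(apply_crop(v, box), probs = probs))
    truth <- if (!is.null(case$truth_mask)) apply_crop(case$truth_mask, box) else NULL
    case_bundle(case$case_id, chans, truth_mask = truth,
                multilabel = case$multilabel)
  })
  list(cohort = out, box = box)
}
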
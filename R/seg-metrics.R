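# Per-case and cohort-level segmentation overlap and distance metrics.

# Coerce a volume_grid / array / logical to a logical 3-D mask.
as_mask <- function(x) {
  if (is_volume_grid(x)) x <- x$data
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("expected a 3-D mask (volume_grid or array)")
  x != 0
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("mask shape mismatch: %s vs %s",
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
}

#' Dice similarity coefficient
#'
#' `2|P intersect T| / (|P| + |T|)` on voxel counts. When both masks are
#' empty the score is 1 (perfect agreement on absence); when exactly one
#' is empty it is 0.
#'
#' @param pred,truth binary masks ([volume_grid] or 3-D arrays) of equal
#'   shape; any nonzero voxel counts as foreground.
#' @return Dice score in [0, 1].
#' @export
dice <- function(pred, truth) {
  p <- as_mask(pred); t <- as_mask(truth)
  check_same_shape(p, t)
  np <- sum(p); nt <- sum(t)
  if (np + nt == 0L) return(1)
  2 * sum(p & t) / (np + nt)
}

#' Jaccard similarity coefficient
#'
#' `|P intersect T| / |P union T|`; both-empty masks score 1. Related to
#' Dice by `D = 2J / (1 + J)`.
#'
#' @inheritParams dice
#' @return Jaccard index in [0, 1].
#' @export
jaccard <- function(pred, truth) {
  p <- as_mask(pred); t <- as_mask(truth)
  check_same_shape(p, t)
  u <- sum(p | t)
  if (u == 0L) return(1)
  sum(p & t) / u
}

#' Voxelwise sensitivity (recall)
#'
#' `TP / (TP + FN)`. Undefined when the truth mask is empty: returns
#' `NaN` by default or raises with `undefined = "error"`.
#'
#' @inheritParams dice
#' @param undefined `"nan"` (default) or `"error"` for the empty-truth case.
#' @return Sensitivity in [0, 1], or `NaN`.
#' @export
sensitivity <- function(pred, truth, undefined = c("nan", "error")) {
  undefined <- match.arg(undefined)
  p <- as_mask(pred); t <- as_mask(truth)
  check_same_shape(p, t)
  nt <- sum(t)
  if (nt == 0L) {
    if (undefined == "error") stop("sensitivity undefined: empty truth mask")
    return(NaN)
  }
  sum(p & t) / nt
}

#' Voxelwise positive predictive value (precision)
#'
#' `TP / (TP + FP)`. Undefined when the predicted mask is empty.
#'
#' @inheritParams sensitivity
#' @return PPV in [0, 1], or `NaN`.
#' @export
ppv <- function(pred, truth, undefined = c("nan", "error")) {
  undefined <- match.arg(undefined)
  p <- as_mask(pred); t <- as_mask(truth)
  check_same_shape(p, t)
  np <- sum(p)
  if (np == 0L) {
    if (undefined == "error") stop("ppv undefined: empty predicted mask")
    return(NaN)
  }
  sum(p & t) / np
}

# Shift a logical array by one voxel along `axis` (dir = +1 brings the
# higher-index neighbor into place), padding with FALSE outside the grid.
shift_logical <- function(m, axis, dir) {
  d <- dim(m); n <- d[axis]
  out <- array(FALSE, dim = d)
  if (n == 1L) return(out)
  lo <- 1:(n - 1L); hi <- 2:n
  if (axis == 1L) {
    if (dir > 0) out[lo, , ] <- m[hi, , ] else out[hi, , ] <- m[lo, , ]
  } else if (axis == 2L) {
    if (dir > 0) out[, lo, ] <- m[, hi, ] else out[, hi, ] <- m[, lo, ]
  } else {
    if (dir > 0) out[, , lo] <- m[, , hi] else out[, , hi] <- m[, , lo]
  }
  out
}

# Boundary voxels under 6-connectivity: foreground voxels with at least
# one face neighbor that is background or outside the grid.
boundary_mask <- function(m) {
  interior <- m
  for (axis in 1:3) for (dir in c(-1, 1))
    interior <- interior & shift_logical(m, axis, dir)
  m & !interior
}

# Physical coordinates (mm) of TRUE voxels in a mask.
boundary_coords <- function(m, spacing) {
  idx <- which(m, arr.ind = TRUE)
  sweep(idx, 2L, spacing, `*`)
}

# Directed mean nearest-neighbor distance from rows of A to rows of B,
# computed in row blocks to bound memory. Distances use explicit
# per-axis differences (not the expanded quadratic form, which loses
# precision for nearby points).
directed_mean_nn <- function(A, B, block = 256L) {
  total <- 0
  for (s in seq(1L, nrow(A), by = block)) {
    e <- min(s + block - 1L, nrow(A))
    Ab <- A[s:e, , drop = FALSE]
    d2 <- outer(Ab[, 1L], B[, 1L], `-`)^2 +
      outer(Ab[, 2L], B[, 2L], `-`)^2 +
      outer(Ab[, 3L], B[, 3L], `-`)^2
    total <- total + sum(sqrt(apply(d2, 1L, min)))
  }
  total / nrow(A)
}

#' Modified Hausdorff distance
#'
#' The Dubuisson-Jain form: the maximum of the two directed mean
#' nearest-neighbor distances between the boundary voxel sets of the two
#' masks (6-connectivity boundary), with Euclidean distances scaled by
#' the voxel spacing. Boundary-based evaluation matches common
#' medical-imaging usage; `boundary = FALSE` uses the full voxel sets.
#'
#' @inheritParams dice
#' @param spacing voxel spacing used to scale distances; default taken
#'   from `pred` when it is a [volume_grid], else 1 mm isotropic.
#' @param boundary compare boundary voxel sets (default) or full masks.
#' @return Non-negative distance (mm for physical spacing, voxel units
#'   under unit spacing).
#' @export
modified_hausdorff <- function(pred, truth, spacing = NULL, boundary = TRUE) {
  if (is.null(spacing))
    spacing <- if (is_volume_grid(pred)) pred$spacing else c(1, 1, 1)
  p <- as_mask(pred); t <- as_mask(truth)
  check_same_shape(p, t)
  if (!sum(p) || !sum(t))
    stop("modified_hausdorff: both masks must be non-empty")
  if (boundary) { p <- boundary_mask(p); t <- boundary_mask(t) }
  A <- boundary_coords(p, spacing)
  B <- boundary_coords(t, spacing)
  max(directed_mean_nn(A, B), directed_mean_nn(B, A))
}

#' Evaluate one predicted segmentation against ground truth
#'
#' @inheritParams dice
#' @param case_id identifier copied into the report.
#' @param spacing spacing for the modified Hausdorff distance.
#' @return One-row data.frame with columns `case_id`, `sensitivity`,
#'   `ppv`, `dice`, `jaccard`, `mhd`. Undefined entries are `NaN`; `mhd`
#'   is `NaN` when either mask is empty.
#' @export
evaluate_case <- function(pred, truth, case_id = NA_character_, spacing = NULL) {
  p <- as_mask(pred); t <- as_mask(truth)
  mhd <- if (sum(p) && sum(t))
    modified_hausdorff(pred, truth, spacing = spacing) else NaN
  data.frame(case_id = case_id,
             sensitivity = sensitivity(pred, truth),
             ppv = ppv(pred, truth),
             dice = dice(pred, truth),
             jaccard = jaccard(pred, truth),
             mhd = mhd,
             stringsAsFactors = FALSE)
}

#' Summarize per-case metric reports over a cohort
#'
#' Unweighted arithmetic mean per metric; undefined (NaN) per-case values
#' are excluded, with the exclusion count reported per metric.
#'
#' @param reports data.frame of rows from [evaluate_case()] (rbind-ed).
#' @return data.frame with one row per metric: `metric`, `mean`, `n`,
#'   `n_excluded`.
#' @export
summarize_metrics <- function(reports) {
  if (is.null(reports) || nrow(reports) == 0L)
    stop("summarize_metrics: no reports")
  metrics <- c("sensitivity", "ppv", "dice", "jaccard", "mhd")
  rows <- lapply(metrics, function(m) {
    v <- reports[[m]]
    ok <- is.finite(v)
    data.frame(metric = m,
               mean = if (any(ok)) mean(v[ok]) else NaN,
               n = sum(ok), n_excluded = sum(!ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
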
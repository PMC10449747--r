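# Core domain types: volume grids, case bundles, label policies, cohort splits.

#' Construct a 3-D volume grid
#'
#' A `volume_grid` couples a 3-D numeric array with its physical voxel
#' spacing in mm. All image channels, probability maps and label masks in
#' the package are carried in this container.
#'
#' @param data 3-D numeric array; must be finite throughout.
#' @param spacing numeric length-3 vector of voxel sizes per axis in mm
#'   (strictly positive). Default 1 mm isotropic.
#' @return An object of class `volume_grid` with fields `data` and `spacing`.
#' @export
volume_grid <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume_grid: `data` must be a 3-D array")
  if (any(dim(data) <= 0L))
    stop("volume_grid: all axis extents must be positive")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume_grid: `spacing` must be 3 strictly positive values")
  if (!all(is.finite(data)))
    stop("volume_grid: data contains NaN or Inf")
  attributes(data) <- list(dim = dim(data))  # strip stray file metadata
  structure(list(data = data, spacing = spacing), class = "volume_grid")
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

is_volume_grid <- function(x) inherits(x, "volume_grid")

#' Construct a case bundle
#'
#' One imaging subject: co-registered channel volumes (a subset of
#' T1, T1c, T2, FLAIR) plus an optional integer ground-truth label mask.
#' All volumes must share the same grid shape; mismatches are an error,
#' never silently resampled.
#'
#' @param case_id unique string identifier within a cohort.
#' @param channels named list of [volume_grid] objects; names from
#'   `c("T1", "T1c", "T2", "FLAIR")`, at least one present.
#' @param truth_mask optional integer-valued [volume_grid] label mask.
#' @param multilabel logical: does `truth_mask` carry sub-region labels
#'   (e.g. necrotic core / edema / enhancing tumor) rather than a single
#'   whole-tumor label?
#' @return An object of class `case_bundle`.
#' @export
case_bundle <- function(case_id, channels, truth_mask = NULL,
                        multilabel = TRUE) {
  if (!is.character(case_id) || length(case_id) != 1L || !nzchar(case_id))
    stop("case_bundle: `case_id` must be a non-empty string")
  if (!is.list(channels) || length(channels) == 0L)
    stop("case_bundle: at least one channel required")
  known <- c("T1", "T1c", "T2", "FLAIR")
  if (is.null(names(channels)) || !all(names(channels) %in% known))
    stop("case_bundle: channel names must be among ", paste(known, collapse = ", "))
  for (ch in channels)
    if (!is_volume_grid(ch)) stop("case_bundle: channels must be volume_grid objects")
  shp <- dim(channels[[1L]])
  for (nm in names(channels))
    if (!identical(dim(channels[[nm]]), shp))
      stop(sprintf("case_bundle: channel '%s' shape mismatch", nm))
  if (!is.null(truth_mask)) {
    if (!is_volume_grid(truth_mask)) stop("case_bundle: truth_mask must be a volume_grid")
    if (!identical(dim(truth_mask), shp))
      stop("case_bundle: truth_mask shape mismatch with channels")
    v <- truth_mask$data
    if (any(v != round(v)))
      stop("case_bundle: truth_mask contains non-integer label values")
  }
  structure(list(case_id = case_id, channels = channels,
                 truth_mask = truth_mask, multilabel = isTRUE(multilabel)),
            class = "case_bundle")
}

#' @export
print.case_bundle <- function(x, ...) {
  cat(sprintf("<case_bundle> %s: channels [%s]%s, %s\n", x$case_id,
              paste(names(x$channels), collapse = ", "),
              if (is.null(x$truth_mask)) ", no truth" else ", truth present",
              paste(dim(x$channels[[1L]]), collapse = "x")))
  invisible(x)
}

#' Label policy for whole-tumor merging
#'
#' Which integer codes in a multi-label mask count as tumor, and which
#' single code the merged whole-tumor (WT) mask should carry. The default
#' follows the BraTS dialect where 1 = necrotic core, 2 = edema and
#' 4 = enhancing tumor.
#'
#' @param sublabels integer codes treated as tumor (non-empty, excluding
#'   the background code).
#' @param wt_code output code for the merged whole-tumor label.
#' @param background_code background code (default 0).
#' @return An object of class `label_policy`.
#' @export
label_policy <- function(sublabels = c(1L, 2L, 4L), wt_code = 1L,
                         background_code = 0L) {
  sublabels <- as.integer(sublabels)
  wt_code <- as.integer(wt_code); background_code <- as.integer(background_code)
  if (length(sublabels) == 0L) stop("label_policy: sublabels must be non-empty")
  if (background_code %in% sublabels)
    stop("label_policy: sublabels must exclude the background code")
  if (wt_code == background_code)
    stop("label_policy: wt_code must differ from background_code")
  structure(list(sublabels = sublabels, wt_code = wt_code,
                 background_code = background_code), class = "label_policy")
}

#' Merge sub-region labels into a single whole-tumor mask
#'
#' Every voxel whose code is in `policy$sublabels` becomes `policy$wt_code`;
#' everything else becomes background. Idempotent when the policy's
#' `wt_code` is itself in `sublabels` (the default).
#'
#' @param mask integer-valued [volume_grid].
#' @param policy a [label_policy].
#' @param unknown what to do with nonzero codes outside `sublabels`:
#'   `"error"` (default) or `"background"` (warn and treat as background).
#' @return Binary [volume_grid] with values in `{background_code, wt_code}`.
#' @export
merge_labels <- function(mask, policy = label_policy(),
                         unknown = c("error", "background")) {
  unknown <- match.arg(unknown)
  stopifnot(is_volume_grid(mask))
  v <- mask$data
  if (any(v != round(v))) stop("merge_labels: mask contains non-integer values")
  codes <- unique(as.vector(v))
  stray <- setdiff(codes, c(policy$background_code, policy$sublabels))
  if (length(stray)) {
    msg <- sprintf("merge_labels: mask contains unknown label code(s): %s",
                   paste(stray, collapse = ", "))
    if (unknown == "error") stop(msg) else warning(msg, "; treated as background")
  }
  out <- array(policy$background_code, dim = dim(v))
  out[v %in% policy$sublabels] <- policy$wt_code
  volume_grid(out, mask$spacing)
}

#' Load one case from NIfTI files
#'
#' Reads the channel volumes (and optionally a ground-truth mask) for one
#' subject. All files must share one grid shape; a mismatch raises an
#' error rather than resampling. Orientation metadata is not used for
#' resampling; the arrays are taken as stored.
#'
#' @param channel_paths named character vector or list mapping channel
#'   name (T1/T1c/T2/FLAIR) to a NIfTI file path.
#' @param truth_path optional path to an integer-label NIfTI mask.
#' @param case_id case identifier; defaults to the basename of the first
#'   channel file stripped of its NIfTI extension.
#' @param multilabel passed through to [case_bundle()].
#' @return A [case_bundle].
#' @export
load_case <- function(channel_paths, truth_path = NULL, case_id = NULL,
                      multilabel = TRUE) {
  channel_paths <- as.list(channel_paths)
  if (length(channel_paths) == 0L) stop("load_case: no channel paths given")
  for (p in c(unlist(channel_paths), truth_path))
    if (!file.exists(p)) stop("load_case: file not found: ", p)
  read_vol <- function(p) {
    img <- RNifti::readNifti(p)
    pd <- RNifti::pixdim(img)[seq_len(3)]
    volume_grid(as.array(img), spacing = pd)
  }
  channels <- lapply(channel_paths, read_vol)
  if (is.null(case_id)) {
    case_id <- sub("\\.nii(\\.gz)?$", "", basename(channel_paths[[1L]]))
  }
  truth <- if (!is.null(truth_path)) read_vol(truth_path) else NULL
  if (!is.null(truth) && any(truth$data != round(truth$data)))
    stop("load_case: truth mask contains non-integer values: ", truth_path)
  case_bundle(case_id, channels, truth_mask = truth, multilabel = multilabel)
}

#' Write a volume grid to a NIfTI file
#'
#' @param vol a [volume_grid].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI on-disk datatype; `"auto"` picks int16 for
#'   integer-valued data and float32 otherwise.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = c("auto", "int16", "float")) {
  datatype <- match.arg(datatype)
  stopifnot(is_volume_grid(vol))
  if (datatype == "auto")
    datatype <- if (all(vol$data == round(vol$data))) "int16" else "float"
  arr <- vol$data
  attr(arr, "pixdim") <- vol$spacing
  img <- RNifti::asNifti(arr, datatype = datatype)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Split a cohort into test / validation / training / pool ids
#'
#' Deterministic seeded split. `test_n` ids are drawn first as the fixed
#' test set, then `floor(validation_fraction * remaining)` as validation.
#' The remainder becomes the training population; when `initial_n` is
#' given, its first `initial_n` ids (after shuffling) are the initial
#' training set and the rest the active-learning pool, otherwise all
#' remaining ids land in `train_ids` and `pool_ids` is empty.
#'
#' @param ids character vector of unique case ids.
#' @param test_n number of test cases (< length(ids)).
#' @param validation_fraction fraction of non-test ids used for validation
#'   (floored; 0 <= f < 1).
#' @param seed integer RNG seed; the split is a pure function of
#'   (`ids`, `test_n`, `validation_fraction`, `initial_n`, `seed`).
#' @param initial_n optional size of the initial training set.
#' @return An object of class `cohort_split` with fields `train_ids`,
#'   `pool_ids`, `validation_ids`, `test_ids`, `seed`.
#' @export
split_cohort <- function(ids, test_n, validation_fraction = 0.08, seed = 1L,
                         initial_n = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("split_cohort: ids must be unique")
  n <- length(ids)
  if (test_n >= n) stop("split_cohort: test_n must be smaller than the cohort")
  if (test_n < 0) stop("split_cohort: test_n must be non-negative")
  if (validation_fraction < 0 || validation_fraction >= 1)
    stop("split_cohort: validation_fraction must be in [0, 1)")
  shuffled <- with_seed(seed, sample(ids, n))
  test_ids <- if (test_n > 0) shuffled[seq_len(test_n)] else character(0)
  rest <- if (test_n > 0) shuffled[-seq_len(test_n)] else shuffled
  n_val <- floor(validation_fraction * length(rest))
  validation_ids <- if (n_val > 0) rest[seq_len(n_val)] else character(0)
  remain <- if (n_val > 0) rest[-seq_len(n_val)] else rest
  if (!is.null(initial_n)) {
    if (initial_n > length(remain))
      stop("split_cohort: initial_n exceeds the available training ids")
    train_ids <- remain[seq_len(initial_n)]
    pool_ids <- remain[-seq_len(initial_n)]
  } else {
    train_ids <- remain
    pool_ids <- character(0)
  }
  structure(list(train_ids = train_ids, pool_ids = pool_ids,
                 validation_ids = validation_ids, test_ids = test_ids,
                 seed = as.integer(seed)), class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("<cohort_split> train %d | pool %d | validation %d | test %d (seed %d)\n",
              length(x$train_ids), length(x$pool_ids),
              length(x$validation_ids), length(x$test_ids), x$seed))
  invisible(x)
}

#' Read a cohort manifest
#'
#' A manifest is a CSV with one row per case: a `case_id` column, one
#' column per channel (named `T1`, `T1c`, `T2`, `FLAIR`) holding NIfTI
#' paths, and an optional `truth` column. Relative paths are resolved
#' against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @param channels which channel columns to load; default: all present.
#' @return List of [case_bundle] objects.
#' @export
read_manifest <- function(path, channels = NULL) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"case_id" %in% names(man)) stop("read_manifest: no case_id column")
  known <- c("T1", "T1c", "T2", "FLAIR")
  present <- intersect(known, names(man))
  if (is.null(channels)) channels <- present
  if (!all(channels %in% present))
    stop("read_manifest: requested channels missing from manifest")
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  lapply(seq_len(nrow(man)), function(i) {
    cp <- lapply(stats::setNames(channels, channels),
                 function(ch) resolve(man[[ch]][i]))
    tp <- if ("truth" %in% names(man) && nzchar(man$truth[i]))
      resolve(man$truth[i]) else NULL
    load_case(cp, truth_path = tp, case_id = man$case_id[i])
  })
}

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so package functions never disturb user RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
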
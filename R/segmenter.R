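# Pluggable segmenter contract and a desk-scale voxelwise reference model.
#
# The active-learning loop only requires the three generics below; any
# model implementing them (including mocks built with manual_segmenter())
# can be driven by run_experiment() unchanged.

#' Construct a training record
#'
#' A case paired with the binary mask actually used for training and the
#' provenance of that mask: expert ground truth, or the model's own
#' prediction substituted for it by the active-learning rule.
#'
#' @param case a [case_bundle].
#' @param label_mask binary [volume_grid] with the same shape as the
#'   case's channels.
#' @param mask_source `"ground_truth"` or `"model_prediction"`.
#' @return An object of class `training_record`.
#' @export
training_record <- function(case, label_mask,
                            mask_source = c("ground_truth", "model_prediction")) {
  mask_source <- match.arg(mask_source)
  stopifnot(inherits(case, "case_bundle"), is_volume_grid(label_mask))
  if (!identical(dim(label_mask), dim(case$channels[[1L]])))
    stop("training_record: label mask shape differs from case channels")
  structure(list(case = case, label_mask = label_mask,
                 mask_source = mask_source), class = "training_record")
}

#' Construct a segmentation result
#'
#' The binary mask is derived from the probability map by thresholding,
#' so `mask == (prob_map >= threshold)` holds by construction.
#'
#' @param case_id case identifier.
#' @param prob_map [volume_grid] of voxelwise foreground probabilities in
#'   [0, 1].
#' @param threshold decision threshold (default 0.5).
#' @param model_tag string identifying the producing model iteration.
#' @return An object of class `segmentation_result` with fields
#'   `case_id`, `mask`, `prob_map`, `threshold`, `model_tag`.
#' @export
segmentation_result <- function(case_id, prob_map, threshold = 0.5,
                                model_tag = "unknown") {
  stopifnot(is_volume_grid(prob_map))
  pv <- prob_map$data
  if (min(pv) < 0 || max(pv) > 1)
    stop("segmentation_result: probability map outside [0, 1]")
  mask <- volume_grid(array(as.integer(pv >= threshold), dim = dim(pv)),
                      prob_map$spacing)
  structure(list(case_id = case_id, mask = mask, prob_map = prob_map,
                 threshold = threshold, model_tag = model_tag),
            class = "segmentation_result")
}

# ---- contract generics ------------------------------------------------------

#' Fit a segmenter on training records
#'
#' @param model a segmenter object.
#' @param records non-empty list of [training_record]s on a common grid.
#' @param validation list of [case_bundle]s with ground truth, used for
#'   the per-epoch validation Dice curve.
#' @param epochs number of training epochs.
#' @param seed RNG seed; fitting is deterministic given (data, seed).
#' @param ... method-specific arguments.
#' @return A training history: data.frame with columns `epoch`,
#'   `val_dice` covering all epochs so far (1-based epochs).
#' @export
seg_fit <- function(model, records, validation = list(), epochs = 12L,
                    seed = 1L, ...) UseMethod("seg_fit")

#' Continue training with additional records
#'
#' Training resumes from the current model state on the union of the
#' original and additional records.
#'
#' @inheritParams seg_fit
#' @param additional_records records to add to the training set.
#' @return Updated cumulative training history.
#' @export
seg_continue <- function(model, additional_records, epochs = 12L, seed = 1L,
                         ...) UseMethod("seg_continue")

#' Predict a segmentation for one case
#'
#' @param model a fitted segmenter.
#' @param case a [case_bundle].
#' @param ... method-specific arguments.
#' @return A [segmentation_result].
#' @export
seg_predict <- function(model, case, ...) UseMethod("seg_predict")

#' Restore a segmenter to an earlier epoch checkpoint
#'
#' Used by the active-learning loop to score the pool from the model
#' iteration at the validation-Dice plateau rather than the final one.
#' The default method is a no-op (stateless mocks have nothing to
#' restore).
#'
#' @param model a segmenter.
#' @param epoch 1-based epoch to restore.
#' @return The model, invisibly.
#' @export
seg_restore <- function(model, epoch) UseMethod("seg_restore")

#' @export
seg_restore.default <- function(model, epoch) invisible(model)

#' Is a segmenter fitted?
#' @param model a segmenter.
#' @return logical.
#' @export
seg_is_fitted <- function(model) UseMethod("seg_is_fitted")

#' @export
seg_is_fitted.default <- function(model) TRUE

# ---- mock / externally-defined segmenters ----------------------------------

#' Wrap a prediction function as a contract-conforming segmenter
#'
#' Builds a stateless segmenter whose `seg_predict` calls `predict_fun`
#' on the case and whose fit methods are no-ops. Useful for oracle and
#' canned-output models in tests and pipeline-equivalence checks.
#'
#' @param predict_fun function(case_bundle) returning either a
#'   [segmentation_result] or a probability [volume_grid].
#' @param threshold decision threshold applied when `predict_fun`
#'   returns a probability map.
#' @param tag model tag recorded on results.
#' @return An object of class `c("manual_segmenter", "segmenter")`.
#' @export
manual_segmenter <- function(predict_fun, threshold = 0.5, tag = "manual") {
  structure(list(predict_fun = predict_fun, threshold = threshold, tag = tag),
            class = c("manual_segmenter", "segmenter"))
}

#' @export
seg_fit.manual_segmenter <- function(model, records, validation = list(),
                                     epochs = 12L, seed = 1L, ...) {
  if (length(records) == 0L) stop("seg_fit: empty record list")
  data.frame(epoch = integer(0), val_dice = numeric(0))
}

#' @export
seg_continue.manual_segmenter <- function(model, additional_records,
                                          epochs = 12L, seed = 1L, ...) {
  data.frame(epoch = integer(0), val_dice = numeric(0))
}

#' @export
seg_predict.manual_segmenter <- function(model, case, ...) {
  out <- model$predict_fun(case)
  if (inherits(out, "segmentation_result")) return(out)
  segmentation_result(case$case_id, out, threshold = model$threshold,
                      model_tag = model$tag)
}

# ---- reference voxelwise segmenter -----------------------------------------

#' Configuration for the reference voxel segmenter
#'
#' @param channels channel names used as input (default T1c, T2, FLAIR).
#' @param sigmas standard deviations (voxels) of the two Gaussian
#'   smoothing scales added to the raw intensities.
#' @param threshold probability decision threshold for the binary mask.
#' @param bg_ratio background:foreground voxel sampling ratio used to
#'   balance classes when building the training design matrix.
#' @param fg_cap maximum foreground voxels sampled per case.
#' @param min_bg background voxels sampled for a lesion-free case.
#' @param lambda ridge penalty on the logistic weights.
#' @return A list of class `voxel_seg_config`.
#' @export
voxel_seg_config <- function(channels = c("T1c", "T2", "FLAIR"),
                             sigmas = c(1, 2), threshold = 0.5,
                             bg_ratio = 3, fg_cap = 2000L, min_bg = 512L,
                             lambda = 1e-4) {
  structure(list(channels = channels, sigmas = sigmas, threshold = threshold,
                 bg_ratio = bg_ratio, fg_cap = as.integer(fg_cap),
                 min_bg = as.integer(min_bg), lambda = lambda),
            class = "voxel_seg_config")
}

# Separable Gaussian smoothing with zero padding (background is zero in
# preprocessed brain volumes, so zero padding is the natural extension).
gaussian_smooth3 <- function(a, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); k <- k / sum(k)
  for (axis in 1:3) a <- convolve_axis(a, k, axis)
  a
}

convolve_axis <- function(a, k, axis) {
  d <- dim(a); n <- d[axis]; r <- (length(k) - 1L) %/% 2L
  out <- array(0, dim = d)
  for (j in seq_along(k)) {
    off <- j - r - 1L      # source index offset
    if (abs(off) >= n) next
    src <- max(1L, 1L + off):min(n, n + off)
    dst <- src - off
    if (axis == 1L) out[dst, , ] <- out[dst, , ] + k[j] * a[src, , ]
    else if (axis == 2L) out[, dst, ] <- out[, dst, ] + k[j] * a[, src, ]
    else out[, , dst] <- out[, , dst] + k[j] * a[, , src]
  }
  out
}

# Per-voxel feature matrix for one case: per-case z-scored intensities
# (raw + two smoothed scales) per channel, plus normalized spatial
# coordinates. The z-scoring over each case's support (nonzero) voxels
# makes features comparable across cases regardless of how the global
# intensity normalization happened to scale that particular volume.
voxel_features <- function(case, config) {
  chans <- config$channels
  missing <- setdiff(chans, names(case$channels))
  if (length(missing))
    stop("voxel segmenter: case ", case$case_id, " lacks channel(s): ",
         paste(missing, collapse = ", "))
  d <- dim(case$channels[[chans[1L]]])
  cols <- list()
  for (ch in chans) {
    v <- case$channels[[ch]]$data
    sup <- v != 0
    if (any(sup)) {
      m <- mean(v[sup]); s <- stats::sd(v[sup])
      if (!is.finite(s) || s < 1e-12) s <- 1
      # clamp so that lesion amplitude saturates: keeps the learned
      # decision boundary at a contrast-independent spatial position
      v <- pmin(pmax((v - m) / s, -3), 3)
      v[!sup] <- 0
    }
    cols[[paste0(ch, "_raw")]] <- as.vector(v)
    for (s in config$sigmas)
      cols[[paste0(ch, "_s", s)]] <- as.vector(gaussian_smooth3(v, s))
  }
  gx <- (slice.index(array(0, d), 1L) - 1) / max(d[1L] - 1L, 1L)
  gy <- (slice.index(array(0, d), 2L) - 1) / max(d[2L] - 1L, 1L)
  gz <- (slice.index(array(0, d), 3L) - 1) / max(d[3L] - 1L, 1L)
  cols$coord_x <- as.vector(gx); cols$coord_y <- as.vector(gy)
  cols$coord_z <- as.vector(gz)
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  X
}

# Binary training label volume for a record (already binary by contract).
record_label <- function(record) as.vector(record$label_mask$data != 0)

#' Reference voxelwise segmenter
#'
#' A deliberately simple, CPU-scale probabilistic segmenter implementing
#' the full segmenter contract: per-voxel features (channel intensities,
#' Gaussian-smoothed intensities at two scales, normalized spatial
#' coordinates) feed a ridge-regularized logistic model trained by
#' damped Newton steps, one step per epoch. Class imbalance is handled
#' by sampling `bg_ratio` background voxels per foreground voxel.
#' Per-epoch weight snapshots support checkpoint restoration
#' ([seg_restore()]), and [seg_continue()] resumes from the current
#' weights on the union of old and new records.
#'
#' @param config a [voxel_seg_config].
#' @return An object of class `c("voxel_segmenter", "segmenter")`.
#' @export
reference_voxel_segmenter <- function(config = voxel_seg_config()) {
  stopifnot(inherits(config, "voxel_seg_config"))
  env <- new.env(parent = emptyenv())
  env$config <- config
  env$fitted <- FALSE
  env$X <- NULL; env$y <- NULL
  env$mu <- NULL; env$sd <- NULL
  env$coef <- NULL
  env$snapshots <- list()
  env$history <- data.frame(epoch = integer(0), val_dice = numeric(0))
  env$val_cache <- list()
  env$record_ids <- character(0)
  structure(list(env = env), class = c("voxel_segmenter", "segmenter"))
}

# Sample a balanced voxel subset from one record's label volume. Half of
# the background budget is spent on hard negatives from the shell just
# outside the lesion (where smoothed-intensity halos cause false
# positives), the rest drawn uniformly.
sample_record_rows <- function(yv, dims, config) {
  fg <- which(yv); bg <- which(!yv)
  if (length(fg) > config$fg_cap) fg <- sort(sample(fg, config$fg_cap))
  nbg <- if (length(fg) > 0L) {
    min(length(bg), config$bg_ratio * length(fg))
  } else min(length(bg), config$min_bg)
  if (length(fg) > 0L && nbg > 0L) {
    halo <- gaussian_smooth3(array(as.numeric(yv), dim = dims),
                             max(config$sigmas)) > 0.01
    shell <- which(as.vector(halo) & !yv)
    n_hard <- min(length(shell), nbg %/% 2L)
    hard <- if (n_hard > 0L) sample(shell, n_hard) else integer(0)
    easy <- sample(setdiff(bg, hard), nbg - n_hard)
    bg <- sort(c(hard, easy))
  } else {
    bg <- sort(sample(bg, nbg))
  }
  c(fg, bg)
}

append_design <- function(env, records) {
  for (rec in records) {
    Xc <- voxel_features(rec$case, env$config)
    yv <- record_label(rec)
    rows <- sample_record_rows(yv, dim(rec$label_mask$data), env$config)
    env$X <- rbind(env$X, Xc[rows, , drop = FALSE])
    env$y <- c(env$y, yv[rows])
    env$record_ids <- c(env$record_ids, rec$case$case_id)
  }
}

# Damped Newton steps on the ridge-penalized logistic log-loss; one step
# per epoch, validation Dice recorded after each step.
newton_epochs <- function(env, epochs, validation) {
  Xs <- sweep(sweep(env$X, 2L, env$mu, `-`), 2L, env$sd, `/`)
  Xs <- cbind(intercept = 1, Xs)
  y <- as.numeric(env$y)
  n <- nrow(Xs); p <- ncol(Xs)
  w <- env$coef
  lam <- env$config$lambda
  hist_new <- NULL
  for (e in seq_len(epochs)) {
    eta <- drop(Xs %*% w)
    pr <- 1 / (1 + exp(-eta))
    grad <- drop(crossprod(Xs, pr - y)) / n + lam * w
    wt <- pmax(pr * (1 - pr), 1e-6)
    H <- crossprod(Xs * wt, Xs) / n + lam * diag(p)
    w <- unname(w - drop(solve(H, grad)))
    env$coef <- w
    epoch_idx <- length(env$snapshots) + 1L
    env$snapshots[[epoch_idx]] <- w
    vd <- validation_dice(env, validation)
    hist_new <- rbind(hist_new, data.frame(epoch = epoch_idx, val_dice = vd))
  }
  env$history <- rbind(env$history, hist_new)
  env$history
}

validation_dice <- function(env, validation) {
  if (length(validation) == 0L) return(NA_real_)
  scores <- vapply(validation, function(case) {
    if (is.null(case$truth_mask))
      stop("validation case ", case$case_id, " has no ground truth")
    key <- case$case_id
    if (is.null(env$val_cache[[key]]))
      env$val_cache[[key]] <- voxel_features(case, env$config)
    pr <- predict_prob(env, env$val_cache[[key]])
    truth <- if (case$multilabel) merge_labels(case$truth_mask)$data else case$truth_mask$data
    dice(array(pr >= env$config$threshold, dim = dim(truth)),
         truth != 0)
  }, numeric(1))
  mean(scores)
}

predict_prob <- function(env, X) {
  Xs <- sweep(sweep(X, 2L, env$mu, `-`), 2L, env$sd, `/`)
  eta <- drop(cbind(1, Xs) %*% env$coef)
  1 / (1 + exp(-eta))
}

#' @export
seg_is_fitted.voxel_segmenter <- function(model) model$env$fitted

#' @export
seg_fit.voxel_segmenter <- function(model, records, validation = list(),
                                    epochs = 12L, seed = 1L, ...) {
  env <- model$env
  if (length(records) == 0L) stop("seg_fit: empty record list")
  shp <- dim(records[[1L]]$case$channels[[1L]])
  for (rec in records)
    if (!identical(dim(rec$case$channels[[1L]]), shp))
      stop("seg_fit: records must share one preprocessed grid shape")
  env$X <- NULL; env$y <- NULL; env$record_ids <- character(0)
  with_seed(seed, append_design(env, records))
  env$mu <- colMeans(env$X)
  env$sd <- apply(env$X, 2L, stats::sd)
  env$sd[env$sd < 1e-12] <- 1
  env$coef <- numeric(ncol(env$X) + 1L)
  env$snapshots <- list()
  env$history <- data.frame(epoch = integer(0), val_dice = numeric(0))
  env$fitted <- TRUE
  newton_epochs(env, epochs, validation)
}

#' @export
seg_continue.voxel_segmenter <- function(model, additional_records,
                                         epochs = 12L, seed = 1L,
                                         validation = list(), ...) {
  env <- model$env
  if (!env$fitted) stop("seg_continue: model has not been fitted")
  dup <- intersect(vapply(additional_records,
                          function(r) r$case$case_id, character(1)),
                   env$record_ids)
  if (length(dup))
    stop("seg_continue: case(s) already in the training set: ",
         paste(dup, collapse = ", "))
  with_seed(seed, append_design(env, additional_records))
  newton_epochs(env, epochs, validation)
}

#' @export
seg_predict.voxel_segmenter <- function(model, case, ...) {
  env <- model$env
  if (!env$fitted) stop("seg_predict: model has not been fitted")
  X <- voxel_features(case, env$config)
  if (ncol(X) != length(env$mu))
    stop("seg_predict: feature dimension mismatch with training")
  pr <- predict_prob(env, X)
  d <- dim(case$channels[[1L]])
  prob <- volume_grid(array(pmin(pmax(pr, 0), 1), dim = d),
                      case$channels[[1L]]$spacing)
  segmentation_result(case$case_id, prob, threshold = env$config$threshold,
                      model_tag = sprintf("voxel_segmenter@epoch%d",
                                          length(env$snapshots)))
}

#' @export
seg_restore.voxel_segmenter <- function(model, epoch) {
  env <- model$env
  epoch <- as.integer(epoch)
  if (!env$fitted) stop("seg_restore: model has not been fitted")
  if (epoch < 1L || epoch > length(env$snapshots))
    stop("seg_restore: no snapshot for epoch ", epoch)
  env$coef <- env$snapshots[[epoch]]
  env$snapshots <- env$snapshots[seq_len(epoch)]
  env$history <- env$history[env$history$epoch <= epoch, , drop = FALSE]
  invisible(model)
}

#' Serialize / restore the reference segmenter state
#'
#' The full model state (configuration, standardization constants,
#' weights, per-epoch snapshots and history, but not the cached training
#' design) is written to a single versioned JSON file.
#'
#' @param model a fitted `voxel_segmenter`.
#' @param path output file.
#' @return `path` invisibly ([save_segmenter()]); a restored model
#'   ([load_segmenter()]). Restored models support prediction and
#'   checkpoint restore but not continued fitting.
#' @export
save_segmenter <- function(model, path) {
  env <- model$env
  if (!env$fitted) stop("save_segmenter: model has not been fitted")
  state <- list(format = "alseg-voxel-segmenter-v1",
                config = unclass(env$config),
                mu = env$mu, sd = env$sd, coef = env$coef,
                snapshots = env$snapshots,
                history = env$history,
                record_ids = env$record_ids)
  jsonlite::write_json(state, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  state <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(state$format, "alseg-voxel-segmenter-v1"))
    stop("load_segmenter: unrecognized model file format")
  cfg <- do.call(voxel_seg_config, state$config[setdiff(names(state$config), NULL)])
  model <- reference_voxel_segmenter(cfg)
  env <- model$env
  env$mu <- stats::setNames(as.numeric(state$mu), names(state$mu))
  env$sd <- stats::setNames(as.numeric(state$sd), names(state$sd))
  env$coef <- as.numeric(state$coef)
  env$snapshots <- lapply(state$snapshots, as.numeric)
  env$history <- as.data.frame(state$history)
  env$record_ids <- as.character(state$record_ids)
  env$fitted <- TRUE
  model
}
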
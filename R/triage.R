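# Reference-free segmentation-quality triage: three-class taxonomy,
# feature-based Dice-class predictor, and classifier evaluation
# (confusion matrix, one-vs-rest metrics, ROC/AUC, escalation summary).

#' Quality class levels
#'
#' The three-way triage taxonomy, ordered worst to best:
#' `"poor"` (re-segment from scratch), `"adjust"` (acceptable with expert
#' adjustments), `"acceptable"` (no review needed).
#' @export
QUALITY_CLASSES <- c("poor", "adjust", "acceptable")

# Coerce to an ordered factor over the three quality classes.
quality_factor <- function(x) {
  f <- factor(as.character(x), levels = QUALITY_CLASSES, ordered = TRUE)
  if (anyNA(f) && !anyNA(x))
    stop("unknown quality class; expected one of: ",
         paste(QUALITY_CLASSES, collapse = ", "))
  f
}

#' Triage thresholds
#'
#' Dice cut-points separating the three quality classes. Defaults 0.6
#' and 0.8: below 0.6 is poor, 0.6 up to (excluding) 0.8 needs
#' adjustments, 0.8 and above is acceptable.
#'
#' @param lower,upper Dice cut-points with `0 < lower < upper < 1`.
#' @return An object of class `triage_thresholds`.
#' @export
triage_thresholds <- function(lower = 0.6, upper = 0.8) {
  if (!(lower > 0 && lower < upper && upper < 1))
    stop("triage_thresholds: need 0 < lower < upper < 1")
  structure(list(lower = lower, upper = upper), class = "triage_thresholds")
}

#' Bin a Dice score into a quality class
#'
#' Half-open convention: `dice < lower` is poor, `lower <= dice < upper`
#' needs adjustments, `dice >= upper` is acceptable. The boundary values
#' therefore fall upward (0.6 bins to adjust, 0.8 to acceptable).
#'
#' @param dice_value Dice score(s) in [0, 1]; vectorized.
#' @param thresholds a [triage_thresholds].
#' @return Ordered factor over [QUALITY_CLASSES].
#' @export
bin_quality <- function(dice_value, thresholds = triage_thresholds()) {
  if (any(!is.finite(dice_value)) || any(dice_value < 0) || any(dice_value > 1))
    stop("bin_quality: dice values must lie in [0, 1]")
  cls <- ifelse(dice_value < thresholds$lower, "poor",
                ifelse(dice_value < thresholds$upper, "adjust", "acceptable"))
  quality_factor(cls)
}

# ---- triage predictor contract ---------------------------------------------

#' Predict a quality class for one case
#'
#' @param predictor a triage predictor object.
#' @param case a [case_bundle].
#' @param prob_map segmentation probability [volume_grid] for the case.
#' @param ... method-specific arguments.
#' @return List with `class` (ordered factor level) and `scores` (named
#'   probability triple over [QUALITY_CLASSES] summing to 1).
#' @export
triage_predict <- function(predictor, case, prob_map, ...)
  UseMethod("triage_predict")

#' Oracle triage predictor
#'
#' A reference predictor that consults the case's ground truth: it
#' thresholds the probability map, computes the true Dice score, and
#' bins it with [bin_quality()]. Scores are the one-hot indicator of
#' that class. Used for pipeline-equivalence checks; a real deployment
#' uses a reference-free predictor such as [fit_baseline_triage()].
#'
#' @param thresholds a [triage_thresholds].
#' @param decision_threshold probability cut for the binary mask.
#' @return An object of class `c("oracle_triage", "triage_predictor")`.
#' @export
oracle_triage_predictor <- function(thresholds = triage_thresholds(),
                                    decision_threshold = 0.5) {
  structure(list(thresholds = thresholds,
                 decision_threshold = decision_threshold),
            class = c("oracle_triage", "triage_predictor"))
}

#' @export
triage_predict.oracle_triage <- function(predictor, case, prob_map, ...) {
  if (is.null(case$truth_mask))
    stop("oracle triage requires ground truth on the case")
  truth <- if (case$multilabel) merge_labels(case$truth_mask) else case$truth_mask
  mask <- prob_map$data >= predictor$decision_threshold
  d <- dice(array(mask, dim = dim(prob_map$data)), truth)
  cls <- bin_quality(d, predictor$thresholds)
  scores <- stats::setNames(as.numeric(QUALITY_CLASSES == as.character(cls)),
                            QUALITY_CLASSES)
  list(class = cls, scores = scores)
}

# ---- baseline feature-based predictor --------------------------------------

# Central-difference gradient magnitude of a 3-D array.
gradient_magnitude <- function(a) {
  d <- dim(a)
  g2 <- array(0, dim = d)
  for (axis in 1:3) {
    n <- d[axis]
    if (n < 2L) next
    fwd <- bwd <- a
    if (axis == 1L) { fwd[1:(n - 1), , ] <- a[2:n, , ]; bwd[2:n, , ] <- a[1:(n - 1), , ] }
    else if (axis == 2L) { fwd[, 1:(n - 1), ] <- a[, 2:n, ]; bwd[, 2:n, ] <- a[, 1:(n - 1), ] }
    else { fwd[, , 1:(n - 1)] <- a[, , 2:n]; bwd[, , 2:n] <- a[, , 1:(n - 1)] }
    g2 <- g2 + ((fwd - bwd) / 2)^2
  }
  sqrt(g2)
}

# Number of 6-connected components of a logical mask.
count_components <- function(m) {
  d <- dim(m)
  idx <- which(m)
  if (!length(idx)) return(0L)
  visited <- logical(prod(d))
  strides <- c(1L, d[1L], d[1L] * d[2L])
  ncomp <- 0L
  for (start in idx) {
    if (visited[start]) next
    ncomp <- ncomp + 1L
    stack <- start
    visited[start] <- TRUE
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ci <- arrayInd(cur, d)
      for (axis in 1:3) for (dir in c(-1L, 1L)) {
        if (ci[axis] + dir < 1L || ci[axis] + dir > d[axis]) next
        nb <- cur + dir * strides[axis]
        if (m[nb] && !visited[nb]) { visited[nb] <- TRUE; stack <- c(stack, nb) }
      }
    }
  }
  ncomp
}

#' Quality-triage features for one predicted segmentation
#'
#' A fixed-length reference-free feature vector summarizing a predicted
#' segmentation and the model's confidence in it: predicted volume
#' fraction; mean probability and mean binary entropy over the predicted
#' foreground; the uncertainty mass (fraction of voxels with probability
#' in (0.3, 0.7)); per-channel boundary gradient agreement (mean image
#' gradient magnitude on the predicted boundary relative to the whole
#' volume -- masks that hug image edges score high); and the number of
#' 6-connected components of the thresholded mask.
#'
#' @param case a [case_bundle].
#' @param prob_map probability [volume_grid] (values in [0, 1]).
#' @param decision_threshold probability cut for the binary mask.
#' @param channels channels used for gradient features; default: all
#'   channels of the case.
#' @return Named numeric vector.
#' @export
baseline_triage_features <- function(case, prob_map, decision_threshold = 0.5,
                                     channels = NULL) {
  stopifnot(is_volume_grid(prob_map))
  p <- prob_map$data
  if (length(p) == 0L) stop("baseline_triage_features: empty probability map")
  if (is.null(channels)) channels <- names(case$channels)
  mask <- p >= decision_threshold
  nfg <- sum(mask)
  feats <- c(volume_fraction = nfg / length(p))
  if (nfg > 0L) {
    pf <- p[mask]
    eps <- 1e-12
    ent <- -(pf * log(pmax(pf, eps)) + (1 - pf) * log(pmax(1 - pf, eps)))
    feats <- c(feats, fg_mean_prob = mean(pf), fg_mean_entropy = mean(ent))
  } else {
    feats <- c(feats, fg_mean_prob = 0, fg_mean_entropy = 0)
  }
  feats <- c(feats, uncertainty_mass = mean(p > 0.3 & p < 0.7))
  bnd <- boundary_mask(mask)
  for (ch in channels) {
    g <- gradient_magnitude(case$channels[[ch]]$data)
    agree <- if (sum(bnd) > 0L) mean(g[bnd]) / (mean(g) + 1e-12) else 0
    feats[[paste0("grad_agree_", ch)]] <- agree
  }
  feats[["n_components"]] <- count_components(mask)
  feats
}

#' Fit the baseline quality-triage classifier
#'
#' A multinomial logistic model (via [nnet::multinom()]) over triage
#' feature vectors, trained on cases whose true Dice class is known
#' (held out from the active-learning pool). Features are standardized
#' internally.
#'
#' @param features numeric matrix or data.frame, one row per labelled
#'   case (columns as from [baseline_triage_features()]).
#' @param classes true quality classes (coercible to [QUALITY_CLASSES]).
#' @param seed RNG seed for the optimizer's weight initialization.
#' @param decision_threshold probability cut used when featurizing new
#'   cases at prediction time.
#' @param channels channel set used when featurizing new cases.
#' @return An object of class `c("baseline_triage", "triage_predictor")`.
#' @export
fit_baseline_triage <- function(features, classes, seed = 1L,
                                decision_threshold = 0.5, channels = NULL) {
  X <- as.matrix(features)
  cls <- quality_factor(classes)
  if (nrow(X) != length(cls))
    stop("fit_baseline_triage: features and classes length mismatch")
  if (length(unique(as.character(cls))) < 2L)
    stop("fit_baseline_triage: need at least two classes represented")
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd); sd[sd < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2L, mu, `-`), 2L, sd, `/`)
  df <- data.frame(Xs, check.names = TRUE)
  df$.class <- factor(as.character(cls),
                      levels = intersect(QUALITY_CLASSES, as.character(cls)))
  fit <- with_seed(seed, nnet::multinom(.class ~ ., data = df, trace = FALSE,
                                        maxit = 500))
  structure(list(fit = fit, mu = mu, sd = sd,
                 feature_names = colnames(X),
                 levels = levels(df$.class),
                 decision_threshold = decision_threshold,
                 channels = channels),
            class = c("baseline_triage", "triage_predictor"))
}

#' Predict quality classes from triage feature rows
#'
#' @param predictor a fitted `baseline_triage` predictor.
#' @param features matrix/data.frame of feature rows matching the
#'   training columns.
#' @return List with `class` (ordered factor) and `scores` (matrix, one
#'   row per case, columns [QUALITY_CLASSES], rows summing to 1).
#' @export
triage_predict_features <- function(predictor, features) {
  stopifnot(inherits(predictor, "baseline_triage"))
  X <- as.matrix(features)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- X[, predictor$feature_names, drop = FALSE]
  Xs <- sweep(sweep(X, 2L, predictor$mu, `-`), 2L, predictor$sd, `/`)
  df <- data.frame(Xs, check.names = TRUE)
  pr <- stats::predict(predictor$fit, newdata = df, type = "probs")
  if (is.null(dim(pr))) {
    if (length(predictor$levels) == 2L) {
      # multinom collapses two-class output to P(second level)
      pr <- cbind(1 - pr, pr)
      colnames(pr) <- predictor$levels
      if (nrow(X) == 1L) pr <- pr[1L, , drop = FALSE]
    } else pr <- matrix(pr, nrow = 1L, dimnames = list(NULL, names(pr)))
  }
  full <- matrix(0, nrow = nrow(X), ncol = 3L,
                 dimnames = list(NULL, QUALITY_CLASSES))
  full[, colnames(pr)] <- pr
  full <- full / rowSums(full)
  cls <- quality_factor(QUALITY_CLASSES[max.col(full, ties.method = "first")])
  list(class = cls, scores = full)
}

#' @export
triage_predict.baseline_triage <- function(predictor, case, prob_map, ...) {
  f <- baseline_triage_features(case, prob_map,
                                decision_threshold = predictor$decision_threshold,
                                channels = predictor$channels)
  out <- triage_predict_features(predictor, matrix(f, nrow = 1L,
                                                   dimnames = list(NULL, names(f))))
  list(class = out$class[1L], scores = out$scores[1L, ])
}

# ---- classifier evaluation --------------------------------------------------

#' Three-class confusion matrix
#'
#' @param true_classes,predicted_classes equal-length vectors coercible
#'   to [QUALITY_CLASSES].
#' @return A 3x3 integer matrix of class `confusion_matrix3`; rows are
#'   true classes, columns predicted classes.
#' @export
confusion_matrix3 <- function(true_classes, predicted_classes) {
  t <- quality_factor(true_classes)
  p <- quality_factor(predicted_classes)
  if (length(t) != length(p))
    stop("confusion_matrix3: length mismatch between true and predicted")
  m <- table(true = t, predicted = p)
  structure(matrix(as.integer(m), nrow = 3L,
                   dimnames = list(true = QUALITY_CLASSES,
                                   predicted = QUALITY_CLASSES)),
            class = c("confusion_matrix3", "matrix"))
}

#' One-vs-rest metrics for one quality class
#'
#' Treating `target` as positive: sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, positive predictive value `TP/(TP+FP)`, negative
#' predictive value `TN/(TN+FN)`, and F-score (harmonic mean of
#' sensitivity and PPV). Ratios with a zero denominator are `NaN`.
#'
#' @param cm a [confusion_matrix3()] with positive total.
#' @param target one of [QUALITY_CLASSES].
#' @return Named list of proportions.
#' @export
class_metrics <- function(cm, target) {
  stopifnot(inherits(cm, "confusion_matrix3"))
  if (sum(cm) == 0L) stop("class_metrics: empty confusion matrix")
  target <- match.arg(target, QUALITY_CLASSES)
  tp <- cm[target, target]
  fn <- sum(cm[target, ]) - tp
  fp <- sum(cm[, target]) - tp
  tn <- sum(cm) - tp - fn - fp
  ratio <- function(a, b) if (a + b == 0) NaN else a / (a + b)
  sens <- ratio(tp, fn); spec <- ratio(tn, fp)
  ppv <- ratio(tp, fp); npv <- ratio(tn, fn)
  f <- if (is.finite(sens) && is.finite(ppv) && (sens + ppv) > 0)
    2 * sens * ppv / (sens + ppv) else NaN
  list(target = target, sensitivity = sens, specificity = spec,
       ppv = ppv, npv = npv, f_score = f)
}

#' One-vs-rest ROC AUC
#'
#' Area under the one-vs-rest ROC for the target class, computed from
#' the target-class scores with the midpoint (average-rank) tie
#' convention; equivalently the probability that a random positive
#' outranks a random negative, ties counted half.
#'
#' @param true_classes vector coercible to [QUALITY_CLASSES].
#' @param scores matrix of class scores (columns named by class) or a
#'   numeric vector of target-class scores.
#' @param target the positive class.
#' @return AUC in [0, 1].
#' @export
roc_auc_ovr <- function(true_classes, scores, target) {
  target <- match.arg(target, QUALITY_CLASSES)
  t <- quality_factor(true_classes)
  s <- if (is.matrix(scores) || is.data.frame(scores))
    as.numeric(as.matrix(scores)[, target]) else as.numeric(scores)
  if (length(s) != length(t)) stop("roc_auc_ovr: scores/classes length mismatch")
  pos <- t == target
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("roc_auc_ovr: need both positive and negative examples of ", target)
  r <- rank(s, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Accuracy and escalation summary of a triage confusion matrix
#'
#' Three proportions describing the practical safety of the triage:
#' overall accuracy; among misclassified cases, the fraction sent to a
#' class that still receives expert review (poor or adjust); and the
#' fraction of all cases either classified correctly or still reviewed.
#'
#' @param cm a [confusion_matrix3()].
#' @return Named list: `accuracy`, `still_reviewed_among_misclassified`
#'   (`NaN` when nothing is misclassified), `safe_fraction`.
#' @export
escalation_summary <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix3"))
  total <- sum(cm)
  if (total == 0L) stop("escalation_summary: empty confusion matrix")
  correct <- sum(diag(cm))
  mis <- total - correct
  off <- cm; diag(off) <- 0L
  mis_reviewed <- sum(off[, c("poor", "adjust")])
  list(accuracy = correct / total,
       still_reviewed_among_misclassified = if (mis > 0) mis_reviewed / mis else NaN,
       safe_fraction = (correct + mis_reviewed) / total)
}

#' Table of one-vs-rest metrics for all three classes
#'
#' @param cm a [confusion_matrix3()].
#' @param true_classes,scores optional: when given, adds a one-vs-rest
#'   AUC column via [roc_auc_ovr()].
#' @return data.frame, one row per class, columns `class`, `n`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `f_score` (and `auc`).
#' @export
triage_report <- function(cm, true_classes = NULL, scores = NULL) {
  rows <- lapply(QUALITY_CLASSES, function(cl) {
    m <- class_metrics(cm, cl)
    df <- data.frame(class = cl, n = sum(cm[cl, ]),
                     sensitivity = m$sensitivity, specificity = m$specificity,
                     ppv = m$ppv, npv = m$npv, f_score = m$f_score,
                     stringsAsFactors = FALSE)
    if (!is.null(true_classes) && !is.null(scores))
      df$auc <- roc_auc_ovr(true_classes, scores, cl)
    df
  })
  do.call(rbind, rows)
}
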
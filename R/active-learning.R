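# Staged active-learning orchestration: plateau-based checkpoint
# selection, pool scoring (oracle Dice or reference-free triage), label
# substitution above threshold, continued training, fixed-test-set
# evaluation.

#' Round plan for an active-learning experiment
#'
#' @param initial_n size of the initial ground-truth training set.
#' @param increments ordered vector of pool batch sizes, one per
#'   active-learning round (may be empty: plain training).
#' @param mode `"oracle"` (score pool predictions against ground truth)
#'   or `"triage"` (score with a reference-free quality predictor).
#' @param oracle_threshold Dice threshold tau in oracle mode: cases at
#'   or above it keep the model's prediction as label, cases below it
#'   get expert ground truth. 0.7 is the conventional good-overlap cut;
#'   0.8 aligns oracle mode with the triage acceptable class.
#' @param thresholds [triage_thresholds()] used in triage mode.
#' @return An object of class `round_plan`.
#' @export
round_plan <- function(initial_n, increments = integer(0),
                       mode = c("oracle", "triage"),
                       oracle_threshold = 0.7,
                       thresholds = triage_thresholds()) {
  mode <- match.arg(mode)
  initial_n <- as.integer(initial_n)
  increments <- as.integer(increments)
  if (initial_n < 1L) stop("round_plan: initial_n must be positive")
  if (length(increments) && any(increments < 1L))
    stop("round_plan: increments must be positive")
  if (oracle_threshold <= 0 || oracle_threshold >= 1)
    stop("round_plan: oracle_threshold must lie in (0, 1)")
  structure(list(initial_n = initial_n, increments = increments,
                 mode = mode, oracle_threshold = oracle_threshold,
                 thresholds = thresholds), class = "round_plan")
}

#' Detect the validation-metric plateau epoch
#'
#' Returns the smallest (1-based) epoch `e` such that the trailing
#' window `[e - window + 1, e]` has range at most `epsilon` and the
#' metric has not dropped by more than `epsilon` across the window. If
#' no window qualifies, the last epoch is returned with a warning: the
#' curve never plateaued.
#'
#' @param history numeric vector of per-epoch validation metric values,
#'   or a training-history data.frame with a `val_dice` column.
#' @param window window length in epochs (default 5).
#' @param epsilon maximum metric range within the window (default 0.005).
#' @return 1-based epoch index.
#' @export
detect_plateau <- function(history, window = 5L, epsilon = 0.005) {
  h <- if (is.data.frame(history)) history$val_dice else as.numeric(history)
  n <- length(h)
  if (n < window) stop("detect_plateau: history shorter than the window")
  for (e in window:n) {
    w <- h[(e - window + 1L):e]
    if (max(w) - min(w) <= epsilon && h[e] >= w[1L] - epsilon) return(e)
  }
  warning("detect_plateau: no plateau found; returning the last epoch")
  n
}

#' Score a pool against ground truth (oracle mode)
#'
#' Dice of the model's prediction versus ground truth for each pool
#' case.
#'
#' @param model a fitted segmenter.
#' @param pool list of [case_bundle]s carrying ground truth.
#' @param predictions optional named list of [segmentation_result]s to
#'   reuse instead of re-predicting.
#' @return Named numeric vector of Dice scores, one per case.
#' @export
score_pool_oracle <- function(model, pool, predictions = NULL) {
  ids <- vapply(pool, function(c) c$case_id, character(1))
  stats::setNames(vapply(pool, function(case) {
    if (is.null(case$truth_mask))
      stop("score_pool_oracle: case ", case$case_id, " has no ground truth")
    pred <- predictions[[case$case_id]]
    if (is.null(pred)) pred <- seg_predict(model, case)
    truth <- if (case$multilabel) merge_labels(case$truth_mask) else case$truth_mask
    dice(pred$mask, truth)
  }, numeric(1)), ids)
}

#' Score a pool with a reference-free triage predictor (triage mode)
#'
#' Predicts a quality class per pool case from the case channels and
#' the segmenter's probability map; ground truth is never consulted.
#'
#' @param triage a triage predictor (see [triage_predict()]).
#' @param model a fitted segmenter.
#' @param pool list of [case_bundle]s (truth not required).
#' @param predictions optional named list of [segmentation_result]s.
#' @return Named character vector of quality classes.
#' @export
score_pool_triage <- function(triage, model, pool, predictions = NULL) {
  ids <- vapply(pool, function(c) c$case_id, character(1))
  stats::setNames(vapply(pool, function(case) {
    pred <- predictions[[case$case_id]]
    if (is.null(pred)) pred <- seg_predict(model, case)
    out <- triage_predict(triage, case, pred$prob_map)
    as.character(out$class)
  }, character(1)), ids)
}

#' Build the augmented training set for one round
#'
#' Appends one record per pool case to the current training set. A case
#' gets its expert ground-truth label when the model is judged to have
#' struggled -- oracle mode: Dice below `oracle_threshold`; triage
#' mode: predicted class other than acceptable -- and the model's own
#' predicted mask otherwise. Order is the pool order; no case may
#' appear twice.
#'
#' @param current list of existing [training_record]s.
#' @param pool list of [case_bundle]s in batch order.
#' @param predictions named list of [segmentation_result]s covering the
#'   pool.
#' @param scores named Dice scores (oracle mode) or `NULL`.
#' @param classes named quality classes (triage mode) or `NULL`.
#' @param oracle_threshold Dice threshold tau (oracle mode).
#' @return List with `records` (augmented list of [training_record]s)
#'   and `decisions` (data.frame: `case_id`, `score` or `class`,
#'   `mask_source`).
#' @export
build_augmented_set <- function(current, pool, predictions, scores = NULL,
                                classes = NULL, oracle_threshold = 0.7) {
  if (is.null(scores) == is.null(classes))
    stop("build_augmented_set: provide exactly one of scores or classes")
  cur_ids <- vapply(current, function(r) r$case$case_id, character(1))
  pool_ids <- vapply(pool, function(c) c$case_id, character(1))
  dup <- c(pool_ids[duplicated(pool_ids)], intersect(pool_ids, cur_ids))
  if (length(dup))
    stop("build_augmented_set: duplicate case id(s): ",
         paste(unique(dup), collapse = ", "))
  records <- current
  rows <- list()
  for (case in pool) {
    id <- case$case_id
    pred <- predictions[[id]]
    if (is.null(pred)) stop("build_augmented_set: missing prediction for ", id)
    if (!is.null(scores)) {
      if (is.na(scores[id])) stop("build_augmented_set: missing score for ", id)
      use_gt <- scores[[id]] < oracle_threshold
      rows[[id]] <- data.frame(case_id = id, score = scores[[id]],
                               stringsAsFactors = FALSE)
    } else {
      if (!id %in% names(classes))
        stop("build_augmented_set: missing class for ", id)
      use_gt <- as.character(classes[[id]]) != "acceptable"
      rows[[id]] <- data.frame(case_id = id, class = as.character(classes[[id]]),
                               stringsAsFactors = FALSE)
    }
    if (use_gt) {
      if (is.null(case$truth_mask))
        stop("build_augmented_set: ground truth required for ", id)
      mask <- if (case$multilabel) merge_labels(case$truth_mask) else case$truth_mask
      rec <- training_record(case, mask, "ground_truth")
    } else {
      rec <- training_record(case, pred$mask, "model_prediction")
    }
    rows[[id]]$mask_source <- rec$mask_source
    records <- c(records, list(rec))
  }
  list(records = records,
       decisions = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Manual annotation burden
#'
#' Fraction of training records whose label came from expert ground
#' truth rather than a substituted model prediction.
#'
#' @param records non-empty list of [training_record]s.
#' @return Proportion in [0, 1].
#' @export
manual_burden <- function(records) {
  if (length(records) == 0L) stop("manual_burden: empty record list")
  mean(vapply(records, function(r) r$mask_source == "ground_truth", logical(1)))
}

#' Run a staged active-learning experiment
#'
#' Implements the full loop: seeded cohort split (fixed test set, a
#' validation set for the training curve, initial training ids and a
#' shuffled pool); initial fit on `initial_n` ground-truth records;
#' then, per round: restore the model to its validation-Dice plateau
#' checkpoint, predict the next pool batch, score it (oracle Dice or
#' reference-free triage), substitute labels by the threshold rule,
#' continue training on the union, and evaluate on the fixed test set.
#'
#' In triage mode, pool ground truth is consulted only for cases routed
#' to ground truth (emulating an expert segmenting on demand); every
#' such access is counted in the round outcome (`n_truth_accesses`) so
#' the reference-free constraint is auditable. Post-hoc test evaluation
#' always uses truth.
#'
#' @param cohort list of preprocessed [case_bundle]s with ground truth.
#' @param plan a [round_plan].
#' @param segmenter_factory zero-argument function returning an
#'   unfitted segmenter.
#' @param triage_factory triage predictor, or function(model) returning
#'   one; required in triage mode. Train reference-free predictors on a
#'   labelled subset disjoint from this cohort's pool.
#' @param seed experiment seed driving the split, batch order and all
#'   model fitting.
#' @param test_n fixed test-set size.
#' @param validation_fraction validation fraction of non-test ids.
#' @param epochs_initial epochs for the initial fit.
#' @param epochs_round epochs of continued training per round.
#' @param plateau_window,plateau_epsilon see [detect_plateau()].
#' @return An object of class `al_experiment`: list with `split`,
#'   `plan`, `initial_history`, `initial_test`, `rounds` (list of round
#'   outcomes), `records` (final training records), `model`.
#' @export
run_experiment <- function(cohort, plan, segmenter_factory,
                           triage_factory = NULL, seed = 1L,
                           test_n = 10L, validation_fraction = 0.08,
                           epochs_initial = 12L, epochs_round = 6L,
                           plateau_window = 5L, plateau_epsilon = 0.005) {
  stopifnot(inherits(plan, "round_plan"))
  if (plan$mode == "triage" && is.null(triage_factory))
    stop("run_experiment: triage mode requires a triage factory")
  ids <- vapply(cohort, function(c) c$case_id, character(1))
  if (anyDuplicated(ids)) stop("run_experiment: duplicate case ids in cohort")
  by_id <- stats::setNames(cohort, ids)
  split <- split_cohort(ids, test_n = test_n,
                        validation_fraction = validation_fraction,
                        seed = seed, initial_n = plan$initial_n)
  if (sum(plan$increments) > length(split$pool_ids))
    stop("run_experiment: plan infeasible; pool has ",
         length(split$pool_ids), " cases but increments need ",
         sum(plan$increments))
  validation <- by_id[split$validation_ids]
  test_cases <- by_id[split$test_ids]

  gt_record <- function(case) {
    if (is.null(case$truth_mask))
      stop("run_experiment: case ", case$case_id, " has no ground truth")
    mask <- if (case$multilabel) merge_labels(case$truth_mask) else case$truth_mask
    training_record(case, mask, "ground_truth")
  }
  records <- lapply(by_id[split$train_ids], gt_record)
  names(records) <- NULL

  model <- segmenter_factory()
  history <- seg_fit(model, records, validation = validation,
                     epochs = epochs_initial, seed = seed)
  triage <- NULL
  if (plan$mode == "triage") {
    triage <- if (is.function(triage_factory)) triage_factory(model) else triage_factory
  }

  eval_test <- function() {
    if (length(test_cases) == 0L) return(NULL)
    reports <- do.call(rbind, lapply(test_cases, function(case) {
      pred <- seg_predict(model, case)
      truth <- if (case$multilabel) merge_labels(case$truth_mask) else case$truth_mask
      evaluate_case(pred$mask, truth, case_id = case$case_id,
                    spacing = case$channels[[1L]]$spacing)
    }))
    rownames(reports) <- NULL
    list(reports = reports, summary = summarize_metrics(reports))
  }
  initial_test <- eval_test()

  rounds <- list()
  pool_cursor <- 0L
  for (k in seq_along(plan$increments)) {
    # checkpoint: score the pool from the plateau iteration, not the last
    plateau_epoch <- NA_integer_
    if (nrow(history) >= plateau_window && !all(is.na(history$val_dice))) {
      plateau_epoch <- detect_plateau(history, window = plateau_window,
                                      epsilon = plateau_epsilon)
      seg_restore(model, plateau_epoch)
      history <- history[history$epoch <= plateau_epoch, , drop = FALSE]
    }
    batch_ids <- split$pool_ids[pool_cursor + seq_len(plan$increments[k])]
    pool_cursor <- pool_cursor + plan$increments[k]
    batch <- by_id[batch_ids]
    predictions <- lapply(batch, function(case) seg_predict(model, case))
    names(predictions) <- batch_ids
    if (plan$mode == "oracle") {
      scores <- score_pool_oracle(model, batch, predictions)
      aug <- build_augmented_set(records, batch, predictions, scores = scores,
                                 oracle_threshold = plan$oracle_threshold)
    } else {
      classes <- score_pool_triage(triage, model, batch, predictions)
      aug <- build_augmented_set(records, batch, predictions, classes = classes)
    }
    new_records <- aug$records[(length(records) + 1L):length(aug$records)]
    records <- aug$records
    history <- seg_continue(model, new_records, epochs = epochs_round,
                            seed = seed + k, validation = validation)
    test_eval <- eval_test()
    n_gt <- sum(aug$decisions$mask_source == "ground_truth")
    rounds[[k]] <- list(
      round = k,
      plateau_epoch = plateau_epoch,
      decisions = aug$decisions,
      n_ground_truth = n_gt,
      n_prediction = nrow(aug$decisions) - n_gt,
      n_truth_accesses = if (plan$mode == "triage") n_gt else nrow(aug$decisions),
      history = history,
      test = test_eval)
  }
  structure(list(split = split, plan = plan,
                 initial_history = history[seq_len(min(epochs_initial,
                                                       nrow(history))), ,
                                           drop = FALSE],
                 initial_test = initial_test,
                 rounds = rounds, records = records, model = model),
            class = "al_experiment")
}

#' @export
print.al_experiment <- function(x, ...) {
  cat(sprintf("<al_experiment> mode %s: initial %d + increments [%s]\n",
              x$plan$mode, x$plan$initial_n,
              paste(x$plan$increments, collapse = ", ")))
  mean_dice <- function(tst) {
    if (is.null(tst)) return(NA_real_)
    tst$summary$mean[tst$summary$metric == "dice"]
  }
  cat(sprintf("  initial mean test Dice: %.3f\n", mean_dice(x$initial_test)))
  for (r in x$rounds)
    cat(sprintf("  round %d: %d ground truth / %d prediction; mean test Dice %.3f\n",
                r$round, r$n_ground_truth, r$n_prediction, mean_dice(r$test)))
  cat(sprintf("  manual burden: %.3f\n", manual_burden(x$records)))
  invisible(x)
}
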
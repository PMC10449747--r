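test_that("bin_quality applies the half-open class boundaries", {
  th <- triage_thresholds()
  expect_equal(as.character(bin_quality(0.55, th)), "poor")
  expect_equal(as.character(bin_quality(0.70, th)), "adjust")
  expect_equal(as.character(bin_quality(0.85, th)), "acceptable")
  # boundary values fall upward under the half-open convention
  expect_equal(as.character(bin_quality(0.60, th)), "adjust")
  expect_equal(as.character(bin_quality(0.80, th)), "acceptable")
  expect_error(bin_quality(1.2, th), "0, 1")
  expect_error(triage_thresholds(0.8, 0.6), "lower < upper")
  # monotone: a higher Dice never maps to a lower class
  withr::local_seed(23)
  d <- sort(stats::runif(100))
  cls <- bin_quality(d, th)
  expect_true(all(diff(as.integer(cls)) >= 0))
})

test_that("confusion_matrix3 counts true-by-predicted pairs", {
  cm <- t100_confusion()
  expect_equal(sum(cm), 100L)
  expect_equal(sum(diag(cm)), 82L)
  expect_equal(unname(cm["poor", ]), c(3L, 1L, 0L))
  expect_equal(unname(cm["adjust", ]), c(0L, 6L, 5L))
  expect_equal(unname(cm["acceptable", ]), c(0L, 12L, 73L))
  empty <- confusion_matrix3(character(0), character(0))
  expect_true(all(empty == 0L))
  perfect <- confusion_matrix3(rep(QUALITY_CLASSES, 3), rep(QUALITY_CLASSES, 3))
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0L))
  expect_error(confusion_matrix3("poor", c("poor", "adjust")), "length")
  expect_error(confusion_matrix3("bad", "poor"), "unknown quality class")
})

test_that("class_metrics follows the one-vs-rest contingency identities", {
  diagm <- confusion_matrix3(rep(QUALITY_CLASSES, 4), rep(QUALITY_CLASSES, 4))
  for (cl in QUALITY_CLASSES) {
    m <- class_metrics(diagm, cl)
    expect_equal(m$sensitivity, 1); expect_equal(m$specificity, 1)
    expect_equal(m$ppv, 1); expect_equal(m$f_score, 1)
  }
  # row/diagonal bookkeeping on random matrices
  withr::local_seed(29)
  for (rep in 1:10) {
    t <- sample(QUALITY_CLASSES, 40, TRUE)
    p <- sample(QUALITY_CLASSES, 40, TRUE)
    cm <- confusion_matrix3(t, p)
    tps <- vapply(QUALITY_CLASSES, function(cl) cm[cl, cl], integer(1))
    expect_equal(sum(tps), sum(diag(cm)))
    es <- escalation_summary(cm)
    expect_equal(es$accuracy, sum(diag(cm)) / sum(cm))
    for (cl in QUALITY_CLASSES) {
      m <- class_metrics(cm, cl)
      if (is.finite(m$sensitivity))
        expect_equal(m$sensitivity, cm[cl, cl] / sum(cm[cl, ]))
      if (is.finite(m$ppv))
        expect_equal(m$ppv, cm[cl, cl] / sum(cm[, cl]))
    }
  }
  expect_error(class_metrics(confusion_matrix3(character(0), character(0)),
                             "poor"), "empty")
})

test_that("escalation_summary handles perfect and empty classification", {
  diagm <- confusion_matrix3(rep(QUALITY_CLASSES, 2), rep(QUALITY_CLASSES, 2))
  es <- escalation_summary(diagm)
  expect_equal(es$accuracy, 1)
  expect_true(is.nan(es$still_reviewed_among_misclassified))
  expect_equal(es$safe_fraction, 1)
})

test_that("roc_auc_ovr matches the pair-counting oracle and its landmarks", {
  # perfectly separating scores
  t <- c(rep("acceptable", 5), rep("poor", 5))
  s <- c(rep(0.9, 5), rep(0.1, 5))
  expect_equal(roc_auc_ovr(t, s, "acceptable"), 1)
  # scores independent of truth hover near 0.5
  withr::local_seed(31)
  t2 <- sample(QUALITY_CLASSES, 200, TRUE)
  s2 <- stats::runif(200)
  expect_lt(abs(roc_auc_ovr(t2, s2, "acceptable") - 0.5), 0.1)
  # brute-force pair oracle on random small instances with ties
  for (rep in 1:30) {
    n <- sample(5:50, 1)
    t3 <- sample(c("poor", "acceptable"), n, TRUE)
    if (length(unique(t3)) < 2) next
    s3 <- sample(seq(0, 1, by = 0.25), n, TRUE)   # coarse grid forces ties
    got <- roc_auc_ovr(t3, s3, "acceptable")
    expect_equal(got, oracle_auc(t3 == "acceptable", s3), tolerance = 1e-12)
  }
  expect_error(roc_auc_ovr(rep("poor", 5), stats::runif(5), "poor"),
               "both positive and negative")
})

test_that("triage features capture confidence, uncertainty and fragmentation", {
  d <- c(16, 16, 10)
  case <- generate_phantom_case(phantom_config(shape = as.integer(d),
                                               radius_range = c(2, 3),
                                               seed = 5L), 1L)
  zero <- vg(array(0, dim = d))
  f0 <- baseline_triage_features(case, zero)
  expect_equal(unname(f0["volume_fraction"]), 0)
  expect_equal(unname(f0["uncertainty_mass"]), 0)
  expect_equal(unname(f0["n_components"]), 0)
  # crisp binary map: no entropy, no uncertainty mass
  crisp <- array(0, dim = d); crisp[6:10, 6:10, 4:6] <- 1
  f1 <- baseline_triage_features(case, vg(crisp))
  expect_equal(unname(f1["fg_mean_entropy"]), 0)
  expect_equal(unname(f1["uncertainty_mass"]), 0)
  expect_equal(unname(f1["fg_mean_prob"]), 1)
  expect_equal(unname(f1["n_components"]), 1)
  # blurring the same mask strictly increases the uncertainty mass
  blurred <- alseg:::gaussian_smooth3(crisp, 1.5)
  f2 <- baseline_triage_features(case, vg(pmin(pmax(blurred, 0), 1)))
  expect_gt(f2[["uncertainty_mass"]], f1[["uncertainty_mass"]])
  # two disconnected blobs are counted as two components
  two <- array(0, dim = d)
  two[2:4, 2:4, 2:4] <- 1; two[10:12, 10:12, 6:8] <- 1
  f3 <- baseline_triage_features(case, vg(two))
  expect_equal(unname(f3["n_components"]), 2)
})

test_that("the baseline triage classifier separates clean feature clusters", {
  withr::local_seed(37)
  n <- 30
  feats <- rbind(
    cbind(stats::rnorm(n, 0), stats::rnorm(n, 0)),
    cbind(stats::rnorm(n, 6), stats::rnorm(n, 0)),
    cbind(stats::rnorm(n, 0), stats::rnorm(n, 6)))
  colnames(feats) <- c("f1", "f2")
  cls <- rep(QUALITY_CLASSES, each = n)
  fit <- fit_baseline_triage(feats, cls, seed = 1)
  pred <- triage_predict_features(fit, feats)
  expect_equal(mean(as.character(pred$class) == cls), 1)
  expect_equal(rowSums(pred$scores), rep(1, nrow(feats)), tolerance = 1e-9)
  # determinism under a fixed seed
  fit2 <- fit_baseline_triage(feats, cls, seed = 1)
  pred2 <- triage_predict_features(fit2, feats)
  expect_identical(as.character(pred$class), as.character(pred2$class))
  expect_error(fit_baseline_triage(feats[1:n, ], cls[1:n]), "two classes")
})

test_that("the oracle triage predictor reproduces Dice binning exactly", {
  cohort <- make_cohort(6, seed = 111, shape = c(20L, 20L, 14L),
                        difficulty_range = c(0.05, 0.95))
  model <- truth_segmenter()
  pred <- oracle_triage_predictor()
  for (case in cohort) {
    res <- seg_predict(model, case)
    out <- triage_predict(pred, case, res$prob_map)
    d <- dice(res$mask, merge_labels(case$truth_mask))
    expect_identical(as.character(out$class),
                     as.character(bin_quality(d)))
    expect_equal(sum(out$scores), 1, tolerance = 1e-9)
    expect_equal(as.character(out$class),
                 names(which.max(out$scores)))
  }
})

test_that("triage_report assembles per-class rows with optional AUC", {
  cm <- t100_confusion()
  rep1 <- triage_report(cm)
  expect_equal(rep1$class, QUALITY_CLASSES)
  expect_equal(rep1$n, c(4L, 11L, 85L))
  expect_false("auc" %in% names(rep1))
  withr::local_seed(41)
  t <- sample(QUALITY_CLASSES, 60, TRUE)
  scores <- matrix(stats::runif(180), ncol = 3,
                   dimnames = list(NULL, QUALITY_CLASSES))
  scores <- scores / rowSums(scores)
  rep2 <- triage_report(confusion_matrix3(t, t), t, scores)
  expect_true(all(rep2$auc >= 0 & rep2$auc <= 1))
})
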
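# The reference segmenter is exercised on small phantom cohorts; shapes
# are kept small so the whole file runs in well under a minute.

test_that("segmentation_result derives the mask from the probability map", {
  withr::local_seed(19)
  d <- c(10, 8, 6)
  pm <- vg(array(stats::runif(prod(d)), dim = d))
  res <- segmentation_result("x", pm, threshold = 0.5)
  expect_identical(res$mask$data != 0, pm$data >= 0.5)
  res7 <- segmentation_result("x", pm, threshold = 0.7)
  expect_identical(res7$mask$data != 0, pm$data >= 0.7)
  bad <- vg(array(seq(-0.1, 1, length.out = prod(d)), dim = d))
  expect_error(segmentation_result("x", bad), "outside")
})

test_that("training_record validates mask shape and source tag", {
  case <- generate_phantom_case(phantom_config(shape = c(16L, 16L, 12L),
                                               radius_range = c(2, 4),
                                               seed = 1L), 1L)
  wt <- merge_labels(case$truth_mask)
  rec <- training_record(case, wt, "model_prediction")
  expect_equal(rec$mask_source, "model_prediction")
  expect_error(training_record(case, vg(array(0L, dim = c(8, 8, 6)))),
               "shape")
  expect_error(training_record(case, wt, "expert"), "arg")
})

test_that("reference segmenter learns easy phantoms and improves over epochs", {
  cohort <- make_cohort(14, seed = 101, shape = c(28L, 28L, 20L),
                        difficulty = 0.15)
  recs <- gt_records(cohort[1:10])
  model <- reference_voxel_segmenter()
  expect_false(seg_is_fitted(model))
  hist <- seg_fit(model, recs, validation = cohort[11:12], epochs = 8,
                  seed = 101)
  expect_true(seg_is_fitted(model))
  expect_equal(hist$epoch, 1:8)
  expect_gte(hist$val_dice[8], hist$val_dice[1])
  expect_gt(hist$val_dice[8], 0.7)
  # held-out performance on a high-contrast cohort
  test_dice <- vapply(cohort[13:14], function(c)
    dice(seg_predict(model, c)$mask, merge_labels(c$truth_mask)), numeric(1))
  expect_gt(mean(test_dice), 0.7)
  # prediction invariants
  res <- seg_predict(model, cohort[[13]])
  expect_true(all(res$prob_map$data >= 0 & res$prob_map$data <= 1))
  expect_identical(res$mask$data != 0, res$prob_map$data >= 0.5)
})

test_that("validation Dice improves over epochs on a non-trivial cohort", {
  cohort <- make_cohort(12, seed = 110, shape = c(28L, 28L, 20L),
                        difficulty = 0.6)
  model <- reference_voxel_segmenter()
  hist <- seg_fit(model, gt_records(cohort[1:10]), validation = cohort[11:12],
                  epochs = 8, seed = 110)
  expect_gt(hist$val_dice[8], hist$val_dice[1])
})

test_that("fitting is deterministic given data and seed", {
  cohort <- make_cohort(6, seed = 102, shape = c(24L, 24L, 16L))
  recs <- gt_records(cohort[1:5])
  m1 <- reference_voxel_segmenter()
  m2 <- reference_voxel_segmenter()
  h1 <- seg_fit(m1, recs, validation = cohort[6], epochs = 5, seed = 7)
  h2 <- seg_fit(m2, recs, validation = cohort[6], epochs = 5, seed = 7)
  expect_identical(h1, h2)
  p1 <- seg_predict(m1, cohort[[6]])
  p2 <- seg_predict(m2, cohort[[6]])
  expect_identical(p1$prob_map$data, p2$prob_map$data)
})

test_that("a trained model predicts a near-empty mask on a lesion-free phantom", {
  cohort <- make_cohort(10, seed = 103, shape = c(24L, 24L, 16L),
                        difficulty = 0.2)
  model <- reference_voxel_segmenter()
  seg_fit(model, gt_records(cohort), epochs = 8, seed = 3)
  blank <- preprocess_cohort(list(generate_phantom_case(
    phantom_config(shape = c(24L, 24L, 16L), lesion_free_fraction = 1,
                   radius_range = c(2, 5), seed = 104L), 1L)))$cohort[[1L]]
  res <- seg_predict(model, blank)
  expect_lt(mean(res$mask$data), 0.01)
})

test_that("continue_fit resumes on the union and rejects misuse", {
  cohort <- make_cohort(10, seed = 105, shape = c(24L, 24L, 16L))
  model <- reference_voxel_segmenter()
  expect_error(seg_continue(model, gt_records(cohort[1:2])), "not been fitted")
  expect_error(seg_fit(model, list()), "empty")
  seg_fit(model, gt_records(cohort[1:4]), validation = cohort[9:10],
          epochs = 5, seed = 1)
  # duplicate case ids are rejected
  expect_error(seg_continue(model, gt_records(cohort[4])), "already")
  h <- seg_continue(model, gt_records(cohort[5:8]), epochs = 4, seed = 2,
                    validation = cohort[9:10])
  expect_equal(nrow(h), 9)
  expect_equal(h$epoch, 1:9)
  # continued training on more ground truth does not collapse validation Dice
  expect_gt(h$val_dice[9], h$val_dice[5] - 0.1)
})

test_that("seg_restore rolls the model back to an epoch checkpoint", {
  cohort <- make_cohort(6, seed = 106, shape = c(24L, 24L, 16L))
  model <- reference_voxel_segmenter()
  seg_fit(model, gt_records(cohort[1:5]), validation = cohort[6],
          epochs = 6, seed = 1)
  full_pred <- seg_predict(model, cohort[[6]])$prob_map$data
  w6 <- model$env$coef
  seg_restore(model, 3)
  expect_equal(length(model$env$snapshots), 3L)
  expect_equal(max(model$env$history$epoch), 3L)
  restored_pred <- seg_predict(model, cohort[[6]])$prob_map$data
  expect_false(identical(restored_pred, full_pred))
  expect_identical(model$env$coef, model$env$snapshots[[3L]])
  expect_error(seg_restore(model, 10), "no snapshot")
  # restoring a mock is a harmless no-op
  expect_silent(seg_restore(truth_segmenter(), 5))
})

test_that("the mask-source tag is metadata and does not affect optimization", {
  cohort <- make_cohort(5, seed = 107, shape = c(24L, 24L, 16L))
  as_source <- function(src) lapply(cohort, function(c)
    training_record(c, merge_labels(c$truth_mask), src))
  m1 <- reference_voxel_segmenter(); m2 <- reference_voxel_segmenter()
  seg_fit(m1, as_source("ground_truth"), epochs = 4, seed = 9)
  seg_fit(m2, as_source("model_prediction"), epochs = 4, seed = 9)
  expect_identical(m1$env$coef, m2$env$coef)
})

test_that("model state round-trips through the serialized file", {
  cohort <- make_cohort(6, seed = 108, shape = c(24L, 24L, 16L))
  model <- reference_voxel_segmenter()
  seg_fit(model, gt_records(cohort[1:5]), epochs = 4, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  save_segmenter(model, path)
  back <- load_segmenter(path)
  expect_equal(back$env$coef, model$env$coef)
  p1 <- seg_predict(model, cohort[[6]])$prob_map$data
  p2 <- seg_predict(back, cohort[[6]])$prob_map$data
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("feature extraction is constant on constant volumes and validates channels", {
  d <- c(12, 10, 8)
  const <- case_bundle("flat", list(T1c = vg(array(0.4, dim = d)),
                                    T2 = vg(array(0.4, dim = d)),
                                    FLAIR = vg(array(0.4, dim = d))))
  X <- alseg:::voxel_features(const, voxel_seg_config())
  for (col in grep("_s", colnames(X), value = TRUE))
    expect_lt(stats::sd(X[, col]), 0.35)   # only edge effects vary
  model <- reference_voxel_segmenter(voxel_seg_config(channels = c("T1", "T2")))
  cohort <- make_cohort(2, seed = 109, shape = c(16L, 16L, 12L))
  no_t1 <- case_bundle("x", cohort[[1]]$channels[c("T2", "FLAIR")])
  expect_error(seg_fit(model, list(training_record(
    no_t1, vg(array(0L, dim = dim(no_t1$channels[[1]]))))),
    epochs = 2, seed = 1), "lacks channel")
})
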
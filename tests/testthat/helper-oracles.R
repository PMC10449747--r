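# Independent brute-force oracles used to cross-check the package's
# metric implementations, plus small fixture builders. The oracles are
# deliberately naive (explicit loops, no shared code with the package
# internals beyond the public mask containers).

# Overlap counts by explicit voxelwise loop over linear indices.
oracle_overlap <- function(p, t) {
  np <- 0L; nt <- 0L; ni <- 0L; nu <- 0L
  for (i in seq_along(p)) {
    a <- p[i] != 0; b <- t[i] != 0
    if (a) np <- np + 1L
    if (b) nt <- nt + 1L
    if (a && b) ni <- ni + 1L
    if (a || b) nu <- nu + 1L
  }
  list(np = np, nt = nt, ni = ni, nu = nu)
}

oracle_dice <- function(p, t) {
  o <- oracle_overlap(p, t)
  if (o$np + o$nt == 0L) return(1)
  2 * o$ni / (o$np + o$nt)
}

oracle_jaccard <- function(p, t) {
  o <- oracle_overlap(p, t)
  if (o$nu == 0L) return(1)
  o$ni / o$nu
}

# Boundary voxel coordinates by explicit neighbor checks (6-connectivity;
# grid edges count as background).
oracle_boundary <- function(m) {
  d <- dim(m)
  out <- NULL
  idx <- which(m != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    on_bnd <- FALSE
    for (axis in 1:3) for (dir in c(-1L, 1L)) {
      nb <- v; nb[axis] <- nb[axis] + dir
      if (nb[axis] < 1L || nb[axis] > d[axis] ||
          m[nb[1L], nb[2L], nb[3L]] == 0) on_bnd <- TRUE
    }
    if (on_bnd) out <- rbind(out, v)
  }
  out
}

# Dubuisson-Jain modified Hausdorff by all-pairs distances.
oracle_mhd <- function(p, t, spacing = c(1, 1, 1)) {
  A <- oracle_boundary(p); B <- oracle_boundary(t)
  dmat <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    dmat[i, j] <- sqrt(sum(((A[i, ] - B[j, ]) * spacing)^2))
  max(mean(apply(dmat, 1L, min)), mean(apply(dmat, 2L, min)))
}

# Classical (max-min) Hausdorff on the same boundary sets.
oracle_hausdorff <- function(p, t, spacing = c(1, 1, 1)) {
  A <- oracle_boundary(p); B <- oracle_boundary(t)
  dmat <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    dmat[i, j] <- sqrt(sum(((A[i, ] - B[j, ]) * spacing)^2))
  max(max(apply(dmat, 1L, min)), max(apply(dmat, 2L, min)))
}

# AUC by concordant-pair counting with half-credit for ties.
oracle_auc <- function(labels, scores) {
  pos <- which(labels); neg <- which(!labels)
  total <- 0
  for (i in pos) for (j in neg) {
    if (scores[i] > scores[j]) total <- total + 1
    else if (scores[i] == scores[j]) total <- total + 0.5
  }
  total / (length(pos) * length(neg))
}

# Random logical mask with foreground probability p.
random_mask <- function(dims, p = 0.3) {
  array(stats::runif(prod(dims)) < p, dim = dims)
}

# Random connected-ish blob mask: a ball at a random center.
random_blob <- function(dims, rmax = 3) {
  ctr <- sapply(dims, function(n) sample(seq_len(n), 1L))
  r <- stats::runif(1, 1, rmax)
  co <- list(x = slice.index(array(0, dims), 1L),
             y = slice.index(array(0, dims), 2L),
             z = slice.index(array(0, dims), 3L))
  (co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2 <= r^2
}

# Wrap an array as a unit-spacing volume_grid.
vg <- function(a, spacing = c(1, 1, 1)) volume_grid(a, spacing)

# Small preprocessed phantom cohort (shared shapes keep tests fast);
# lesion radii are scaled down to fit the reduced grids.
test_radius_range <- function(shape) {
  m <- min(shape)
  c(max(2L, m %/% 6L), max(3L, m %/% 3L))
}

make_cohort <- function(n, seed, shape = c(32L, 32L, 24L), difficulty = NULL,
                        difficulty_range = NULL, ...) {
  cfg <- phantom_config(shape = shape, n_cases = n,
                        difficulty = if (is.null(difficulty)) 0.5 else difficulty,
                        difficulty_range = difficulty_range, seed = seed,
                        radius_range = test_radius_range(shape), ...)
  preprocess_cohort(generate_cohort(cfg)$cases)$cohort
}

# Ground-truth training records for a cohort.
gt_records <- function(cohort) {
  recs <- lapply(cohort, function(c)
    training_record(c, merge_labels(c$truth_mask), "ground_truth"))
  names(recs) <- NULL
  recs
}

# Mock segmenter that returns the (merged) ground truth as a crisp
# probability map.
truth_segmenter <- function() {
  manual_segmenter(function(case) {
    wt <- merge_labels(case$truth_mask)
    volume_grid(array(as.numeric(wt$data != 0), dim = dim(wt$data)),
                wt$spacing)
  }, tag = "truth-mock")
}

# Mock segmenter that always returns an empty probability map.
empty_segmenter <- function() {
  manual_segmenter(function(case) {
    d <- dim(case$channels[[1L]])
    volume_grid(array(0, dim = d), case$channels[[1L]]$spacing)
  }, tag = "empty-mock")
}

# Triage mock that always answers with one fixed class.
canned_triage <- function(cls = "acceptable") {
  structure(list(cls = cls),
            class = c("canned_triage", "triage_predictor"))
}

triage_predict.canned_triage <- function(predictor, case, prob_map, ...) {
  scores <- stats::setNames(as.numeric(QUALITY_CLASSES == predictor$cls),
                            QUALITY_CLASSES)
  list(class = factor(predictor$cls, levels = QUALITY_CLASSES, ordered = TRUE),
       scores = scores)
}
.S3method("triage_predict", "canned_triage", triage_predict.canned_triage)

# The three-class confusion matrix printed for the T100 test set:
# rows true poor/adjust/acceptable, columns predicted.
t100_confusion <- function() {
  confusion_matrix3(
    true_classes = rep(c("poor", "adjust", "acceptable"), times = c(4, 11, 85)),
    predicted_classes = c(rep("poor", 3), "adjust",
                          rep("adjust", 6), rep("acceptable", 5),
                          rep("adjust", 12), rep("acceptable", 73)))
}
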
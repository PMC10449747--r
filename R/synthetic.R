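# Seeded generator of multi-channel brain lesion phantoms: an ellipsoidal
# "brain" containing nested three-compartment lesions (necrotic core,
# enhancing rim, edema) with channel-specific contrast and additive noise.

#' Phantom cohort configuration
#'
#' Parameters of the synthetic BraTS-like cohort generator. Lesions are
#' nested deformed ellipsoids -- necrotic core inside an enhancing rim
#' inside edema -- labelled with the BraTS dialect (1 = necrotic core,
#' 2 = edema, 4 = enhancing tumor), so the default [label_policy()]
#' applies unchanged. Each channel adds compartment-specific contrast to
#' a base tissue intensity; Gaussian noise is added inside the brain
#' only, keeping the background exactly zero so MIP-based cropping
#' behaves as on skull-stripped data.
#'
#' A single `difficulty` scalar in [0, 1] couples the two knobs that
#' control how hard a case is for a segmenter: lesion contrast is scaled
#' by `1 - 0.75 * difficulty` and noise by `0.5 + 2.5 * difficulty`.
#' `difficulty_range` draws a per-case difficulty uniformly, giving a
#' mixed cohort whose predicted segmentations span the whole quality
#' range.
#'
#' @param shape voxel grid extents (default 48 x 48 x 32).
#' @param n_cases number of cases.
#' @param channels channel names to synthesize.
#' @param n_lesions_range inclusive range of lesion count per case.
#' @param radius_range inclusive range (voxels) of the edema radius.
#' @param noise_sd baseline Gaussian noise standard deviation.
#' @param difficulty scalar difficulty in [0, 1].
#' @param difficulty_range optional length-2 range for per-case
#'   difficulty (overrides `difficulty`).
#' @param lesion_free_fraction expected fraction of lesion-free cases.
#' @param spacing voxel spacing (mm).
#' @param seed cohort RNG seed; each case is reproducible from
#'   (`seed`, case index) alone.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(48L, 48L, 32L), n_cases = 10L,
                           channels = c("T1", "T1c", "T2", "FLAIR"),
                           n_lesions_range = c(1L, 2L),
                           radius_range = c(6, 10),
                           noise_sd = 0.04,
                           difficulty = 0.5,
                           difficulty_range = NULL,
                           lesion_free_fraction = 0,
                           spacing = c(1, 1, 1),
                           seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("phantom_config: shape must be 3 extents of at least 8 voxels")
  if (max(radius_range) * 2 >= min(shape))
    stop("phantom_config: lesion radii must fit inside the grid")
  if (!is.null(difficulty_range)) {
    if (length(difficulty_range) != 2L || any(difficulty_range < 0) ||
        any(difficulty_range > 1) || difficulty_range[1] > difficulty_range[2])
      stop("phantom_config: difficulty_range must be an increasing pair in [0, 1]")
  } else if (difficulty < 0 || difficulty > 1)
    stop("phantom_config: difficulty must lie in [0, 1]")
  if (lesion_free_fraction < 0 || lesion_free_fraction > 1)
    stop("phantom_config: lesion_free_fraction must lie in [0, 1]")
  structure(list(shape = shape, n_cases = as.integer(n_cases),
                 channels = channels,
                 n_lesions_range = as.integer(n_lesions_range),
                 radius_range = radius_range, noise_sd = noise_sd,
                 difficulty = difficulty, difficulty_range = difficulty_range,
                 lesion_free_fraction = lesion_free_fraction,
                 spacing = spacing, seed = as.integer(seed)),
            class = "phantom_config")
}

# Base tissue intensity and per-compartment additive contrast, per channel.
# Rows: core (necrotic), rim (enhancing), edema. T1c enhances the rim and
# darkens the necrotic core; T2/FLAIR light up edema; T1 is low-contrast.
phantom_intensities <- function() {
  list(base = c(T1 = 0.55, T1c = 0.50, T2 = 0.45, FLAIR = 0.50),
       contrast = rbind(
         core  = c(T1 = -0.15, T1c = -0.20, T2 = 0.35, FLAIR = 0.15),
         rim   = c(T1 =  0.05, T1c =  0.45, T2 = 0.15, FLAIR = 0.20),
         edema = c(T1 = -0.05, T1c =  0.05, T2 = 0.30, FLAIR = 0.40)))
}

# Deterministic per-case seed below 2^31.
case_seed <- function(seed, case_index)
  as.integer((as.numeric(seed) * 7919 + as.numeric(case_index) * 104729) %%
               2147483629)

# Squared normalized ellipsoid distance field for center `ctr`, radius r,
# per-axis anisotropy `aniso` (same for all nesting levels of one lesion).
ellipsoid_field <- function(coords, ctr, r, aniso) {
  ((coords$x - ctr[1]) / (r * aniso[1]))^2 +
    ((coords$y - ctr[2]) / (r * aniso[2]))^2 +
    ((coords$z - ctr[3]) / (r * aniso[3]))^2
}

grid_coords <- function(shape) {
  list(x = slice.index(array(0, shape), 1L),
       y = slice.index(array(0, shape), 2L),
       z = slice.index(array(0, shape), 3L))
}

#' Generate one phantom case
#'
#' Deterministic given (`config$seed`, `case_index`): the same pair
#' always yields a bit-identical case.
#'
#' @param config a [phantom_config].
#' @param case_index 1-based case index within the cohort.
#' @return A [case_bundle] with a multilabel truth mask (codes 1/2/4).
#' @export
generate_phantom_case <- function(config, case_index) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(case_seed(config$seed, case_index), {
    shape <- config$shape
    co <- grid_coords(shape)
    ctr0 <- (shape + 1) / 2
    brain_ax <- 0.42 * shape
    brain <- (((co$x - ctr0[1]) / brain_ax[1])^2 +
                ((co$y - ctr0[2]) / brain_ax[2])^2 +
                ((co$z - ctr0[3]) / brain_ax[3])^2) <= 1
    diff <- if (!is.null(config$difficulty_range)) {
      stats::runif(1, config$difficulty_range[1], config$difficulty_range[2])
    } else config$difficulty
    contrast_scale <- 1 - 0.95 * diff
    noise_sd <- config$noise_sd * (0.5 + 6 * diff)

    labels <- array(0L, dim = shape)
    lesion_free <- stats::runif(1) < config$lesion_free_fraction
    if (!lesion_free) {
      n_les <- if (config$n_lesions_range[1] == config$n_lesions_range[2]) {
        config$n_lesions_range[1]
      } else sample(config$n_lesions_range[1]:config$n_lesions_range[2], 1L)
      for (l in seq_len(n_les)) {
        r <- stats::runif(1, config$radius_range[1], config$radius_range[2])
        aniso <- stats::runif(3, 0.75, 1.3)
        # center drawn well inside the brain so the lesion stays interior
        ctr <- ctr0 + stats::runif(3, -0.45, 0.45) * (brain_ax - r * max(aniso))
        fld <- ellipsoid_field(co, ctr, r, aniso)
        edema <- fld <= 1 & brain
        rim <- fld <= 0.65^2 & brain
        core <- fld <= 0.35^2 & brain
        labels[edema & labels == 0L] <- 2L
        labels[rim] <- 4L
        labels[core] <- 1L
      }
    }

    inten <- phantom_intensities()
    channels <- list()
    # inter-patient variability: per-case, per-channel jitter of tissue
    # base intensity and lesion contrast, so small training sets do not
    # cover the appearance distribution
    base_jit <- stats::runif(length(config$channels), 0.9, 1.1)
    contrast_jit <- stats::runif(length(config$channels), 0.7, 1.3)
    names(base_jit) <- names(contrast_jit) <- config$channels
    for (ch in config$channels) {
      v <- array(0, dim = shape)
      v[brain] <- inten$base[[ch]] * base_jit[[ch]]
      cs <- contrast_scale * contrast_jit[[ch]] * inten$contrast[, ch]
      v[labels == 1L] <- v[labels == 1L] + cs[["core"]]
      v[labels == 4L] <- v[labels == 4L] + cs[["rim"]]
      v[labels == 2L] <- v[labels == 2L] + cs[["edema"]]
      noise <- array(0, dim = shape)
      noise[brain] <- stats::rnorm(sum(brain), 0, noise_sd)
      v <- pmax(v + noise, 0)
      channels[[ch]] <- volume_grid(array(v, dim = shape), config$spacing)
    }
    case_bundle(sprintf("phantom_%04d", case_index), channels,
                truth_mask = volume_grid(labels, config$spacing),
                multilabel = TRUE)
  })
}

#' Generate a phantom cohort
#'
#' Generates `config$n_cases` cases; when `dir` is given, each volume is
#' written as NIfTI and a manifest CSV (`case_id`, one column per
#' channel, `truth`) consumable by [read_manifest()] is produced.
#'
#' @param config a [phantom_config].
#' @param dir optional output directory.
#' @return List with `cases` (list of [case_bundle]) and, when written,
#'   `manifest` (path to the manifest CSV).
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$n_cases < 1L) stop("generate_cohort: n_cases must be >= 1")
  cases <- lapply(seq_len(config$n_cases),
                  function(i) generate_phantom_case(config, i))
  manifest <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    rows <- lapply(cases, function(case) {
      paths <- list(case_id = case$case_id)
      for (ch in names(case$channels)) {
        fn <- sprintf("%s_%s.nii.gz", case$case_id, ch)
        write_volume(case$channels[[ch]], file.path(dir, fn))
        paths[[ch]] <- fn
      }
      fn <- sprintf("%s_truth.nii.gz", case$case_id)
      write_volume(case$truth_mask, file.path(dir, fn))
      paths$truth <- fn
      as.data.frame(paths, stringsAsFactors = FALSE)
    })
    man <- do.call(rbind, rows)
    manifest <- file.path(dir, "manifest.csv")
    utils::write.csv(man, manifest, row.names = FALSE)
  }
  list(cases = cases, manifest = manifest)
}
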
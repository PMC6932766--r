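#' Phantom generator configuration
#'
#' Describes a synthetic 2D amyloid-PET-like slice: an ellipse ("brain") on a
#' black frame, with a bright interior core (white matter has high
#' nonspecific tracer binding) and a cortical rim whose uptake rises with
#' disease class — amyloid positivity shows as elevated rim signal that
#' erodes the gray/white contrast. Images are smoothed with a Gaussian filter
#' emulating the uniform-resolution preprocessing applied to clinical PET
#' (8 mm FWHM; about 8 px at the phantom's ~1 mm/px scale) and corrupted with
#' additive Gaussian noise, clipped at zero.
#'
#' @param image_size pixels per side, black frame included (default 256).
#' @param brain_axes ellipse semi-axes as fractions of `image_size`
#'   (default row 0.30, column 0.36: wider than tall, like an axial slice).
#' @param core_uptake interior intensity, arbitrary units (default 1).
#' @param rim_uptake_nc cortical rim intensity for the NC class (default
#'   0.35).
#' @param effect_size named non-decreasing increments over
#'   `SMC <= EMCI <= LMCI <= AD`, as fractions of the core-rim contrast
#'   (`core_uptake - rim_uptake_nc`) added to the rim uptake; NC is always 0.
#' @param rim_fraction inner edge of the rim band as a fraction of the
#'   ellipse radius (default 0.80, i.e. the outer 20% of the ellipse).
#' @param noise_sigma additive Gaussian noise SD, same units as
#'   `core_uptake` (default 0.08).
#' @param smooth_fwhm_px Gaussian smoothing FWHM in pixels (default 8).
#' @param jitter maximum random translation (fraction of `image_size`) and
#'   scale perturbation per image (default 0.03).
#' @param n_per_class images per class for [generate_dataset()] (default
#'   100).
#' @param seed master seed for [generate_dataset()].
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 256L,
                           brain_axes = c(0.30, 0.36),
                           core_uptake = 1,
                           rim_uptake_nc = 0.35,
                           effect_size = c(SMC = 0.05, EMCI = 0.12,
                                           LMCI = 0.30, AD = 0.60),
                           rim_fraction = 0.80,
                           noise_sigma = 0.08,
                           smooth_fwhm_px = 8,
                           jitter = 0.03,
                           n_per_class = 100L,
                           seed = 1L) {
  if (rim_uptake_nc <= 0 || rim_uptake_nc >= core_uptake)
    stop_amypet("need 0 < rim_uptake_nc < core_uptake",
                class = "amypet_validation_error")
  need <- c("SMC", "EMCI", "LMCI", "AD")
  if (!all(need %in% names(effect_size)))
    stop_amypet("effect_size must name SMC, EMCI, LMCI, AD",
                class = "amypet_validation_error")
  es <- effect_size[need]
  if (any(es < 0) || any(diff(es) < 0))
    stop_amypet("effect sizes must be >= 0 and non-decreasing over SMC <= EMCI <= LMCI <= AD",
                class = "amypet_validation_error")
  if (noise_sigma < 0)
    stop_amypet("noise_sigma must be >= 0", class = "amypet_validation_error")
  if (rim_fraction <= 0 || rim_fraction >= 1)
    stop_amypet("rim_fraction must be in (0, 1)",
                class = "amypet_validation_error")
  structure(list(
    image_size = as.integer(image_size), brain_axes = brain_axes,
    core_uptake = core_uptake, rim_uptake_nc = rim_uptake_nc,
    effect_size = es, rim_fraction = rim_fraction,
    noise_sigma = noise_sigma, smooth_fwhm_px = smooth_fwhm_px,
    jitter = jitter, n_per_class = as.integer(n_per_class),
    seed = as.integer(seed),
    # shared nominal ceiling so every image is written on the same scale
    intensity_ceiling = 1.5 * core_uptake
  ), class = "phantom_config")
}

# Separable Gaussian blur with zero padding (the frame is black anyway).
gaussian_blur <- function(px, fwhm) {
  if (fwhm <= 0) return(px)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  conv_mat <- function(n) {
    K <- matrix(0, n, n)
    for (d in -r:r) {
      i <- seq_len(n)
      j <- i + d
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- k[d + r + 1]
    }
    K
  }
  Kr <- conv_mat(nrow(px))
  Kc <- if (ncol(px) == nrow(px)) Kr else conv_mat(ncol(px))
  Kr %*% px %*% t(Kc)
}

# Draws one phantom from the *current* RNG stream.
phantom_draw <- function(cls, cfg) {
  cls <- toupper(cls)
  if (!cls %in% AMYPET_CLASSES)
    stop_amypet("unknown class: %s", cls, class = "amypet_validation_error")
  n <- cfg$image_size
  scale <- 1 + runif(1, -cfg$jitter, cfg$jitter)
  shift <- runif(2, -cfg$jitter, cfg$jitter) * n
  a_r <- cfg$brain_axes[1] * n * scale
  a_c <- cfg$brain_axes[2] * n * scale
  ctr <- (n + 1) / 2 + shift

  rows <- (seq_len(n) - ctr[1]) / a_r
  cols <- (seq_len(n) - ctr[2]) / a_c
  r2 <- outer(rows^2, cols^2, `+`)   # squared normalized elliptical radius

  rim_uptake <- cfg$rim_uptake_nc +
    (if (cls == "NC") 0 else cfg$effect_size[[cls]]) *
      (cfg$core_uptake - cfg$rim_uptake_nc)
  px <- matrix(0, n, n)
  px[r2 <= 1] <- rim_uptake
  px[r2 <= cfg$rim_fraction^2] <- cfg$core_uptake

  px <- gaussian_blur(px, cfg$smooth_fwhm_px)
  if (cfg$noise_sigma > 0)
    px <- px + matrix(rnorm(n * n, 0, cfg$noise_sigma), n, n)
  raw_image(pmax(px, 0), source_id = cls,
            max_intensity = cfg$intensity_ceiling)
}

#' Generate one synthetic phantom slice
#'
#' Deterministic given `(cls, cfg, seed)`. With zero noise and jitter, two
#' classes differ only inside the (blurred) cortical rim band.
#'
#' @param cls class label (`NC`, `SMC`, `EMCI`, `LMCI`, `AD`).
#' @param cfg a [phantom_config()].
#' @param seed integer seed for this image's jitter and noise.
#' @return A [raw_image()] whose nominal `max_intensity` is the shared
#'   intensity ceiling from `cfg` (identical for all classes).
#' @export
generate_phantom <- function(cls, cfg = phantom_config(), seed = 1L) {
  with_seed(seed, phantom_draw(cls, cfg))
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_per_class` 8-bit grayscale PNGs per class plus a
#' `manifest.csv` (`source_id,path,label`) into `out_dir`. All randomness is
#' governed by `cfg$seed`; two runs with the same config produce identical
#' manifests and identical image bytes.
#'
#' @param cfg a [phantom_config()].
#' @param out_dir output directory (created if missing).
#' @return The manifest, as returned by [load_manifest()].
#' @export
generate_dataset <- function(cfg = phantom_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  with_seed(cfg$seed, {
    for (cls in AMYPET_CLASSES) {
      for (i in seq_len(cfg$n_per_class)) {
        id <- sprintf("%s_%03d", cls, i)
        fn <- paste0(id, ".png")
        img <- phantom_draw(cls, cfg)
        write_image(img, file.path(out_dir, fn))
        rows[[id]] <- data.frame(source_id = id, path = fn, label = cls,
                                 stringsAsFactors = FALSE)
      }
    }
  })
  man <- do.call(rbind, rows)
  utils::write.csv(man, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  load_manifest(file.path(out_dir, "manifest.csv"))
}

#' Generate phantom features in memory
#'
#' Convenience route used by tests and simulation studies: generates phantoms
#' for the requested classes and runs the preparation phase directly, without
#' writing PNG files. Equivalent to [generate_dataset()] +
#' [prepare_manifest()] up to 8-bit quantization of the intermediate files.
#'
#' @param cfg a [phantom_config()].
#' @param prep a [prep_config()].
#' @param classes classes to generate (default: all five).
#' @return A feature `data.frame` as from [prepare_manifest()].
#' @export
phantom_features <- function(cfg = phantom_config(), prep = prep_config(),
                             classes = AMYPET_CLASSES) {
  rows <- list()
  with_seed(cfg$seed, {
    for (cls in classes) {
      for (i in seq_len(cfg$n_per_class)) {
        img <- phantom_draw(cls, cfg)
        img$source_id <- sprintf("%s_%03d", cls, i)
        rows[[img$source_id]] <-
          c(list(source_id = img$source_id, label = cls),
            as.list(prepare(img, prep)$values))
      }
    }
  })
  n_feat <- (prep$target_size %/% prep$segment_size)^2
  nm <- sprintf(paste0("f%0", max(3L, nchar(n_feat - 1L)), "d"),
                seq_len(n_feat) - 1L)
  out <- do.call(rbind, lapply(rows, function(r) {
    df <- as.data.frame(r, stringsAsFactors = FALSE)
    names(df) <- c("source_id", "label", nm)
    df
  }))
  rownames(out) <- NULL
  out
}
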
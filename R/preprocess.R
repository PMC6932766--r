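#' Image-preparation configuration
#'
#' Settings for the three-step preparation phase: autocrop of the black frame,
#' bilinear resize to a square `target_size` grid, and APPN block averaging
#' with `segment_size`-pixel blocks. The defaults (200-pixel grid, 10-pixel
#' segments) yield 400 normalized network inputs.
#'
#' @param target_size pixels per side after resizing (default 200).
#' @param segment_size pixels per APPN block side (default 10); must divide
#'   `target_size`.
#' @param crop_threshold fraction of the image maximum in `[0, 1)` at or below
#'   which a pixel counts as background during cropping (default 0: only
#'   strictly positive pixels survive).
#' @return A list of class `prep_config`.
#' @export
prep_config <- function(target_size = 200L, segment_size = 10L,
                        crop_threshold = 0) {
  target_size <- as.integer(target_size)
  segment_size <- as.integer(segment_size)
  if (target_size < 1L || segment_size < 1L)
    stop_amypet("sizes must be positive", class = "amypet_range_error")
  if (target_size %% segment_size != 0L)
    stop_amypet("target_size (%d) must be divisible by segment_size (%d)",
                target_size, segment_size, class = "amypet_validation_error")
  if (crop_threshold < 0 || crop_threshold >= 1)
    stop_amypet("crop_threshold must be in [0, 1)", class = "amypet_range_error")
  structure(list(target_size = target_size, segment_size = segment_size,
                 crop_threshold = crop_threshold),
            class = "prep_config")
}

#' Crop away the background frame around a brain slice
#'
#' Returns the minimal axis-aligned bounding box containing every pixel whose
#' intensity exceeds `crop_threshold * max(img)`. Interior pixels are not
#' modified. An image that is entirely background cannot be cropped and
#' raises a degenerate-input error.
#'
#' @param img a [raw_image()].
#' @param crop_threshold background threshold as a fraction of the image
#'   maximum, in `[0, 1)`.
#' @return A cropped [raw_image()].
#' @export
autocrop <- function(img, crop_threshold = 0) {
  stopifnot(inherits(img, "raw_image"))
  if (crop_threshold < 0 || crop_threshold >= 1)
    stop_amypet("crop_threshold must be in [0, 1)", class = "amypet_range_error")
  cut <- crop_threshold * max(img$pixels)
  fg <- img$pixels > cut
  if (!any(fg))
    stop_amypet("image '%s' is entirely background; nothing to crop to",
                img$source_id, class = "amypet_degenerate_error")
  rows <- which(rowSums(fg) > 0)
  cols <- which(colSums(fg) > 0)
  out <- img
  out$pixels <- img$pixels[rows[1]:rows[length(rows)],
                           cols[1]:cols[length(cols)], drop = FALSE]
  out$height <- nrow(out$pixels)
  out$width <- ncol(out$pixels)
  out
}

# Corner-aligned 1D linear interpolation operator: a (n_to x n_from) matrix L
# such that y = L %*% x samples x at positions t*(n_from-1)/(n_to-1).
linear_interp_matrix <- function(n_from, n_to) {
  L <- matrix(0, n_to, n_from)
  if (n_from == 1L) { L[, 1] <- 1; return(L) }
  pos <- if (n_to == 1L) (n_from - 1) / 2 else
    (seq_len(n_to) - 1) * (n_from - 1) / (n_to - 1)
  i0 <- pmin(floor(pos), n_from - 2)
  w <- pos - i0
  for (t in seq_len(n_to)) {
    L[t, i0[t] + 1] <- L[t, i0[t] + 1] + (1 - w[t])
    L[t, i0[t] + 2] <- L[t, i0[t] + 2] + w[t]
  }
  L
}

#' Resize an image to a square grid by bilinear interpolation
#'
#' Uses the corner-aligned sampling convention: output pixel `(i, j)` (0-based)
#' samples the source at `(i*(H-1)/(T-1), j*(W-1)/(T-1))`. Interpolation is
#' separable, so the result equals the per-pixel bilinear formula. Output
#' intensities are convex combinations of input pixels and therefore stay
#' within the input range.
#'
#' @param img a [raw_image()].
#' @param target_size pixels per side of the output grid.
#' @return A resized [raw_image()].
#' @export
resize_image <- function(img, target_size) {
  stopifnot(inherits(img, "raw_image"))
  target_size <- as.integer(target_size)
  if (target_size < 1L)
    stop_amypet("target_size must be >= 1", class = "amypet_range_error")
  out <- img
  if (img$height == target_size && img$width == target_size) return(out)
  Lr <- linear_interp_matrix(img$height, target_size)
  Lc <- linear_interp_matrix(img$width, target_size)
  out$pixels <- Lr %*% img$pixels %*% t(Lc)
  out$height <- target_size
  out$width <- target_size
  out
}

#' APPN block-average feature extraction
#'
#' Average Pixel Per Node: the image is partitioned into non-overlapping
#' `segment_size x segment_size` blocks and each feature is the arithmetic
#' mean gray value of one block, divided by the normalization ceiling so that
#' every feature lies in `[0, 1]`. Features are ordered row-major: the
#' top-left block first, then left-to-right along each block row.
#'
#' The ceiling is, in order of preference: the `norm_max` argument, the
#' image's nominal `max_intensity` (e.g. 255 for 8-bit rasters), or the
#' image's observed maximum. A fixed, dataset-wide ceiling should be used
#' when comparing images (see [prepare_manifest()]): per-image normalization
#' would erase the between-image uptake differences being classified.
#'
#' @param img a square [raw_image()] whose side is divisible by
#'   `segment_size`.
#' @param segment_size pixels per block side.
#' @param norm_max optional normalization ceiling overriding the image's.
#' @return A list of class `feature_vector` with fields `values` (numeric,
#'   length `(side/segment_size)^2`), `length`, and `source_id`.
#' @export
appn <- function(img, segment_size = 10L, norm_max = NULL) {
  stopifnot(inherits(img, "raw_image"))
  segment_size <- as.integer(segment_size)
  side <- img$height
  if (img$width != side || side %% segment_size != 0L)
    stop_amypet("image must be square with side divisible by segment_size (got %dx%d, segment %d)",
                img$height, img$width, segment_size, class = "amypet_shape_error")
  nb <- side %/% segment_size
  # block sums via a block-indicator operator; exact mean by construction
  B <- matrix(0, side, nb)
  B[cbind(seq_len(side), rep(seq_len(nb), each = segment_size))] <- 1
  means <- (t(B) %*% img$pixels %*% B) / segment_size^2
  denom <- norm_max %||% img$max_intensity
  if (is.na(denom)) denom <- max(img$pixels)
  if (denom <= 0) denom <- 1
  vals <- as.vector(t(means)) / denom   # row-major block order
  vals <- pmin(pmax(vals, 0), 1)
  structure(list(values = vals, length = length(vals),
                 source_id = img$source_id),
            class = "feature_vector")
}

#' Full image-preparation phase for one image
#'
#' The composition autocrop -> resize -> APPN, yielding the normalized input
#' pattern for the network. Deterministic: no randomness is involved.
#'
#' @param img a [raw_image()].
#' @param cfg a [prep_config()].
#' @param norm_max optional dataset-wide normalization ceiling (see [appn()]).
#' @return A `feature_vector` of length `(target_size/segment_size)^2`.
#' @export
prepare <- function(img, cfg = prep_config(), norm_max = NULL) {
  cropped <- autocrop(img, cfg$crop_threshold)
  resized <- resize_image(cropped, cfg$target_size)
  appn(resized, cfg$segment_size, norm_max = norm_max)
}

#' Prepare features for every image in a manifest
#'
#' Loads each image, runs the preparation phase, and assembles a labeled
#' feature table. Images with a known nominal intensity ceiling (integer
#' rasters) are normalized by it; if any image lacks one, the dataset-wide
#' maximum observed intensity is used for *all* images without a ceiling so
#' that between-image contrast is preserved.
#'
#' @param manifest an `amypet_manifest` from [load_manifest()].
#' @param cfg a [prep_config()].
#' @param slice_index optional slice selector passed to [load_image()].
#' @return A `data.frame` with columns `source_id`, `label`, and `f000` ...
#'   (one column per APPN feature, zero-padded row-major block index).
#' @export
prepare_manifest <- function(manifest, cfg = prep_config(),
                             slice_index = NULL) {
  paths <- manifest_paths(manifest)
  imgs <- lapply(paths, load_image, slice_index = slice_index)
  for (i in seq_along(imgs)) imgs[[i]]$source_id <- manifest$source_id[i]
  no_ceiling <- vapply(imgs, function(im) is.na(im$max_intensity), logical(1))
  global_max <- if (any(no_ceiling))
    max(vapply(imgs[no_ceiling], function(im) max(im$pixels), 0)) else NA_real_
  feats <- lapply(imgs, function(im) {
    nm <- if (is.na(im$max_intensity)) global_max else NULL
    prepare(im, cfg, norm_max = nm)$values
  })
  n_feat <- (cfg$target_size %/% cfg$segment_size)^2
  mat <- do.call(rbind, feats)
  colnames(mat) <- sprintf(paste0("f%0", max(3L, nchar(n_feat - 1L)), "d"),
                           seq_len(n_feat) - 1L)
  cbind(data.frame(source_id = manifest$source_id, label = manifest$label,
                   stringsAsFactors = FALSE),
        as.data.frame(mat))
}

#' Extract the feature matrix from a prepared feature table
#' @param features a `data.frame` from [prepare_manifest()].
#' @return Numeric matrix, one row per image.
#' @export
feature_matrix <- function(features) {
  fc <- grep("^f[0-9]+$", names(features), value = TRUE)
  as.matrix(features[, fc, drop = FALSE])
}
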
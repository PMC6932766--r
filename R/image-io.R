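#' Construct a raw grayscale image
#'
#' The basic pixel container used throughout the pipeline: a numeric matrix of
#' non-negative intensities in arbitrary scanner units, plus the nominal
#' maximum representable intensity when the source format declares one
#' (255 for 8-bit rasters, 65535 for 16-bit; `NA` for floating-point volumes
#' whose absolute scale is unknown).
#'
#' @param pixels numeric matrix (rows = image rows).
#' @param source_id opaque identifier carried through to feature vectors.
#' @param max_intensity nominal intensity ceiling, or `NA` if unknown.
#' @return An object of class `raw_image` with fields `pixels`, `height`,
#'   `width`, `source_id`, `max_intensity`.
#' @export
raw_image <- function(pixels, source_id = "", max_intensity = NA_real_) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_amypet("pixels must be a numeric matrix", class = "amypet_format_error")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop_amypet("image must have at least one pixel", class = "amypet_format_error")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop_amypet("intensities must be finite and non-negative",
                class = "amypet_format_error")
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         source_id = as.character(source_id),
         max_intensity = as.numeric(max_intensity)),
    class = "raw_image"
  )
}

#' @export
print.raw_image <- function(x, ...) {
  cat(sprintf("<raw_image> %dx%d  id='%s'  range [%g, %g]  nominal max %s\n",
              x$height, x$width, x$source_id,
              min(x$pixels), max(x$pixels),
              ifelse(is.na(x$max_intensity), "unknown",
                     format(x$max_intensity))))
  invisible(x)
}

#' Read a 2D grayscale image (or one slice of a volume)
#'
#' Supported formats, chosen by file extension: PNG (`.png`), baseline
#' uncompressed TIFF (`.tif`/`.tiff`), and NIfTI-1 volumes (`.nii`,
#' `.nii.gz`). Multi-channel rasters are collapsed to a single channel by the
#' unweighted mean of the color channels (an alpha channel, if present, is
#' dropped). Raster intensities are returned in their native integer units
#' (0..255 for 8-bit); volume voxels are returned as stored, after applying
#' the NIfTI scaling slope/intercept if set.
#'
#' For volumes the convention is: the *first* array axis is the slice axis and
#' the last two axes are the in-plane axes; `slice_index` (1-based) selects
#' the plane, defaulting to the middle one. 2D rasters ignore `slice_index`.
#'
#' @param path file to read.
#' @param slice_index 1-based plane index for 3D volumes (default: middle).
#' @return A [raw_image()].
#' @export
load_image <- function(path, slice_index = NULL) {
  if (!file.exists(path))
    stop_amypet("file not found: %s", path, class = "amypet_format_error")
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  full <- tolower(path)
  img <- if (grepl("\\.png$", full)) {
    read_png_gray(path)
  } else if (grepl("\\.tiff?$", full)) {
    read_tiff_gray(path)
  } else if (grepl("\\.nii(\\.gz)?$", full)) {
    read_nifti_slice(path, slice_index)
  } else {
    stop_amypet("unsupported image format: %s", path,
                class = "amypet_format_error")
  }
  img$source_id <- tools::file_path_sans_ext(basename(sub("\\.gz$", "", path)))
  img
}

collapse_channels <- function(a) {
  if (length(dim(a)) == 2L) return(a)
  nc <- dim(a)[3]
  if (nc == 2L || nc == 4L) nc <- nc - 1L  # gray+alpha or RGBA: drop alpha
  ch <- a[, , seq_len(nc), drop = FALSE]
  apply(ch, c(1, 2), mean)
}

read_png_gray <- function(path) {
  a <- png::readPNG(path, info = TRUE)
  info <- attr(a, "info")
  depth <- if (!is.null(info) && !is.null(info$bit.depth)) info$bit.depth else 8L
  maxv <- 2^depth - 1
  px <- collapse_channels(a) * maxv
  # readPNG returns k/maxv; undo the scaling exactly for integer sources
  px <- round(px * 1e9) / 1e9
  attributes(px) <- list(dim = dim(px))  # drop readPNG's info attribute
  raw_image(px, max_intensity = maxv)
}

#' Write a raw image as an 8-bit grayscale PNG
#'
#' Intensities are mapped linearly from `[0, max_intensity]` to 0..255;
#' values above the nominal ceiling are clipped. If the image has no nominal
#' ceiling its observed maximum is used instead.
#'
#' @param img a [raw_image()].
#' @param path destination `.png` path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "raw_image"))
  ceiling_ <- img$max_intensity
  if (is.na(ceiling_)) ceiling_ <- max(img$pixels)
  if (ceiling_ <= 0) ceiling_ <- 1
  scaled <- pmin(pmax(img$pixels / ceiling_, 0), 1)
  png::writePNG(scaled, target = path)
  invisible(path)
}

## --- minimal baseline TIFF reader (uncompressed gray / RGB) ----------------

read_tiff_gray <- function(path) {
  raw_bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_bytes) < 8L)
    stop_amypet("not a TIFF file: %s", path, class = "amypet_format_error")
  endian <- if (rawToChar(raw_bytes[1:2]) == "II") "little"
            else if (rawToChar(raw_bytes[1:2]) == "MM") "big"
            else stop_amypet("not a TIFF file: %s", path,
                             class = "amypet_format_error")
  u16 <- function(off) readBin(raw_bytes[(off + 1):(off + 2)], "integer",
                               size = 2, signed = FALSE, endian = endian)
  u32 <- function(off) readBin(raw_bytes[(off + 1):(off + 4)], "integer",
                               size = 4, endian = endian)
  ifd <- u32(4L)
  n_entries <- u16(ifd)
  tags <- list()
  for (i in seq_len(n_entries)) {
    off <- ifd + 2L + (i - 1L) * 12L
    tag <- u16(off); typ <- u16(off + 2L); cnt <- u32(off + 4L)
    sz <- c(1L, 1L, 2L, 4L, 8L)[typ]  # BYTE ASCII SHORT LONG RATIONAL
    rd <- function(o, k) {
      if (typ == 3L) vapply(seq_len(k) - 1L, function(j) u16(o + 2L * j), 0L)
      else if (typ == 4L) vapply(seq_len(k) - 1L, function(j) u32(o + 4L * j), 0L)
      else NA_integer_
    }
    val <- if (is.na(sz) || typ > 4L) NA_integer_
           else if (sz * cnt <= 4L) rd(off + 8L, cnt) else rd(u32(off + 8L), cnt)
    tags[[as.character(tag)]] <- val
  }
  g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
  width <- g(256); height <- g(257)
  bits <- g(258, 8L); spp <- g(277, 1L)
  compression <- g(259, 1L)
  if (is.null(width) || is.null(height))
    stop_amypet("TIFF missing dimensions: %s", path, class = "amypet_format_error")
  if (compression != 1L)
    stop_amypet("only uncompressed TIFF is supported: %s", path,
                class = "amypet_format_error")
  bps <- bits[1]
  if (!all(bits == bps) || !bps %in% c(8L, 16L))
    stop_amypet("unsupported TIFF bit depth: %s", path,
                class = "amypet_format_error")
  offsets <- g(273); counts <- g(279)
  if (is.null(offsets))
    stop_amypet("TIFF missing strip offsets: %s", path,
                class = "amypet_format_error")
  if (is.null(counts))
    counts <- rep((width * height * spp * bps / 8L) / length(offsets),
                  length(offsets))
  data <- unlist(lapply(seq_along(offsets), function(i) {
    seg <- raw_bytes[(offsets[i] + 1L):(offsets[i] + counts[i])]
    readBin(seg, "integer", n = counts[i] / (bps / 8L), size = bps / 8L,
            signed = FALSE, endian = endian)
  }))
  maxv <- 2^bps - 1
  if (spp == 1L) {
    px <- matrix(data, nrow = height, ncol = width, byrow = TRUE)
  } else {
    # interleaved samples; average the first 3 (RGB), dropping any extras
    arr <- array(data, dim = c(spp, width, height))
    nuse <- min(spp, 3L)
    px <- t(apply(arr[seq_len(nuse), , , drop = FALSE], c(2, 3), mean))
  }
  raw_image(px, max_intensity = maxv)
}

## --- minimal NIfTI-1 reader ------------------------------------------------

read_nifti_slice <- function(path, slice_index = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L)
    stop_amypet("truncated NIfTI header: %s", path, class = "amypet_format_error")
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
    if (sz != 348L)
      stop_amypet("not a NIfTI-1 file: %s", path, class = "amypet_format_error")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop_amypet("not a NIfTI-1 file (bad magic): %s", path,
                class = "amypet_format_error")
  dim8 <- readBin(hdr[41:56], "integer", n = 8, size = 2, endian = endian)
  ndim <- dim8[1]
  datatype <- readBin(hdr[71:72], "integer", size = 2, endian = endian)
  vox_offset <- readBin(hdr[109:112], "numeric", size = 4, endian = endian)
  scl_slope <- readBin(hdr[113:116], "numeric", size = 4, endian = endian)
  scl_inter <- readBin(hdr[117:120], "numeric", size = 4, endian = endian)
  dims <- pmax(dim8[2:(1 + max(ndim, 1))], 1L)
  nvox <- prod(dims)
  rd <- switch(as.character(datatype),
    "2"   = function(n) readBin(con, "integer", n, size = 1, signed = FALSE,
                                endian = endian),
    "4"   = function(n) readBin(con, "integer", n, size = 2, endian = endian),
    "8"   = function(n) readBin(con, "integer", n, size = 4, endian = endian),
    "16"  = function(n) readBin(con, "numeric", n, size = 4, endian = endian),
    "64"  = function(n) readBin(con, "numeric", n, size = 8, endian = endian),
    "512" = function(n) readBin(con, "integer", n, size = 2, signed = FALSE,
                                endian = endian),
    stop_amypet("unsupported NIfTI datatype %d: %s", datatype, path,
                class = "amypet_format_error")
  )
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  voxels <- as.numeric(rd(nvox))
  if (length(voxels) < nvox)
    stop_amypet("truncated NIfTI data: %s", path, class = "amypet_format_error")
  if (!is.na(scl_slope) && scl_slope != 0)
    voxels <- voxels * scl_slope + scl_inter
  if (ndim <= 2L || (ndim >= 3L && dims[1] == 1L && ndim == 3L)) {
    px <- matrix(voxels, nrow = dims[1], ncol = dims[2])
    return(raw_image(px, max_intensity = NA_real_))
  }
  if (ndim > 3L && any(dims[4:length(dims)] > 1L))
    stop_amypet("4D+ volumes are not supported: %s", path,
                class = "amypet_format_error")
  vol <- array(voxels[seq_len(prod(dims[1:3]))], dim = dims[1:3])
  n_slices <- dims[1]
  si <- slice_index %||% (floor(n_slices / 2) + 1L)
  if (si < 1L || si > n_slices)
    stop_amypet("slice_index %d out of bounds [1, %d]", si, n_slices,
                class = "amypet_range_error")
  raw_image(vol[si, , ], max_intensity = NA_real_)
}

## --- manifest --------------------------------------------------------------

#' Read and validate a dataset manifest
#'
#' A manifest is a CSV with header `source_id,path,label` mapping each image
#' file to one of the five diagnostic classes (`NC`, `SMC`, `EMCI`, `LMCI`,
#' `AD`; matched case-insensitively). `source_id`s must be unique. Relative
#' `path`s are interpreted relative to the manifest's own directory.
#'
#' @param path manifest CSV.
#' @return A `data.frame` of class `amypet_manifest` with columns
#'   `source_id`, `path`, `label`; the manifest directory is attached as
#'   attribute `"dir"`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path))
    stop_amypet("manifest not found: %s", path, class = "amypet_format_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("source_id", "path", "label")
  if (!all(need %in% names(df)))
    stop_amypet("manifest must have columns source_id,path,label",
                class = "amypet_validation_error")
  df <- df[, need]
  lab <- toupper(trimws(df$label))
  bad <- which(!lab %in% AMYPET_CLASSES)
  if (length(bad))
    stop_amypet("row %d: unknown label '%s' (expected one of %s)",
                bad[1], df$label[bad[1]], paste(AMYPET_CLASSES, collapse = ", "),
                class = "amypet_validation_error")
  dup <- df$source_id[duplicated(df$source_id)]
  if (length(dup))
    stop_amypet("duplicate source_id: %s", dup[1],
                class = "amypet_validation_error")
  df$label <- lab
  attr(df, "dir") <- dirname(normalizePath(path))
  class(df) <- c("amypet_manifest", "data.frame")
  df
}

#' Resolve manifest image paths against the manifest directory
#' @param manifest a manifest from [load_manifest()].
#' @return Character vector of absolute-ish paths.
#' @export
manifest_paths <- function(manifest) {
  dir <- attr(manifest, "dir") %||% "."
  ifelse(grepl("^(/|[A-Za-z]:)", manifest$path), manifest$path,
         file.path(dir, manifest$path))
}
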
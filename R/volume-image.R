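#' 3D volumetric image with spacing, respiratory phase and intensity scale
#'
#' The basic container the pipeline passes around: a 3D numeric array plus the
#' metadata every operation depends on. `scale` records whether voxel values
#' are raw reconstructed grey values or calibrated Hounsfield units (HU); it is
#' never implicit, so calibrated and uncalibrated volumes cannot be mixed up.
#'
#' @param values 3D numeric array (x, y, z).
#' @param spacing_mm voxel spacing in mm; scalar (isotropic) or length-3.
#' @param phase respiratory phase: `"expiration"`, `"inspiration"` or
#'   `"unknown"`.
#' @param scale intensity scale: `"raw"` or `"HU"`.
#' @param subject,week optional subject identifier and study week.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(values, spacing_mm, phase = "unknown", scale = "raw",
                         subject = NA_character_, week = NA_real_) {
  stopifnot(is.array(values), length(dim(values)) == 3L, all(dim(values) > 0L))
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0))
  phase <- match.arg(phase, c("expiration", "inspiration", "unknown"))
  scale <- match.arg(scale, c("raw", "HU"))
  structure(
    list(values = values, spacing_mm = as.numeric(spacing_mm), phase = phase,
         scale = scale, subject = subject, week = week),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<volume_image> %d x %d x %d voxels, spacing %s mm, phase=%s, scale=%s\n",
    d[1], d[2], d[3], paste(signif(x$spacing_mm, 4), collapse = "x"),
    x$phase, x$scale))
  cat(sprintf("  intensity range [%.1f, %.1f]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$values)

voxel_volume_mm3 <- function(image) prod(image$spacing_mm)

#' Write a volume as MetaImage (.mhd header + .raw data)
#'
#' Plain-text MetaImage header alongside a little-endian float64 raw file,
#' readable by ITK/SimpleITK/ImageJ. Spacing metadata is preserved.
#'
#' @param image a [volume_image()].
#' @param path output path ending in `.mhd`.
#' @return `path`, invisibly.
#' @export
write_mhd <- function(image, path) {
  stopifnot(inherits(image, "volume_image"), grepl("\\.mhd$", path))
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  d <- dim(image$values)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    "Offset = 0 0 0",
    sprintf("ElementSpacing = %.9g %.9g %.9g", image$spacing_mm[1],
            image$spacing_mm[2], image$spacing_mm[3]),
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    "ElementType = MET_DOUBLE",
    sprintf("ElementDataFile = %s", raw_name)
  )
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.vector(image$values), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a MetaImage (.mhd) volume
#'
#' Supports the subset written by [write_mhd()] plus MET_FLOAT/MET_SHORT/
#' MET_UCHAR uncompressed local raw files.
#'
#' @param path path to the `.mhd` header.
#' @inheritParams volume_image
#' @return A [volume_image()].
#' @export
read_mhd <- function(path, phase = "unknown", scale = "raw",
                     subject = NA_character_, week = NA_real_) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  get <- function(k) vals[match(k, keys)]
  if (!is.na(get("CompressedData")) && toupper(get("CompressedData")) == "TRUE")
    stop("compressed MetaImage not supported")
  d <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  sp <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])
  typ <- get("ElementType")
  size <- switch(typ, MET_DOUBLE = 8L, MET_FLOAT = 4L, MET_SHORT = 2L,
                 MET_UCHAR = 1L, stop("unsupported ElementType: ", typ))
  what <- if (typ %in% c("MET_DOUBLE", "MET_FLOAT")) numeric() else integer()
  con <- file(file.path(dirname(path), get("ElementDataFile")), "rb")
  on.exit(close(con))
  v <- readBin(con, what, n = prod(d), size = size, endian = "little",
               signed = size > 1L)
  volume_image(array(as.numeric(v), dim = d), sp, phase = phase, scale = scale,
               subject = subject, week = week)
}

#' Dice overlap coefficient between two boolean masks
#'
#' `2|A n B| / (|A| + |B|)`; 1 for identical non-empty masks.
#'
#' @param a,b logical arrays of identical dimension.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(NA_real_)
  2 * sum(a & b) / (sa + sb)
}

# derive independent sub-seeds (< 2^31) from one master seed
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
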
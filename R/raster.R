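#' @keywords internal
"_PACKAGE"

# Rasters are plain R objects: a grayscale image is a numeric matrix, an RGB
# image a rows x cols x 3 array. Processing functions expect values in [0, 1];
# the synthetic generator emits 8-bit [0, 255] arrays which `as_unit()` rescales.

#' Rescale an 8-bit raster to [0, 1]
#'
#' @param x numeric matrix or array with values in \[0, 255\].
#' @return the same raster divided by 255.
#' @export
as_unit <- function(x) x / 255

#' Luminance of an RGB raster
#'
#' Rec. 601 luma weights (0.299, 0.587, 0.114). A grayscale matrix is
#' returned unchanged, so downstream code can accept either form.
#'
#' @param img numeric matrix or rows x cols x 3 array.
#' @return numeric matrix.
#' @export
luminance <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Read a PNG or TIFF image as a normalized raster
#'
#' @param path file path; format chosen by extension (png, tif, tiff).
#' @return numeric matrix (grayscale) or rows x cols x 3 array with values in
#'   \[0, 1\]; the original bit depth is recorded in attribute `"bit_depth"`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    bits <- 8L
    raw <- png::readPNG(path, native = FALSE)
    # png stores 16-bit as values with finer granularity than 1/255
    if (any(abs(raw * 255 - round(raw * 255)) > 1e-6)) bits <- 16L
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    info <- attributes(img)
    bits <- if (!is.null(info$bits.per.sample)) as.integer(info$bits.per.sample) else 8L
    attributes(img) <- list(dim = dim(img))
  } else {
    stop("unsupported image format: ", ext)
  }
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3] # drop alpha
  if (length(dim(img)) == 3L && dim(img)[3] == 2L) img <- img[, , 1]   # gray+alpha
  attr(img, "bit_depth") <- bits
  img
}

#' Write a raster to PNG or TIFF
#'
#' Values are clamped to \[0, 1\]. TIFF output is written as 32-bit float so
#' that filtered rasters round-trip losslessly; PNG output is 8-bit.
#'
#' @param img raster in \[0, 1\].
#' @param path destination path (extension selects format).
#' @return `path`, invisibly.
#' @export
write_raster <- function(img, path) {
  attr(img, "bit_depth") <- NULL
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 32L)
  } else {
    stop("unsupported image format: ", ext)
  }
  invisible(path)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
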
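#' 8-bit RGB image container
#'
#' An `rgb_image` is an integer array of dimension height x width x 3
#' (channels ordered red, green, blue) with every value in \[0, 255\]. It is
#' the pixel container every imaging function in this package consumes and
#' returns.
#'
#' @param pixels Numeric array of dimension H x W x 3 with values in
#'   \[0, 255\]. Non-integer values are rounded half-up.
#' @return An `rgb_image` object.
#' @examples
#' img <- rgb_image(array(c(200, 150, 100), dim = c(1, 1, 3)))
#' dim(img)
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  }
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) {
    stop("image must have height >= 1 and width >= 1", call. = FALSE)
  }
  px <- round_half_up(pixels)
  if (anyNA(px) || min(px) < 0 || max(px) > 255) {
    stop("channel values must lie in [0, 255] with no missing values",
         call. = FALSE)
  }
  storage.mode(px) <- "integer"
  structure(px, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d pixels, 3 channels (R, G, B)\n", d[1], d[2]))
  rng <- vapply(1:3, function(k) range(x[, , k]), numeric(2))
  cat(sprintf("  R: [%d, %d]  G: [%d, %d]  B: [%d, %d]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

is_rgb_image <- function(x) inherits(x, "rgb_image")

assert_rgb_image <- function(x, arg = "image") {
  if (!is_rgb_image(x)) stop(sprintf("`%s` must be an rgb_image", arg), call. = FALSE)
  invisible(x)
}

# Deterministic half-up rounding (round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Image height and width
#'
#' @param image An [rgb_image()].
#' @return Integer pixel count along the axis.
#' @export
image_height <- function(image) {
  assert_rgb_image(image)
  dim(image)[1]
}

#' @rdname image_height
#' @export
image_width <- function(image) {
  assert_rgb_image(image)
  dim(image)[2]
}

#' Read an image file as an 8-bit RGB array
#'
#' Reads PNG, TIFF, or JPEG files into the canonical [rgb_image()] form:
#' higher bit depths are rescaled to 8-bit full scale, single-channel
#' (grayscale) images are replicated across the three channels, and any alpha
#' channel is dropped.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg` file.
#' @return An [rgb_image()].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop(sprintf("unsupported image format: .%s (PNG/TIFF/JPEG only)", ext),
         call. = FALSE)
  )
  # readers return values in [0, 1]; full scale maps to 255 at any bit depth
  if (length(dim(raw)) == 2L) {
    raw <- array(raw, dim = c(dim(raw), 3L))
  } else if (dim(raw)[3] >= 4L) {
    raw <- raw[, , 1:3, drop = FALSE]
  } else if (dim(raw)[3] == 2L) { # gray + alpha
    raw <- array(raw[, , 1L], dim = c(dim(raw)[1:2], 3L))
  } else if (dim(raw)[3] == 1L) {
    raw <- array(raw[, , 1L], dim = c(dim(raw)[1:2], 3L))
  }
  rgb_image(raw * 255)
}

#' Write an 8-bit RGB image to disk
#'
#' @param image An [rgb_image()].
#' @param path Output path; the extension selects PNG, TIFF, or JPEG.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  assert_rgb_image(image)
  arr <- unclass(image) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(arr, path),
    tif  = ,
    tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    jpg  = ,
    jpeg = jpeg::writeJPEG(arr, path, quality = 1),
    stop(sprintf("unsupported image format: .%s", ext), call. = FALSE)
  )
  invisible(path)
}

#' Write a binary mask as a single-channel PNG
#'
#' Foreground (`TRUE`) pixels are written as 255, background as 0.
#'
#' @param mask Logical matrix.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
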
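#' Mask analyzable tissue pixels
#'
#' Excludes near-white pixels (specular glare and gastric juice: every
#' channel at or above `white_cutoff`) and near-black pixels (unlit
#' background and shadow: every channel at or below `black_cutoff`); all
#' remaining pixels are treated as tissue.
#'
#' @param image An [rgb_image()].
#' @param white_cutoff Value in \[0, 255\]; a pixel with `min(R, G, B) >=
#'   white_cutoff` is excluded as glare/juice. Default 240.
#' @param black_cutoff Value in \[0, 255\]; a pixel with `max(R, G, B) <=
#'   black_cutoff` is excluded as background. Default 20.
#' @return Logical H x W matrix, `TRUE` for tissue.
#' @export
tissue_mask <- function(image, white_cutoff = 240, black_cutoff = 20) {
  assert_rgb_image(image)
  if (white_cutoff <= black_cutoff) {
    stop("`white_cutoff` must exceed `black_cutoff`", call. = FALSE)
  }
  mn <- pmin(image[, , 1L], image[, , 2L], image[, , 3L])
  mx <- pmax(image[, , 1L], image[, , 2L], image[, , 3L])
  mn < white_cutoff & mx > black_cutoff
}

#' Histogram of red values within a mask
#'
#' Counts, for each red value 0-255, the number of masked pixels carrying
#' it; erythematous images pile mass into the high-red bins.
#'
#' @param image An [rgb_image()].
#' @param mask Logical H x W matrix; defaults to every pixel.
#' @return A `red_histogram`: list with `counts` (integer vector of length
#'   256, bin `v` at index `v + 1`) and `total` (masked pixel count).
#' @seealso [tidy.red_histogram()] for a tibble view, [autoplot.red_histogram()].
#' @export
red_histogram <- function(image, mask = NULL) {
  assert_rgb_image(image)
  if (is.null(mask)) mask <- matrix(TRUE, dim(image)[1], dim(image)[2])
  if (!is.logical(mask) || !identical(dim(mask), dim(image)[1:2])) {
    stop("`mask` must be a logical matrix matching the image", call. = FALSE)
  }
  red <- image[, , 1L][mask]
  counts <- tabulate(red + 1L, nbins = 256L)
  structure(list(counts = counts, total = length(red)),
            class = "red_histogram")
}

#' @export
print.red_histogram <- function(x, ...) {
  cat(sprintf("<red_histogram> %d pixels", x$total))
  if (x$total > 0) {
    nz <- which(x$counts > 0) - 1L
    cat(sprintf(", red values %d-%d, mode at %d",
                min(nz), max(nz), which.max(x$counts) - 1L))
  }
  cat("\n")
  invisible(x)
}

#' @describeIn red_histogram Tidy view: one row per red value.
#' @param x A `red_histogram`.
#' @param ... Unused.
#' @method tidy red_histogram
#' @export
tidy.red_histogram <- function(x, ...) {
  tibble::tibble(red_value = 0:255, count = x$counts)
}

#' Otsu threshold on a masked red histogram
#'
#' Picks the red value `t` maximizing the between-class variance of the
#' two classes `red < t` and `red >= t`. Used as the automatic,
#' reproducible default when no expert-chosen red threshold is supplied.
#'
#' @param x A `red_histogram` or an [rgb_image()].
#' @param mask Optional logical mask (only when `x` is an image).
#' @return Integer threshold in \[0, 255\]; segmenting at `red >= t`
#'   bisects the histogram. Ties resolve to the smallest maximizing `t`.
#' @export
otsu_red_threshold <- function(x, mask = NULL) {
  h <- if (inherits(x, "red_histogram")) x else red_histogram(x, mask)
  if (h$total == 0) stop("empty histogram: no pixels to threshold", call. = FALSE)
  counts <- h$counts
  p <- counts / h$total
  v <- 0:255
  omega <- cumsum(p)                  # mass of class {red < t} for t = v + 1
  mu <- cumsum(p * v)
  mu_t <- mu[256]
  # between-class variance when splitting below value t (classes <t vs >=t)
  w0 <- c(0, omega[1:255])            # class {red < t}, t = 0..255
  m0 <- c(0, mu[1:255])
  sigma_b <- (mu_t * w0 - m0)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  which.max(sigma_b) - 1L
}

#' Erythema segmentation by red-value thresholding
#'
#' Bisects the tissue into erythematous (red value at or above the
#' threshold) and non-erythematous pixels, mirroring the white/black
#' damage-zone split used in manual workflows, and counts both.
#'
#' @param image An [rgb_image()].
#' @param red_threshold Red value in \[0, 255\]; when `NULL` (the default)
#'   it is chosen per-image by Otsu's method on the masked red histogram.
#' @param tissue Logical H x W tissue mask; when `NULL`, computed by
#'   [tissue_mask()] with the supplied cutoffs.
#' @param white_cutoff,black_cutoff Passed to [tissue_mask()] when `tissue`
#'   is not given.
#' @return An `erythema_result`: list with `mask` (logical H x W, `TRUE` =
#'   erythematous), `erythema_pixels`, `tissue_pixels`, `erythema_fraction`,
#'   `red_threshold`, and the masked `histogram`.
#' @export
segment_erythema <- function(image, red_threshold = NULL, tissue = NULL,
                             white_cutoff = 240, black_cutoff = 20) {
  assert_rgb_image(image)
  if (is.null(tissue)) tissue <- tissue_mask(image, white_cutoff, black_cutoff)
  if (!is.logical(tissue) || !identical(dim(tissue), dim(image)[1:2])) {
    stop("`tissue` must be a logical matrix matching the image", call. = FALSE)
  }
  n_tissue <- sum(tissue)
  if (n_tissue == 0L) {
    stop("empty tissue mask: erythema fraction undefined", call. = FALSE)
  }
  hist <- red_histogram(image, tissue)
  if (is.null(red_threshold)) red_threshold <- otsu_red_threshold(hist)
  stopifnot(red_threshold >= 0, red_threshold <= 255)
  mask <- tissue & image[, , 1L] >= red_threshold
  n_ery <- sum(mask)
  structure(
    list(mask = mask,
         erythema_pixels = n_ery,
         tissue_pixels = n_tissue,
         erythema_fraction = n_ery / n_tissue,
         red_threshold = red_threshold,
         histogram = hist),
    class = "erythema_result"
  )
}

#' @export
print.erythema_result <- function(x, ...) {
  cat(sprintf(
    "<erythema_result> %d / %d tissue pixels erythematous (%.2f%%), red threshold %d\n",
    x$erythema_pixels, x$tissue_pixels, 100 * x$erythema_fraction,
    x$red_threshold))
  invisible(x)
}

#' @describeIn segment_erythema One-row tibble of the segmentation counts.
#' @param x An `erythema_result`.
#' @param ... Unused.
#' @method glance erythema_result
#' @export
glance.erythema_result <- function(x, ...) {
  tibble::tibble(
    erythema_pixels = x$erythema_pixels,
    tissue_pixels = x$tissue_pixels,
    erythema_fraction = x$erythema_fraction,
    red_threshold = x$red_threshold
  )
}

#' 3D color-density relief map
#'
#' Converts one channel into a height field in \[0, 1\]: the denser the
#' color, the taller the relief, so lesions rise out of the tissue when the
#' map is rendered in 3D.
#'
#' @param image An [rgb_image()].
#' @param channel One of `"red"`, `"green"`, `"blue"`.
#' @return A `relief_map`: numeric H x W matrix of heights in \[0, 1\]
#'   (channel value / 255), with the source channel as an attribute.
#' @export
relief_map <- function(image, channel = c("red", "green", "blue")) {
  assert_rgb_image(image)
  channel <- match.arg(channel)
  k <- match(channel, c("red", "green", "blue"))
  structure(image[, , k] / 255, channel = channel, class = "relief_map")
}

#' @export
print.relief_map <- function(x, ...) {
  cat(sprintf("<relief_map> %d x %d, %s channel, heights in [%.3f, %.3f]\n",
              nrow(x), ncol(x), attr(x, "channel"), min(x), max(x)))
  invisible(x)
}

#' Dark-spot lesion mask
#'
#' Stress-model (water immersion-restraint) ulcers present as dark foreign
#' spots rather than red stripes; this detector flags tissue pixels whose
#' maximum channel value falls below a darkness cutoff.
#'
#' @param image An [rgb_image()].
#' @param value_cutoff Pixels with `max(R, G, B) <= value_cutoff` are
#'   flagged. Default 80.
#' @param tissue Optional logical tissue mask restricting the search.
#' @return Logical H x W matrix, `TRUE` at dark-spot pixels.
#' @export
dark_spot_mask <- function(image, value_cutoff = 80, tissue = NULL) {
  assert_rgb_image(image)
  mx <- pmax(image[, , 1L], image[, , 2L], image[, , 3L])
  out <- mx <= value_cutoff
  if (!is.null(tissue)) out <- out & tissue
  out
}

#' Export erythema counts and histogram to disk
#'
#' Writes the red-value histogram as a two-column CSV (`red_value,count`),
#' the counts as JSON, and the erythema mask as a 0/255 PNG.
#'
#' @param result An `erythema_result` from [segment_erythema()].
#' @param prefix Path prefix; files `<prefix>_histogram.csv`,
#'   `<prefix>_result.json` and `<prefix>_mask.png` are produced.
#' @return The written paths, invisibly.
#' @export
export_erythema_result <- function(result, prefix) {
  stopifnot(inherits(result, "erythema_result"))
  paths <- c(histogram = paste0(prefix, "_histogram.csv"),
             json = paste0(prefix, "_result.json"),
             mask = paste0(prefix, "_mask.png"))
  utils::write.csv(tidy(result$histogram), paths[["histogram"]],
                   row.names = FALSE)
  jsonlite::write_json(glance(result), paths[["json"]],
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  write_mask(result$mask, paths[["mask"]])
  invisible(paths)
}
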
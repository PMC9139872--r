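#' Shield an image to a single color channel
#'
#' Computational analogue of photographing through a colored cellophane film:
#' only the designated channel's values are kept, the other two channels are
#' zeroed, so markers of the shielded color disappear against black.
#'
#' @param image An [rgb_image()].
#' @param color One of `"red"`, `"green"`, `"blue"`.
#' @return An [rgb_image()] with the two non-designated channels set to 0.
#' @examples
#' img <- rgb_image(array(c(200, 150, 100), dim = c(1, 1, 3)))
#' shield_channel(img, "red")[1, 1, ]
#' @export
shield_channel <- function(image, color = c("red", "green", "blue")) {
  assert_rgb_image(image)
  color <- match.arg(color)
  keep <- match(color, c("red", "green", "blue"))
  out <- unclass(image)
  out[, , setdiff(1:3, keep)] <- 0L
  rgb_image(out)
}

#' Unify low-red pixels with the background
#'
#' Pixels whose red value falls below `threshold` are set to black
#' (0, 0, 0) and excluded from the returned foreground mask; pixels at or
#' above the threshold pass through unchanged. This removes the faint red
#' cast that healthy tissue carries before erythema pixels are counted.
#'
#' @param image An [rgb_image()] (typically red-shielded, but raw works too).
#' @param threshold Red value in \[0, 255\]; pixels with red `< threshold`
#'   become background.
#' @return A list with elements `image` (the suppressed [rgb_image()]) and
#'   `mask` (logical H x W matrix, `TRUE` where the pixel was kept).
#' @export
suppress_low_red <- function(image, threshold) {
  assert_rgb_image(image)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 256)
  keep <- image[, , 1L] >= threshold
  out <- unclass(image)
  out[, , 1L][!keep] <- 0L
  out[, , 2L][!keep] <- 0L
  out[, , 3L][!keep] <- 0L
  list(image = rgb_image(out), mask = keep)
}

#' Rescale image brightness by white-balance level
#'
#' Brightness levels follow the high/medium/low convention of endoscopy
#' white-balance settings: level 50 is high (pixels scaled x2), 100 is the
#' identity, 200 is low (pixels scaled x0.5). In general every channel is
#' multiplied by `100 / level`, rounded half-up and clipped to \[0, 255\].
#'
#' @param image An [rgb_image()].
#' @param level Positive brightness level; 50, 100 and 200 are the canonical
#'   high/medium/low settings.
#' @return An [rgb_image()].
#' @export
adjust_brightness <- function(image, level) {
  assert_rgb_image(image)
  if (!is.numeric(level) || length(level) != 1L || level <= 0) {
    stop("`level` must be a single positive number", call. = FALSE)
  }
  rgb_image(clip255(round_half_up(unclass(image) * (100 / level))))
}

#' Color-card patch measurement
#'
#' Mean RGB values of each patch of a printed reference card, either measured
#' from a photograph or taken from the card's reference sheet.
#'
#' @param patch_values Numeric matrix with one row per patch and columns
#'   red, green, blue, values in \[0, 255\]. A data frame with columns
#'   `red`, `green`, `blue` is also accepted.
#' @return A `color_card_measurement` (tibble with columns `patch`, `red`,
#'   `green`, `blue`).
#' @export
color_card_measurement <- function(patch_values) {
  if (is.data.frame(patch_values)) {
    patch_values <- as.matrix(patch_values[, c("red", "green", "blue")])
  }
  stopifnot(is.matrix(patch_values), ncol(patch_values) == 3L)
  if (nrow(patch_values) < 2L) {
    stop("a color card needs at least 2 patches", call. = FALSE)
  }
  if (min(patch_values) < 0 || max(patch_values) > 255) {
    stop("patch values must lie in [0, 255]", call. = FALSE)
  }
  out <- tibble::tibble(
    patch = seq_len(nrow(patch_values)),
    red = patch_values[, 1L], green = patch_values[, 2L],
    blue = patch_values[, 3L]
  )
  class(out) <- c("color_card_measurement", class(out))
  out
}

#' Measure card patches from an image
#'
#' Averages each channel over the rectangular patch regions of a card layout.
#' Layouts use 0-based, half-open pixel boxes (`x`, `y`, `w`, `h`) as stored
#' in the JSON sidecar format read by [read_card_layout()].
#'
#' @param image An [rgb_image()] containing the photographed card.
#' @param layout Data frame with columns `x`, `y`, `w`, `h` (and optionally
#'   reference `red`, `green`, `blue`).
#' @return A [color_card_measurement()].
#' @export
measure_card_patches <- function(image, layout) {
  assert_rgb_image(image)
  stopifnot(all(c("x", "y", "w", "h") %in% names(layout)))
  vals <- t(vapply(seq_len(nrow(layout)), function(i) {
    rows <- (layout$y[i] + 1L):(layout$y[i] + layout$h[i])
    cols <- (layout$x[i] + 1L):(layout$x[i] + layout$w[i])
    vapply(1:3, function(k) mean(image[rows, cols, k]), numeric(1))
  }, numeric(3)))
  color_card_measurement(vals)
}

#' Read a card layout JSON sidecar
#'
#' The sidecar lists one object per patch with pixel bounding box
#' `x`, `y`, `w`, `h` (0-based, half-open) and the patch's reference RGB
#' triple under `reference`.
#'
#' @param path Path to the JSON sidecar.
#' @return A tibble with columns `x`, `y`, `w`, `h`, `red`, `green`, `blue`.
#' @export
read_card_layout <- function(path) {
  raw <- jsonlite::fromJSON(path)
  patches <- if (is.data.frame(raw)) raw else raw$patches
  ref <- patches$reference
  if (is.list(ref) && !is.data.frame(ref)) ref <- do.call(rbind, ref)
  tibble::tibble(
    x = patches$x, y = patches$y, w = patches$w, h = patches$h,
    red = ref[, 1], green = ref[, 2], blue = ref[, 3]
  )
}

#' Correct image colors against a reference card
#'
#' Fits, per channel, a linear gain + offset mapping the measured patch means
#' onto the reference patch means by ordinary least squares, applies it to
#' every pixel, and clips to \[0, 255\]. This plays the role of the
#' proprietary card-calibration step in a controlled-photography workflow:
#' a color cast that is affine per channel is removed exactly.
#'
#' @param image An [rgb_image()] to correct.
#' @param measured [color_card_measurement()] from the photograph.
#' @param reference [color_card_measurement()] of the card's true values.
#' @return The corrected [rgb_image()].
#' @export
correct_with_card <- function(image, measured, reference) {
  assert_rgb_image(image)
  fit <- card_correction_fit(measured, reference)
  out <- unclass(image)
  for (k in 1:3) {
    out[, , k] <- clip255(round_half_up(out[, , k] * fit$gain[k] + fit$offset[k]))
  }
  rgb_image(out)
}

#' Per-channel gain and offset of a card correction
#'
#' The least-squares coefficients that [correct_with_card()] applies.
#'
#' @inheritParams correct_with_card
#' @return A tibble with columns `channel`, `gain`, `offset`.
#' @export
card_correction_fit <- function(measured, reference) {
  if (nrow(measured) != nrow(reference)) {
    stop("measured and reference cards must have the same patch count",
         call. = FALSE)
  }
  if (nrow(measured) < 2L) stop("need at least 2 patches", call. = FALSE)
  chans <- c("red", "green", "blue")
  fits <- lapply(chans, function(ch) {
    m <- measured[[ch]]
    r <- reference[[ch]]
    sxx <- sum((m - mean(m))^2)
    if (sxx == 0) {
      stop("degenerate calibration: all measured patches identical in the ",
           ch, " channel", call. = FALSE)
    }
    gain <- sum((m - mean(m)) * (r - mean(r))) / sxx
    tibble::tibble(channel = ch, gain = gain, offset = mean(r) - gain * mean(m))
  })
  dplyr::bind_rows(fits)
}
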
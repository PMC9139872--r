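#' Evaluate code under a fixed, restored RNG state
#'
#' All fixture generators draw from R's Mersenne-Twister generator
#' (normal.kind `"Inversion"`) seeded explicitly, and restore the caller's
#' RNG state afterwards, so fixtures are bit-reproducible and generation
#' never perturbs surrounding code.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_fixture_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}

#' Generate a synthetic gastric-ulcer image with ground truth
#'
#' Renders a pink tissue field with per-pixel Gaussian noise and paints
#' lesions of a known phenotype on it: `ethanol_stripe` draws elongated
#' high-red stripes (the ethanol-induced linear erythema), `wire_spot`
#' draws dark round spots (the water immersion-restraint stress phenotype).
#' The lesion mask is produced by ranking pixels on their distance to the
#' lesion skeletons and taking exactly the requested area, so the returned
#' ground truth hits `area_fraction_target` to within one pixel. An
#' optional near-white specular patch and a horizontal lighting gradient
#' emulate glare and uneven illumination.
#'
#' @param phenotype `"ethanol_stripe"` or `"wire_spot"`.
#' @param n_lesions Number of stripes or spots. Default 3.
#' @param lesion_red Red value of lesion pixels before noise; defaults to
#'   245 for stripes and 50 for dark spots.
#' @param background_rgb Tissue color triple; default pink (205, 145, 150).
#' @param area_fraction_target Fraction of the frame covered by lesions,
#'   in \[0, 0.5\]. Default 0.1.
#' @param noise_sd Per-pixel Gaussian noise SD in channel units. Default 3.
#' @param specular Add a near-white glare disk. Default `FALSE`.
#' @param gradient Peak-to-peak amplitude of a horizontal brightness ramp
#'   added before noise. Default 0.
#' @param size `c(height, width)`; default `c(512, 512)`.
#' @param seed Integer seed; identical spec + seed gives identical bytes.
#' @return List with `image` ([rgb_image()]), `mask` (logical ground
#'   truth, `TRUE` at lesion pixels) and `spec` (the generating
#'   parameters).
#' @export
make_gastric_image <- function(phenotype = c("ethanol_stripe", "wire_spot"),
                               n_lesions = 3L,
                               lesion_red = NULL,
                               background_rgb = c(205, 145, 150),
                               area_fraction_target = 0.1,
                               noise_sd = 3,
                               specular = FALSE,
                               gradient = 0,
                               size = c(512L, 512L),
                               seed = 1L) {
  phenotype <- match.arg(phenotype)
  if (is.null(lesion_red)) {
    lesion_red <- if (phenotype == "ethanol_stripe") 245 else 50
  }
  if (area_fraction_target < 0 || area_fraction_target > 0.5) {
    stop("`area_fraction_target` must lie in [0, 0.5]: larger lesion loads ",
         "leave no background to segment against", call. = FALSE)
  }
  h <- size[1]; w <- size[2]
  target_n <- round(area_fraction_target * h * w)

  with_fixture_seed(seed, {
    mask <- matrix(FALSE, h, w)
    if (target_n > 0) {
      rows <- matrix(seq_len(h), h, w)
      cols <- matrix(seq_len(w), h, w, byrow = TRUE)
      d <- matrix(Inf, h, w)
      for (i in seq_len(n_lesions)) {
        cx <- stats::runif(1, 0.15 * w, 0.85 * w)
        cy <- stats::runif(1, 0.15 * h, 0.85 * h)
        if (phenotype == "ethanol_stripe") {
          theta <- stats::runif(1, 0, pi)
          half <- 0.30 * min(h, w)
          dx <- cos(theta) * half; dy <- sin(theta) * half
          # distance from each pixel to the segment (cx-dx,cy-dy)-(cx+dx,cy+dy)
          vx <- cols - (cx - dx); vy <- rows - (cy - dy)
          t_ <- pmin(pmax((vx * (2 * dx) + vy * (2 * dy)) / (4 * (dx^2 + dy^2)), 0), 1)
          di <- sqrt((vx - t_ * 2 * dx)^2 + (vy - t_ * 2 * dy)^2)
        } else {
          di <- sqrt((cols - cx)^2 + (rows - cy)^2)
        }
        d <- pmin(d, di)
      }
      ord <- order(as.vector(d), seq_len(h * w))  # stable, deterministic ties
      mask[ord[seq_len(target_n)]] <- TRUE
    }

    px <- array(0, dim = c(h, w, 3))
    for (k in 1:3) px[, , k] <- background_rgb[k]
    lesion_rgb <- if (phenotype == "ethanol_stripe") {
      c(lesion_red, round(background_rgb[2] * 0.45),
        round(background_rgb[3] * 0.45))
    } else {
      c(lesion_red, round(lesion_red * 0.8), round(lesion_red * 0.8))
    }
    for (k in 1:3) px[, , k][mask] <- lesion_rgb[k]

    if (specular) {
      scx <- stats::runif(1, 0.2 * w, 0.8 * w)
      scy <- stats::runif(1, 0.2 * h, 0.8 * h)
      r <- 0.08 * min(h, w)
      rows2 <- matrix(seq_len(h), h, w)
      cols2 <- matrix(seq_len(w), h, w, byrow = TRUE)
      spec_px <- (cols2 - scx)^2 + (rows2 - scy)^2 <= r^2 & !mask
      for (k in 1:3) px[, , k][spec_px] <- 252
    }

    if (gradient != 0) {
      ramp <- matrix(seq(-gradient / 2, gradient / 2, length.out = w),
                     h, w, byrow = TRUE)
      for (k in 1:3) px[, , k] <- px[, , k] + ramp
    }
    if (noise_sd > 0) px <- px + stats::rnorm(length(px), 0, noise_sd)

    list(image = rgb_image(clip255(round_half_up(px))),
         mask = mask,
         spec = list(phenotype = phenotype, n_lesions = n_lesions,
                     lesion_red = lesion_red, background_rgb = background_rgb,
                     area_fraction_target = area_fraction_target,
                     noise_sd = noise_sd, specular = specular,
                     gradient = gradient, size = c(h, w), seed = seed))
  })
}

#' Render a synthetic blood-dilution well plate
#'
#' Draws one circular well per dilution on a light plate, with the well's
#' mean red value set by the calibration line: red = 255 * (slope * x +
#' intercept), clipped to the displayable range, plus optional per-pixel
#' noise. Returns the well regions and the response table so a measured
#' standard curve can be round-tripped against the generating line.
#'
#' @param curve A `calibration_curve` providing the rendering line.
#' @param series Concentration vector, e.g. [dilution_series()].
#' @param noise_sd Per-pixel Gaussian noise SD in channel units. Default 0.
#' @param seed Integer seed (used only when `noise_sd > 0`). Default 1.
#' @param well_radius Well radius in pixels. Default 24.
#' @return List with `image` ([rgb_image()]), `rois` (tibble `well`,
#'   `concentration`, `cx`, `cy`, `r`) and `responses` (tibble `well`,
#'   `concentration`, `response_ideal` from the line, `response_rendered`
#'   after clipping and 8-bit quantization, and a `clipped` flag).
#' @export
make_well_plate <- function(curve, series = dilution_series(), noise_sd = 0,
                            seed = 1L, well_radius = 24L) {
  stopifnot(inherits(curve, "calibration_curve"))
  n <- length(series)
  ncol_ <- ceiling(n / 2)
  pitch <- 2L * well_radius + 16L
  h <- 2L * pitch + 8L
  w <- ncol_ * pitch + 8L

  ideal <- curve$slope * series + curve$intercept
  red8 <- clip255(round_half_up(255 * ideal))

  px <- array(230, dim = c(h, w, 3))            # light plastic plate
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  rois <- tibble::tibble(
    well = seq_len(n), concentration = series,
    cx = ((seq_len(n) - 1L) %% ncol_) * pitch + pitch / 2 + 4,
    cy = ((seq_len(n) - 1L) %/% ncol_) * pitch + pitch / 2 + 4,
    r = well_radius
  )
  for (i in seq_len(n)) {
    inside <- (cols - rois$cx[i])^2 + (rows - rois$cy[i])^2 <= well_radius^2
    px[, , 1L][inside] <- red8[i]
    px[, , 2L][inside] <- round(red8[i] * 0.22)
    px[, , 3L][inside] <- round(red8[i] * 0.25)
  }
  if (noise_sd > 0) {
    px <- with_fixture_seed(seed, px + stats::rnorm(length(px), 0, noise_sd))
  }
  list(
    image = rgb_image(clip255(round_half_up(px))),
    rois = rois,
    responses = tibble::tibble(
      well = seq_len(n), concentration = series,
      response_ideal = ideal,
      response_rendered = red8 / 255,
      clipped = ideal < 0 | ideal > 1
    )
  )
}

#' Measure well responses from a plate image
#'
#' Mean red value inside each well region, expressed on the response scale
#' (red / 255) for fitting with [fit_standard()].
#'
#' @param image Plate [rgb_image()].
#' @param rois Tibble of well regions as returned by [make_well_plate()].
#' @return A tibble with `well`, `concentration`, `mean_red`, `response`.
#' @export
measure_wells <- function(image, rois) {
  assert_rgb_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  mean_red <- vapply(seq_len(nrow(rois)), function(i) {
    inside <- (cols - rois$cx[i])^2 + (rows - rois$cy[i])^2 <= rois$r[i]^2
    mean(image[, , 1L][inside])
  }, numeric(1))
  tibble::tibble(well = rois$well, concentration = rois$concentration,
                 mean_red = mean_red, response = mean_red / 255)
}

#' Simulate multi-rater score panels for two methods
#'
#' Emulates a panel of trained raters scoring the same subjects with the
#' manual rubric (CCO) and with image analysis (IA): each cell is the
#' subject's true ulcer index plus method-specific Gaussian rater noise,
#' floored at 0. The defaults mirror an eight-rater panel in which manual
#' observation is the noisier method.
#'
#' @param true_ui Numeric vector of true ulcer-index values, one per
#'   subject.
#' @param n_raters Number of raters (>= 2). Default 8.
#' @param rater_noise_sd_cco,rater_noise_sd_ia Rater noise SD for the
#'   manual and image-analysis methods. Defaults 15 and 3.
#' @param seed Integer seed.
#' @return List of two subjects x raters matrices, `cco` and `ia`.
#' @export
make_rater_panel <- function(true_ui, n_raters = 8L,
                             rater_noise_sd_cco = 15,
                             rater_noise_sd_ia = 3,
                             seed = 1L) {
  stopifnot(n_raters >= 2L, rater_noise_sd_cco >= 0, rater_noise_sd_ia >= 0)
  n <- length(true_ui)
  with_fixture_seed(seed, {
    draw <- function(sd) {
      m <- matrix(rep(true_ui, n_raters), n, n_raters) +
        stats::rnorm(n * n_raters, 0, sd)
      m <- pmax(m, 0)
      dimnames(m) <- list(paste0("subject", seq_len(n)),
                          paste0("rater", seq_len(n_raters)))
      m
    }
    list(cco = draw(rater_noise_sd_cco), ia = draw(rater_noise_sd_ia))
  })
}

#' Materialize a fixture directory
#'
#' Writes a self-contained set of synthetic inputs for the pipeline: control
#' and treated lesion images with their ground-truth masks, a well-plate
#' image with its ROI and response tables, and a long-format rater-panel
#' CSV.
#'
#' @param dir Output directory (created if needed).
#' @param n_control,n_treated Number of control / treated images. Defaults
#'   3 and 3.
#' @param treated_area Lesion area fraction of treated images. Default 0.12.
#' @param control_area Lesion area fraction of control images. Default 0.01.
#' @param size Image size `c(height, width)`. Default `c(256, 256)`.
#' @param curve Calibration curve used for the plate; default the erythema
#'   standard [calibration_curve()]`(0.4432, -0.0282)`.
#' @param seed Integer seed.
#' @return The directory path, invisibly.
#' @export
write_fixture_dir <- function(dir, n_control = 3L, n_treated = 3L,
                              treated_area = 0.12, control_area = 0.01,
                              size = c(256L, 256L),
                              curve = calibration_curve(0.4432, -0.0282),
                              seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_one <- function(name, area, sub_seed) {
    fx <- make_gastric_image(area_fraction_target = area, size = size,
                             seed = sub_seed)
    write_image(fx$image, file.path(dir, paste0(name, ".png")))
    write_mask(fx$mask, file.path(dir, paste0(name, "_truth.png")))
  }
  for (i in seq_len(n_control)) {
    write_one(sprintf("control_%02d", i), control_area, seed + i)
  }
  for (i in seq_len(n_treated)) {
    write_one(sprintf("treated_%02d", i), treated_area, seed + 100L + i)
  }
  plate <- make_well_plate(curve, seed = seed)
  write_image(plate$image, file.path(dir, "plate.png"))
  utils::write.csv(plate$rois, file.path(dir, "plate_rois.csv"),
                   row.names = FALSE)
  utils::write.csv(plate$responses, file.path(dir, "plate_responses.csv"),
                   row.names = FALSE)
  panels <- make_rater_panel(true_ui = c(100, 160, 220, 280, 340), seed = seed)
  long <- dplyr::bind_rows(lapply(names(panels), function(m) {
    p <- panels[[m]]
    tibble::tibble(
      subject_id = rep(rownames(p), times = ncol(p)),
      rater_id = rep(colnames(p), each = nrow(p)),
      method = m, score = as.vector(p)
    )
  }))
  utils::write.csv(long, file.path(dir, "rater_panel.csv"), row.names = FALSE)
  invisible(dir)
}
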
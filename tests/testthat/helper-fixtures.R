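# Small in-code fixtures shared across test files.

uniform_image <- function(r, g = r, b = r, h = 4, w = 4) {
  rgb_image(array(rep(c(r, g, b), each = h * w), dim = c(h, w, 3)))
}

# image whose left half has one red value and right half another
split_red_image <- function(red_left, red_right, h = 4, w = 4, g = 100, b = 100) {
  px <- array(0, dim = c(h, w, 3))
  px[, , 1] <- cbind(matrix(red_left, h, w / 2), matrix(red_right, h, w / 2))
  px[, , 2] <- g
  px[, , 3] <- b
  rgb_image(px)
}

random_image <- function(h, w, seed) {
  withr::with_seed(seed, {
    rgb_image(array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3)))
  })
}

# flat synthetic color card: per-patch means, directly in measurement form
card_from_matrix <- function(m) color_card_measurement(m)

erythema_standard_line <- function(x) 0.4432 * x - 0.0282
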
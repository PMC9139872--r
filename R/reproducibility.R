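#' Per-subject standard deviation across raters
#'
#' Quantifies how far a panel of raters disagree on each subject: the
#' sample standard deviation (n - 1 denominator) of the scores each subject
#' received.
#'
#' @param panel Either a subjects x raters numeric matrix with no missing
#'   cells, or a long data frame with columns `subject`, `rater`, `score`.
#' @return A tibble with columns `subject`, `mean_score`, `sd`, `n_raters`.
#' @examples
#' rater_sd(matrix(c(90, 110, 100, 100), nrow = 2, byrow = TRUE))
#' @export
rater_sd <- function(panel) {
  if (is.matrix(panel)) {
    subjects <- rownames(panel) %||% as.character(seq_len(nrow(panel)))
    panel <- tibble::tibble(
      subject = rep(subjects, times = ncol(panel)),
      rater = rep(colnames(panel) %||% as.character(seq_len(ncol(panel))),
                  each = nrow(panel)),
      score = as.vector(panel)
    )
  }
  stopifnot(all(c("subject", "score") %in% names(panel)))
  if (anyNA(panel$score)) stop("panel has missing cells", call. = FALSE)
  if (any(panel$score < 0)) stop("scores must be >= 0", call. = FALSE)
  out <- panel |>
    dplyr::group_by(subject = .data$subject) |>
    dplyr::summarise(
      mean_score = mean(.data$score),
      sd = stats::sd(.data$score),
      n_raters = dplyr::n(),
      .groups = "drop"
    )
  if (any(out$n_raters < 2L)) {
    stop("need at least 2 raters per subject", call. = FALSE)
  }
  out
}

#' Bland-Altman agreement between two scoring methods
#'
#' Summarizes paired scores from two methods by the mean of their
#' differences (bias) and the limits of agreement, bias +/- 1.96 times the
#' standard deviation of the differences, the interval expected to contain
#' about 95% of paired differences.
#'
#' @param method_a,method_b Paired numeric vectors of equal length >= 2
#'   (differences are `a - b`).
#' @param loa_multiplier Half-width of the limits in SD units; 1.96 is the
#'   conventional value.
#' @return A `bland_altman` object: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `pairs` (count), and `data` (tibble of per-pair `mean` and
#'   `difference` for plotting).
#' @seealso [autoplot.bland_altman()]
#' @export
bland_altman <- function(method_a, method_b, loa_multiplier = 1.96) {
  if (length(method_a) != length(method_b)) {
    stop("methods must supply paired values of equal length", call. = FALSE)
  }
  if (length(method_a) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- method_a - method_b
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(
    list(bias = bias,
         sd_diff = sd_diff,
         loa_low = bias - loa_multiplier * sd_diff,
         loa_high = bias + loa_multiplier * sd_diff,
         loa_multiplier = loa_multiplier,
         pairs = length(d),
         data = tibble::tibble(mean = (method_a + method_b) / 2,
                               difference = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> %d pairs, bias %.3f, limits of agreement [%.3f, %.3f]\n",
    x$pairs, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' @describeIn bland_altman Per-pair means and differences.
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) x$data

#' @describeIn bland_altman One-row summary (bias, SD, limits, pair count).
#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd_diff = x$sd_diff, loa_low = x$loa_low,
                 loa_high = x$loa_high, pairs = x$pairs)
}

#' Read a long-format rater panel CSV
#'
#' Columns `subject_id`, `rater_id`, `method`, `score`; returns one
#' subjects x raters matrix per method.
#'
#' @param path CSV path.
#' @return Named list of numeric matrices, one per method level.
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "rater_id", "method", "score") %in% names(df)))
  lapply(split(df, df$method), function(d) {
    wide <- tidyr::pivot_wider(tibble::as_tibble(d[c("subject_id", "rater_id", "score")]),
                               names_from = "rater_id", values_from = "score")
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$subject_id
    m
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
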
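#' Spreadsheet-style descriptive statistics of a WQI vector
#'
#' Reproduces the descriptive-statistics block familiar from spreadsheet
#' analysis toolpaks: mean, standard error, median, standard deviation,
#' sample variance (n - 1 denominator), range, minimum, maximum, sum, a
#' Student-t 95% confidence half-width, and the 10/25/50/75/90/95%
#' quantiles by linear interpolation between order statistics with
#' inclusive endpoints ([stats::quantile()] type 7, the spreadsheet
#' convention).
#'
#' @param x Numeric vector of non-negative WQI values, or a `wqi_tbl` from
#'   [compute_wqi()] (its `wqi` column is used; `NA` entries are dropped
#'   with a warning).
#' @param conf_level Confidence level for the t-based half-width
#'   (default 0.95).
#' @return A one-row tibble with columns `n`, `mean`, `se`, `median`, `sd`,
#'   `variance`, `range`, `min`, `max`, `sum`, `ci95_halfwidth`, `q10`,
#'   `q25`, `q50`, `q75`, `q90`, `q95`.
#' @examples
#' describe_wqi(c(6.23, 23.16, 162.08))
#' @export
describe_wqi <- function(x, conf_level = 0.95) {
  if (inherits(x, "wqi_tbl")) x <- x$wqi
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  if (anyNA(x)) {
    warning("dropping ", sum(is.na(x)), " NA value(s)", call. = FALSE)
    x <- x[!is.na(x)]
  }
  n <- length(x)
  if (n < 2) stop("need at least 2 values (variance undefined)", call. = FALSE)
  if (any(x < 0)) stop("WQI values must be non-negative", call. = FALSE)
  sdev <- stats::sd(x)
  se <- sdev / sqrt(n)
  q <- stats::quantile(x, probs = c(.10, .25, .50, .75, .90, .95),
                       type = 7, names = FALSE)
  tibble::tibble(
    n = n,
    mean = mean(x),
    se = se,
    median = stats::median(x),
    sd = sdev,
    variance = stats::var(x),
    range = max(x) - min(x),
    min = min(x),
    max = max(x),
    sum = sum(x),
    ci95_halfwidth = stats::qt(1 - (1 - conf_level) / 2, df = n - 1) * se,
    q10 = q[1], q25 = q[2], q50 = q[3], q75 = q[4], q90 = q[5], q95 = q[6]
  )
}

#' Share of samples in each quality class
#'
#' Tallies classified WQI results into the five quality bands and reports
#' counts and proportions. Every class label appears in the output, with a
#' zero share where no sample falls in it; shares sum to 1.
#'
#' @param x A `wqi_tbl` from [compute_wqi()], a factor of class labels, or
#'   a numeric WQI vector (classified with [classify_wqi()] first).
#' @return A tibble with columns `class`, `n`, `share`.
#' @examples
#' class_shares(c(10, 20, 60, 150))
#' @export
class_shares <- function(x) {
  if (inherits(x, "wqi_tbl")) x <- x$class
  if (is.numeric(x)) x <- classify_wqi(x)
  if (!is.factor(x)) stop("`x` must be a wqi_tbl, factor or numeric vector",
                          call. = FALSE)
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("no classified samples supplied", call. = FALSE)
  x <- factor(as.character(x), levels = wqi_class_labels())
  counts <- table(x)
  tibble::tibble(
    class = factor(names(counts), levels = wqi_class_labels()),
    n = as.integer(counts),
    share = as.numeric(counts) / length(x)
  )
}

#' Plot class shares as a bar chart
#'
#' @param shares A tibble from [class_shares()].
#' @return A ggplot object.
#' @export
plot_class_shares <- function(shares) {
  ggplot2::ggplot(shares, ggplot2::aes(x = .data$class, y = .data$share)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "Share of samples") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
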
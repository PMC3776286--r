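#' Water-quality classification bands
#'
#' The five-band interpretation of WQI values used for drinking water:
#' below 50 excellent, 50--100 good, 100--200 poor, 200--300 very poor,
#' above 300 unsuitable for drinking. Shared band endpoints are resolved
#' half-open: each band includes its lower endpoint and excludes its upper
#' one, so every non-negative WQI receives exactly one label.
#'
#' @return A tibble with columns `class`, `lower`, `upper`.
#' @examples
#' wqi_classes()
#' @export
wqi_classes <- function() {
  tibble::tibble(
    class = wqi_class_labels(),
    lower = c(0, 50, 100, 200, 300),
    upper = c(50, 100, 200, 300, Inf)
  )
}

wqi_class_labels <- function() {
  c("Excellent water quality", "Good water quality", "Poor water quality",
    "Very poor water quality", "Unsuitable for drinking")
}

#' Classify WQI values
#'
#' Maps non-negative WQI values onto the five classification bands (see
#' [wqi_classes()]); bands are closed below and open above, so a WQI of
#' exactly 100 is "Poor water quality".
#'
#' @param wqi Numeric vector of non-negative index values (`NA` passes
#'   through).
#' @return A factor with the five class labels as levels.
#' @examples
#' classify_wqi(c(10, 49.99, 50, 162.08, 300))
#' @export
classify_wqi <- function(wqi) {
  if (!is.numeric(wqi)) stop("`wqi` must be numeric", call. = FALSE)
  if (any(wqi < 0, na.rm = TRUE)) {
    stop("WQI values must be non-negative", call. = FALSE)
  }
  cut(wqi, breaks = c(0, 50, 100, 200, 300, Inf), labels = wqi_class_labels(),
      right = FALSE, include.lowest = TRUE)
}

#' Renormalize weights over the available parameters
#'
#' The dynamic-weight rule: given the subset of parameters actually usable
#' in a record, each weight is divided by the sum of weights over that
#' subset, so the dynamic weights always sum to one and the index keeps its
#' 0--100-anchored scale whatever data are missing.
#'
#' @param criteria A [wq_criteria] tibble.
#' @param used Character vector of parameter names available in the record.
#' @return Named numeric vector of dynamic weights summing to 1.
#' @examples
#' dynamic_weights(default_criteria(), c("ph", "nitrate"))
#' @export
dynamic_weights <- function(criteria, used) {
  stopifnot(inherits(criteria, "wq_criteria"))
  used <- as.character(used)
  if (length(used) == 0) {
    stop("no usable parameters: cannot renormalize weights", call. = FALSE)
  }
  unknown <- setdiff(used, criteria$parameter)
  if (length(unknown) > 0) {
    stop("parameters not in the criteria set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  w <- criteria$weight[match(used, criteria$parameter)]
  if (any(is.na(w) | w <= 0)) {
    stop("all used parameters need a positive weight", call. = FALSE)
  }
  stats::setNames(w / sum(w), used)
}

#' Quality value of a banded (pH-type) parameter
#'
#' Inside the acceptable band the quality value is zero. Below the band it
#' is `(band_low / ph) * 100 * dyn_weight`, penalising acidity; above it,
#' `(ph / band_high) * 100 * dyn_weight`. Band endpoints are inclusive.
#'
#' @param ph Measured pH, in (0, 14].
#' @param dyn_weight Dynamic weight in `[0, 1]`.
#' @param band_low,band_high Acceptable band (default 6.5--8.5).
#' @return Non-negative quality value.
#' @examples
#' quality_value_ph(6.0, 0.5)  # (6.5 / 6.0) * 100 * 0.5
#' @export
quality_value_ph <- function(ph, dyn_weight, band_low = 6.5, band_high = 8.5) {
  if (any(!is.na(ph) & (ph <= 0 | ph > 14))) {
    stop("pH must lie in (0, 14]", call. = FALSE)
  }
  check_weight(dyn_weight)
  out <- numeric(length(ph))
  low <- !is.na(ph) & ph < band_low
  high <- !is.na(ph) & ph > band_high
  dyn_weight <- rep_len(dyn_weight, length(ph))
  out[low] <- band_low / ph[low] * 100 * dyn_weight[low]
  out[high] <- ph[high] / band_high * 100 * dyn_weight[high]
  out[is.na(ph)] <- NA_real_
  out
}

#' Quality value of an upper-limit parameter
#'
#' The measured concentration is normalised against the guideline limit and
#' scaled by the dynamic weight: `conc / limit * 100 * dyn_weight`. A
#' parameter sitting exactly at its limit with full weight contributes 100.
#'
#' @param conc Non-negative concentration (mg/L; NTU for turbidity).
#' @param limit Positive guideline limit, same units.
#' @param dyn_weight Dynamic weight in `[0, 1]`.
#' @return Non-negative quality value.
#' @examples
#' quality_value_generic(25, 50, 0.5)
#' @export
quality_value_generic <- function(conc, limit, dyn_weight) {
  if (any(!is.na(conc) & conc < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (any(is.na(limit) | limit <= 0)) {
    stop("limit values must be positive", call. = FALSE)
  }
  check_weight(dyn_weight)
  conc / limit * 100 * dyn_weight
}

check_weight <- function(w) {
  if (any(!is.na(w) & (w < 0 | w > 1))) {
    stop("dynamic weights must lie in [0, 1]", call. = FALSE)
  }
  invisible(w)
}

#' Resolve which parameters are usable in each record
#'
#' A parameter enters a record's index computation only if it is globally
#' included in the criteria set, its per-record selection code is neither
#' `-1` (excluded for this record) nor `0` (no data), and its value is
#' present. Everything else is skipped with a reason: `excluded_globally`,
#' `excluded_override` or `no_data`. Selection codes are read from optional
#' `<parameter>_code` columns; a global exclusion cannot be re-enabled per
#' record.
#'
#' @param data A data frame of samples: one row per sample, one numeric
#'   column per parameter, optional `sample_id` and `<parameter>_code`
#'   columns.
#' @param criteria A [wq_criteria] tibble.
#' @return A tibble with columns `sample_id`, `parameter`, `status`
#'   (`"used"` or a skip reason).
#' @examples
#' d <- data.frame(ph = 7.2, nitrate = NA, tds = 400)
#' resolve_availability(d, default_criteria())
#' @export
resolve_availability <- function(data, criteria) {
  av <- availability(data, criteria)
  tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(sample_id = av$sample_id),
                     tibble::as_tibble(av$status)),
    -"sample_id", names_to = "parameter", values_to = "status"
  )
}

# Matrix-form availability resolution shared by resolve_availability() and
# compute_wqi(). Returns per-record value, code and status matrices over the
# criteria parameters (columns in criteria order).
availability <- function(data, criteria) {
  stopifnot(inherits(criteria, "wq_criteria"))
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  if (n == 0) stop("no sample records supplied", call. = FALSE)
  sample_id <- if ("sample_id" %in% names(data)) {
    as.character(data$sample_id)
  } else {
    sprintf("S%d", seq_len(n))
  }
  params <- criteria$parameter
  p <- length(params)

  vals <- matrix(NA_real_, n, p, dimnames = list(NULL, params))
  codes <- matrix(NA_real_, n, p, dimnames = list(NULL, params))
  for (j in seq_len(p)) {
    if (params[j] %in% names(data)) {
      v <- data[[params[j]]]
      if (!is.numeric(v)) {
        stop("column `", params[j], "` must be numeric", call. = FALSE)
      }
      vals[, j] <- as.numeric(v)
    }
    code_col <- paste0(params[j], "_code")
    if (code_col %in% names(data)) {
      cd <- as.numeric(data[[code_col]])
      bad <- !is.na(cd) & !cd %in% c(-1, 0, 1)
      if (any(bad)) {
        stop("selection codes in `", code_col, "` must be -1, 0 or 1",
             call. = FALSE)
      }
      codes[, j] <- cd
    }
  }

  status <- matrix("used", n, p, dimnames = list(NULL, params))
  excluded <- matrix(rep(!criteria$included, each = n), n, p)
  status[excluded] <- "excluded_globally"
  override <- !excluded & !is.na(codes) & codes == -1
  status[override] <- "excluded_override"
  nodata <- !excluded & !override & (is.na(vals) | (!is.na(codes) & codes == 0))
  status[nodata] <- "no_data"

  list(sample_id = sample_id, values = vals, status = status,
       used = status == "used")
}

#' Compute the water quality index
#'
#' The package's central computation. For each sample the usable parameters
#' are resolved (see [resolve_availability()]), weights are renormalized
#' over that subset, each parameter's quality value is computed
#' ([quality_value_generic()]; [quality_value_ph()] for the banded
#' parameter), and the WQI is their sum, classified into the five quality
#' bands.
#'
#' @param data A data frame of samples (see [resolve_availability()] for
#'   the expected columns). Columns not named by the criteria set (other
#'   than `sample_id`, `location` and `<parameter>_code`) are ignored here;
#'   [read_samples()] performs strict column validation.
#' @param criteria A [wq_criteria] tibble; defaults to [default_criteria()].
#' @param on_empty What to do with a record in which no parameter is
#'   usable: `"error"` (default) or `"na"` (WQI set to `NA`, record kept).
#' @return A tibble of class `wqi_tbl` with one row per sample: `sample_id`,
#'   `n_used`, `wqi`, `class`. Per-parameter detail is attached and
#'   retrieved with [wqi_details()] (dynamic weights and quality values of
#'   used parameters) and [wqi_skipped()] (skip reasons).
#' @examples
#' d <- data.frame(sample_id = "A", ph = 7.1, nitrate = 10)
#' r <- compute_wqi(d)
#' r$wqi  # 10 / 50 * 100 * (5 / 9)
#' wqi_details(r)
#' @export
compute_wqi <- function(data, criteria = default_criteria(),
                        on_empty = c("error", "na")) {
  on_empty <- match.arg(on_empty)
  av <- availability(data, criteria)
  n <- nrow(av$values)
  params <- criteria$parameter
  banded <- is_banded(criteria)

  empty <- rowSums(av$used) == 0
  if (any(empty)) {
    msg <- paste0("no usable parameters for sample(s): ",
                  paste(av$sample_id[empty], collapse = ", "))
    if (on_empty == "error") stop(msg, call. = FALSE)
  }

  used_vals <- av$values
  used_vals[!av$used] <- NA_real_
  neg <- !is.na(used_vals) & used_vals < 0 &
    matrix(rep(!banded, each = n), n, length(params))
  if (any(neg)) {
    stop("negative concentrations for sample(s): ",
         paste(unique(av$sample_id[rowSums(neg) > 0]), collapse = ", "),
         call. = FALSE)
  }
  if (any(banded)) {
    phv <- used_vals[, which(banded)]
    bad <- !is.na(phv) & (phv <= 0 | phv > 14)
    if (any(bad)) {
      stop("pH outside (0, 14] for sample(s): ",
           paste(av$sample_id[bad], collapse = ", "), call. = FALSE)
    }
  }

  w <- criteria$weight
  denom <- av$used %*% w
  dynw <- sweep(av$used, 2, w, `*`) / as.vector(denom)
  dynw[!av$used] <- NA_real_

  qv <- matrix(NA_real_, n, length(params), dimnames = list(NULL, params))
  for (j in seq_along(params)) {
    rows <- av$used[, j]
    if (!any(rows)) next
    qv[rows, j] <- if (banded[j]) {
      quality_value_ph(av$values[rows, j], dynw[rows, j],
                       criteria$band_low[j], criteria$band_high[j])
    } else {
      quality_value_generic(av$values[rows, j], criteria$limit[j],
                            dynw[rows, j])
    }
  }

  wqi <- rowSums(qv, na.rm = TRUE)
  wqi[empty] <- NA_real_

  # A record whose only usable parameter is an in-band pH scores 0
  # ("excellent") on no real evidence; keep it but flag it.
  ph_only <- rep(FALSE, n)
  if (any(banded)) {
    ph_only <- rowSums(av$used) == 1 & av$used[, which(banded)] & !empty
    if (any(ph_only)) {
      warning("WQI based only on an in-band ", params[which(banded)],
              " for sample(s): ",
              paste(av$sample_id[ph_only], collapse = ", "), call. = FALSE)
    }
  }

  out <- tibble::tibble(
    sample_id = av$sample_id,
    n_used = as.integer(rowSums(av$used)),
    wqi = wqi,
    class = classify_wqi(wqi)
  )

  details <- tibble::tibble(
    sample_id = rep(av$sample_id, each = length(params)),
    parameter = rep(params, times = n),
    value = as.vector(t(av$values)),
    dynamic_weight = as.vector(t(dynw)),
    quality_value = as.vector(t(qv))
  )
  details <- details[as.vector(t(av$used)), , drop = FALSE]

  skipped <- resolve_long(av)
  skipped <- skipped[skipped$status != "used", , drop = FALSE]
  names(skipped)[names(skipped) == "status"] <- "reason"

  attr(out, "details") <- details
  attr(out, "skipped") <- skipped
  attr(out, "flagged") <- av$sample_id[ph_only]
  attr(out, "criteria") <- criteria
  class(out) <- c("wqi_tbl", class(out))
  out
}

resolve_long <- function(av) {
  tibble::tibble(
    sample_id = rep(av$sample_id, each = ncol(av$status)),
    parameter = rep(colnames(av$status), times = nrow(av$status)),
    status = as.vector(t(av$status))
  )
}

#' Per-parameter detail of a WQI computation
#'
#' @param x A `wqi_tbl` from [compute_wqi()].
#' @return `wqi_details()`: a tibble of used parameters per sample with
#'   `value`, `dynamic_weight` and `quality_value`; dynamic weights sum to 1
#'   and quality values sum to the sample's WQI. `wqi_skipped()`: a tibble
#'   of skipped parameters with their `reason`.
#' @export
wqi_details <- function(x) {
  stopifnot(inherits(x, "wqi_tbl"))
  attr(x, "details")
}

#' @rdname wqi_details
#' @export
wqi_skipped <- function(x) {
  stopifnot(inherits(x, "wqi_tbl"))
  attr(x, "skipped")
}

#' Plot the WQI distribution with classification bands
#'
#' Histogram of computed index values with the class band boundaries
#' overlaid.
#'
#' @param object A `wqi_tbl` from [compute_wqi()].
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.wqi_tbl <- function(object, bins = 30, ...) {
  breaks <- wqi_classes()$lower[-1]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wqi)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = breaks, linetype = "dashed",
                        colour = "grey30") +
    ggplot2::labs(x = "Water quality index", y = "Samples") +
    ggplot2::theme_minimal()
}
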
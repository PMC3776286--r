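#' Build a water-quality criteria set
#'
#' A criteria set defines the index: which parameters enter the WQI, their
#' weight factors, and the guideline limit they are normalised against. All
#' parameters but pH carry a single upper limit (mg/L; NTU for turbidity);
#' pH carries an acceptable band (`band_low`--`band_high`, pH units) inside
#' which its quality value is zero.
#'
#' @param x A data frame with columns `parameter` (character, unique),
#'   `weight` (positive numeric), and either `limit` (positive, for
#'   upper-limit parameters) or `band_low`/`band_high` (for the single banded
#'   parameter). An optional logical column `included` (default `TRUE`)
#'   carries the global selection flag: excluded parameters stay in the set
#'   but never enter a computation unless re-included.
#'
#' @return A `wq_criteria` tibble with columns `parameter`, `weight`,
#'   `limit`, `band_low`, `band_high`, `included`.
#'
#' @details Constraints enforced: unique parameter names; at most 40
#'   parameters; positive weight for every included parameter; at most one
#'   banded parameter per set; `band_low < band_high`; at least one included
#'   parameter.
#'
#' @examples
#' wq_criteria(data.frame(parameter = c("nitrate", "fluoride"),
#'                        weight = c(5, 4), limit = c(50, 1.5)))
#' @export
wq_criteria <- function(x) {
  x <- tibble::as_tibble(x)
  if (!all(c("parameter", "weight") %in% names(x))) {
    stop("criteria need at least `parameter` and `weight` columns", call. = FALSE)
  }
  if (!"limit" %in% names(x)) x$limit <- NA_real_
  if (!"band_low" %in% names(x)) x$band_low <- NA_real_
  if (!"band_high" %in% names(x)) x$band_high <- NA_real_
  if (!"included" %in% names(x)) x$included <- TRUE
  x <- dplyr::mutate(
    x,
    parameter = as.character(.data$parameter),
    dplyr::across(c("weight", "limit", "band_low", "band_high"), as.numeric),
    included = as.logical(.data$included)
  )
  x <- dplyr::select(x, "parameter", "weight", "limit", "band_low",
                     "band_high", "included")
  validate_criteria(x)
  class(x) <- c("wq_criteria", class(x))
  x
}

validate_criteria <- function(x) {
  if (nrow(x) == 0) stop("criteria set is empty", call. = FALSE)
  if (nrow(x) > 40) {
    stop("criteria sets support at most 40 parameters; got ", nrow(x),
         call. = FALSE)
  }
  if (anyDuplicated(x$parameter)) {
    dups <- unique(x$parameter[duplicated(x$parameter)])
    stop("duplicated parameter names: ", paste(dups, collapse = ", "),
         call. = FALSE)
  }
  banded <- is_banded(x)
  if (sum(banded) > 1) {
    stop("at most one banded (pH-type) parameter is allowed per criteria set",
         call. = FALSE)
  }
  bad_band <- banded & !(x$band_low < x$band_high)
  if (any(bad_band)) {
    stop("band_low must be less than band_high for ",
         paste(x$parameter[bad_band], collapse = ", "), call. = FALSE)
  }
  needs_limit <- !banded
  bad_limit <- needs_limit & (is.na(x$limit) | x$limit <= 0)
  if (any(bad_limit)) {
    stop("missing or non-positive limit for: ",
         paste(x$parameter[bad_limit], collapse = ", "), call. = FALSE)
  }
  bad_w <- x$included & (is.na(x$weight) | x$weight <= 0)
  if (any(bad_w)) {
    stop("included parameters need a positive weight: ",
         paste(x$parameter[bad_w], collapse = ", "), call. = FALSE)
  }
  if (!any(x$included)) {
    stop("criteria set has no included parameter", call. = FALSE)
  }
  invisible(x)
}

is_banded <- function(criteria) {
  !is.na(criteria$band_low) & !is.na(criteria$band_high)
}

#' Default drinking-water criteria set
#'
#' The 13-parameter drinking-water index definition used throughout the
#' package: pH (acceptable band 6.5--8.5), calcium, magnesium, chloride,
#' total dissolved solids (TDS), fluoride, manganese, nitrate, iron,
#' sulfate, ammonium, sodium and turbidity, with weight factors and
#' guideline limit values (mg/L; NTU for turbidity). Total hardness is
#' shipped in the set but excluded by default: it is a linear function of
#' calcium and magnesium, and including all three would double-count
#' hardness in the index.
#'
#' @param include_hardness Include total hardness (weight 2, limit
#'   500 mg/L) in computations. Default `FALSE`.
#'
#' @return A [wq_criteria] tibble.
#' @examples
#' default_criteria()
#' @export
default_criteria <- function(include_hardness = FALSE) {
  x <- tibble::tribble(
    ~parameter,       ~weight, ~limit, ~band_low, ~band_high,
    "ph",                   4,     NA,       6.5,        8.5,
    "calcium",              2,    300,        NA,         NA,
    "magnesium",            2,     30,        NA,         NA,
    "chloride",             3,    250,        NA,         NA,
    "tds",                  4,   1000,        NA,         NA,
    "fluoride",             4,    1.5,        NA,         NA,
    "manganese",            4,    0.1,        NA,         NA,
    "nitrate",              5,     50,        NA,         NA,
    "iron",                 4,    0.3,        NA,         NA,
    "sulfate",              4,    250,        NA,         NA,
    "ammonium",             3,    1.5,        NA,         NA,
    "sodium",               3,    200,        NA,         NA,
    "turbidity",            4,      5,        NA,         NA,
    "total_hardness",       2,    500,        NA,         NA
  )
  x$included <- c(rep(TRUE, 13), isTRUE(include_hardness))
  wq_criteria(x)
}

#' Read or write a criteria set as JSON
#'
#' Plain-text JSON persistence for criteria configurations, so an index
#' definition can be versioned next to the data it scores. `NA` band/limit
#' fields are dropped on write and restored on read.
#'
#' @param path File path.
#' @param criteria A [wq_criteria] tibble.
#' @return `read_criteria()` returns a [wq_criteria] tibble;
#'   `write_criteria()` returns `path` invisibly.
#' @export
read_criteria <- function(path) {
  if (!file.exists(path)) stop("criteria file not found: ", path, call. = FALSE)
  wq_criteria(jsonlite::fromJSON(path))
}

#' @rdname read_criteria
#' @export
write_criteria <- function(criteria, path) {
  stopifnot(inherits(criteria, "wq_criteria"))
  jsonlite::write_json(as.data.frame(criteria), path, auto_unbox = FALSE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

# Included parameters of a criteria set, in set order.
included_parameters <- function(criteria) {
  criteria$parameter[criteria$included]
}
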
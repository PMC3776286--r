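#' Read a wide-format sample table
#'
#' Reads a CSV (RFC 4180, UTF-8, decimal point) or xlsx file with one row
#' per sample and one column per parameter, validates it against a criteria
#' set, and returns a tibble ready for [compute_wqi()]. Optional columns:
#' `sample_id`, `location`, and a `<parameter>_code` selection-code column
#' per parameter (codes `1` include, `-1` exclude for that record, `0` no
#' data; blanks mean no override). Blank or `NA` cells are missing values —
#' there is no need to type an explicit `0` code for them. Rows with
#' non-numeric text in a numeric column are logged and skipped; the
#' skipped-row count is reported in a message and in the `parse_log`
#' attribute.
#'
#' @param path Path to a `.csv` or `.xlsx` file.
#' @param criteria A [wq_criteria] tibble the columns are validated
#'   against; columns naming parameters outside the set are an error.
#' @param format `"csv"` or `"xlsx"`; inferred from the extension by
#'   default.
#' @return A tibble with attributes `parse_log` (tibble of skipped rows and
#'   issues) and `source` (the input path).
#' @export
read_samples <- function(path, criteria = default_criteria(), format = NULL) {
  stopifnot(inherits(criteria, "wq_criteria"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  raw <- switch(
    format,
    csv = readr::read_csv(path, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE),
    xlsx = {
      x <- readxl::read_excel(path, col_types = "text")
      tibble::as_tibble(x)
    },
    stop("unsupported format: ", format, call. = FALSE)
  )

  params <- criteria$parameter
  meta_cols <- c("sample_id", "location")
  code_cols <- paste0(params, "_code")
  unknown <- setdiff(names(raw), c(meta_cols, params, code_cols))
  if (length(unknown) > 0) {
    stop("unknown parameter column(s): ", paste(unknown, collapse = ", "),
         "; declare them in the criteria set first", call. = FALSE)
  }

  numeric_cols <- intersect(names(raw), c(params, code_cols))
  parsed <- raw
  bad_cells <- matrix(FALSE, nrow(raw), length(numeric_cols))
  for (j in seq_along(numeric_cols)) {
    cell <- trimws(raw[[numeric_cols[j]]])
    cell[cell == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(cell))
    bad_cells[, j] <- !is.na(cell) & is.na(num)
    parsed[[numeric_cols[j]]] <- num
  }
  bad_rows <- rowSums(bad_cells) > 0
  log <- tibble::tibble(row = integer(), issue = character())
  if (any(bad_rows)) {
    for (i in which(bad_rows)) {
      cols <- numeric_cols[bad_cells[i, ]]
      log <- dplyr::bind_rows(log, tibble::tibble(
        row = i,
        issue = paste0("non-numeric value in ", paste(cols, collapse = ", "))
      ))
    }
    message("skipped ", sum(bad_rows), " malformed row(s) of ", nrow(raw))
    parsed <- parsed[!bad_rows, , drop = FALSE]
  }
  if (!"sample_id" %in% names(parsed)) {
    parsed$sample_id <- sprintf("S%d", seq_len(nrow(parsed)))
  }
  parsed <- dplyr::relocate(parsed, "sample_id")
  attr(parsed, "parse_log") <- log
  attr(parsed, "source") <- path
  parsed
}

#' Write the three-part monitoring report
#'
#' Emits the standard three-part report of an index run: part 1 ("Original
#' Data") echoes the input table verbatim, part 2 ("Quality Values") holds
#' the per-parameter quality values of each sample, and part 3 ("Water
#' Quality Index") the WQI and its interpretation. Parts are written as
#' three CSV files named `<stem>_original_data.csv`,
#' `<stem>_quality_values.csv` and `<stem>_water_quality_index.csv`, at
#' full numeric precision (rounding is a display concern; see the CLI's
#' `--round`).
#'
#' @param data The sample tibble the results were computed from.
#' @param results A `wqi_tbl` from [compute_wqi()], aligned 1:1 with
#'   `data`.
#' @param path Output stem: a path with or without a `.csv` extension.
#' @param format Only `"csv"` is supported; `"xlsx"` signals an error (no
#'   xlsx writer is a declared dependency).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_report <- function(data, results, path, format = c("csv", "xlsx")) {
  format <- match.arg(format)
  if (format == "xlsx") {
    stop("xlsx report output is not supported; use format = \"csv\"",
         call. = FALSE)
  }
  stopifnot(inherits(results, "wqi_tbl"))
  data <- tibble::as_tibble(data)
  if (nrow(data) != nrow(results)) {
    stop("results (", nrow(results), " rows) do not align with data (",
         nrow(data), " rows)", call. = FALSE)
  }
  stem <- sub("\\.csv$", "", path, ignore.case = TRUE)
  dir <- dirname(stem)
  if (!dir.exists(dir)) {
    stop("output directory does not exist: ", dir, call. = FALSE)
  }
  paths <- c(
    original_data = paste0(stem, "_original_data.csv"),
    quality_values = paste0(stem, "_quality_values.csv"),
    water_quality_index = paste0(stem, "_water_quality_index.csv")
  )

  readr::write_csv(data, paths[["original_data"]], na = "")

  qv <- wqi_details(results)
  qv_wide <- tidyr::pivot_wider(
    qv[, c("sample_id", "parameter", "quality_value")],
    names_from = "parameter", values_from = "quality_value"
  )
  # keep report rows in dataset order, including samples with nothing used
  qv_wide <- dplyr::left_join(results[, "sample_id"], qv_wide,
                              by = "sample_id")
  readr::write_csv(qv_wide, paths[["quality_values"]], na = "")

  part3 <- tibble::tibble(
    sample_id = results$sample_id,
    wqi = results$wqi,
    interpretation = as.character(results$class)
  )
  readr::write_csv(part3, paths[["water_quality_index"]], na = "")

  invisible(paths)
}
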
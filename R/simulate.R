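#' Configuration for the synthetic drinking-water generator
#'
#' Describes the joint distribution the generator draws from: lognormal
#' marginals for concentrations (positivity and the right skew typical of
#' hydrochemical data), a truncated normal for pH, a block correlation
#' structure on the latent (log-concentration) scale, and independent
#' per-cell missingness (MCAR).
#'
#' @param marginals A data frame with columns `parameter`, `meanlog`,
#'   `sdlog` (log-concentration scale) for every non-pH parameter.
#' @param blocks Named list of blocks, each `list(parameters = <chr>,
#'   r = <within-block correlation in [0, 1)>)`. Parameters not named in
#'   any block are independent. Blocks must be disjoint.
#' @param ph_mean,ph_sd Mean and SD of pH (pH units), truncated to (0, 14].
#' @param missing_rate Per-cell missingness probability in `[0, 1)`; a
#'   scalar applied to every parameter or a named vector.
#' @return A list of class `wq_sim_config`.
#' @seealso [default_sim_config()], [simulate_samples()]
#' @export
sim_config <- function(marginals, blocks = list(), ph_mean = 7.4, ph_sd = 0.4,
                       missing_rate = 0.05) {
  marginals <- tibble::as_tibble(marginals)
  stopifnot(all(c("parameter", "meanlog", "sdlog") %in% names(marginals)))
  block_params <- unlist(lapply(blocks, `[[`, "parameters"))
  if (anyDuplicated(block_params)) {
    stop("correlation blocks must be disjoint", call. = FALSE)
  }
  rs <- vapply(blocks, `[[`, numeric(1), "r")
  if (any(rs < 0 | rs >= 1)) {
    stop("within-block correlations must lie in [0, 1)", call. = FALSE)
  }
  params <- c("ph", marginals$parameter)
  unknown <- setdiff(block_params, params)
  if (length(unknown) > 0) {
    stop("block parameters without marginals: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(missing_rate < 0 | missing_rate >= 1)) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  structure(list(marginals = marginals, blocks = blocks, ph_mean = ph_mean,
                 ph_sd = ph_sd, missing_rate = missing_rate),
            class = "wq_sim_config")
}

#' Default synthetic-data configuration
#'
#' Emulates a national drinking-water monitoring dataset over the 13
#' default criteria parameters: a six-parameter salinity block (magnesium,
#' chloride, TDS, fluoride, sulfate, sodium; within-block correlation
#' 0.85), a hardness block (calcium, manganese; 0.6), a surface-impact
#' block (nitrate, turbidity; 0.6), with ammonium, iron and pH independent.
#' Lognormal marginals place each parameter's median concentration at half
#' its guideline limit (`meanlog = log(limit / 2)`, `sdlog = 0.6`); pH is
#' normal with mean 7.4 and SD 0.4. Cells go missing independently at rate
#' 0.05.
#'
#' @return A `wq_sim_config`.
#' @examples
#' default_sim_config()
#' @export
default_sim_config <- function() {
  crit <- default_criteria()
  conc <- crit[crit$included & crit$parameter != "ph", ]
  sim_config(
    marginals = tibble::tibble(
      parameter = conc$parameter,
      meanlog = log(conc$limit / 2),
      sdlog = 0.6
    ),
    blocks = list(
      salinity = list(parameters = c("magnesium", "chloride", "tds",
                                     "fluoride", "sulfate", "sodium"),
                      r = 0.85),
      hardness = list(parameters = c("calcium", "manganese"), r = 0.6),
      surface = list(parameters = c("nitrate", "turbidity"), r = 0.6)
    ),
    ph_mean = 7.4, ph_sd = 0.4,
    missing_rate = 0.05
  )
}

# Latent correlation matrix implied by a config's blocks.
sim_correlation <- function(config) {
  params <- c("ph", config$marginals$parameter)
  p <- length(params)
  R <- diag(p)
  dimnames(R) <- list(params, params)
  for (b in config$blocks) {
    idx <- match(b$parameters, params)
    R[idx, idx] <- b$r
    for (i in idx) R[i, i] <- 1
  }
  R
}

#' Generate a synthetic drinking-water dataset
#'
#' Draws correlated latent normals per block, maps concentration
#' parameters through `exp()` to strictly positive values, draws pH from a
#' truncated normal on (0, 14], and then blanks cells independently at the
#' configured missingness rates. Output is byte-identical for identical
#' `(config, n, seed)`.
#'
#' @param n Number of sample records.
#' @param config A `wq_sim_config`; defaults to [default_sim_config()].
#' @param seed Integer RNG seed (required, for reproducibility).
#' @param missing_rate Optional override of the config's missingness rate.
#' @return A tibble with `sample_id` and one numeric column per parameter;
#'   missing cells are `NA`.
#' @examples
#' simulate_samples(5, seed = 1)
#' @export
simulate_samples <- function(n, config = default_sim_config(), seed,
                             missing_rate = NULL) {
  stopifnot(inherits(config, "wq_sim_config"), n >= 1)
  if (missing(seed)) stop("`seed` is required for reproducibility",
                          call. = FALSE)
  if (!is.null(missing_rate)) config$missing_rate <- missing_rate
  if (any(config$missing_rate < 0 | config$missing_rate >= 1)) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }

  R <- sim_correlation(config)
  params <- colnames(R)
  p <- length(params)
  L <- tryCatch(chol(R), error = function(e) {
    stop("implied correlation matrix is not positive definite", call. = FALSE)
  })

  set.seed(as.integer(seed))
  Z <- matrix(stats::rnorm(n * p), n, p) %*% L
  colnames(Z) <- params

  X <- matrix(NA_real_, n, p, dimnames = list(NULL, params))
  for (v in config$marginals$parameter) {
    m <- config$marginals[config$marginals$parameter == v, ]
    X[, v] <- exp(m$meanlog + m$sdlog * Z[, v])
  }
  ph <- config$ph_mean + config$ph_sd * Z[, "ph"]
  # truncate pH to (0, 14] by redrawing offenders (pH is independent of the
  # blocks, so redraws do not disturb the correlation structure)
  out_of_range <- ph <= 0 | ph > 14
  while (any(out_of_range)) {
    ph[out_of_range] <- stats::rnorm(sum(out_of_range), config$ph_mean,
                                     config$ph_sd)
    out_of_range <- ph <= 0 | ph > 14
  }
  X[, "ph"] <- ph

  rates <- if (length(config$missing_rate) == 1) {
    stats::setNames(rep(config$missing_rate, p), params)
  } else {
    config$missing_rate[params]
  }
  for (v in params) {
    if (rates[[v]] > 0) {
      X[stats::runif(n) < rates[[v]], v] <- NA_real_
    }
  }

  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("S%05d", seq_len(n))),
    tibble::as_tibble(X)
  )
}
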
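#' Keep only complete cases over the included criteria parameters
#'
#' PCA requires a complete data matrix, so records missing any included
#' parameter are dropped first. A parameter column absent from the data
#' counts as missing for every record.
#'
#' @param data A data frame of samples.
#' @param criteria A [wq_criteria] tibble; defaults to [default_criteria()].
#' @return The subset of `data` rows with a present value for every
#'   included parameter, with attribute `n_dropped`.
#' @examples
#' d <- data.frame(nitrate = c(1, NA, 3), fluoride = c(0.2, 0.3, 0.4))
#' crit <- wq_criteria(data.frame(parameter = c("nitrate", "fluoride"),
#'                                weight = c(5, 4), limit = c(50, 1.5)))
#' filter_complete(d, crit)
#' @export
filter_complete <- function(data, criteria = default_criteria()) {
  stopifnot(inherits(criteria, "wq_criteria"))
  data <- tibble::as_tibble(data)
  params <- included_parameters(criteria)
  present <- vapply(params, function(p) {
    if (p %in% names(data)) !is.na(data[[p]]) else rep(FALSE, nrow(data))
  }, logical(nrow(data)))
  if (nrow(data) == 1) present <- matrix(present, nrow = 1)
  keep <- rowSums(present) == length(params)
  out <- data[keep, , drop = FALSE]
  if (nrow(out) < length(params) + 1) {
    stop("only ", nrow(out), " complete record(s) for ", length(params),
         " parameters; PCA is underdetermined", call. = FALSE)
  }
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Kaiser retention rule
#'
#' Retains the components whose eigenvalue (equivalently, SS loading for an
#' unrotated solution) strictly exceeds 1 — a component must explain more
#' variance than a single standardized variable to be kept.
#'
#' @param eigenvalues Numeric vector of eigenvalues sorted in decreasing
#'   order.
#' @return Integer indices of the retained components.
#' @examples
#' kaiser_retain(c(6.09, 1.76, 1.34, 1.19, 0.9, 0.5))
#' @export
kaiser_retain <- function(eigenvalues) {
  if (!is.numeric(eigenvalues) || length(eigenvalues) == 0) {
    stop("`eigenvalues` must be a non-empty numeric vector", call. = FALSE)
  }
  if (is.unsorted(rev(eigenvalues), strictly = FALSE)) {
    stop("eigenvalues must be sorted in decreasing order", call. = FALSE)
  }
  keep <- which(eigenvalues > 1)
  if (length(keep) == 0) {
    stop("no eigenvalue exceeds 1; specify the number of components manually",
         call. = FALSE)
  }
  keep
}

#' Loading diagnostics: SS loadings, explained variance, communalities
#'
#' From a p x k matrix of correlation-scaled loadings, computes the column
#' sums of squares (SS loadings; equal to the eigenvalues for an unrotated
#' solution), the proportion of total variance each component explains
#' (`ss / p`), the proportion of the *retained* variance it explains
#' (`ss / sum(ss)`), their running totals, and the per-variable communality
#' `h2` (row sum of squares) and uniqueness `u2 = 1 - h2`.
#'
#' @param loadings Numeric p x k matrix.
#' @param n_vars Number of variables p the proportions refer to; defaults
#'   to `nrow(loadings)`.
#' @return A list with elements `ss_loadings`, `proportion_var`,
#'   `cumulative_var`, `proportion_explained`, `cumulative_proportion`
#'   (length k) and `h2`, `u2` (length p).
#' @examples
#' L <- cbind(c(0.9, 0.1), c(-0.1, 0.8))
#' loading_diagnostics(L)
#' @export
loading_diagnostics <- function(loadings, n_vars = nrow(loadings)) {
  loadings <- as.matrix(loadings)
  if (ncol(loadings) < 1) stop("need at least one component", call. = FALSE)
  ss <- colSums(loadings^2)
  h2 <- rowSums(loadings^2)
  if (any(h2 > 1 + 1e-6)) {
    stop("communalities exceed 1: loadings are not correlation-scaled",
         call. = FALSE)
  }
  list(
    ss_loadings = ss,
    proportion_var = ss / n_vars,
    cumulative_var = cumsum(ss / n_vars),
    proportion_explained = ss / sum(ss),
    cumulative_proportion = cumsum(ss / sum(ss)),
    h2 = h2,
    u2 = 1 - h2
  )
}

#' Principal component analysis on the correlation matrix
#'
#' Standardizes the selected columns to z-scores, eigendecomposes their
#' correlation matrix, scales eigenvectors to correlation loadings
#' (`loading[i, j] = eigvec[i, j] * sqrt(eigval[j])`), retains components
#' by the Kaiser rule ([kaiser_retain()]) unless `n_components` is given,
#' and computes standardized (mean-0, variance-1) component scores. Each
#' component's sign is fixed so its largest-magnitude loading is positive.
#' An optional varimax rotation of the retained loadings is available for
#' sensitivity checks; SS loadings then no longer equal eigenvalues.
#'
#' @param data A data frame with no missing values in the selected columns
#'   (see [filter_complete()]).
#' @param vars Character vector of columns to analyse; defaults to every
#'   included parameter of `criteria` present in the data.
#' @param criteria Criteria set supplying the default `vars`.
#' @param rotate `"none"` (default) or `"varimax"`.
#' @param n_components Optional fixed number of components, overriding the
#'   Kaiser rule.
#' @return An object of class `wq_pca`: a list with `loadings` (p x k),
#'   `eigenvalues` (all p), `retained`, `ss_loadings`, `proportion_var`,
#'   `cumulative_var`, `proportion_explained`, `cumulative_proportion`,
#'   `h2`, `u2`, `scores` (n x k, standardized), `rotation`, `vars`, `n`.
#'   Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' set.seed(1)
#' d <- as.data.frame(matrix(rnorm(300), 100, 3))
#' wq_pca(d, vars = names(d))
#' @export
wq_pca <- function(data, vars = NULL, criteria = default_criteria(),
                   rotate = c("none", "varimax"), n_components = NULL) {
  rotate <- match.arg(rotate)
  data <- tibble::as_tibble(data)
  if (is.null(vars)) {
    vars <- intersect(included_parameters(criteria), names(data))
  }
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    stop("columns not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(data[vars])
  if (!is.numeric(X)) stop("selected columns must be numeric", call. = FALSE)
  if (anyNA(X)) {
    stop("missing values in the data matrix; apply filter_complete() first",
         call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X)
  if (n <= p) {
    stop("need more records (", n, ") than variables (", p, ")", call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(vars[sds == 0], collapse = ", "),
         call. = FALSE)
  }

  Z <- scale(X)
  R <- stats::cor(X)
  e <- eigen(R, symmetric = TRUE)
  eigenvalues <- e$values

  retained <- if (is.null(n_components)) {
    kaiser_retain(eigenvalues)
  } else {
    seq_len(n_components)
  }
  k <- length(retained)

  vecs <- e$vectors[, retained, drop = FALSE]
  # eigenvector sign is arbitrary; anchor each component's dominant loading
  # positive for reproducible output
  flip <- apply(vecs, 2, function(v) sign(v[which.max(abs(v))]))
  vecs <- sweep(vecs, 2, flip, `*`)

  loadings <- sweep(vecs, 2, sqrt(eigenvalues[retained]), `*`)
  scores <- sweep(Z %*% vecs, 2, sqrt(eigenvalues[retained]), `/`)

  if (rotate == "varimax") {
    rot <- stats::varimax(loadings)
    loadings <- unclass(rot$loadings)
    scores <- scores %*% rot$rotmat
    # re-anchor signs after rotation
    flip2 <- apply(loadings, 2, function(v) sign(v[which.max(abs(v))]))
    loadings <- sweep(loadings, 2, flip2, `*`)
    scores <- sweep(scores, 2, flip2, `*`)
  }
  dimnames(loadings) <- list(vars, paste0("PC", seq_len(k)))
  colnames(scores) <- paste0("PC", seq_len(k))

  diag_ <- loading_diagnostics(loadings, n_vars = p)
  structure(
    c(list(loadings = loadings, eigenvalues = eigenvalues,
           retained = retained, scores = scores, rotation = rotate,
           vars = vars, n = n, p = p),
      diag_),
    class = "wq_pca"
  )
}

#' @export
print.wq_pca <- function(x, digits = 2, ...) {
  k <- ncol(x$loadings)
  cat("Correlation-matrix PCA (", x$p, " variables, n = ", x$n, ", ",
      k, " component(s) retained, rotation: ", x$rotation, ")\n\n", sep = "")
  tab <- cbind(round(x$loadings, digits), h2 = round(x$h2, digits),
               u2 = round(x$u2, digits + 1))
  print(tab, ...)
  cat("\n")
  summ <- rbind(`SS loadings` = x$ss_loadings,
                `Proportion Var` = x$proportion_var,
                `Cumulative Var` = x$cumulative_var,
                `Proportion explained` = x$proportion_explained,
                `Cumulative proportion` = x$cumulative_proportion)
  colnames(summ) <- colnames(x$loadings)
  print(round(summ, digits))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PCA fit into a long loading table
#'
#' @param x A `wq_pca` object.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `component`, `loading`, `h2`,
#'   `u2`.
#' @method tidy wq_pca
#' @export
tidy.wq_pca <- function(x, ...) {
  out <- tibble::as_tibble(x$loadings, rownames = "parameter")
  out <- tidyr::pivot_longer(out, -"parameter", names_to = "component",
                             values_to = "loading")
  dplyr::left_join(
    out,
    tibble::tibble(parameter = x$vars, h2 = x$h2, u2 = x$u2),
    by = "parameter"
  )
}

#' One-row summary of a PCA fit
#'
#' @param x A `wq_pca` object.
#' @param ... Unused.
#' @return A tibble with `n`, `p`, `k`, `cumulative_var` (variance share of
#'   the retained components) and `rotation`.
#' @method glance wq_pca
#' @export
glance.wq_pca <- function(x, ...) {
  tibble::tibble(
    n = x$n, p = x$p, k = ncol(x$loadings),
    cumulative_var = x$cumulative_var[length(x$cumulative_var)],
    rotation = x$rotation
  )
}

#' Scree plot of a PCA fit
#'
#' Eigenvalues by component rank, with the Kaiser threshold line at 1.
#'
#' @param object A `wq_pca` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.wq_pca <- function(object, ...) {
  d <- tibble::tibble(component = seq_along(object$eigenvalues),
                      eigenvalue = object$eigenvalues)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$eigenvalue)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Component", y = "Eigenvalue") +
    ggplot2::theme_minimal()
}

#' Regress the WQI on retained component scores
#'
#' Ordinary least squares of the computed index on the standardized
#' component scores, the standard check that a handful of components
#' reproduces the index. With mean-zero scores the intercept equals the
#' mean WQI.
#'
#' @param pca A `wq_pca` object (scores are taken from it), or an n x k
#'   numeric matrix of scores.
#' @param wqi Numeric response of length n (e.g. the `wqi` column of a
#'   [compute_wqi()] result).
#' @return An object of class `wqi_lm` wrapping the [stats::lm()] fit, with
#'   [generics::tidy()] and [generics::glance()] methods.
#' @examples
#' set.seed(1)
#' s <- matrix(rnorm(40), 20, 2)
#' fit_wqi_scores(s, 3 + s %*% c(2, 1) + rnorm(20, sd = 0.1))
#' @export
fit_wqi_scores <- function(pca, wqi) {
  scores <- if (inherits(pca, "wq_pca")) pca$scores else as.matrix(pca)
  wqi <- as.numeric(wqi)
  n <- nrow(scores); k <- ncol(scores)
  if (length(wqi) != n) {
    stop("length of `wqi` (", length(wqi), ") does not match the ", n,
         " score rows", call. = FALSE)
  }
  if (n <= k + 1) stop("need n > k + 1 observations", call. = FALSE)
  if (is.null(colnames(scores))) colnames(scores) <- paste0("PC", seq_len(k))
  d <- data.frame(wqi = wqi, scores, check.names = FALSE)
  fit <- stats::lm(wqi ~ ., data = d)
  if (fit$rank < k + 1) {
    stop("rank-deficient score matrix: coefficients are not identifiable",
         call. = FALSE)
  }
  structure(list(fit = fit, k = k), class = "wqi_lm")
}

#' @export
print.wqi_lm <- function(x, ...) {
  cat("OLS of WQI on", x$k, "component score(s)\n\n")
  print(tidy(x))
  cat("\n")
  print(glance(x))
  invisible(x)
}

#' Coefficient table of a WQI-on-scores regression
#'
#' @param x A `wqi_lm` object.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`
#'   (t value) and `p.value` (two-sided).
#' @method tidy wqi_lm
#' @export
tidy.wqi_lm <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(co),
    estimate = unname(co[, "Estimate"]),
    std.error = unname(co[, "Std. Error"]),
    statistic = unname(co[, "t value"]),
    p.value = unname(co[, "Pr(>|t|)"])
  )
}

#' Fit summary of a WQI-on-scores regression
#'
#' @param x A `wqi_lm` object.
#' @param ... Unused.
#' @return A tibble with `r.squared`, `adj.r.squared`, `sigma`, `statistic`
#'   (overall F), `p.value`, `df`, `nobs`.
#' @method glance wqi_lm
#' @export
glance.wqi_lm <- function(x, ...) {
  s <- summary(x$fit)
  f <- s$fstatistic
  tibble::tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    statistic = unname(f[1]),
    p.value = unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE)),
    df = unname(f[2]),
    nobs = length(s$residuals)
  )
}
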
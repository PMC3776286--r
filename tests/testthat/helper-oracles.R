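# Independent oracles and fixture builders shared across the suite.

# One-shot weighted-mean formula for the index of a single record:
# sum(ratio_i * 100 * w_i) / sum(w_i) over the available parameters.
# Deliberately computed in a different shape from the package's
# per-parameter quality-value path.
naive_wqi <- function(values, criteria) {
  crit <- criteria[criteria$included, ]
  avail <- crit$parameter[!is.na(values[crit$parameter])]
  stopifnot(length(avail) > 0)
  w <- crit$weight[match(avail, crit$parameter)]
  ratio <- vapply(avail, function(p) {
    row <- crit[crit$parameter == p, ]
    v <- values[[p]]
    if (!is.na(row$band_low)) {
      if (v < row$band_low) row$band_low / v
      else if (v > row$band_high) v / row$band_high
      else 0
    } else {
      v / row$limit
    }
  }, numeric(1))
  sum(ratio * 100 * w) / sum(w)
}

# Brute-force eigensolver: repeated power iteration with Hotelling
# deflation. Independent of base eigen(); used to cross-check the PCA path.
power_eigen <- function(A, k = ncol(A), tol = 1e-24, max_iter = 100000) {
  p <- ncol(A)
  vals <- numeric(k)
  vecs <- matrix(0, p, k)
  B <- A
  for (j in seq_len(k)) {
    v <- seq_len(p) / p + 0.5
    v <- v / sqrt(sum(v^2))
    for (i in seq_len(max_iter)) {
      w <- drop(B %*% v)
      w <- w / sqrt(sum(w^2))
      if (sum((w - v)^2) < tol || sum((w + v)^2) < tol) {
        v <- w
        break
      }
      v <- w
    }
    lam <- drop(crossprod(v, B %*% v))
    vals[j] <- lam
    vecs[, j] <- v
    B <- B - lam * tcrossprod(v)
  }
  list(values = vals, vectors = vecs)
}

# Criteria set mirroring a 21-parameter monitoring template plus one
# user-defined pesticide slot (22 included parameters in total).
template_criteria_22 <- function() {
  base <- as.data.frame(default_criteria(include_hardness = TRUE))
  extra <- data.frame(
    parameter = c("zinc", "copper", "arsenic", "lead", "cadmium", "chromium",
                  "cyanide", "d24"),
    weight = c(2, 2, 5, 5, 5, 4, 4, 3),
    limit = c(3, 2, 0.01, 0.01, 0.003, 0.05, 0.07, 0.03),
    band_low = NA_real_, band_high = NA_real_, included = TRUE
  )
  wq_criteria(rbind(base, extra))
}

# A single record for the 22-parameter template: every parameter measured
# except ammonium; total hardness switched off for this record by override.
template_record <- function() {
  crit <- template_criteria_22()
  vals <- as.list(stats::setNames(crit$limit / 2, crit$parameter))
  vals$ph <- 7.3
  vals$ammonium <- NA_real_
  c(list(sample_id = "F1"), vals, list(total_hardness_code = -1))
}

# Random single-record tables over the default 13 parameters with random
# missingness; returns a data frame row compute_wqi() accepts.
random_record <- function(criteria, missing_rate = 0.25) {
  crit <- criteria[criteria$included, ]
  vals <- lapply(seq_len(nrow(crit)), function(i) {
    if (stats::runif(1) < missing_rate) return(NA_real_)
    if (!is.na(crit$band_low[i])) stats::runif(1, 5.5, 9.5)
    else stats::rexp(1, rate = 1 / crit$limit[i])
  })
  stats::setNames(as.data.frame(vals), crit$parameter)
}

expect_loadings_equal <- function(a, b, tol = 1e-8) {
  stopifnot(ncol(a) == ncol(b))
  for (j in seq_len(ncol(a))) {
    s <- sign(sum(a[, j] * b[, j]))
    expect_lt(max(abs(a[, j] - s * b[, j])), tol)
  }
}
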
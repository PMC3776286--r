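---
title: "Dynamic-weight water quality indices: model, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic-weight water quality indices: model, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynwqi)
```

## The index model

A water quality index (WQI) condenses a multi-parameter water sample into a
single dimensionless number. dynwqi implements a weighted-arithmetic index
over a *criteria set*: a list of parameters, each with a weight factor
$w_i > 0$ expressing its health relevance and a guideline limit $L_i$
(mg/L; NTU for turbidity) against which measurements are normalised. For a
record in which the set $U$ of parameters is actually usable, each
parameter receives a *dynamic weight*

$$\tilde w_i = \frac{w_i}{\sum_{j \in U} w_j},$$

its *quality value* is

$$q_i = \frac{c_i}{L_i} \cdot 100 \cdot \tilde w_i$$

for an upper-limit parameter with concentration $c_i$, and the index is the
sum $\mathrm{WQI} = \sum_{i \in U} q_i$. pH is the one banded parameter:
its quality value is 0 while pH lies in the acceptable band
$[6.5, 8.5]$ (endpoints inclusive), $\frac{6.5}{\mathrm{pH}} \cdot 100
\cdot \tilde w$ below it and $\frac{\mathrm{pH}}{8.5} \cdot 100 \cdot
\tilde w$ above it, so deviation on either side of neutrality is penalised.

The renormalization is the point of the package. Classical fixed-weight
indices cannot score a record missing any constituent parameter, which in
decentralised monitoring programmes discards large parts of a database.
Re-scaling the weights over the available subset keeps every record usable
and preserves the scale anchor: a record whose usable parameters all sit
exactly at their limits scores exactly 100 (and $100(1 - \tilde
w_{\mathrm{pH}})$ when an in-band pH is among them). The engine is
algebraically equivalent to the one-shot form
$\sum_{i \in U} (c_i/L_i) \cdot 100 \cdot w_i / \sum_{j \in U} w_j$, and
the test suite checks that equivalence to $10^{-9}$ against an
independently coded oracle.

Why proportional renormalization, rather than, say, refitting weights?
Proportionality is the only rule that (a) needs no data beyond the record
itself, (b) reduces to the fixed-weight index on complete records, and
(c) is invariant to rescaling the whole weight table. It also yields a
useful identity used as a test: deleting a parameter whose concentration
ratio equals the weighted mean ratio of the remaining set leaves the index
unchanged.

### Availability and selection codes

A parameter enters $U$ only if it is globally included in the criteria
set, its per-record selection code is neither $-1$ (analyst exclusion for
that record) nor $0$ (no data), and its value is present. Blank cells are
treated as code 0 automatically — requiring analysts to type the zero by
hand would add a failure mode without adding information. Per-record codes
can exclude but never re-include: global exclusion wins. Every skipped
parameter is recorded with its reason (`excluded_globally`,
`excluded_override`, `no_data`) in the result's audit trail.

Degenerate cases: a record with no usable parameter has no defined index
and errors by default (`on_empty = "na"` keeps the record with a missing
index instead). A record whose only usable parameter is an in-band pH
scores 0 — formally "excellent", on no real evidence — so it is flagged
with a warning.

### Classification

Index values map to five bands: below 50 excellent, 50–100 good, 100–200
poor, 200–300 very poor, above 300 unsuitable for drinking. The published
band table shares its endpoints, so a convention is needed; dynwqi uses
half-open intervals $[l, u)$ (a WQI of exactly 100 is "Poor"), which makes
the mapping total and deterministic on $[0, \infty)$. The default criteria
set ships 13 parameters (pH, calcium, magnesium, chloride, TDS, fluoride,
manganese, nitrate, iron, sulfate, ammonium, sodium, turbidity; weights
summing to 46). Total hardness is present but excluded by default because
it is determined by calcium and magnesium and would double-count hardness;
its weight (2) and limit (500 mg/L, the common aesthetic guideline) are
the package's own choices and only matter if a user re-includes it.

## Descriptive statistics

`describe_wqi()` reproduces the spreadsheet descriptive-statistics block
analysts expect to see in monitoring reports: mean, standard error
$s/\sqrt{n}$, median, standard deviation and sample variance ($n-1$
denominator), range, extremes, sum, a Student-$t$ confidence half-width
$t_{0.975,\,n-1} \cdot s/\sqrt{n}$, and quantiles. Quantiles use linear
interpolation between order statistics with inclusive endpoints
(`type = 7`, the spreadsheet `PERCENTILE`-style convention), chosen to
match the toolpak output format this block mirrors. `class_shares()`
reports the proportion of samples per band, always listing all five bands.

## PCA validation stage

The standard multivariate check on a monitoring dataset is a principal
component analysis of the correlation matrix followed by a regression of
the index on the component scores. `wq_pca()`:

* filters to complete cases first (`filter_complete()`; PCA needs a
  complete matrix, and at least $p + 1$ records for $p$ variables),
* standardises columns and eigendecomposes the correlation matrix,
* scales eigenvectors to correlation loadings
  $\ell_{ij} = v_{ij}\sqrt{\lambda_j}$,
* retains components by the Kaiser rule, *strictly* $\lambda > 1$ — a
  retained component must beat a single standardized variable, and the
  strict inequality makes the boundary case deterministic,
* reports SS loadings (column sums of squares, equal to eigenvalues when
  unrotated), proportion of total variance $\mathrm{ss}/p$, proportion of
  retained variance $\mathrm{ss}/\sum \mathrm{ss}$, their running sums,
  and the communality/uniqueness split $h^2_i = \sum_j \ell_{ij}^2$,
  $u^2_i = 1 - h^2_i$,
* returns standardized scores (mean 0, variance 1), computed as
  $Z v_j / \sqrt{\lambda_j}$.

Eigenvector sign is mathematically arbitrary; dynwqi fixes each
component's largest-magnitude loading positive so output is reproducible
across platforms. No rotation is applied by default — components keep
their principal-axis meaning and SS loadings equal eigenvalues — but
`rotate = "varimax"` is available for sensitivity checks (communalities
are rotation-invariant, which the tests verify).

`fit_wqi_scores()` is ordinary least squares of the index on the retained
scores, with two-sided $t$ p-values. Because the scores are centered, the
intercept equals the mean index — an identity the tests assert to
$10^{-9}$ — and the coefficient vector is cross-checked against a direct
normal-equations solve. The index is regressed raw (unstandardised), which
is what makes the intercept interpretable as the mean.

## The synthetic generator

Real national monitoring datasets are rarely redistributable, so the
package ships a generator (`simulate_samples()`) that emulates one well
enough to exercise every stage: per-parameter lognormal marginals
(guaranteeing positivity and the right skew typical of hydrochemistry), a
truncated-normal pH on $(0, 14]$ (mean 7.4, SD 0.4), a block correlation
structure imposed on the latent log scale, and independent per-cell
missingness (MCAR — the weakest mechanism that still exercises the
dynamic-weight logic).

The default configuration mirrors the component structure national
drinking-water surveys tend to show: a six-parameter salinity block
(magnesium, chloride, TDS, fluoride, sulfate, sodium) at within-block
correlation 0.85, a calcium–manganese block and a nitrate–turbidity block
at 0.6, with ammonium, iron and pH independent. Marginal medians sit at
half the guideline limits (`meanlog = log(L/2)`, `sdlog = 0.6`), which
puts most generated indices below 100 (predominantly excellent/good), and
cells go missing at rate 0.05 — under which complete-case filtering keeps
roughly $0.95^{13} \approx 51\%$ of records.

What the generator does *not* emulate: spatial autocorrelation between
sampling stations, seasonal structure, censoring at detection limits,
non-random missingness, and the heavy contamination tails of genuinely
impaired sources. Passing tests on synthetic data therefore demonstrate
the *algebra* of the pipeline (renormalization, eigenstructure recovery,
regression identities), not field performance on any real network.

One structural caveat is deliberate. The three independent variables
(ammonium, iron, pH) all have population eigenvalue exactly 1 in the
correlation matrix, a degenerate subspace; with finite samples their
eigenvectors can mix, and which of them crosses the strict Kaiser
threshold varies by draw. The structure-recovery test therefore runs at a
fixed seed and asserts block *membership* (the salinity block dominates
the first component; ammonium dominates the retained component it loads
highest on), not loading magnitudes — the property is a typical-case one,
and the degeneracy is a property of the configured structure itself, not
of the estimator.

## Numerical conventions and problem sizes

* Weights renormalize to sum 1 within $10^{-12}$; engine-vs-oracle
  agreement is asserted at $10^{-9}$; eigen-oracle agreement at $10^{-8}$.
* Report files are written at full precision; rounding (default 2
  decimals) is applied only at display time (`--round` in the CLI).
* The test suite runs the structure-recovery check at $n = 2000$, the
  eigensolver cross-check at $n = 1500$, engine-oracle equivalence over
  400 random records with 30% missingness, and the end-to-end smoke run at
  $n = 500$; `scripts/acceptance.R` regenerates a 735-sample survey.
* `simulate_samples()` is byte-reproducible for a fixed `(config, n,
  seed)`; truncation redraws affect only pH, which is independent of every
  block, so rejection sampling cannot distort the correlation structure.

## Known limitations

* The index is linear in concentration ratios; it has no sub-index rating
  curves or fuzzy memberships, and values far above a limit influence the
  index linearly rather than saturating.
* Guideline limits are a flat table; there is no jurisdiction database.
* The banded-parameter rule is hard-wired to one band parameter per
  criteria set (pH in practice).
* Report output is CSV (three files mirroring the classic three-worksheet
  monitoring report); spreadsheet workbooks are read (`.xlsx`) but not
  written.
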
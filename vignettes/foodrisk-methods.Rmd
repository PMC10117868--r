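---
title: "Methods: factor-anchored criterion weighting and TOPSIS ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factor-anchored criterion weighting and TOPSIS ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodrisk)
```

## The model

`foodrisk` ranks countries by macro-level food-insecurity risk from nine
health-economic indicators. The premise is that a country's economic
capacity — summarized by GDP per capita, GDP annual growth rate, and
per-capita health spending — anchors how informative each food-insecurity
criterion is: criteria that track economic capacity closely should carry
more weight in the final ranking than criteria that vary independently of
it. Three stages implement this.

### Stage 1 — factor scoring

The three economic indicators are z-scored (sample standard deviation,
denominator $n-1$) and reduced to one factor by a principal-component
decomposition of their correlation matrix. With leading eigenvalue
$\lambda_1$ and eigenvector $u_1$, the loadings are $l = u_1
\sqrt{\lambda_1}$, sign-fixed so $\sum_j l_j > 0$ ("higher score = richer,
higher-spending country"). Regression-method score coefficients are $b =
l/\lambda_1$, and the per-country factor score is $f_i = z_i^\top b$; by
construction the scores have mean 0 and sample variance 1 exactly.
Bartlett's sphericity test,
$\chi^2 = -(n - 1 - \tfrac{2p+5}{6})\ln\det R$ on $p(p-1)/2$ degrees of
freedom, guards against running the reduction on essentially uncorrelated
indicators. Only one factor is extracted; the remaining eigenvalues are
reported but unused. Because everything is correlation-based, the stage is
invariant to the units of the raw indicators.

On the packaged 14-country OECD 2020 table (`oecd2020()`) this gives
$\lambda_1 = 1.988$ (66.27% of variance), loadings $(0.478, 0.910,
0.965)$, and a Bartlett p-value of $4.5\times 10^{-4}$:

```{r factor}
fm <- fit_single_factor(standardize_columns(
  oecd2020(), c("gdp_growth_pct", "health_spending", "gdp_per_capita")))
fm
```

### Stage 2 — distance-based criterion weighting

The six criteria and the factor-score vector are treated as seven points in
14-dimensional country space. Euclidean proximities between them are
embedded in two dimensions by metric SMACOF, and each criterion's distance
$d_i$ to `Factor_1` in the common space is converted to a weight:
$$x_i = \frac{d_i}{\sum_k d_k}, \qquad W_i = \frac{1 - x_i}{k - 1},$$
so that $\sum_i W_i = 1$ and weights are strictly anti-monotone in
distance. The transform is invariant to rescaling all distances by a
positive constant, which makes the weights independent of the overall scale
of the embedding.

**Proximity standardization.** How the seven variables are standardized
before distances are taken is the one genuinely open design choice in this
stage, and it changes the answer qualitatively:

* `scale = "case"` (pipeline default) z-scores each country's *row* across
  the seven variables. Distances then reflect how much of a country profile
  each variable occupies, so large-magnitude variables (crop production per
  million people, hundreds to thousands of tons) land far from the
  unit-scale factor while small-magnitude ones (the producer-protection
  ratio, near 1) land close. This is the convention under which the
  packaged reference analysis was produced, and it is what reproduces its
  distance ordering (protection < inflation < support < household < meat <
  crop) and weight table.
* `scale = "variable"` z-scores each column, making the distance a pure
  function of inter-variable correlation, $d_{ab} =
  \sqrt{2(n-1)(1-r_{ab})}$. This is the statistically interpretable mode —
  a criterion is "close to the factor" exactly when it is highly correlated
  with it — and it is the mode used for the synthetic recovery studies
  below. On the reference data it produces a very different ordering (crop
  production is the criterion *most* correlated with the factor), which is
  worth keeping in mind when interpreting the default weights.

Proximities are then rescaled so $\sum_{a<b} \hat d_{ab}^2 = k(k-1)/2$
(the convention of SPSS-style MDS output); this fixes coordinate units
without affecting stress, orderings, or weights.

**SMACOF numerics.** Raw stress $\sigma(X) = \sum_{a<b}(\hat d_{ab} -
d_{ab}(X))^2$ is minimized by the Guttman-transform majorization update,
which never increases stress. Initialization is Torgerson classical scaling
(`cmdscale`), making the default pipeline fully deterministic; a seeded
random start is available for checking local minima. Iteration stops when
the relative stress decrease falls below `tol` ($10^{-9}$ by default,
`max_iter` 10,000); hitting the cap sets a `converged = FALSE` flag rather
than failing, since a slightly unconverged configuration is still usable.
Fit is reported as stress-1, $\sqrt{\sum(\hat d - d)^2 / \sum \hat d^2}$,
and s-stress (the squared-distance analogue). MDS configurations are
defined only up to rotation and reflection; nothing downstream depends on
the orientation because only inter-point distances are used.

```{r weights}
res <- run_pipeline(pipeline_config(log_level = "quiet"), table = oecd2020())
res$embedding$stress1
res$weights
```

The embedding attains stress-1 $\approx 0.049$ on the reference
proximities; the recovered distance and weight orderings match the shipped
reference tables (`reference_distances()`, `reference_weights()`) and
the weights agree with them to about $\pm 0.005$. Exact numerical
agreement is not attainable — the reference solution came from a
proprietary optimizer whose configuration is published only to three
decimals — which is why the pipeline also accepts the reference distances
or weights as injected inputs (`inject_distances`, `inject_weights`) to
drive the downstream stage exactly.

### Stage 3 — TOPSIS

The six criterion columns form the decision matrix: benefit criteria (meat
consumption, crop production per million, producer support, producer
protection) and cost criteria (household spending share of GDP, food
inflation). Values are normalized, weighted ($v_{ij} = r_{ij} W_j$),
and compared with the positive/negative ideal vectors ($A^*_j$: column max
for benefits, min for costs; $A^-_j$ reversed). Separations are Euclidean,
$S^*_i = \lVert v_i - A^* \rVert_2$, $S^-_i = \lVert v_i - A^- \rVert_2$,
and the closeness coefficient $C^*_i = S^-_i/(S^-_i + S^*_i) \in [0,1]$
ranks countries from lowest risk (rank 1, highest $C^*$) to highest. Ties
are broken by input order and flagged; they cannot occur on generic data.

**Normalization dialects.** The textbook vector rule is $r_{ij} =
d_{ij}/\sqrt{\sum_k d_{kj}^2}$. The reference analysis, however, was
computed with $r_{ij} = d_{ij}^2/\sqrt{\sum_k d_{kj}^2}$ — the entry is
squared first — a variant that appears in spreadsheet TOPSIS workflows.
Both are implemented (`dialect = "vector"` / `"squared"`), verified cell
by cell against the reference tables, and distinguished by a testable
property: the vector dialect is invariant to rescaling any criterion
column, the squared dialect is not (its normalized values scale linearly
with the column). `"squared"` is the default because the package's first
job is to reproduce the reference analysis; for new analyses the vector
dialect is the defensible choice.

```{r topsis}
res2 <- run_pipeline(pipeline_config(log_level = "quiet"),
                     table = oecd2020(),
                     inject_weights = reference_weights())
head(ranking_table(res2$topsis), 3)
tail(ranking_table(res2$topsis), 1)
```

With the reference weights injected, the closeness coefficients reproduce
the reference ranking to the published precision (United States 0.99630658,
New Zealand 0.66731006, ..., Colombia 0.00125943) and the full 1–14 order.

## The reference dataset and its quirks

`oecd2020()` transcribes the source compilation verbatim, and three
transcription artifacts are preserved deliberately rather than corrected,
because every downstream reference value derives from them:

* Some population counts are not plausible census figures (e.g. New
  Zealand 50,902; Switzerland 863,817) but are exactly consistent with the
  printed per-million crop values; such rows carry
  `population_as_printed = TRUE`.
* The source's column headers swap the unit annotations of producer
  support and producer protection; columns here are named by value
  semantics (support in percent of gross farm receipts, protection as a
  price ratio).
* The source's own normalized-matrix table contains one internally
  inconsistent cell (Canada's crop entry). Its influence on other
  countries' crop values enters only through a column denominator and is
  below $3\times10^{-6}$ relative; reproduction checks therefore compare
  crop-dependent cells at that looser precision and everything else at the
  published precision.

A related limit: the reference weight table is printed to nine decimals
but was computed from unrounded distances, so re-deriving it from the
three-decimal distance column agrees only to about $3\times10^{-5}$ —
an irreducible rounding gap, not an implementation artifact.

## The synthetic generator

`generate_synthetic()` draws from the minimal generative model consistent
with the stage-1 assumption: a latent factor $f \sim N(0,1)$ per country,
indicators $x_j = \lambda_j f + \sqrt{1-\lambda_j^2}\,\varepsilon_j$, and
criteria $c_i = \rho_i f + \sigma\sqrt{1-\rho_i^2}\,\varepsilon_i$
(rescaled to unit variance, then affinely mapped to positive
reference-like ranges and clamped at zero). Defaults are the study
conditions of the reference analysis: $n = 14$, $\lambda = (0.478, 0.910,
0.965)$, and $\rho = (0.37, 0.44, 0.38, 0.31, -0.38, -0.33)$ as measured
on the reference table, with `noise_sd` $= 1$ so realized correlations
equal the targets (for other values the implied correlations
$\rho/\sqrt{\rho^2 + \sigma^2(1-\rho^2)}$ are reported as ground truth).
The affine spreads are narrower relative to their means than the real
crop column (whose standard deviation exceeds its mean — incompatible
with a nonnegative Gaussian affine map); the generator is a test harness
for the *method*, not a calibrated model of OECD marginals, so passing
recovery tests say nothing about real-data marginal shapes, outliers, or
the cross-criterion dependence beyond the single factor.

Two calibration properties are exercised in the test suite: empirical
criterion–factor correlations converge to the implied targets (checked at
$n = 1000$, tolerance 0.05), and weight-ordering recovery — running the
full pipeline in `scale = "variable"` mode on 200 replicates at $n = 50$,
`noise_sd = 0.3` recovers the rank order of the true correlations with
mean Kendall $\tau > 0.8$. Problem sizes throughout the suite (fixture
$n = 14$; property checks at $n \le 5000$; 200 recovery replicates) were
chosen as the smallest sizes at which the corresponding population
quantities are estimated stably.

## Degenerate inputs and errors

Zero-variance columns, singular correlation matrices, all-zero criterion
columns, negative decision values, all-zero distance vectors, and
single-alternative TOPSIS calls all raise classed errors
(`foodrisk_degenerate_error`, `foodrisk_domain_error`, ...) naming the
offending column where applicable; pipeline stages wrap these with the
stage name. A zero cost value is *not* an error — it is the best possible
cost and becomes the positive ideal for that criterion.

## Known limitations

* The MDS stage is approximate by nature: different optimizers (or random
  starts) can reach configurations whose distances to the anchor differ in
  the third decimal, which propagates to the weights at about the same
  magnitude. Orderings are stable on the reference data; exact weight
  reproduction requires injecting the reference distances.
* The case-standardized proximity mode ties criterion weights to variable
  magnitudes. That is faithful to the reference analysis but means the
  default weights are not invariant to the units chosen for the criteria;
  use `proximity_scaling = "variable"` for a unit-free analysis.
* Single-year, cross-sectional only; no panel structure, no uncertainty
  quantification on the ranking.
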
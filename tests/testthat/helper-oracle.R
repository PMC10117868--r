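## Brute-force TOPSIS oracle written directly from the defining formulas,
## scalar loops only — deliberately independent of the package's vectorized
## implementation.
brute_topsis <- function(values, weights, directions,
                         dialect = c("squared", "vector")) {
  dialect <- match.arg(dialect)
  m <- nrow(values); k <- ncol(values)
  r <- matrix(0, m, k)
  for (j in seq_len(k)) {
    ss <- 0
    for (i in seq_len(m)) ss <- ss + values[i, j]^2
    for (i in seq_len(m)) {
      r[i, j] <- if (dialect == "squared") values[i, j]^2 / sqrt(ss)
                 else values[i, j] / sqrt(ss)
    }
  }
  v <- matrix(0, m, k)
  for (i in seq_len(m)) for (j in seq_len(k)) v[i, j] <- r[i, j] * weights[j]
  A_star <- A_minus <- numeric(k)
  for (j in seq_len(k)) {
    if (directions[j] == "benefit") {
      A_star[j] <- max(v[, j]); A_minus[j] <- min(v[, j])
    } else {
      A_star[j] <- min(v[, j]); A_minus[j] <- max(v[, j])
    }
  }
  S_star <- S_minus <- C_star <- numeric(m)
  for (i in seq_len(m)) {
    s1 <- 0; s2 <- 0
    for (j in seq_len(k)) {
      s1 <- s1 + (v[i, j] - A_star[j])^2
      s2 <- s2 + (v[i, j] - A_minus[j])^2
    }
    S_star[i] <- sqrt(s1); S_minus[i] <- sqrt(s2)
    C_star[i] <- S_minus[i] / (S_minus[i] + S_star[i])
  }
  list(normalized = r, weighted = v, A_star = A_star, A_minus = A_minus,
       S_star = S_star, S_minus = S_minus, C_star = C_star)
}

## a tiny valid country table for plumbing tests
toy_country_table <- function(n = 5) {
  set.seed(42)
  data.frame(
    country = paste0("X", seq_len(n)),
    meat_total = 50 + seq_len(n),
    crop_per_million = 100 * seq_len(n),
    producer_support_pct = 5 + seq_len(n),
    producer_protection_ratio = 1 + 0.1 * seq_len(n),
    household_spending_pct_gdp = 50 + 2 * seq_len(n),
    food_inflation_pct = seq_len(n),
    gdp_growth_pct = seq_len(n) - 3,
    health_spending = 1000 * seq_len(n),
    gdp_per_capita = 20000 + 3000 * seq_len(n) + rnorm(n, 0, 500)
  )
}

fixture_factor_model <- function(tab = oecd2020()) {
  fit_single_factor(standardize_columns(
    tab, c("gdp_growth_pct", "health_spending", "gdp_per_capita")))
}
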
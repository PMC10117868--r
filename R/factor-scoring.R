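#' Column-wise z-standardization
#'
#' Centers and scales the selected columns so each has mean 0 and sample
#' standard deviation 1 (denominator \eqn{n-1}).
#'
#' @param table a [`country_table`][as_country_table], data frame, or numeric
#'   matrix.
#' @param columns column names to standardize; default all numeric columns.
#' @return a countries x columns numeric matrix of z-scores; row names are
#'   country labels when available.
#' @export
#' @examples
#' standardize_columns(oecd2020(), c("gdp_per_capita", "health_spending"))
standardize_columns <- function(table, columns = NULL) {
  m <- .as_numeric_matrix(table, columns)
  if (nrow(m) < 3L)
    fr_stop("need at least 3 rows to standardize", "foodrisk_degenerate_error")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds)))
    fr_stop(sprintf("zero-variance column(s): %s",
                    paste(colnames(m)[sds == 0 | !is.finite(sds)], collapse = ", ")),
            "foodrisk_degenerate_error")
  z <- scale(m)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z
}

.as_numeric_matrix <- function(table, columns = NULL) {
  if (is.matrix(table)) {
    m <- table
    if (!is.null(columns)) m <- m[, columns, drop = FALSE]
  } else if (is.data.frame(table)) {
    if (is.null(columns))
      columns <- names(table)[vapply(table, is.numeric, logical(1))]
    missing <- setdiff(columns, names(table))
    if (length(missing))
      fr_stop(sprintf("unknown column(s): %s", paste(missing, collapse = ", ")),
              "foodrisk_schema_error")
    m <- as.matrix(table[, columns, drop = FALSE])
    if ("country" %in% names(table)) rownames(m) <- table$country
  } else {
    fr_stop("expected a matrix or data frame", "foodrisk_schema_error")
  }
  if (!is.numeric(m))
    fr_stop("selected columns are not all numeric", "foodrisk_parse_error")
  m
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix of the variables is an identity
#' matrix (i.e. whether the variables are correlated enough to justify a
#' factor reduction). The statistic is
#' \deqn{\chi^2 = -\left(n - 1 - \frac{2p + 5}{6}\right)\ln\det R}
#' with \eqn{p(p-1)/2} degrees of freedom and an upper-tail chi-square
#' p-value.
#'
#' @param z a countries x variables numeric matrix (standardization does not
#'   change the result; correlations are computed internally).
#' @return an object of class `bartlett_test` with elements `statistic`,
#'   `df`, `p.value`, `n`, `p`.
#' @export
#' @examples
#' bartlett_sphericity(standardize_columns(
#'   oecd2020(), c("gdp_growth_pct", "health_spending", "gdp_per_capita")))
bartlett_sphericity <- function(z) {
  m <- .as_numeric_matrix(z)
  n <- nrow(m); p <- ncol(m)
  if (n <= p)
    fr_stop("need more rows than columns for the sphericity test",
            "foodrisk_degenerate_error")
  R <- stats::cor(m)
  detR <- det(R)
  if (!is.finite(detR) || detR <= .Machine$double.eps)
    fr_stop("correlation matrix is (numerically) singular",
            "foodrisk_numerical_error")
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  structure(
    list(statistic = chi2, df = df,
         p.value = stats::pchisq(chi2, df, lower.tail = FALSE),
         n = n, p = p),
    class = "bartlett_test"
  )
}

#' @export
print.bartlett_test <- function(x, ...) {
  cat("Bartlett's test of sphericity\n")
  cat(sprintf("  chi-squared = %.4f, df = %d, p-value = %.4g (n = %d, p = %d)\n",
              x$statistic, x$df, x$p.value, x$n, x$p))
  invisible(x)
}

#' Single-factor principal-component model
#'
#' Extracts the first principal component of the correlation matrix of the
#' (standardized) economic indicators as the latent factor `Factor_1`.
#' Loadings are the first eigenvector scaled by \eqn{\sqrt{\lambda_1}}, with
#' the sign fixed so the loading sum is positive ("higher = richer").
#' Regression-method score coefficients are `loadings / lambda_1`, and
#' per-country factor scores are the standardized data times the
#' coefficients; by construction they have mean 0 and sample variance 1.
#'
#' @param z standardized matrix from [standardize_columns()] (mean 0, sd 1
#'   per column, denominator \eqn{n-1}).
#' @return an object of class `factor_model`: `variable_labels`,
#'   `eigenvalues` (descending, summing to the number of variables),
#'   `variance_explained_pct` (per component), `loadings`,
#'   `score_coefficients`, `scores` (named per country), `bartlett`
#'   (a [bartlett_sphericity()] result), `n`.
#' @export
#' @examples
#' z <- standardize_columns(
#'   oecd2020(), c("gdp_growth_pct", "health_spending", "gdp_per_capita"))
#' fm <- fit_single_factor(z)
#' fm$eigenvalues[1]          # ~1.988
#' fm$variance_explained_pct[1] # ~66.27
fit_single_factor <- function(z) {
  m <- .as_numeric_matrix(z)
  n <- nrow(m); p <- ncol(m)
  mu <- colMeans(m); sdv <- apply(m, 2, stats::sd)
  if (any(abs(mu) > 1e-8) || any(abs(sdv - 1) > 1e-8))
    fr_stop("input must be standardized (use standardize_columns())",
            "foodrisk_domain_error")
  R <- stats::cor(m)
  if (any(!is.finite(R)))
    fr_stop("correlation matrix contains non-finite values",
            "foodrisk_numerical_error")
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    fr_stop("correlation matrix is not positive semi-definite",
            "foodrisk_numerical_error")
  lambda1 <- e$values[1]
  loadings <- e$vectors[, 1] * sqrt(lambda1)
  if (sum(loadings) < 0) loadings <- -loadings
  coefs <- loadings / lambda1
  scores <- drop(m %*% coefs)
  names(scores) <- rownames(m)
  labels <- colnames(m)
  names(loadings) <- names(coefs) <- labels
  structure(
    list(variable_labels = labels,
         eigenvalues = e$values,
         variance_explained_pct = 100 * e$values / p,
         loadings = loadings,
         score_coefficients = coefs,
         scores = scores,
         bartlett = bartlett_sphericity(m),
         n = n),
    class = "factor_model"
  )
}

#' @export
print.factor_model <- function(x, digits = 3, ...) {
  cat("Single-factor principal-component model (Factor_1)\n")
  tab <- data.frame(
    eigenvalue = round(x$eigenvalues, digits),
    pct_variance = round(x$variance_explained_pct, digits),
    cumulative_pct = round(cumsum(x$variance_explained_pct), digits)
  )
  print(tab)
  cat("\nComponent 1 loadings and regression score coefficients:\n")
  print(round(cbind(loading = x$loadings, coefficient = x$score_coefficients),
              digits))
  cat("\n")
  print(x$bartlett)
  invisible(x)
}

#' Plot per-country factor scores
#'
#' Dot chart of `Factor_1` scores sorted from highest (most favourable
#' economic position) to lowest.
#'
#' @param x a [fit_single_factor()] result.
#' @param ... passed to [graphics::dotchart()].
#' @export
plot.factor_model <- function(x, ...) {
  s <- sort(x$scores)
  graphics::dotchart(s, labels = names(s), xlab = "Factor_1 score", ...)
  invisible(x)
}
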
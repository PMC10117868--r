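#' Euclidean proximity matrix between variables
#'
#' Treats each variable (criterion or factor score vector) as a point in
#' country space and computes all pairwise Euclidean distances
#' \deqn{d(a,b) = \sqrt{\sum_{i=1}^{n} (x_{a,i} - x_{b,i})^2}}
#' over the \eqn{n} countries. The result is the proximity input for
#' [smacof_embed()].
#'
#' `scale` controls how values are standardized before distances are taken:
#' \describe{
#'   \item{`"case"`}{each country's row is z-scored across the variables
#'     (SPSS-style case standardization). Distances then reflect each
#'     variable's share of the within-country profile, which is what
#'     reproduces the reference analysis; the pipeline default.}
#'   \item{`"variable"`}{each column is z-scored; distances become a pure
#'     function of inter-variable correlation,
#'     \eqn{d = \sqrt{2(n-1)(1-r)}}.}
#'   \item{`"none"`}{raw values.}
#' }
#'
#' @param table a [`country_table`][as_country_table], data frame, or
#'   countries x variables matrix.
#' @param columns variable columns to include (default: the six criterion
#'   columns when present, else all numeric columns).
#' @param factor_scores optional named numeric vector of per-country factor
#'   scores appended as the variable `Factor_1`.
#' @param scale standardization applied before the distance computation.
#' @return a `proximity_matrix`: symmetric k x k matrix, zero diagonal.
#' @export
#' @examples
#' tab <- oecd2020()
#' z <- standardize_columns(tab, c("gdp_growth_pct", "health_spending",
#'                                 "gdp_per_capita"))
#' fm <- fit_single_factor(z)
#' variable_distance_matrix(tab, factor_scores = fm$scores)
variable_distance_matrix <- function(table, columns = NULL, factor_scores = NULL,
                                     scale = c("case", "variable", "none")) {
  scale <- match.arg(scale)
  if (is.null(columns) && is.data.frame(table)) {
    crit <- c("meat_total", "crop_per_million", "producer_support_pct",
              "producer_protection_ratio", "household_spending_pct_gdp",
              "food_inflation_pct")
    if (all(crit %in% names(table))) columns <- crit
  }
  m <- .as_numeric_matrix(table, columns)
  if (!is.null(factor_scores)) {
    if (length(factor_scores) != nrow(m))
      fr_stop(sprintf("factor_scores has length %d but the table has %d rows",
                      length(factor_scores), nrow(m)),
              "foodrisk_dimension_error")
    m <- cbind(m, Factor_1 = as.numeric(factor_scores))
  }
  v <- switch(scale,
    case     = t(apply(m, 1, function(r) (r - mean(r)) / stats::sd(r))),
    variable = standardize_columns(m),
    none     = m
  )
  if (scale == "case") colnames(v) <- colnames(m)
  d <- as.matrix(stats::dist(t(v)))
  structure(d, class = c("proximity_matrix", "matrix"))
}

#' Normalize proximities to the PROXSCAL convention
#'
#' Rescales a proximity matrix so the sum of squared dissimilarities over
#' all pairs equals \eqn{k(k-1)/2}. Rescaling changes nothing substantive
#' (ratio-MDS configurations scale along, stress and derived weights are
#' scale-invariant); it only fixes the coordinate units of the common space
#' to the convention used by SPSS-style MDS output, making configurations
#' comparable across inputs.
#'
#' @param prox a symmetric proximity matrix.
#' @return the rescaled `proximity_matrix`.
#' @export
normalize_proximities <- function(prox) {
  .check_proximity(prox)
  k <- nrow(prox)
  ss <- sum(prox[upper.tri(prox)]^2)
  if (ss <= 0)
    fr_stop("all proximities are zero", "foodrisk_degenerate_error")
  out <- prox * sqrt((k * (k - 1) / 2) / ss)
  structure(out, class = c("proximity_matrix", "matrix"))
}

.check_proximity <- function(prox) {
  if (!is.matrix(prox) || nrow(prox) != ncol(prox))
    fr_stop("proximity input must be a square matrix", "foodrisk_validation_error")
  if (any(abs(prox - t(prox)) > 1e-8))
    fr_stop("proximity matrix must be symmetric", "foodrisk_validation_error")
  if (any(diag(prox) != 0))
    fr_stop("proximity matrix must have a zero diagonal", "foodrisk_validation_error")
  if (any(prox < 0))
    fr_stop("proximities must be nonnegative", "foodrisk_validation_error")
  invisible(TRUE)
}

#' Metric MDS by SMACOF majorization
#'
#' Embeds the k variables in `dims` dimensions by minimizing raw stress
#' \eqn{\sigma(X) = \sum_{a<b} (\delta_{ab} - d_{ab}(X))^2} with the
#' SMACOF majorization (Guttman transform) update, starting from the
#' Torgerson classical-scaling configuration (deterministic) or a random
#' start. Raw stress never increases across iterations.
#'
#' Reported badness-of-fit measures:
#' \deqn{\mathrm{stress1} = \sqrt{\sum(\delta - d)^2 / \sum \delta^2}, \quad
#'       \mathrm{sstress} = \sqrt{\sum(\delta^2 - d^2)^2 / \sum \delta^4}.}
#'
#' @param prox proximity matrix from [variable_distance_matrix()] (optionally
#'   [normalize_proximities()]).
#' @param dims embedding dimension, must be `< k`; 2 for the common-space map.
#' @param init `"torgerson"` (classical scaling start, the default) or
#'   `"random"`.
#' @param seed integer seed used when `init = "random"`; stored on the
#'   result either way.
#' @param max_iter iteration cap; hitting it sets `converged = FALSE` (a
#'   flag, not an error).
#' @param tol relative raw-stress decrease below which iteration stops.
#' @return an object of class `mds_embedding`: `labels`, `coordinates`
#'   (k x dims), `stress1`, `sstress`, `raw_stress`, `stress_trace`
#'   (stress1 after every iteration), `n_iterations`, `converged`, `seed`,
#'   `init`.
#' @export
smacof_embed <- function(prox, dims = 2, init = c("torgerson", "random"),
                         seed = NULL, max_iter = 10000, tol = 1e-9) {
  init <- match.arg(init)
  .check_proximity(prox)
  k <- nrow(prox)
  if (dims >= k)
    fr_stop("dims must be smaller than the number of points",
            "foodrisk_validation_error")

  X <- if (init == "torgerson") {
    x0 <- suppressWarnings(stats::cmdscale(prox, k = dims))
    if (ncol(x0) < dims)  # degenerate proximities can drop dimensions
      x0 <- cbind(x0, matrix(0, k, dims - ncol(x0)))
    x0
  } else {
    with_seed(seed, matrix(stats::rnorm(k * dims), k, dims))
  }

  delta <- prox
  dmat <- function(X) as.matrix(stats::dist(X))
  raw_stress <- function(D) sum((delta[upper.tri(delta)] - D[upper.tri(D)])^2)
  ss_delta <- sum(delta[upper.tri(delta)]^2)

  D <- dmat(X)
  s_old <- raw_stress(D)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ## Guttman transform: X <- (1/k) B(X) X
    B <- -delta / ifelse(D > 0, D, Inf)
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- B %*% X / k
    D <- dmat(X)
    s_new <- raw_stress(D)
    trace <- c(trace, sqrt(s_new / ss_delta))
    if (s_old - s_new < tol * max(s_old, .Machine$double.xmin) ||
        s_new < 1e-30) {
      converged <- TRUE
      break
    }
    s_old <- s_new
  }
  if (!converged)
    warning("smacof_embed: maximum iterations reached without convergence")

  dimnames(X) <- list(rownames(prox),
                      paste0("Dimension_", seq_len(dims)))
  up <- upper.tri(delta)
  structure(
    list(labels = rownames(prox),
         coordinates = X,
         stress1 = sqrt(raw_stress(D) / ss_delta),
         sstress = sqrt(sum((delta[up]^2 - D[up]^2)^2) / sum(delta[up]^4)),
         raw_stress = raw_stress(D),
         stress_trace = trace,
         n_iterations = it,
         converged = converged,
         seed = seed,
         init = init),
    class = "mds_embedding"
  )
}

#' @export
print.mds_embedding <- function(x, digits = 4, ...) {
  cat(sprintf("SMACOF embedding: %d points in %d dimensions (%s init)\n",
              length(x$labels), ncol(x$coordinates), x$init))
  cat(sprintf("  stress1 = %.5f, s-stress = %.5f, %d iterations%s\n",
              x$stress1, x$sstress, x$n_iterations,
              if (x$converged) "" else " (NOT converged)"))
  print(round(x$coordinates, digits))
  invisible(x)
}

#' Distances from every variable to an anchor variable
#'
#' Euclidean distances in the embedded configuration from each non-anchor
#' point to the anchor (normally `Factor_1`). These distances drive
#' [distances_to_weights()].
#'
#' @param emb an [smacof_embed()] result, or any matrix of coordinates with
#'   labelled rows.
#' @param anchor label of the anchor point.
#' @return named numeric vector of distances, one per non-anchor label, in
#'   configuration order.
#' @export
distances_to_anchor <- function(emb, anchor = "Factor_1") {
  coords <- if (inherits(emb, "mds_embedding")) emb$coordinates else as.matrix(emb)
  if (is.null(rownames(coords)))
    fr_stop("coordinates must have row labels", "foodrisk_validation_error")
  if (!anchor %in% rownames(coords))
    fr_stop(sprintf("anchor '%s' not present in the embedding", anchor),
            "foodrisk_lookup_error")
  a <- coords[anchor, ]
  other <- setdiff(rownames(coords), anchor)
  d <- sqrt(rowSums((coords[other, , drop = FALSE] -
                       matrix(a, length(other), length(a), byrow = TRUE))^2))
  names(d) <- other
  d
}

#' Criterion weights from distances to the factor
#'
#' Converts distances \eqn{d_i \ge 0} of the k criteria to the factor into
#' weights by the ratio/complement transform:
#' \deqn{x_i = d_i / \sum d, \qquad f_i = 1 - x_i, \qquad
#'       W_i = f_i / \sum f = (1 - x_i)/(k - 1).}
#' Criteria nearest the factor get the largest weights (strictly
#' anti-monotone in distance), the weights sum to one, and the transform is
#' invariant to rescaling all distances by a positive constant.
#'
#' @param d named nonnegative numeric vector of criterion-to-factor
#'   distances (at least 2, not all zero).
#' @return an object of class `criterion_weights`: a data frame with columns
#'   `criterion`, `distance`, `ratio` (\eqn{x_i}), `fixed` (\eqn{1-x_i}),
#'   `weight` (\eqn{W_i}).
#' @export
#' @examples
#' distances_to_weights(c(meat = 0.897, crop = 1.769, support = 0.373,
#'                        protection = 0.018, household = 0.790,
#'                        inflation = 0.078))
distances_to_weights <- function(d) {
  d <- unlist(d)
  if (length(d) < 2L)
    fr_stop("need at least 2 criteria", "foodrisk_degenerate_error")
  if (any(!is.finite(d)))
    fr_stop("distances must be finite", "foodrisk_domain_error")
  if (any(d < 0))
    fr_stop("distances must be nonnegative", "foodrisk_domain_error")
  total <- sum(d)
  if (total <= 0)
    fr_stop("all distances are zero; weights are undefined",
            "foodrisk_degenerate_error")
  x <- d / total
  f <- 1 - x
  w <- f / sum(f)
  labels <- if (is.null(names(d))) paste0("criterion_", seq_along(d)) else names(d)
  structure(
    data.frame(criterion = labels, distance = as.numeric(d),
               ratio = as.numeric(x), fixed = as.numeric(f),
               weight = as.numeric(w), row.names = NULL),
    class = c("criterion_weights", "data.frame")
  )
}

#' @export
print.criterion_weights <- function(x, digits = 6, ...) {
  cat("Criterion weights (distance -> ratio -> complement -> weight)\n")
  y <- x
  for (cl in c("distance", "ratio", "fixed", "weight"))
    y[[cl]] <- round(y[[cl]], digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
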
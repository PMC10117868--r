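#' Decision matrix with benefit/cost directions
#'
#' Validates an alternatives x criteria value matrix for TOPSIS: all values
#' nonnegative, no all-zero criterion column, and a direction (`"benefit"`:
#' larger is better; `"cost"`: larger is worse) for every criterion. Cost
#' criteria enter as raw values; directionality is handled later by the
#' ideal solutions, so a zero cost value is legal (and becomes the positive
#' ideal for that criterion).
#'
#' @param values numeric alternatives x criteria matrix (or data frame).
#' @param directions character vector, one of `"benefit"`/`"cost"` per
#'   criterion; a named vector is aligned to the columns by name.
#' @return a `decision_matrix`: the value matrix with a `directions`
#'   attribute.
#' @export
#' @examples
#' decision_matrix(cbind(yield = c(3, 4), price = c(2, 1)),
#'                 c(yield = "benefit", price = "cost"))
decision_matrix <- function(values, directions) {
  m <- .as_numeric_matrix(values)
  if (any(!is.finite(m)))
    fr_stop("decision matrix contains non-finite values", "foodrisk_domain_error")
  if (any(m < 0))
    fr_stop("decision matrix values must be nonnegative", "foodrisk_domain_error")
  if (any(colSums(m) == 0))
    fr_stop(sprintf("all-zero criterion column(s): %s",
                    paste(colnames(m)[colSums(m) == 0], collapse = ", ")),
            "foodrisk_degenerate_error")
  directions <- .align_directions(directions, colnames(m), ncol(m))
  structure(m, directions = directions, class = c("decision_matrix", "matrix"))
}

.align_directions <- function(directions, criteria, k) {
  if (length(directions) != k)
    fr_stop(sprintf("%d directions supplied for %d criteria",
                    length(directions), k),
            "foodrisk_alignment_error")
  if (!is.null(names(directions)) && !is.null(criteria)) {
    missing <- setdiff(criteria, names(directions))
    if (length(missing))
      fr_stop(sprintf("no direction for criterion(s): %s",
                      paste(missing, collapse = ", ")),
              "foodrisk_alignment_error")
    directions <- directions[criteria]
  }
  if (!all(directions %in% c("benefit", "cost")))
    fr_stop("directions must be 'benefit' or 'cost'", "foodrisk_validation_error")
  directions <- as.character(directions)
  names(directions) <- criteria
  directions
}

#' Normalize a decision matrix
#'
#' Two normalization dialects are supported:
#' \describe{
#'   \item{`"vector"`}{the textbook TOPSIS rule
#'     \eqn{r_{ij} = d_{ij} / \sqrt{\sum_k d_{kj}^2}}; every column gets unit
#'     Euclidean norm and the eventual ranking is invariant to rescaling any
#'     criterion column.}
#'   \item{`"squared"`}{\eqn{r_{ij} = d_{ij}^2 / \sqrt{\sum_k d_{kj}^2}},
#'     i.e. the entry is squared before division by the column norm. This
#'     variant is found in some spreadsheet TOPSIS workflows and is the rule
#'     under which the packaged reference analysis was produced, so it is the
#'     pipeline default for reproducing it. It is *not* scale-invariant:
#'     multiplying a column by c multiplies its normalized values by c.}
#' }
#'
#' @param values nonnegative alternatives x criteria matrix.
#' @param dialect `"squared"` or `"vector"`.
#' @return matrix of the same shape.
#' @export
#' @examples
#' topsis_normalize(cbind(x = c(3, 4)), dialect = "vector")  # 0.6, 0.8
topsis_normalize <- function(values, dialect = c("squared", "vector")) {
  dialect <- match.arg(dialect)
  m <- .as_numeric_matrix(values)
  if (any(m < 0))
    fr_stop("normalization requires nonnegative values", "foodrisk_domain_error")
  norms <- sqrt(colSums(m^2))
  if (any(norms == 0))
    fr_stop(sprintf("all-zero criterion column(s): %s",
                    paste(colnames(m)[norms == 0], collapse = ", ")),
            "foodrisk_degenerate_error")
  num <- if (dialect == "squared") m^2 else m
  sweep(num, 2, norms, "/")
}

#' Weight a normalized decision matrix
#'
#' Multiplies each normalized column by its criterion weight:
#' \eqn{v_{ij} = r_{ij} W_j}.
#'
#' @param r normalized matrix from [topsis_normalize()].
#' @param weights a [criterion_weights][distances_to_weights] object or a
#'   numeric weight vector; if both sides are named the weights are aligned
#'   to the columns of `r` by name.
#' @return the weighted normalized matrix.
#' @export
apply_weights <- function(r, weights) {
  m <- .as_numeric_matrix(r)
  w <- .weight_vector(weights, colnames(m), ncol(m))
  sweep(m, 2, w, "*")
}

.weight_vector <- function(weights, criteria, k) {
  if (inherits(weights, "criterion_weights")) {
    w <- stats::setNames(weights$weight, weights$criterion)
  } else {
    w <- weights
  }
  if (length(w) != k)
    fr_stop(sprintf("%d weights supplied for %d criteria", length(w), k),
            "foodrisk_alignment_error")
  if (!is.null(names(w)) && !is.null(criteria)) {
    missing <- setdiff(criteria, names(w))
    if (length(missing))
      fr_stop(sprintf("no weight for criterion(s): %s",
                      paste(missing, collapse = ", ")),
              "foodrisk_alignment_error")
    w <- w[criteria]
  }
  if (any(!is.finite(w)) || any(w < 0))
    fr_stop("weights must be finite and nonnegative", "foodrisk_domain_error")
  as.numeric(w)
}

#' Positive and negative ideal solutions
#'
#' For each criterion the positive ideal \eqn{A^*_j} is the column maximum
#' over alternatives when the criterion is a benefit and the minimum when it
#' is a cost; the negative ideal \eqn{A^-_j} is the reverse.
#'
#' @param v weighted normalized matrix.
#' @param directions benefit/cost direction per criterion (named vectors are
#'   aligned by column name).
#' @return list with numeric vectors `A_star` and `A_minus`.
#' @export
ideal_solutions <- function(v, directions) {
  m <- .as_numeric_matrix(v)
  directions <- .align_directions(directions, colnames(m), ncol(m))
  hi <- apply(m, 2, max)
  lo <- apply(m, 2, min)
  benefit <- directions == "benefit"
  list(A_star = ifelse(benefit, hi, lo),
       A_minus = ifelse(benefit, lo, hi))
}

#' Separation measures and closeness coefficients
#'
#' Euclidean separations of each alternative from the ideal vectors,
#' \deqn{S^*_i = \sqrt{\sum_j (v_{ij} - A^*_j)^2}, \qquad
#'       S^-_i = \sqrt{\sum_j (v_{ij} - A^-_j)^2},}
#' and the closeness coefficient \eqn{C^*_i = S^-_i / (S^-_i + S^*_i) \in
#' [0, 1]}: 1 exactly when the alternative sits at the positive ideal, 0
#' exactly at the negative ideal.
#'
#' @param v weighted normalized matrix with at least 2 alternatives.
#' @param A_star,A_minus ideal vectors from [ideal_solutions()].
#' @return list with numeric vectors `S_star`, `S_minus`, `C_star`.
#' @export
separations_and_closeness <- function(v, A_star, A_minus) {
  m <- .as_numeric_matrix(v)
  if (nrow(m) < 2L)
    fr_stop("closeness coefficients need at least 2 alternatives",
            "foodrisk_degenerate_error")
  if (length(A_star) != ncol(m) || length(A_minus) != ncol(m))
    fr_stop("ideal vectors do not match the criterion count",
            "foodrisk_alignment_error")
  S_star <- sqrt(rowSums(sweep(m, 2, as.numeric(A_star))^2))
  S_minus <- sqrt(rowSums(sweep(m, 2, as.numeric(A_minus))^2))
  C_star <- S_minus / (S_minus + S_star)
  names(S_star) <- names(S_minus) <- names(C_star) <- rownames(m)
  list(S_star = S_star, S_minus = S_minus, C_star = C_star)
}

#' Rank alternatives by closeness coefficient
#'
#' Rank 1 goes to the highest \eqn{C^*} (closest to the positive ideal =
#' lowest risk). Ties are broken by input order (stable) and flagged.
#'
#' @param C_star numeric closeness coefficients.
#' @return list with `ranks` (integer permutation of `1..m`, aligned to the
#'   input order), `order` (indices from best to worst), and `ties`
#'   (logical).
#' @export
topsis_rank <- function(C_star) {
  if (any(!is.finite(C_star)))
    fr_stop("closeness coefficients contain non-finite values",
            "foodrisk_numerical_error")
  ord <- order(-C_star)          # stable: ties keep input order
  ranks <- integer(length(C_star))
  ranks[ord] <- seq_along(C_star)
  names(ranks) <- names(C_star)
  list(ranks = ranks, order = ord, ties = anyDuplicated(C_star) > 0)
}

#' TOPSIS ranking of alternatives
#'
#' Runs the complete TOPSIS chain: [topsis_normalize()] (choice of dialect),
#' [apply_weights()], [ideal_solutions()], [separations_and_closeness()],
#' [topsis_rank()].
#'
#' @param values alternatives x criteria matrix of nonnegative raw values,
#'   or a [decision_matrix()].
#' @param weights criterion weights ([criterion_weights][distances_to_weights]
#'   or numeric vector).
#' @param directions benefit/cost per criterion; taken from the
#'   `decision_matrix` attribute when omitted.
#' @param dialect normalization dialect, see [topsis_normalize()].
#' @return an object of class `topsis_result`: `alternatives`, `criteria`,
#'   `directions`, `weights`, `dialect`, `normalized`, `weighted`, `A_star`,
#'   `A_minus`, `S_star`, `S_minus`, `C_star`, `ranks`, `ties`.
#' @export
#' @examples
#' m <- cbind(meat = c(10, 20), inflation = c(5, 1))
#' topsis(m, weights = c(0.5, 0.5),
#'        directions = c("benefit", "cost"), dialect = "vector")
topsis <- function(values, weights, directions = NULL,
                   dialect = c("squared", "vector")) {
  dialect <- match.arg(dialect)
  if (is.null(directions)) {
    directions <- attr(values, "directions")
    if (is.null(directions))
      fr_stop("directions must be supplied (or use decision_matrix())",
              "foodrisk_validation_error")
  }
  dm <- decision_matrix(values, directions)
  directions <- attr(dm, "directions")
  m <- unclass(dm)
  attr(m, "directions") <- NULL
  r <- topsis_normalize(m, dialect = dialect)
  w <- .weight_vector(weights, colnames(r), ncol(r))
  v <- apply_weights(r, stats::setNames(w, colnames(r)))
  ideals <- ideal_solutions(v, directions)
  sep <- separations_and_closeness(v, ideals$A_star, ideals$A_minus)
  rk <- topsis_rank(sep$C_star)
  structure(
    list(alternatives = rownames(dm),
         criteria = colnames(dm),
         directions = directions,
         weights = stats::setNames(w, colnames(dm)),
         dialect = dialect,
         normalized = r,
         weighted = v,
         A_star = ideals$A_star,
         A_minus = ideals$A_minus,
         S_star = sep$S_star,
         S_minus = sep$S_minus,
         C_star = sep$C_star,
         ranks = rk$ranks,
         ties = rk$ties),
    class = "topsis_result"
  )
}

#' Ranking table of a TOPSIS result
#'
#' @param x a [topsis()] result.
#' @return data frame with one row per alternative, sorted by rank, holding
#'   the separations and closeness coefficient.
#' @export
ranking_table <- function(x) {
  stopifnot(inherits(x, "topsis_result"))
  out <- data.frame(rank = x$ranks,
                    alternative = x$alternatives,
                    S_star = x$S_star,
                    S_minus = x$S_minus,
                    C_star = x$C_star,
                    row.names = NULL)
  out[order(out$rank), , drop = FALSE]
}

#' @export
print.topsis_result <- function(x, digits = 6, ...) {
  cat(sprintf("TOPSIS ranking (%s normalization, %d alternatives, %d criteria)%s\n",
              x$dialect, length(x$alternatives), length(x$criteria),
              if (x$ties) " [ties broken by input order]" else ""))
  tab <- ranking_table(x)
  for (cl in c("S_star", "S_minus", "C_star")) tab[[cl]] <- signif(tab[[cl]], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Plot closeness coefficients
#'
#' Horizontal bar chart of \eqn{C^*} sorted by rank.
#'
#' @param x a [topsis()] result.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.topsis_result <- function(x, ...) {
  tab <- ranking_table(x)
  graphics::barplot(rev(tab$C_star), names.arg = rev(tab$alternative),
                    horiz = TRUE, las = 1, xlab = "closeness coefficient C*",
                    ...)
  invisible(x)
}
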
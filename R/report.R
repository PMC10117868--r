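#' Write a pipeline product to CSV or JSON
#'
#' Serializes any pipeline product — a [`country_table`][as_country_table],
#' [factor_model][fit_single_factor], [mds_embedding][smacof_embed],
#' [criterion_weights][distances_to_weights], or
#' [topsis_result][topsis] — to a delimited or JSON report. Tables written
#' as CSV round-trip: reading a written table reproduces it to full stored
#' precision (numbers are written with 17 significant digits).
#'
#' @param x the object to write.
#' @param destination output file path.
#' @param format `"csv"` or `"json"`.
#' @param ... unused.
#' @return `destination`, invisibly.
#' @export
write_report <- function(x, destination, format = c("csv", "json"), ...) {
  UseMethod("write_report")
}

.write_df <- function(df, destination, format) {
  if (format == "json") {
    jsonlite::write_json(df, destination, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    out <- df
    for (cl in names(out))
      if (is.numeric(out[[cl]]) && !is.integer(out[[cl]]))
        out[[cl]] <- sprintf("%.17g", out[[cl]])
    tryCatch(
      suppressWarnings(utils::write.csv(out, destination, row.names = FALSE,
                                        quote = TRUE)),
      error = function(e) fr_stop(sprintf("cannot write '%s': %s", destination,
                                          conditionMessage(e)),
                                  "foodrisk_io_error")
    )
  }
  invisible(destination)
}

#' @rdname write_report
#' @export
write_report.country_table <- function(x, destination,
                                       format = c("csv", "json"), ...) {
  .write_df(as.data.frame(x), destination, match.arg(format))
}

#' @rdname write_report
#' @export
write_report.criterion_weights <- function(x, destination,
                                           format = c("csv", "json"), ...) {
  .write_df(as.data.frame(x), destination, match.arg(format))
}

#' @rdname write_report
#' @export
write_report.factor_model <- function(x, destination,
                                      format = c("csv", "json"), ...) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      variables = x$variable_labels,
      eigenvalues = x$eigenvalues,
      variance_explained_pct = x$variance_explained_pct,
      cumulative_pct = cumsum(x$variance_explained_pct),
      loadings = as.list(x$loadings),
      score_coefficients = as.list(x$score_coefficients),
      factor_scores = as.list(x$scores),
      bartlett = list(chi2 = x$bartlett$statistic, df = x$bartlett$df,
                      p = x$bartlett$p.value)
    )
    jsonlite::write_json(payload, destination, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(destination)
  } else {
    df <- data.frame(component = seq_along(x$eigenvalues),
                     eigenvalue = x$eigenvalues,
                     pct_variance = x$variance_explained_pct,
                     cumulative_pct = cumsum(x$variance_explained_pct),
                     variable = x$variable_labels,
                     loading = as.numeric(x$loadings),
                     coefficient = as.numeric(x$score_coefficients))
    .write_df(df, destination, "csv")
  }
}

#' @rdname write_report
#' @export
write_report.mds_embedding <- function(x, destination,
                                       format = c("csv", "json"), ...) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(labels = x$labels,
                    coordinates = unname(apply(x$coordinates, 1, as.list)),
                    stress1 = x$stress1, sstress = x$sstress,
                    n_iterations = x$n_iterations, converged = x$converged,
                    init = x$init, seed = x$seed)
    jsonlite::write_json(payload, destination, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(destination)
  } else {
    df <- data.frame(label = x$labels, as.data.frame(x$coordinates),
                     row.names = NULL)
    df$stress1 <- x$stress1
    df$sstress <- x$sstress
    .write_df(df, destination, "csv")
  }
}

#' @rdname write_report
#' @export
write_report.topsis_result <- function(x, destination,
                                       format = c("csv", "json"), ...) {
  format <- match.arg(format)
  tab <- ranking_table(x)
  if (format == "json") {
    payload <- list(dialect = x$dialect, ties = x$ties,
                    criteria = x$criteria,
                    directions = as.list(x$directions),
                    weights = as.list(x$weights),
                    A_star = as.numeric(x$A_star),
                    A_minus = as.numeric(x$A_minus),
                    ranking = tab)
    jsonlite::write_json(payload, destination, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(destination)
  } else {
    .write_df(tab, destination, "csv")
  }
}

#' @rdname write_report
#' @export
write_report.data.frame <- function(x, destination,
                                    format = c("csv", "json"), ...) {
  .write_df(x, destination, match.arg(format))
}
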
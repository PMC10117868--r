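#' Reference values of the original OECD 2020 analysis
#'
#' The analysis that the [oecd2020()] dataset comes from was originally run
#' with proprietary MDS software, whose exact optimizer settings are not
#' reproducible bit-for-bit. These accessors return its published
#' intermediate values, transcribed as shipped fixtures, so downstream
#' stages can be driven from them exactly (see the `inject_*` arguments of
#' [run_pipeline()]):
#'
#' * `reference_configuration()` — the 7-point common-space coordinates
#'   (six criteria plus `Factor_1`) of the 2-D MDS solution;
#' * `reference_distances()` — the published criterion-to-`Factor_1`
#'   distances (3 decimals);
#' * `reference_weights()` — the published criterion-weight table
#'   (distance, ratio, complement, weight at 9 decimals).
#'
#' Criterion labels use this package's canonical column names.
#'
#' @return `reference_configuration()`: a labelled 7 x 2 coordinate matrix;
#'   `reference_distances()`: a named numeric vector;
#'   `reference_weights()`: a [criterion_weights][distances_to_weights]
#'   data frame.
#' @export
reference_distances <- function() {
  df <- utils::read.csv(system.file("extdata", "ref_distances.csv",
                                    package = "foodrisk", mustWork = TRUE))
  stats::setNames(df$distance, df$criterion)
}

#' @rdname reference_distances
#' @export
reference_configuration <- function() {
  df <- utils::read.csv(system.file("extdata", "ref_configuration.csv",
                                    package = "foodrisk", mustWork = TRUE))
  m <- as.matrix(df[, c("Dimension_1", "Dimension_2")])
  rownames(m) <- df$label
  m
}

#' @rdname reference_distances
#' @export
reference_weights <- function() {
  df <- utils::read.csv(system.file("extdata", "ref_weights.csv",
                                    package = "foodrisk", mustWork = TRUE))
  structure(df, class = c("criterion_weights", "data.frame"))
}
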
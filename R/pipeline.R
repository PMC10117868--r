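#' Pipeline configuration
#'
#' Collects every setting of the three-stage pipeline in one validated
#' list. `read_pipeline_config()` loads the same structure from a YAML or
#' JSON file (keys identical to the argument names; nested `mds` list for
#' the MDS settings).
#'
#' @param input path to the input CSV, or `NULL` to pass a table directly to
#'   [run_pipeline()].
#' @param schema column mapping, see [country_schema()].
#' @param factor_columns the three economic indicator columns reduced to
#'   `Factor_1`.
#' @param criterion_columns the six criterion columns ranked by TOPSIS;
#'   must be disjoint from `factor_columns`.
#' @param directions benefit/cost per criterion (named or positional).
#' @param dialect TOPSIS normalization dialect, see [topsis_normalize()].
#' @param weights_source `"pipeline"` (stages 1-2 compute the weights) or
#'   `"file"` (read from `weights_file`, skipping MDS).
#' @param weights_file CSV with columns `criterion`, `weight` (or a full
#'   [criterion_weights][distances_to_weights] table) when
#'   `weights_source = "file"`.
#' @param proximity_scaling standardization for the proximity matrix, see
#'   [variable_distance_matrix()].
#' @param mds list of MDS settings: `init`, `seed`, `tol`, `max_iter`.
#' @param out_dir directory for stage artifacts (created if missing);
#'   `NULL` writes nothing.
#' @param log_level `"info"` (one message per stage) or `"quiet"`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL,
                            schema = country_schema(),
                            factor_columns = c("gdp_growth_pct",
                                               "health_spending",
                                               "gdp_per_capita"),
                            criterion_columns = c("meat_total",
                                                  "crop_per_million",
                                                  "producer_support_pct",
                                                  "producer_protection_ratio",
                                                  "household_spending_pct_gdp",
                                                  "food_inflation_pct"),
                            directions = c(
                              meat_total = "benefit",
                              crop_per_million = "benefit",
                              producer_support_pct = "benefit",
                              producer_protection_ratio = "benefit",
                              household_spending_pct_gdp = "cost",
                              food_inflation_pct = "cost"),
                            dialect = c("squared", "vector"),
                            weights_source = c("pipeline", "file"),
                            weights_file = NULL,
                            proximity_scaling = c("case", "variable", "none"),
                            mds = list(init = "torgerson", seed = 1L,
                                       tol = 1e-9, max_iter = 10000),
                            out_dir = NULL,
                            log_level = c("info", "quiet")) {
  dialect <- match.arg(dialect)
  weights_source <- match.arg(weights_source)
  proximity_scaling <- match.arg(proximity_scaling)
  log_level <- match.arg(log_level)
  if (length(intersect(factor_columns, criterion_columns)))
    fr_stop("factor_columns and criterion_columns must be disjoint",
            "foodrisk_validation_error")
  directions <- .align_directions(directions, criterion_columns,
                                  length(criterion_columns))
  if (weights_source == "file" && is.null(weights_file))
    fr_stop("weights_source = 'file' needs weights_file",
            "foodrisk_validation_error")
  defaults <- list(init = "torgerson", seed = 1L, tol = 1e-9, max_iter = 10000)
  mds <- utils::modifyList(defaults, as.list(mds))
  structure(
    list(input = input, schema = schema, factor_columns = factor_columns,
         criterion_columns = criterion_columns, directions = directions,
         dialect = dialect, weights_source = weights_source,
         weights_file = weights_file, proximity_scaling = proximity_scaling,
         mds = mds, out_dir = out_dir, log_level = log_level),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML (`.yml`/`.yaml`) or JSON (`.json`) configuration file.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    fr_stop(sprintf("config file not found: %s", path), "foodrisk_io_error")
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    fr_stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
            "foodrisk_validation_error")
  if (!is.null(raw$schema)) raw$schema <- do.call(country_schema, as.list(raw$schema))
  do.call(pipeline_config, raw)
}

.log <- function(config, fmt, ...) {
  if (identical(config$log_level, "info"))
    message(sprintf(paste0("[foodrisk] ", fmt), ...))
}

.stage <- function(name, expr) {
  tryCatch(expr, foodrisk_error = function(e) {
    fr_stop(sprintf("stage '%s' failed: %s (check the stage inputs and config)",
                    name, conditionMessage(e)),
            class(e)[1])
  })
}

#' Load an intermediate artifact for stage injection
#'
#' Reads a previously written (or transcribed) stage artifact so
#' [run_pipeline()] can resume downstream of it: per-country factor scores,
#' criterion-to-factor distances, criterion weights, or a weighted
#' normalized decision matrix.
#'
#' @param artifact path to a CSV file. Expected columns: `factor_scores`:
#'   `country`, `score`; `distances`: `criterion`, `distance`; `weights`:
#'   `criterion`, `weight`; `weighted_matrix`: `country` plus one column per
#'   criterion.
#' @param stage which stage product the file holds.
#' @return the parsed artifact in the form [run_pipeline()] accepts for the
#'   matching `inject_*` argument.
#' @export
inject_stage <- function(artifact,
                         stage = c("factor_scores", "distances", "weights",
                                   "weighted_matrix")) {
  stage <- match.arg(stage)
  if (!file.exists(artifact) || file.size(artifact) == 0)
    fr_stop(sprintf("injection artifact missing or empty: %s", artifact),
            "foodrisk_injection_error")
  df <- tryCatch(utils::read.csv(artifact, check.names = FALSE),
                 error = function(e)
                   fr_stop(sprintf("cannot parse injection artifact: %s",
                                   conditionMessage(e)),
                           "foodrisk_injection_error"))
  need <- switch(stage,
                 factor_scores = c("country", "score"),
                 distances = c("criterion", "distance"),
                 weights = c("criterion", "weight"),
                 weighted_matrix = "country")
  missing <- setdiff(need, names(df))
  if (length(missing))
    fr_stop(sprintf("injection artifact for stage '%s' lacks column(s): %s",
                    stage, paste(missing, collapse = ", ")),
            "foodrisk_injection_error")
  switch(stage,
         factor_scores = stats::setNames(as.numeric(df$score), df$country),
         distances = stats::setNames(as.numeric(df$distance), df$criterion),
         weights = stats::setNames(as.numeric(df$weight), df$criterion),
         weighted_matrix = {
           m <- as.matrix(df[, setdiff(names(df), "country"), drop = FALSE])
           rownames(m) <- df$country
           m
         })
}

#' Run the three-stage food-insecurity pipeline
#'
#' Executes factor scoring, distance-based criterion weighting, and TOPSIS
#' ranking end-to-end, or from any injected intermediate (injected stages
#' skip the upstream computation and are logged). With `out_dir` set, each
#' stage product is written via [write_report()] together with a
#' `manifest.json` recording the seed, dialect, and package version;
#' identical config and seed give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param table a [`country_table`][as_country_table] (overrides
#'   `config$input`).
#' @param inject_factor_scores named per-country factor scores (or the
#'   result of [inject_stage()]).
#' @param inject_distances named criterion-to-factor distances.
#' @param inject_weights named criterion weights or a
#'   [criterion_weights][distances_to_weights] object.
#' @param inject_weighted_matrix weighted normalized decision matrix
#'   (countries x criteria).
#' @return an object of class `pipeline_result`: `table`, `factor_model`,
#'   `proximities`, `embedding`, `distances`, `weights`, `topsis`, `config`
#'   (upstream elements are `NULL` when skipped by injection).
#' @export
#' @examples
#' res <- run_pipeline(pipeline_config(log_level = "quiet"),
#'                     table = oecd2020())
#' ranking_table(res$topsis)[c(1, 14), ]
run_pipeline <- function(config = pipeline_config(), table = NULL,
                         inject_factor_scores = NULL,
                         inject_distances = NULL,
                         inject_weights = NULL,
                         inject_weighted_matrix = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(table)) {
    if (is.null(config$input))
      fr_stop("no input: set config$input or pass a table",
              "foodrisk_validation_error")
    table <- .stage("load", load_country_table(config$input, config$schema))
  } else if (!inherits(table, "country_table")) {
    table <- .stage("load", as_country_table(table))
  }

  need_weights <- is.null(inject_weights) && is.null(inject_weighted_matrix)
  need_mds <- need_weights && is.null(inject_distances) &&
    config$weights_source == "pipeline"
  need_factor <- need_mds && is.null(inject_factor_scores)

  fm <- NULL
  scores <- inject_factor_scores
  if (need_factor) {
    fm <- .stage("factor_scoring", {
      z <- standardize_columns(table, config$factor_columns)
      fit_single_factor(z)
    })
    scores <- fm$scores
    .log(config,
         "factor stage: lambda1 = %.4f (%.2f%% variance), Bartlett p = %.3g",
         fm$eigenvalues[1], fm$variance_explained_pct[1], fm$bartlett$p.value)
  } else if (!is.null(inject_factor_scores)) {
    .log(config, "factor stage skipped: scores injected")
  }

  prox <- NULL; emb <- NULL; dists <- inject_distances
  weights <- inject_weights
  if (need_weights && config$weights_source == "file") {
    weights <- .stage("weights", inject_stage(config$weights_file, "weights"))
    .log(config, "weights read from file: %s", config$weights_file)
  } else if (need_mds) {
    prox <- .stage("mds_weighting", {
      normalize_proximities(variable_distance_matrix(
        table, columns = config$criterion_columns, factor_scores = scores,
        scale = config$proximity_scaling))
    })
    emb <- .stage("mds_weighting", smacof_embed(
      prox, dims = 2, init = config$mds$init, seed = config$mds$seed,
      max_iter = config$mds$max_iter, tol = config$mds$tol))
    dists <- distances_to_anchor(emb, "Factor_1")
    .log(config, "mds stage: stress1 = %.5f after %d iterations",
         emb$stress1, emb$n_iterations)
  } else if (!is.null(inject_distances)) {
    .log(config, "mds stage skipped: distances injected")
  }

  if (is.null(weights) && !is.null(dists))
    weights <- distances_to_weights(dists)
  if (!is.null(weights) && !inherits(weights, "criterion_weights") &&
      is.null(inject_weighted_matrix)) {
    w <- .weight_vector(weights, config$criterion_columns,
                        length(config$criterion_columns))
    weights <- structure(
      data.frame(criterion = config$criterion_columns, distance = NA_real_,
                 ratio = NA_real_, fixed = NA_real_, weight = w),
      class = c("criterion_weights", "data.frame"))
  }
  if (inherits(weights, "criterion_weights"))
    .log(config, "weights: sum = %.6f, max on '%s'", sum(weights$weight),
         weights$criterion[which.max(weights$weight)])

  ts <- if (!is.null(inject_weighted_matrix)) {
    .stage("topsis", {
      v <- .as_numeric_matrix(inject_weighted_matrix)
      directions <- .align_directions(config$directions, colnames(v), ncol(v))
      ideals <- ideal_solutions(v, directions)
      sep <- separations_and_closeness(v, ideals$A_star, ideals$A_minus)
      rk <- topsis_rank(sep$C_star)
      structure(
        list(alternatives = rownames(v), criteria = colnames(v),
             directions = directions, weights = NULL, dialect = config$dialect,
             normalized = NULL, weighted = v,
             A_star = ideals$A_star, A_minus = ideals$A_minus,
             S_star = sep$S_star, S_minus = sep$S_minus, C_star = sep$C_star,
             ranks = rk$ranks, ties = rk$ties),
        class = "topsis_result")
    })
  } else {
    .stage("topsis", {
      m <- .as_numeric_matrix(table, config$criterion_columns)
      topsis(m, weights = weights, directions = config$directions,
             dialect = config$dialect)
    })
  }
  tab <- ranking_table(ts)
  .log(config, "topsis (%s): rank 1 = %s (C* = %.6f), rank %d = %s (C* = %.6f)",
       ts$dialect, tab$alternative[1], tab$C_star[1],
       nrow(tab), tab$alternative[nrow(tab)], tab$C_star[nrow(tab)])

  result <- structure(
    list(table = table, factor_model = fm, proximities = prox,
         embedding = emb, distances = dists, weights = weights,
         topsis = ts, config = config),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) .write_artifacts(result, config)
  result
}

.write_artifacts <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  write_report(result$table, p("input_table.csv"), "csv")
  if (!is.null(result$factor_model)) {
    write_report(result$factor_model, p("factor_model.csv"), "csv")
    write_report(result$factor_model, p("factor_model.json"), "json")
  }
  if (!is.null(result$embedding)) {
    write_report(result$embedding, p("embedding.csv"), "csv")
    .write_df(data.frame(criterion = names(result$distances),
                         distance = as.numeric(result$distances)),
              p("distances.csv"), "csv")
  }
  if (inherits(result$weights, "criterion_weights"))
    write_report(result$weights, p("weights.csv"), "csv")
  write_report(result$topsis, p("ranking.csv"), "csv")
  write_report(result$topsis, p("ranking.json"), "json")
  manifest <- list(
    package = "foodrisk",
    version = as.character(utils::packageVersion("foodrisk")),
    dialect = config$dialect,
    proximity_scaling = config$proximity_scaling,
    mds = config$mds[c("init", "seed", "tol", "max_iter")]
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("foodrisk pipeline result\n")
  if (!is.null(x$factor_model))
    cat(sprintf("  factor stage: lambda1 = %.4f (%.2f%% variance)\n",
                x$factor_model$eigenvalues[1],
                x$factor_model$variance_explained_pct[1]))
  if (!is.null(x$embedding))
    cat(sprintf("  mds stage: stress1 = %.5f\n", x$embedding$stress1))
  if (inherits(x$weights, "criterion_weights"))
    cat(sprintf("  weights: %s\n",
                paste(sprintf("%s = %.4f", x$weights$criterion,
                              x$weights$weight), collapse = ", ")))
  tab <- ranking_table(x$topsis)
  cat(sprintf("  ranking (%s dialect):\n", x$topsis$dialect))
  print(utils::head(tab, 3), row.names = FALSE)
  cat("  ...\n")
  print(utils::tail(tab, 1), row.names = FALSE)
  invisible(x)
}
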
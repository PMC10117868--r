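#' Column schema for country-indicator tables
#'
#' Maps the canonical column names used throughout the package to the column
#' names found in an input file. Override any entry to read files with other
#' headers, e.g. `country_schema(country = "nation")`.
#'
#' @param ... named character overrides, `canonical = "file column"`.
#' @return named character vector (canonical name -> file column name).
#' @export
#' @examples
#' country_schema()
#' country_schema(meat_total = "meat_kg_pc")
country_schema <- function(...) {
  schema <- c(
    country                    = "country",
    meat_total                 = "meat_total",
    crop_total                 = "crop_total",
    population                 = "population",
    crop_per_million           = "crop_per_million",
    producer_support_pct       = "producer_support_pct",
    producer_protection_ratio  = "producer_protection_ratio",
    household_spending_pct_gdp = "household_spending_pct_gdp",
    food_inflation_pct         = "food_inflation_pct",
    gdp_growth_pct             = "gdp_growth_pct",
    health_spending            = "health_spending",
    gdp_per_capita             = "gdp_per_capita"
  )
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(schema))
    if (length(bad))
      fr_stop(sprintf("unknown schema field(s): %s", paste(bad, collapse = ", ")),
              "foodrisk_schema_error")
    schema[names(over)] <- over
  }
  schema
}

## canonical columns that must be present and numeric
.required_numeric <- c(
  "meat_total", "crop_per_million", "producer_support_pct",
  "producer_protection_ratio", "household_spending_pct_gdp",
  "food_inflation_pct", "gdp_growth_pct", "health_spending", "gdp_per_capita"
)

## optional sub-component columns; when present their totals are checked
.meat_parts <- c("meat_beef", "meat_pork", "meat_poultry", "meat_sheep")
.crop_parts <- c("crop_wheat", "crop_maize", "crop_rice", "crop_soybean")

#' Crop production per one million inhabitants
#'
#' Rescales a national crop total (tons) to tons per 1 million people, the
#' form in which crop production enters the decision matrix: raw national
#' totals have such a large spread that they would otherwise dominate every
#' distance computation.
#'
#' @param crop_total total crop production, tons.
#' @param population population, persons; must be positive.
#' @return `crop_total / (population / 1e6)`, tons per million people.
#' @export
#' @examples
#' derive_crop_per_million(31789.35, 25693267) # ~1237.25
derive_crop_per_million <- function(crop_total, population) {
  if (any(!is.finite(population)) || any(population <= 0))
    fr_stop("population must be > 0", "foodrisk_domain_error")
  crop_total / (population / 1e6)
}

#' Validate and classify a country-indicator data frame
#'
#' Checks the invariants every pipeline stage relies on: required columns
#' present and numeric, no missing values, unique country labels, all
#' criterion columns except GDP growth nonnegative, meat/crop totals equal to
#' the sum of their sub-components when sub-components are present, and
#' `crop_per_million` consistent (within 0.2%) with `crop_total` and
#' `population` when both are present. Missing `crop_per_million` is derived
#' on the fly via [derive_crop_per_million()].
#'
#' @param df a data frame already using canonical column names.
#' @return the validated data frame, classed `country_table`.
#' @export
as_country_table <- function(df) {
  if (!is.data.frame(df) || nrow(df) == 0L)
    fr_stop("input has no rows", "foodrisk_schema_error")
  if (!"country" %in% names(df))
    fr_stop("missing required column: country", "foodrisk_schema_error")
  df$country <- as.character(df$country)
  if (anyDuplicated(df$country))
    fr_stop(sprintf("duplicate country label(s): %s",
                    paste(unique(df$country[duplicated(df$country)]), collapse = ", ")),
            "foodrisk_validation_error")

  if (!"crop_per_million" %in% names(df) &&
      all(c("crop_total", "population") %in% names(df)))
    df$crop_per_million <- derive_crop_per_million(df$crop_total, df$population)

  missing <- setdiff(.required_numeric, names(df))
  if (length(missing))
    fr_stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
            "foodrisk_schema_error")

  num_cols <- intersect(
    c(.required_numeric, "crop_total", "population", .meat_parts, .crop_parts),
    names(df)
  )
  for (cl in num_cols) {
    v <- fr_num(df[[cl]])
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (length(bad))
      fr_stop(sprintf("non-numeric value in column '%s', row %d ('%s')",
                      cl, bad[1], as.character(df[[cl]][bad[1]])),
              "foodrisk_parse_error")
    if (anyNA(v))
      fr_stop(sprintf("missing value in required column '%s'", cl),
              "foodrisk_validation_error")
    df[[cl]] <- v
  }

  nonneg <- setdiff(.required_numeric, "gdp_growth_pct")
  for (cl in nonneg)
    if (any(df[[cl]] < 0))
      fr_stop(sprintf("column '%s' must be nonnegative", cl),
              "foodrisk_validation_error")

  ## totals agree with printed sub-components; 0.02 allows each of the four
  ## parts to carry half-a-last-digit rounding
  check_total <- function(parts, total) {
    if (all(parts %in% names(df))) {
      s <- rowSums(df[parts])
      off <- which(abs(s - df[[total]]) > 0.02 + 1e-9)
      if (length(off))
        fr_stop(sprintf("%s does not match the sum of its sub-components (row %d: %s vs %s)",
                        total, off[1], format(df[[total]][off[1]]), format(s[off[1]])),
                "foodrisk_validation_error")
    }
  }
  check_total(.meat_parts, "meat_total")
  check_total(.crop_parts, "crop_total")

  if (all(c("crop_total", "population") %in% names(df))) {
    expect <- derive_crop_per_million(df$crop_total, df$population)
    rel <- abs(expect - df$crop_per_million) / pmax(abs(expect), 1e-12)
    if (any(rel > 0.002))
      fr_stop(sprintf("crop_per_million inconsistent with crop_total/population (row %d)",
                      which(rel > 0.002)[1]),
              "foodrisk_validation_error")
  }

  class(df) <- c("country_table", "data.frame")
  df
}

#' Read a country-indicator table from CSV
#'
#' Reads a comma-delimited file with a header row (UTF-8, decimal point), one
#' row per country, renames columns to the canonical schema, and validates it
#' via [as_country_table()]. Row order is preserved and units are not
#' touched.
#'
#' @param source path (or connection) to a CSV file.
#' @param schema column mapping from [country_schema()].
#' @return a validated [`country_table`][as_country_table] data frame.
#' @export
#' @examples
#' tab <- oecd2020()
#' tab$meat_total[tab$country == "United States"] # 101.57
load_country_table <- function(source, schema = country_schema()) {
  df <- tryCatch(
    utils::read.csv(source, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character"),
    error = function(e) fr_stop(sprintf("cannot parse '%s' as CSV: %s",
                                        as.character(source)[1], conditionMessage(e)),
                                "foodrisk_schema_error")
  )
  if (nrow(df) == 0L || ncol(df) == 0L)
    fr_stop("empty input: no data rows", "foodrisk_schema_error")

  ## map file columns to canonical names; untouched extras ride along
  for (canon in names(schema)) {
    file_col <- schema[[canon]]
    if (file_col %in% names(df) && canon != file_col) {
      df[[canon]] <- df[[file_col]]
      df[[file_col]] <- NULL
    }
  }
  if ("population_as_printed" %in% names(df))
    df$population_as_printed <- as.logical(df$population_as_printed)
  as_country_table(df)
}

#' The packaged 14-country OECD 2020 reference dataset
#'
#' Loads the reference table of six food-insecurity criteria and three
#' economic indicators for 14 OECD countries in 2020, transcribed verbatim
#' from the source compilation, including the meat and crop sub-components.
#'
#' Two transcription quirks are preserved deliberately because every
#' downstream reference value derives from them: (i) some population counts
#' are internally consistent with the printed per-million crop values but are
#' not plausible census figures (Chile, New Zealand, Switzerland, United
#' States); these rows carry `population_as_printed = TRUE`. (ii) In the
#' source's column headers the unit annotations of producer support and
#' producer protection are swapped; columns here are named by value
#' semantics: `producer_support_pct` is a percentage of gross farm receipts
#' (0.98--53.4) and `producer_protection_ratio` is a dimensionless
#' price ratio (1.00--1.73).
#'
#' @return a [`country_table`][as_country_table] with 14 rows.
#' @export
#' @examples
#' oecd2020()[, c("country", "meat_total", "crop_per_million")]
oecd2020 <- function() {
  load_country_table(oecd2020_path())
}

#' @rdname oecd2020
#' @return `oecd2020_path()`: path to the packaged CSV.
#' @export
oecd2020_path <- function() {
  system.file("extdata", "oecd2020.csv", package = "foodrisk", mustWork = TRUE)
}

#' @export
print.country_table <- function(x, ...) {
  cat(sprintf("country_table: %d countries x %d columns\n", nrow(x), ncol(x)))
  print.data.frame(x, ...)
  invisible(x)
}
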
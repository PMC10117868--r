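test_that("packaged OECD 2020 table loads with the expected countries and values", {
  tab <- oecd2020()
  expect_s3_class(tab, "country_table")
  expect_equal(nrow(tab), 14L)
  expect_setequal(tab$country,
                  c("Australia", "Canada", "Chile", "Colombia", "Israel",
                    "Japan", "Korea", "Mexico", "New Zealand", "Norway",
                    "Switzerland", "Turkey", "United Kingdom", "United States"))
  expect_equal(tab$meat_total[tab$country == "United States"], 101.57)
  expect_equal(tab$producer_support_pct[tab$country == "Norway"], 53.40)
  expect_equal(tab$food_inflation_pct[tab$country == "Israel"], 0)
  expect_true(all(tab$population_as_printed %in% c(TRUE, FALSE)))
})

test_that("meat and crop totals equal the sum of their sub-components", {
  tab <- oecd2020()
  meat_sum <- rowSums(tab[, c("meat_beef", "meat_pork", "meat_poultry",
                              "meat_sheep")])
  crop_sum <- rowSums(tab[, c("crop_wheat", "crop_maize", "crop_rice",
                              "crop_soybean")])
  expect_lt(max(abs(meat_sum - tab$meat_total)), 0.02 + 1e-9)
  expect_lt(max(abs(crop_sum - tab$crop_total)), 0.02 + 1e-9)
})

test_that("per-million crop values are self-consistent with population", {
  tab <- oecd2020()
  recomputed <- derive_crop_per_million(tab$crop_total, tab$population)
  rel <- abs(recomputed - tab$crop_per_million) / recomputed
  expect_lt(max(rel), 0.002)
})

test_that("derive_crop_per_million matches hand-checked values and rejects bad input", {
  expect_equal(derive_crop_per_million(31789.35, 25693267), 1237.25,
               tolerance = 0.1 / 1237.25)
  expect_equal(derive_crop_per_million(663.83, 50902), 13041.39,
               tolerance = 1 / 13041.39)
  expect_equal(derive_crop_per_million(0, 1e6), 0)
  expect_error(derive_crop_per_million(100, 0), class = "foodrisk_domain_error")
  expect_error(derive_crop_per_million(100, -5), class = "foodrisk_domain_error")
})

test_that("crop_per_million is derived when absent", {
  df <- toy_country_table()
  df$crop_total <- df$crop_per_million * 2      # population of 2 million
  df$population <- rep(2e6, nrow(df))
  expected <- df$crop_per_million
  df$crop_per_million <- NULL
  tab <- as_country_table(df)
  expect_equal(tab$crop_per_million, expected)
})

test_that("loader rejects malformed inputs with classed errors", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("", empty)
  expect_error(load_country_table(empty), class = "foodrisk_schema_error")

  tab <- oecd2020()

  dup <- as.data.frame(tab)[c(1:14, 1), ]
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(dup, f, row.names = FALSE)
  expect_error(load_country_table(f), class = "foodrisk_validation_error")

  nocol <- as.data.frame(tab)
  nocol$meat_total <- NULL
  nocol[c("meat_beef", "meat_pork", "meat_poultry", "meat_sheep")] <- NULL
  write.csv(nocol, f, row.names = FALSE)
  err <- expect_error(load_country_table(f), class = "foodrisk_schema_error")
  expect_match(conditionMessage(err), "meat_total")

  badcell <- as.data.frame(tab)
  badcell$health_spending[3] <- "n/a"
  write.csv(badcell, f, row.names = FALSE)
  err <- expect_error(load_country_table(f), class = "foodrisk_parse_error")
  expect_match(conditionMessage(err), "health_spending")
  expect_match(conditionMessage(err), "row 3")

  neg <- as.data.frame(tab)
  neg$food_inflation_pct[1] <- -1
  write.csv(neg, f, row.names = FALSE)
  expect_error(load_country_table(f), class = "foodrisk_validation_error")
})

test_that("schema mapping renames file columns and rejects unknown fields", {
  tab <- as.data.frame(oecd2020())
  names(tab)[names(tab) == "meat_total"] <- "meat_kg_pc"
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  expect_error(load_country_table(f), class = "foodrisk_schema_error")
  reread <- load_country_table(f, country_schema(meat_total = "meat_kg_pc"))
  expect_equal(reread$meat_total, oecd2020()$meat_total)
  expect_error(country_schema(not_a_field = "x"), class = "foodrisk_schema_error")
})

test_that("written tables round-trip to full stored precision", {
  tab <- oecd2020()
  f <- withr::local_tempfile(fileext = ".csv")
  write_report(tab, f, "csv")
  back <- load_country_table(f)
  num <- names(tab)[vapply(tab, is.numeric, logical(1))]
  for (cl in num) expect_identical(back[[cl]], tab[[cl]])
  expect_identical(back$country, tab$country)
})

test_that("unwritable destination raises an I/O error", {
  expect_error(write_report(oecd2020(), "/nonexistent-dir/x/y.csv", "csv"),
               class = "foodrisk_io_error")
})
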
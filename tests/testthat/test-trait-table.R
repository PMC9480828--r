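test_that("delimited round trip preserves values, mask and ordering", {
  fx <- small_fixture(seed = 11)
  tbl <- fx$table
  tf <- withr::local_tempfile(fileext = ".csv")
  sf <- withr::local_tempfile(fileext = ".json")
  write_trait_table(tbl, tf, schema_path = sf)
  back <- read_trait_table(tf, sf)
  expect_identical(back$ids, tbl$ids)
  expect_identical(missing_mask(back), missing_mask(tbl))
  expect_equal(back$values, tbl$values)
  expect_identical(trait_names(back), trait_names(tbl))
})

test_that("parsing maps missing tokens and validates labels and ids", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("accession,height,color",
               "A1,10.5,green",
               "A2,,yellow",
               "A3,9,green"), tf)
  tbl <- read_trait_table(tf, toy_schema())
  expect_equal(sum(missing_mask(tbl)), 1L)
  expect_true(is.na(tbl$values$height[2]))

  writeLines(c("accession,height,color",
               "A1,10.5,green",
               "A2,11,magenta"), tf)
  expect_error(read_trait_table(tf, toy_schema()), "color.*row.*2|magenta")

  writeLines(c("accession,height,color",
               "A1,10.5,green",
               "A1,11,yellow"), tf)
  expect_error(read_trait_table(tf, toy_schema()), "duplicate accession")

  writeLines(c("accession,height,color,bogus",
               "A1,10.5,green,x"), tf)
  expect_error(read_trait_table(tf, toy_schema()), "unknown trait")
})

test_that("duplicate accessions are removed, keeping first occurrence", {
  tbl <- trait_table(
    data.frame(height = c(1, 2, 3, 4, 2), color = c("g", "y", "g", "g", "y")),
    list(trait_schema("height", "quantitative"),
         trait_schema("color", "qualitative", categories = c("g", "y"))),
    ids = paste0("A", 1:5))
  dd <- dedupe_accessions(tbl)
  expect_identical(dd$removed_ids, "A5")
  expect_identical(dd$table$ids, paste0("A", 1:4))
  # idempotent, retained cells untouched
  dd2 <- dedupe_accessions(dd$table)
  expect_identical(dd2$removed_ids, character(0))
  expect_equal(dd2$table$values, dd$table$values)
})

test_that("duplicate detection treats missing = missing as equal", {
  tbl <- trait_table(
    data.frame(height = c(1, NA, 1, NA), color = c("g", "y", "g", "y")),
    list(trait_schema("height", "quantitative"),
         trait_schema("color", "qualitative", categories = c("g", "y"))),
    ids = paste0("A", 1:4))
  dd <- dedupe_accessions(tbl)
  expect_identical(dd$removed_ids, c("A3", "A4"))
})

test_that("planted duplicates in a catalogue-sized fixture are all removed", {
  fx <- edamame_fixture(seed = 5, n_duplicates = 13)
  expect_equal(n_accessions(fx$table), 213L)
  dd <- dedupe_accessions(fx$table)
  expect_equal(n_accessions(dd$table), 200L)
  expect_equal(length(dd$removed_ids), 13L)
})

test_that("invariant traits are dropped, judged on observed values", {
  tbl <- trait_table(
    data.frame(leaflets = c(3, 3, 3, 3), height = c(1, 2, 3, 4),
               partial = c(5, NA, 5, NA)),
    list(trait_schema("leaflets", "quantitative"),
         trait_schema("height", "quantitative"),
         trait_schema("partial", "quantitative")))
  di <- drop_invariant_traits(tbl)
  expect_setequal(di$removed_traits, c("leaflets", "partial"))
  expect_identical(trait_names(di$table), "height")
  # all-variable table is the identity
  di2 <- drop_invariant_traits(di$table)
  expect_identical(di2$removed_traits, character(0))
})

test_that("missingness profile reports rates and strata", {
  fx <- small_fixture(seed = 3, miss = 0)
  prof <- missingness_profile(fx$truth$complete)
  expect_true(all(prof$per_trait == 0))
  expect_equal(unname(prof$strata["none"]), 8)

  tbl <- toy_table()
  prof <- missingness_profile(tbl)
  expect_equal(unname(prof$per_trait), c(0.2, 0.2))
  expect_equal(prof$overall, mean(prof$per_trait))

  fx <- edamame_fixture(seed = 2)
  prof <- missingness_profile(fx$table)
  expect_equal(unname(prof$strata), c(6L, 23L, 8L, 9L))
  expect_equal(sum(prof$strata), 46L)
})

test_that("qualitative cells outside declared categories are rejected", {
  expect_error(
    trait_table(data.frame(color = "blue"),
                list(trait_schema("color", "qualitative",
                                  categories = c("g", "y")))),
    "outside declared categories")
})
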
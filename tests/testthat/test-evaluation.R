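test_that("bootstrap Levene test behaves at its fixed points", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7, 2.9)
  lev <- levene_bootstrap(x, x, B = 200, seed = 1)
  expect_equal(lev$p_value, 1)
  expect_equal(lev$statistic, 0)
  expect_equal(levene_bootstrap(rep(2, 5), rep(2, 7))$p_value, 1)
  lev <- levene_bootstrap(rnorm(30), rnorm(30), seed = 2)
  expect_equal(lev$B, 1000)
})

test_that("bootstrap Levene detects heteroscedasticity", {
  hits <- 0
  for (s in 1:5) {
    set.seed(s)
    p <- levene_bootstrap(rnorm(100, sd = 1), rnorm(100, sd = 5),
                          B = 500, seed = s)$p_value
    hits <- hits + (p < 0.05)
  }
  expect_equal(hits, 5)
})

test_that("identical collections yield no significant trait differences", {
  fx <- small_fixture(seed = 3, miss = 0)
  ec <- fx$truth$complete
  res <- compare_traits(ec, ec, B = 200, seed = 1)
  done <- !is.na(res$tests$p_value)
  expect_true(all(!res$tests$significant[done]))
  expect_equal(res$significant_fraction, 0)
})

test_that("a planted mean shift is flagged in the shifted trait only", {
  hit <- other_frac <- c()
  for (s in 1:5) {
    fx <- small_fixture(seed = 200 + s, miss = 0)
    ec <- fx$truth$complete
    set.seed(s)
    half <- sample(ec$ids, 40)
    cc <- subset_accessions(ec, half)
    shift <- 3 * sd(ec$values$qt03)
    cc$values$qt03 <- cc$values$qt03 + shift
    res <- compare_traits(ec, cc, B = 200, seed = s)
    tests <- res$tests[!is.na(res$tests$p_value), ]
    hit <- c(hit, tests$significant[tests$trait == "qt03"])
    other_frac <- c(other_frac, mean(tests$significant[tests$trait != "qt03"]))
  }
  expect_true(all(hit))
  expect_lte(mean(other_frac), 0.05 + 3 * sqrt(0.05 * 0.95 / (5 * 7)))
})

test_that("the five indices are exact on the identity and the hand toy", {
  fx <- small_fixture(seed = 5, miss = 0)
  ec <- fx$truth$complete
  idx <- five_indices(ec, ec$ids)
  expect_equal(idx$MD_pct, 0)
  expect_equal(idx$VD_pct, 0)
  expect_equal(idx$CR_pct, 100)
  expect_equal(idx$VR_pct, 100)
  expect_equal(idx$coverage_pct, 100)
  expect_true(idx$representative)

  ec1 <- trait_table(data.frame(t = 1:5),
                     list(trait_schema("t", "quantitative")),
                     ids = paste0("A", 1:5))
  idx <- suppressWarnings(five_indices(ec1, c("A2", "A4")))
  expect_equal(idx$MD_pct, 0)
  expect_equal(idx$VD_pct, 25)
  expect_equal(idx$CR_pct, 50)
  expect_equal(idx$VR_pct, sqrt(2 / 2.5) * 100)
  expect_false(idx$representative)                       # CR% = 50 fails
})

test_that("indices ignore accession and trait order", {
  fx <- small_fixture(seed = 6, miss = 0)
  ec <- fx$truth$complete
  set.seed(4)
  cc_ids <- sample(ec$ids, 25)
  a <- suppressWarnings(five_indices(ec, cc_ids))
  ec_shuffled <- subset_accessions(ec, sample(ec$ids))
  ec_shuffled <- subset_traits(ec_shuffled, sample(trait_names(ec)))
  b <- suppressWarnings(five_indices(ec_shuffled, rev(cc_ids)))
  for (f in c("MD_pct", "VD_pct", "CR_pct", "VR_pct"))
    expect_equal(a[[f]], b[[f]])
})

test_that("zero-denominator traits are excluded with a warning", {
  ec <- trait_table(data.frame(t = c(-1, 0, 1), u = c(1, 2, 3)),
                    list(trait_schema("t", "quantitative"),
                         trait_schema("u", "quantitative")),
                    ids = paste0("A", 1:3))
  w <- capture_warnings(idx <- five_indices(ec, c("A1", "A3")))
  expect_true(any(grepl("MD%", w, fixed = TRUE)))
  expect_false(is.na(idx$CR_pct))
})
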
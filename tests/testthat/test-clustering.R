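test_that("mixed encoding follows the stated scaling conventions", {
  tbl <- trait_table(
    data.frame(h = c(1, 2, 3, 4), c = c("a", "a", "b", "b")),
    list(trait_schema("h", "quantitative"),
         trait_schema("c", "qualitative", categories = c("a", "b"))))
  enc <- encode_mixed(tbl)
  expect_equal(mean(enc$X[, 1]), 0)
  expect_equal(sd(enc$X[, 1]), 1)
  # category mismatch contributes squared distance exactly 1
  d2 <- sum((enc$X[1, enc$trait_of_col == 2] -
             enc$X[3, enc$trait_of_col == 2])^2)
  expect_equal(d2, 1)
  # the column map recovers every trait's columns
  expect_identical(enc$names[enc$trait_of_col], c("h", "c", "c"))
  expect_error(encode_mixed(toy_table()), "fully observed")
})

test_that("well-separated blobs are recovered exactly", {
  for (s in 1:5) {
    set.seed(s)
    X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 8), 20))
    lab <- rep(1:2, each = 20)
    fit <- weighted_kmeans(X, 2, nstart = 10, seed = s)
    expect_equal(ari(fit$assignments, lab), 1)
  }
})

test_that("variance explained hits its definitional limits", {
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2)
  expect_equal(weighted_kmeans(X, 1, nstart = 2, seed = 1)$variance_explained, 0)
  fit_n <- weighted_kmeans(X, 20, nstart = 2, seed = 1)
  expect_equal(fit_n$variance_explained, 1)
})

test_that("the objective decreases monotonically within a run", {
  fx <- small_fixture(seed = 9, miss = 0)
  fit <- weighted_kmeans(encode_mixed(fx$truth$complete), 4, nstart = 5,
                         seed = 2)
  expect_true(all(diff(fit$objective_trace) <= 1e-8))
})

test_that("large lambda recovers standard k-means", {
  set.seed(11)
  X <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 6), 30))
  fit <- weighted_kmeans(X, 2, lambda = 1e6, nstart = 10, seed = 4)
  km <- kmeans(X, 2, nstart = 10)
  expect_equal(ari(fit$assignments, km$cluster), 1)
  expect_true(all(abs(fit$trait_weights - 0.5) < 1e-3))
})

test_that("row permutation changes nothing but the labels", {
  fx <- small_fixture(seed = 13, miss = 0)
  enc <- encode_mixed(fx$truth$complete)
  fit1 <- weighted_kmeans(enc, 3, nstart = 20, seed = 5)
  set.seed(1)
  perm <- sample(nrow(enc$X))
  enc2 <- enc
  enc2$X <- enc$X[perm, ]
  enc2$ids <- enc$ids[perm]
  fit2 <- weighted_kmeans(enc2, 3, nstart = 20, seed = 5)
  expect_equal(ari(fit1$assignments[perm], fit2$assignments), 1)
})

test_that("select_k finds a planted structure and records rules", {
  # Nei > 0.8 requires at least five clusters, so the smallest recoverable
  # planted structure under the published criteria has k >= 5
  cfg <- germplasm_config(n_accessions = 91, n_quant = 6, n_qual = 4,
                          cluster_sizes = c(13, 13, 13, 13, 13, 13, 13),
                          latent_dim = 6, cluster_separation = 4,
                          noise_sd = 1.3, missing_rates = rep(0, 10))
  tr <- simulate_germplasm(cfg, seed = 17)
  sel <- select_k(tr$complete, k_range = 2:9, nstart = 15, seed = 3)
  expect_equal(sel$best$k, 7)
  expect_equal(ari(sel$best$assignments, tr$labels), 1)
  expect_true(all(c("pass_H", "pass_Nei", "pass_VE") %in% names(sel$report)))

  # a single blob satisfies nothing; the fallback rule fires
  set.seed(2)
  X <- matrix(rnorm(200), 100, 2)
  one <- trait_table(data.frame(a = X[, 1], b = X[, 2]),
                     list(trait_schema("a", "quantitative"),
                          trait_schema("b", "quantitative")))
  sel2 <- select_k(one, k_range = 2:5, nstart = 5, seed = 4)
  expect_match(sel2$rule, "no k satisfied")
})

test_that("reference collection cluster sizes pass the optimality criteria", {
  sizes <- c(40, 29, 1, 17, 23, 45, 45)
  expect_gt(shannon_weaver(sizes), 0.90)
  expect_gt(nei_index(sizes), 0.80)
})

test_that("1-D per-trait clustering matches planted and exhaustive truth", {
  set.seed(8)
  v <- c(rnorm(40, 0, 0.5), rnorm(40, 10, 0.5))
  res <- per_trait_clusters(v)
  # the evenness criterion favors refining the two modes; the found
  # classes must nest cleanly inside the planted separation
  expect_gte(res$k, 2)
  tab <- table(res$labels, rep(1:2, each = 40))
  expect_true(all(rowSums(tab > 0) == 1))

  expect_equal(per_trait_clusters(rep(3, 10))$k, 1)
  expect_equal(per_trait_clusters(c(2, 7, 2, 7))$labels, c(1, 2, 1, 2))

  # {1,1,2,2,9,9}: compare against exhaustive search over contiguous
  # partitions of the sorted values, applying the same selection criteria
  v <- c(1, 1, 2, 2, 9, 9)
  res <- per_trait_clusters(v)
  oracle_1d <- function(values, k_max = 3) {
    x <- as.numeric(scale(sort(values)))
    n <- length(x)
    tss <- sum((x - mean(x))^2)
    per_k <- lapply(2:k_max, function(k) {
      best_wss <- Inf; best_sizes <- NULL
      for (cu in utils::combn(n - 1, k - 1, simplify = FALSE)) {
        lab <- findInterval(seq_len(n), c(1, cu + 1))
        wss <- sum((x - ave(x, lab))^2)
        if (wss < best_wss) { best_wss <- wss; best_sizes <- tabulate(lab, k) }
      }
      ve <- 1 - best_wss / tss
      c(k = k, pass = (shannon_weaver(best_sizes) > 0.9) +
          (nei_index(best_sizes) > 0.8) + (ve > 0.75), ve = ve)
    })
    tab <- do.call(rbind, per_k)
    full <- which(tab[, "pass"] == 3)
    if (length(full)) return(tab[full[1], "k"])
    cand <- which(tab[, "pass"] == max(tab[, "pass"]))
    unname(tab[cand[which.max(tab[cand, "ve"])], "k"])
  }
  expect_equal(res$k, oracle_1d(v))
})
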
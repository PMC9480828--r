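test_that("rhat matches hand-evaluated cases and conventions", {
  # identical non-constant chains: B = 0, so the formula gives sqrt((L-1)/L)
  expect_equal(rhat(cbind(c(1, 2, 3), c(1, 2, 3))), sqrt(2 / 3))
  expect_equal(rhat(cbind(c(0, 0, 0, 0), c(10, 10, 10, 10))), Inf)
  # chains (1,2,1,2) and (2,1,2,1): W = 1/3, B = 0
  expect_equal(rhat(cbind(c(1, 2, 1, 2), c(2, 1, 2, 1))), sqrt(3 / 4))
  # direct evaluation of the formula on arbitrary chains
  tr <- cbind(c(1, 3, 2, 5), c(2, 4, 4, 6), c(0, 1, 2, 1))
  L <- nrow(tr)
  W <- mean(apply(tr, 2, var))
  B <- L * var(colMeans(tr))
  expect_equal(rhat(tr), sqrt(((L - 1) / L * W + B / L) / W))
  expect_error(rhat(cbind(1, 2)), ">= 2 chains")
})

test_that("rhat is invariant to permuting the chains", {
  set.seed(42)
  tr <- matrix(rnorm(40), 10, 4)
  expect_equal(rhat(tr), rhat(tr[, c(3, 1, 4, 2)]))
})

test_that("a fully observed table passes through imputation untouched", {
  fx <- small_fixture(seed = 2, miss = 0)
  cfg <- imputation_config(stage1_iters = 2, stage2_iters = 2)
  mi <- impute_traits(fx$truth$complete, cfg, seed = 1)
  for (m in mi$completed)
    expect_identical(m$values, fx$truth$complete$values)
  expect_true(all(mi$convergence$converged))
  pooled <- pool_imputations(mi, fx$truth$complete)
  expect_identical(pooled$values, fx$truth$complete$values)
})

test_that("a duplicated predictor pins the imputation to its nearest donor", {
  # trait B duplicates trait A; B's one missing cell sits at an extreme A
  # value whose unique nearest donor (by fitted mean) is the largest
  # observed case, so every chain must impute that donor's value
  a <- c(0, 1, 2, 3, 4, 100)
  b <- a; b[6] <- NA
  tbl <- trait_table(data.frame(A = a, B = b),
                     list(trait_schema("A", "quantitative"),
                          trait_schema("B", "quantitative")))
  cfg <- imputation_config(n_chains = 2, stage1_iters = 3, stage2_iters = 2,
                           pmm_donors = 1)
  mi <- suppressWarnings(impute_traits(tbl, cfg, seed = 3))
  for (m in mi$completed) expect_equal(m$values$B[6], 4)
})

test_that("observed cells are preserved bit-exactly in members and pool", {
  fx <- small_fixture(seed = 7, miss = 0.25)
  cfg <- imputation_config(stage1_iters = 4, stage2_iters = 2)
  mi <- suppressWarnings(impute_traits(fx$table, cfg, seed = 5))
  mask <- missing_mask(fx$table)
  pooled <- pool_imputations(mi, fx$table)
  for (j in seq_len(n_traits(fx$table))) {
    obs <- !mask[, j]
    for (m in mi$completed)
      expect_identical(m$values[[j]][obs], fx$table$values[[j]][obs])
    expect_identical(pooled$values[[j]][obs], fx$table$values[[j]][obs])
  }
  expect_identical(unname(pooled$imputed), unname(mask))
})

test_that("pooling takes means and majority votes with the stated ties", {
  schema <- list(trait_schema("q", "quantitative"),
                 trait_schema("c", "qualitative", categories = c("a", "b")))
  original <- trait_table(data.frame(q = c(1, NA), c = c(NA, "b")), schema)
  mk <- function(qv, cv)
    trait_table(data.frame(q = c(1, qv), c = c(cv, "b")), schema)
  members <- list(mk(4, "a"), mk(6, "a"), mk(4, "b"), mk(6, "b"))
  pooled <- pool_imputations(members, original)
  expect_equal(pooled$values$q[2], 5)
  # 2-2 vote; observed marginal has only "b", so the tie goes to "b"
  expect_identical(pooled$values$c[1], "b")
  # with equal observed marginals the schema category order decides
  original2 <- trait_table(data.frame(q = c(1, 1, NA), c = c(NA, "a", "b")),
                           schema)
  mk2 <- function(cv) trait_table(
    data.frame(q = c(1, 1, 1), c = c(cv, "a", "b")), schema)
  pooled2 <- pool_imputations(list(mk2("a"), mk2("b")), original2)
  expect_identical(pooled2$values$c[1], "a")
})

test_that("traits with no observed values are refused", {
  tbl <- trait_table(data.frame(A = c(1, 2, 3), B = NA_real_),
                     list(trait_schema("A", "quantitative"),
                          trait_schema("B", "quantitative")))
  expect_error(impute_traits(tbl, imputation_config()), "no observed values")
})

test_that("imputation beats marginal baselines on a small MAR fixture", {
  wins_rmse <- wins_acc <- 0
  for (s in 1:4) {
    fx <- small_fixture(seed = 100 + s, miss = 0.25)
    cfg <- imputation_config(stage1_iters = 8, stage2_iters = 3)
    mi <- suppressWarnings(impute_traits(fx$table, cfg, seed = s))
    pooled <- pool_imputations(mi, fx$table)
    mask <- missing_mask(fx$table)
    truth <- fx$truth$complete
    rq <- rb <- aq <- ab <- c()
    for (j in seq_len(n_traits(fx$table))) {
      mis <- mask[, j]
      if (!any(mis)) next
      tv <- truth$values[[j]][mis]
      pv <- pooled$values[[j]][mis]
      if (fx$table$schema[[j]]$kind == "quantitative") {
        rq <- c(rq, (pv - tv)^2)
        rb <- c(rb, (mean(fx$table$values[[j]], na.rm = TRUE) - tv)^2)
      } else {
        mode_v <- names(which.max(table(fx$table$values[[j]])))
        aq <- c(aq, pv == tv)
        ab <- c(ab, mode_v == tv)
      }
    }
    wins_rmse <- wins_rmse + (mean(rq) < mean(rb))
    wins_acc <- wins_acc + (mean(aq) >= mean(ab))
  }
  expect_gte(wins_rmse, 3)
  expect_gte(wins_acc, 3)
})

test_that("the multinomial Newton fit matches the reference optimizer", {
  skip_if_not_installed("nnet")
  set.seed(31)
  n <- 150; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  b <- matrix(rnorm(2 * (p + 1), sd = 0.8), 2)
  eta <- cbind(cbind(1, X) %*% t(b), 0)
  y <- factor(apply(exp(eta) / rowSums(exp(eta)), 1,
                    function(pr) sample(3, 1, prob = pr)))
  rw <- runif(n, 0.5, 1.5)
  Y <- matrix(0, n, 2)
  for (k in 1:2) Y[, k] <- as.numeric(y == k)
  pen <- diag(1e-8, p + 1)
  B <- germcore:::mlogit_fit(cbind(1, X), Y, rw, pen,
                             matrix(0, 2, p + 1), maxit = 50)
  ref <- nnet::multinom(relevel(y, ref = "3") ~ X, weights = rw,
                        trace = FALSE, maxit = 300, reltol = 1e-13)
  expect_equal(unname(B), unname(coef(ref)), tolerance = 1e-3)
})
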
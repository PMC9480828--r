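#' Configure the synthetic germplasm generator
#'
#' The generator draws accessions from a small number of latent phenotypic
#' clusters. Each accession gets a latent factor vector (cluster center plus
#' unit Gaussian scatter); quantitative traits are linear loadings on the
#' factors plus noise, and qualitative traits are latent scores cut at fixed
#' thresholds into categories. Traits load primarily on one factor each
#' (round-robin), which yields blocks of strongly correlated traits and weak
#' background correlation between blocks -- the correlation mix typical of
#' multi-trait germplasm characterization data.
#'
#' @param n_accessions Number of accessions.
#' @param n_quant,n_qual Numbers of quantitative and qualitative traits.
#' @param cluster_sizes Integer vector of latent cluster sizes; must sum to
#'   `n_accessions`. A cluster of size 1 is generated as an extreme outlier
#'   accession (its center is pushed away from the origin), emulating a
#'   collection that holds one phenotypically unique variety.
#' @param latent_dim Number of latent factors.
#' @param trait_loading Primary loading of a trait on its own factor.
#' @param cross_loading Standard deviation of the small loadings on all
#'   other factors.
#' @param cluster_separation Standard deviation of cluster centers in latent
#'   space; larger values separate the clusters more cleanly.
#' @param noise_sd Trait-specific noise standard deviation.
#' @param categories_per_qual Integer vector (recycled) of category counts
#'   for the qualitative traits.
#' @param missing_rates Numeric vector of per-trait target missing rates in
#'   \[0, 1), length `n_quant + n_qual`, in trait order (quantitative traits
#'   first). At least one quantitative trait must have rate 0 so that a
#'   missing-at-random driver remains observable.
#' @param mar_strength Slope of the logistic missingness mechanism on the
#'   standardized driver trait; 0 gives missing completely at random.
#' @param mar_driver Name or index of the fully observed quantitative trait
#'   that drives missingness (default: first quantitative trait with target
#'   rate 0).
#' @return A `germplasm_config` list.
#' @export
germplasm_config <- function(n_accessions = 200,
                             n_quant = 21, n_qual = 25,
                             cluster_sizes = c(40, 29, 1, 17, 23, 45, 45),
                             latent_dim = 6,
                             trait_loading = 1,
                             cross_loading = 0.05,
                             cluster_separation = 3.7,
                             noise_sd = 0.6,
                             categories_per_qual = c(3, 2, 4, 3, 5),
                             missing_rates = rep(0, n_quant + n_qual),
                             mar_strength = 1,
                             mar_driver = NULL) {
  stopifnot(n_accessions >= 2, n_quant >= 1, n_qual >= 0,
            all(cluster_sizes >= 1),
            sum(cluster_sizes) == n_accessions,
            latent_dim >= 1, trait_loading > 0, cluster_separation >= 0,
            noise_sd > 0, all(categories_per_qual >= 2))
  m <- n_quant + n_qual
  if (length(missing_rates) != m)
    stop("missing_rates must have length n_quant + n_qual = ", m)
  if (any(missing_rates < 0 | missing_rates >= 1))
    stop("missing_rates must lie in [0, 1)")
  if (!any(missing_rates[seq_len(n_quant)] == 0))
    stop("at least one quantitative trait must be fully observed ",
         "(the MAR driver)")
  structure(list(n_accessions = n_accessions, n_quant = n_quant,
                 n_qual = n_qual, cluster_sizes = as.integer(cluster_sizes),
                 latent_dim = latent_dim, trait_loading = trait_loading,
                 cross_loading = cross_loading,
                 cluster_separation = cluster_separation,
                 noise_sd = noise_sd,
                 categories_per_qual = categories_per_qual,
                 missing_rates = missing_rates,
                 mar_strength = mar_strength, mar_driver = mar_driver),
            class = "germplasm_config")
}

generator_trait_names <- function(config) {
  c(sprintf("qt%02d", seq_len(config$n_quant)),
    if (config$n_qual) sprintf("ql%02d", seq_len(config$n_qual)))
}

#' Simulate a complete germplasm population
#'
#' Draws a fully observed mixed-type phenotype table with known latent
#' cluster labels. Deterministic given `seed`.
#'
#' @param config A [germplasm_config()].
#' @param seed Integer seed.
#' @return An object of class `germ_truth`: a list with `complete` (a fully
#'   observed [trait_table()]), `labels` (integer cluster label per
#'   accession) and `config`.
#' @export
simulate_germplasm <- function(config, seed = 1) {
  stopifnot(inherits(config, "germplasm_config"))
  with_seed(seed, {
    n <- config$n_accessions
    d <- config$latent_dim
    ncl <- length(config$cluster_sizes)
    labels <- rep(seq_len(ncl), config$cluster_sizes)

    centers <- matrix(stats::rnorm(ncl * d, sd = config$cluster_separation),
                      ncl, d)
    # orthogonalize the center configuration under size weighting so that
    # each latent dimension carries between-cluster variance of exactly
    # cluster_separation^2 and no spurious cross-factor trait correlation
    # arises from a handful of random center positions
    if (ncl > d) {
      w <- config$cluster_sizes / n
      A <- sweep(centers, 2L, colSums(centers * w)) * sqrt(w)
      Q <- qr.Q(qr(A))[, seq_len(d), drop = FALSE]
      centers <- sweep(Q * config$cluster_separation, 1L, sqrt(w), "/")
    }
    singleton <- config$cluster_sizes == 1L
    if (any(singleton)) {
      # outlier accession: push its center well outside the main cloud
      centers[singleton, ] <- 4 * config$cluster_separation *
        sign(centers[singleton, , drop = FALSE])
    }
    Z <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * d), n, d)

    m <- config$n_quant + config$n_qual
    primary <- ((seq_len(m) - 1L) %% d) + 1L
    Lambda <- matrix(stats::rnorm(m * d, sd = config$cross_loading), m, d)
    Lambda[cbind(seq_len(m), primary)] <- config$trait_loading
    scores <- Z %*% t(Lambda) +
      matrix(stats::rnorm(n * m, sd = config$noise_sd), n, m)

    nm <- generator_trait_names(config)
    ncat <- rep_len(config$categories_per_qual, config$n_qual)
    schema <- vector("list", m)
    values <- vector("list", m)
    for (j in seq_len(config$n_quant)) {
      schema[[j]] <- trait_schema(nm[j], "quantitative")
      # positive measurement scale, as for real phenotypes (lengths,
      # weights); affine, so correlation and cluster structure are
      # untouched but mean- and CV-based indices stay well defined
      values[[j]] <- round(100 + 5 * scores[, j], 4)
    }
    for (jj in seq_len(config$n_qual)) {
      j <- config$n_quant + jj
      K <- ncat[jj]
      cats <- sprintf("c%d", seq_len(K))
      # uneven but fixed category proportions, cut at realized quantiles
      w <- stats::rgamma(K, shape = 5)
      cuts <- stats::quantile(scores[, j], probs = cumsum(w / sum(w))[-K],
                              names = FALSE)
      lab <- cats[findInterval(scores[, j], cuts) + 1L]
      schema[[j]] <- trait_schema(nm[j], "qualitative", categories = cats)
      values[[j]] <- lab
    }
    names(values) <- nm
    tbl <- trait_table(as.data.frame(values, check.names = FALSE), schema,
                       ids = sprintf("ACC%04d", seq_len(n)))
    structure(list(complete = tbl, labels = labels, config = config),
              class = "germ_truth")
  })
}

#' @export
print.germ_truth <- function(x, ...) {
  cat("<germ_truth> ", n_accessions(x$complete), " accessions, ",
      n_traits(x$complete), " traits, ",
      length(x$config$cluster_sizes), " latent clusters\n", sep = "")
  invisible(x)
}

#' Mask cells under a missing-at-random mechanism
#'
#' For each trait with a positive target rate, exactly
#' `round(n * rate)` cells are masked. Cells are chosen by weighted sampling
#' without replacement with weights `plogis(a + mar_strength * z)`, where
#' `z` is the accession's standardized value on the designated always
#' observed driver trait and the intercept `a` is calibrated so the mean
#' masking probability equals the target rate. The mechanism depends only on
#' the (observed) driver, never on the masked value itself, so the
#' missingness is MAR by construction. With `mar_strength = 0` the
#' mechanism reduces to MCAR.
#'
#' @param truth A `germ_truth` from [simulate_germplasm()].
#' @param seed Integer seed.
#' @return A [trait_table()] with missing cells; the truth object retains
#'   every masked value for scoring.
#' @export
apply_mar <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "germ_truth"))
  config <- truth$config
  tbl <- truth$complete
  rates <- config$missing_rates
  nm <- schema_names(tbl$schema)
  drivers <- config$mar_driver
  if (is.null(drivers)) {
    cand <- which(schema_kinds(tbl$schema) == "quantitative" & rates == 0)
    drivers <- nm[cand]
  }
  if (is.numeric(drivers)) drivers <- nm[drivers]
  if (any(rates[match(drivers, nm)] != 0))
    stop("MAR driver trait(s) must be fully observed")
  # one driver per block of correlated traits: a trait's driver is keyed to
  # its primary latent factor, so missingness does not pile onto the same
  # accessions across all traits
  d <- config$latent_dim
  primary <- ((seq_along(nm) - 1L) %% d) + 1L
  driver_of <- drivers[((primary - 1L) %% length(drivers)) + 1L]
  Zs <- vapply(drivers, function(dr) as.numeric(scale(tbl$values[[dr]])),
               numeric(n_accessions(tbl)))
  n <- n_accessions(tbl)
  values <- tbl$values
  with_seed(seed, {
    for (j in seq_along(nm)) {
      r <- rates[j]
      if (r == 0) next
      n_miss <- round(n * r)
      if (n_miss == 0) next
      z <- Zs[, driver_of[j]]
      a <- mar_intercept(z, config$mar_strength, r)
      p <- stats::plogis(a + config$mar_strength * z)
      idx <- sample.int(n, n_miss, prob = p)
      values[idx, j] <- NA
    }
  })
  trait_table(values, tbl$schema, ids = tbl$ids)
}

# calibrate the logistic intercept so mean masking probability hits `rate`
mar_intercept <- function(z, slope, rate) {
  if (slope == 0) return(stats::qlogis(rate))
  f <- function(a) mean(stats::plogis(a + slope * z)) - rate
  stats::uniroot(f, lower = -30, upper = 30)$root
}

#' Append exact duplicate accessions
#'
#' Randomly chosen rows (values and missingness pattern alike) are copied
#' under fresh accession ids and appended, emulating redundant entries in a
#' genebank catalogue. Useful for exercising [dedupe_accessions()].
#'
#' @param table A [trait_table()].
#' @param n_duplicates Number of duplicate rows to plant.
#' @param seed Integer seed.
#' @return A [trait_table()] with `n_duplicates` extra rows.
#' @export
plant_duplicates <- function(table, n_duplicates, seed = 1) {
  if (n_duplicates == 0) return(table)
  with_seed(seed, {
    src <- sample(n_accessions(table), n_duplicates, replace = TRUE)
    values <- rbind(table$values, table$values[src, , drop = FALSE])
    ids <- c(table$ids, sprintf("DUP%04d", seq_len(n_duplicates)))
    trait_table(values, table$schema, ids = ids)
  })
}

#' Study-scale germplasm fixture
#'
#' A ready-made synthetic collection emulating a characterized vegetable
#' soybean (edamame) genebank: 200 accessions, 21 quantitative plus 25
#' qualitative traits, 7 latent clusters with uneven sizes
#' (40, 29, 1, 17, 23, 45, 45 -- including one outlier variety), and
#' per-trait MAR missingness in four strata: 6 traits fully observed, 23
#' with low rates (0.5-26.5%), 8 moderate (49.5-52.5%) and 9 high
#' (64.5-78.5%), giving an overall missing rate near 30%.
#'
#' @param seed Integer seed.
#' @param n_duplicates Exact duplicate accessions to append (0 = none).
#' @return A list with `table` (the masked [trait_table()]), `truth`
#'   (the `germ_truth`) and `config`.
#' @export
edamame_fixture <- function(seed = 1, n_duplicates = 0) {
  config <- edamame_config()
  truth <- simulate_germplasm(config, seed = seed)
  tbl <- apply_mar(truth, seed = seed + 1L)
  if (n_duplicates > 0)
    tbl <- plant_duplicates(tbl, n_duplicates, seed = seed + 2L)
  list(table = tbl, truth = truth, config = config)
}

#' @rdname edamame_fixture
#' @export
edamame_config <- function(noise_sd = 0.6) {
  n_quant <- 21; n_qual <- 25
  m <- n_quant + n_qual
  rates <- numeric(m)
  # 6 fully observed traits: qt01-qt03 (qt01 is the MAR driver), ql01-ql03;
  # the remaining 40 are interleaved so every stratum spans both kinds
  quant_t <- sprintf("qt%02d", 4:21)
  qual_t <- sprintf("ql%02d", 4:25)
  target <- c(quant_t, qual_t)[order(c(seq(1, 40, length.out = 18),
                                       seq(1.5, 40.5, length.out = 22)))]
  strata_rates <- c(seq(0.005, 0.265, length.out = 23),
                    seq(0.495, 0.525, length.out = 8),
                    seq(0.645, 0.785, length.out = 9))
  nm <- c(sprintf("qt%02d", 1:21), sprintf("ql%02d", 1:25))
  rates[match(target, nm)] <- strata_rates
  germplasm_config(n_accessions = 200, n_quant = n_quant, n_qual = n_qual,
                   noise_sd = noise_sd,
                   cluster_sizes = c(40, 29, 1, 17, 23, 45, 45),
                   missing_rates = rates)
}
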
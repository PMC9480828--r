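# Small building blocks shared across the test files. Everything is built
# in code; no fixture files.

toy_schema <- function() {
  list(trait_schema("height", "quantitative", unit = "cm"),
       trait_schema("color", "qualitative",
                    categories = c("green", "yellow", "purple")))
}

toy_table <- function() {
  trait_table(
    data.frame(height = c(10.5, 12, NA, 9, 11),
               color = c("green", NA, "yellow", "green", "purple")),
    toy_schema(),
    ids = paste0("A", 1:5))
}

# a small correlated mixed-type population with planted missingness,
# cheap enough for per-test imputation runs
small_fixture <- function(seed = 1, n = 80, miss = 0.2) {
  cfg <- germplasm_config(
    n_accessions = n, n_quant = 4, n_qual = 4,
    cluster_sizes = c(ceiling(n / 2), floor(n / 2)),
    latent_dim = 2, cluster_separation = 2, noise_sd = 0.8,
    missing_rates = c(0, 0, rep(miss, 6)), mar_strength = 1)
  truth <- simulate_germplasm(cfg, seed = seed)
  list(truth = truth, table = apply_mar(truth, seed = seed + 1),
       config = cfg)
}

# adjusted Rand index (mclust is the usual oracle; fall back to 1-checks)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# independent loop-based recomputation of the diversity indices
oracle_shannon <- function(counts) {
  counts <- counts[counts > 0]
  S <- length(counts)
  if (S == 1) return(0)
  tot <- sum(counts)
  h <- 0
  for (c in counts) {
    p <- c / tot
    h <- h - p * log(p)
  }
  h / log(S)
}

oracle_nei <- function(counts) {
  counts <- counts[counts > 0]
  tot <- sum(counts)
  s <- 0
  for (c in counts) s <- s + (c / tot)^2
  1 - s
}

# exhaustive minimum set cover over a classification grid (tiny inputs)
oracle_min_cover <- function(grid) {
  covers <- lapply(seq_along(grid$ids), function(i) {
    r <- grid$classes[i, ]
    obs <- !is.na(r)
    paste(colnames(grid$classes)[obs], r[obs], sep = "\r")
  })
  universe <- unique(unlist(covers))
  n <- length(covers)
  for (size in seq_len(n)) {
    sets <- utils::combn(n, size, simplify = FALSE)
    for (s in sets) {
      if (all(universe %in% unique(unlist(covers[s])))) return(size)
    }
  }
  n
}
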
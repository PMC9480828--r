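#' Configure the end-to-end analysis pipeline
#'
#' @param imputation An [imputation_config()].
#' @param k_range Candidate cluster numbers for structure analysis.
#' @param lambda Entropy-regularization parameter for clustering.
#' @param nstart Clustering restarts.
#' @param alpha Significance level for the trait difference tests.
#' @param levene_B Bootstrap iterations for the Levene test.
#' @param coverage_min Verdict tolerance for "coverage close to 100".
#' @param branches Which branches to run: `"raw"` (selection straight from
#'   the observed, incomplete table) and/or `"imputed"` (impute, cluster,
#'   then select).
#' @param seed Master seed; every stochastic stage derives its own
#'   sub-seed from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(imputation = imputation_config(),
                            k_range = 2:15, lambda = 0.5, nstart = 100,
                            alpha = 0.05, levene_B = 1000,
                            coverage_min = 95,
                            branches = c("raw", "imputed"), seed = 1) {
  branches <- match.arg(branches, several.ok = TRUE)
  structure(list(imputation = imputation, k_range = k_range,
                 lambda = lambda, nstart = nstart, alpha = alpha,
                 levene_B = levene_B, coverage_min = coverage_min,
                 branches = branches, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full core-collection analysis
#'
#' Load -> preprocess (deduplicate accessions, drop invariant traits,
#' profile missingness) -> raw branch (classification grid and core
#' selection straight from the observed table) and imputed branch
#' (two-stage chained-equations imputation, pooling, weighted k-means
#' structure analysis, per-trait clustering, core selection) -> evaluation
#' (five indices, per-trait difference tests, per-trait diversity change).
#' Identical seed, config and input give an identical report.
#'
#' @param table A [trait_table()] (the entire collection as loaded).
#' @param config A [pipeline_config()].
#' @return An object of class `germcore_report`: a nested list with
#'   `preprocessing`, `missingness`, and per-branch results.
#' @export
run_pipeline <- function(table, config = pipeline_config()) {
  stopifnot(inherits(table, "trait_table"),
            inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 6)
  dd <- dedupe_accessions(table)
  di <- drop_invariant_traits(dd$table)
  ec_raw <- di$table
  report <- list(
    preprocessing = list(
      n_input_accessions = n_accessions(table),
      n_input_traits = n_traits(table),
      removed_accessions = dd$removed_ids,
      removed_traits = di$removed_traits,
      n_accessions = n_accessions(ec_raw),
      n_traits = n_traits(ec_raw)),
    missingness = missingness_profile(ec_raw),
    config = config)

  if ("raw" %in% config$branches) {
    grid_raw <- build_grid(ec_raw)
    core_raw <- select_core(grid_raw)
    cc_raw <- subset_accessions(ec_raw, core_raw$ids)
    report$raw <- list(
      core = core_raw,
      core_size = length(core_raw$ids),
      core_pct = 100 * length(core_raw$ids) / n_accessions(ec_raw),
      indices = suppressWarnings(
        five_indices(ec_raw, cc_raw, coverage_min = config$coverage_min)),
      tests = compare_traits(ec_raw, cc_raw, alpha = config$alpha,
                             B = config$levene_B, seed = seeds[1]))
  }

  if ("imputed" %in% config$branches) {
    mi <- impute_traits(ec_raw, config$imputation, seed = seeds[2])
    ec_impu <- pool_imputations(mi, ec_raw)
    sel <- select_k(ec_impu, k_range = config$k_range,
                    lambda = config$lambda, nstart = config$nstart,
                    seed = seeds[3])
    sizes <- tabulate(sel$best$assignments, sel$best$k)

    nm <- schema_names(ec_impu$schema)
    kinds <- schema_kinds(ec_impu$schema)
    quant_labels <- list()
    for (j in which(kinds == "quantitative")) {
      v <- ec_impu$values[[j]]
      quant_labels[[nm[j]]] <- stats::setNames(
        if (length(unique(v)) < 2L) rep(1L, length(v))
        else per_trait_clusters(v, seed = seeds[4])$labels,
        ec_impu$ids)
    }

    grid_impu <- build_grid(ec_impu)
    core_impu <- select_core(grid_impu)
    cc_impu <- subset_accessions(ec_impu, core_impu$ids)

    ec_div <- trait_diversity(ec_impu, quant_labels = quant_labels)
    cc_div <- trait_diversity(cc_impu, quant_labels = quant_labels)

    report$imputed <- list(
      convergence = mi$convergence,
      ec_impu = ec_impu,
      clustering = sel$best,
      k_report = sel$report,
      cluster_sizes = sizes,
      variance_explained = sel$best$variance_explained,
      H_prime = shannon_weaver(sizes),
      Nei = nei_index(sizes),
      core = core_impu,
      core_size = length(core_impu$ids),
      core_pct = 100 * length(core_impu$ids) / n_accessions(ec_impu),
      indices = suppressWarnings(
        five_indices(ec_impu, cc_impu, quant_labels = quant_labels,
                     coverage_min = config$coverage_min)),
      tests = compare_traits(ec_impu, cc_impu, alpha = config$alpha,
                             B = config$levene_B, seed = seeds[5]),
      diversity_change = diversity_change(ec_div, cc_div))
  }
  class(report) <- "germcore_report"
  report
}

#' @export
print.germcore_report <- function(x, ...) {
  cat("<germcore_report>\n")
  cat(sprintf("  collection: %d accessions x %d traits (overall missing %.1f%%)\n",
              x$preprocessing$n_accessions, x$preprocessing$n_traits,
              100 * x$missingness$overall))
  if (!is.null(x$raw))
    cat(sprintf("  raw branch: core of %d accessions (%.1f%%)\n",
                x$raw$core_size, x$raw$core_pct))
  if (!is.null(x$imputed))
    cat(sprintf(
      "  imputed branch: k = %d (VE %.1f%%, H' %.2f, Nei %.2f), core of %d accessions (%.1f%%)\n",
      x$imputed$clustering$k, 100 * x$imputed$variance_explained,
      x$imputed$H_prime, x$imputed$Nei, x$imputed$core_size,
      x$imputed$core_pct))
  invisible(x)
}

#' Impact of the missing-rate threshold on core selection
#'
#' Restricts the collection to traits whose missing rate is below each
#' threshold (the first threshold of 0 keeps only fully observed traits;
#' intermediate thresholds are exclusive; a threshold of 1 keeps all
#' traits), reruns the requested branches, and tabulates trait counts,
#' overall missing rates and core sizes per threshold.
#'
#' @param table A [trait_table()].
#' @param thresholds Missing-rate thresholds (defaults 0, 0.30, 0.65, 1).
#' @param config A [pipeline_config()].
#' @return A data.frame with one row per threshold.
#' @export
missingness_threshold_study <- function(table,
                                        thresholds = c(0, 0.30, 0.65, 1),
                                        config = pipeline_config()) {
  prof <- missingness_profile(table)
  rows <- lapply(thresholds, function(th) {
    keep <- if (th == 0) prof$per_trait == 0
            else if (th < 1) prof$per_trait < th
            else prof$per_trait <= 1
    out <- data.frame(threshold = th, n_traits = sum(keep),
                      overall_missing = NA_real_,
                      core_raw = NA_integer_, core_impu = NA_integer_)
    if (!any(keep)) return(out)
    sub <- subset_traits(table, names(prof$per_trait)[keep])
    out$overall_missing <- missingness_profile(sub)$overall
    if ("raw" %in% config$branches)
      out$core_raw <- length(select_core(build_grid(sub))$ids)
    if ("imputed" %in% config$branches) {
      if (out$overall_missing == 0) {
        out$core_impu <- length(select_core(build_grid(sub))$ids)
      } else {
        mi <- impute_traits(sub, config$imputation,
                            seed = config$seed + which(thresholds == th))
        sub_impu <- pool_imputations(mi, sub)
        out$core_impu <- length(select_core(build_grid(sub_impu))$ids)
      }
    }
    out
  })
  do.call(rbind, rows)
}
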
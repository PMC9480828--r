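#' Bootstrap Levene test for homogeneity of variances
#'
#' Uses the Brown-Forsythe statistic (one-way ANOVA F on absolute
#' deviations from the group medians), with a bootstrap null distribution
#' built by resampling both groups from the pooled sample after centering
#' each group at its own median. The p-value is the proportion of bootstrap
#' statistics at least as large as the observed one.
#'
#' @param x,y Numeric samples (at least 2 values each).
#' @param B Number of bootstrap iterations (1000 by default).
#' @param seed Integer seed.
#' @return A list with `p_value`, `statistic` and `B`.
#' @export
levene_bootstrap <- function(x, y, B = 1000, seed = 1) {
  x <- as.numeric(stats::na.omit(x)); y <- as.numeric(stats::na.omit(y))
  stopifnot(length(x) >= 2L, length(y) >= 2L, B >= 1)
  obs <- brown_forsythe_stat(x, y)
  if (!is.finite(obs) || obs == 0)
    return(list(p_value = 1, statistic = obs, B = B))
  pooled <- c(x - stats::median(x), y - stats::median(y))
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  p <- with_seed(seed, {
    idx <- matrix(sample.int(N, N * B, replace = TRUE), N, B)
    boot <- vapply(seq_len(B), function(b) {
      v <- pooled[idx[, b]]
      brown_forsythe_stat(v[seq_len(n1)], v[n1 + seq_len(n2)])
    }, numeric(1))
    mean(boot >= obs)
  })
  list(p_value = p, statistic = obs, B = B)
}

brown_forsythe_stat <- function(x, y) {
  dx <- abs(x - stats::median(x)); dy <- abs(y - stats::median(y))
  n1 <- length(dx); n2 <- length(dy); N <- n1 + n2
  gm <- (sum(dx) + sum(dy)) / N
  ssb <- n1 * (mean(dx) - gm)^2 + n2 * (mean(dy) - gm)^2
  ssw <- sum((dx - mean(dx))^2) + sum((dy - mean(dy))^2)
  if (ssw == 0) return(if (ssb == 0) 0 else Inf)
  (ssb / 1) / (ssw / (N - 2))
}

#' Per-trait difference tests between core and entire collection
#'
#' Quantitative traits: a bootstrap Levene test decides between Student's
#' t-test (equal variances) and Welch's t-test (unequal variances) on the
#' observed values. Qualitative traits: a chi-squared test of homogeneity
#' on the category counts; categories absent from both collections are
#' dropped, and categories with expected count below 1 are pooled (smallest
#' first) into an "other" class, recorded in the result. A qualitative
#' trait with a single observed category in both collections is skipped.
#'
#' @param ec,cc Two [trait_table()]s with matched schemas (typically the
#'   entire collection and its core).
#' @param alpha Significance level.
#' @param B Bootstrap iterations for the Levene test.
#' @param seed Integer seed.
#' @return A list with `tests` (per-trait data.frame: test used, Levene p,
#'   p-value, significance flag) and `significant_fraction`.
#' @export
compare_traits <- function(ec, cc, alpha = 0.05, B = 1000, seed = 1) {
  stopifnot(identical(schema_names(ec$schema), schema_names(cc$schema)))
  schema <- ec$schema
  seeds <- derive_seeds(seed, length(schema))
  rows <- lapply(seq_along(schema), function(j) {
    tr <- schema[[j]]
    x <- ec$values[[j]][!is.na(ec$values[[j]])]
    y <- cc$values[[j]][!is.na(cc$values[[j]])]
    out <- data.frame(trait = tr$name, kind = tr$kind, test = NA_character_,
                      levene_p = NA_real_, p_value = NA_real_,
                      significant = NA, pooled_categories = FALSE)
    if (tr$kind == "quantitative") {
      if (length(x) < 2L || length(y) < 2L ||
          (stats::sd(x) == 0 && stats::sd(y) == 0)) {
        out$test <- "skipped"; return(out)
      }
      lev <- levene_bootstrap(x, y, B = B, seed = seeds[j])
      equal_var <- lev$p_value >= alpha
      tt <- stats::t.test(x, y, var.equal = equal_var)
      out$test <- if (equal_var) "student_t" else "welch_t"
      out$levene_p <- lev$p_value
      out$p_value <- tt$p.value
    } else {
      cnt <- rbind(table(factor(x, levels = tr$categories)),
                   table(factor(y, levels = tr$categories)))
      cnt <- cnt[, colSums(cnt) > 0, drop = FALSE]
      if (ncol(cnt) < 2L) { out$test <- "skipped"; return(out) }
      pooled <- pool_small_expected(cnt)
      out$pooled_categories <- pooled$pooled
      if (ncol(pooled$counts) < 2L) { out$test <- "skipped"; return(out) }
      suppressWarnings(ct <- stats::chisq.test(pooled$counts,
                                               correct = FALSE))
      out$test <- "chi_squared"
      out$p_value <- ct$p.value
    }
    out$significant <- out$p_value < alpha
    out
  })
  tests <- do.call(rbind, rows)
  done <- !is.na(tests$p_value)
  list(tests = tests,
       significant_fraction = if (any(done))
         mean(tests$significant[done]) else NA_real_,
       alpha = alpha)
}

# pool categories whose expected count falls below 1, smallest first
pool_small_expected <- function(cnt) {
  pooled <- FALSE
  repeat {
    exp_cnt <- outer(rowSums(cnt), colSums(cnt)) / sum(cnt)
    bad <- which(apply(exp_cnt, 2L, min) < 1)
    if (!length(bad) || ncol(cnt) <= 2L) break
    ord <- order(colSums(cnt))
    merge_from <- ord[1L]
    merge_into <- ord[2L]
    cnt[, merge_into] <- cnt[, merge_into] + cnt[, merge_from]
    colnames(cnt)[merge_into] <- "other"
    cnt <- cnt[, -merge_from, drop = FALSE]
    pooled <- TRUE
  }
  list(counts = cnt, pooled = pooled)
}

#' Five representativeness indices of a core collection
#'
#' Over the quantitative traits:
#' `MD% = mean(|Me - Mc| / Mc) * 100` (means),
#' `VD% = mean(|Ve - Vc| / Vc) * 100` (variances, n-1 denominator),
#' `CR% = mean(Rc / Re) * 100` (ranges) and
#' `VR% = mean(CVc / CVe) * 100` (coefficients of variation), with
#' subscripts e/c for the entire/core collection. Over all traits,
#' `Coverage% = mean(Dc / De) * 100`, where D counts the trait's classes:
#' categories for qualitative traits and optimal 1-D cluster labels (from
#' [per_trait_clusters()] on the entire collection) for quantitative ones.
#' A trait whose index denominator is zero is excluded from that index
#' with a warning. The verdict deems the core representative when
#' `MD% <= 20`, `CR% > 80` and coverage is close to 100 (at least
#' `coverage_min`).
#'
#' @param ec A [trait_table()] for the entire collection.
#' @param cc A [trait_table()] for the core (or a vector of core accession
#'   ids to take from `ec`).
#' @param quant_labels Optional named list of per-accession class labels
#'   for the quantitative traits on `ec` (names = accession ids). Computed
#'   on the fly when `ec` is fully observed; with missing data, quantitative
#'   coverage is reported as `NA`.
#' @param coverage_min Verdict tolerance for "coverage close to 100".
#' @return An object of class `evaluation_indices`.
#' @export
five_indices <- function(ec, cc, quant_labels = NULL, coverage_min = 95) {
  if (!inherits(cc, "trait_table")) cc <- subset_accessions(ec, cc)
  stopifnot(identical(schema_names(ec$schema), schema_names(cc$schema)))
  schema <- ec$schema
  kinds <- schema_kinds(schema)
  nm <- schema_names(schema)
  quant <- which(kinds == "quantitative")

  if (is.null(quant_labels) && !any(is.na(ec$values))) {
    quant_labels <- list()
    for (j in quant) {
      v <- ec$values[[j]]
      quant_labels[[nm[j]]] <- if (length(unique(v)) < 2L)
        stats::setNames(rep(1L, length(v)), ec$ids)
      else stats::setNames(per_trait_clusters(v)$labels, ec$ids)
    }
  }

  stat <- function(v) {
    v <- v[!is.na(v)]
    c(M = mean(v), V = stats::var(v), R = max(v) - min(v),
      CV = stats::sd(v) / mean(v))
  }
  se <- vapply(quant, function(j) stat(ec$values[[j]]), numeric(4))
  sc <- vapply(quant, function(j) stat(cc$values[[j]]), numeric(4))

  ratio_mean <- function(num, den, label) {
    ok <- is.finite(num) & is.finite(den) & den != 0
    if (!all(ok))
      warning("trait(s) excluded from ", label, ": ",
              paste(nm[quant][!ok], collapse = ", "))
    if (!any(ok)) return(NA_real_)
    mean(num[ok] / den[ok]) * 100
  }
  md <- ratio_mean(abs(se["M", ] - sc["M", ]), sc["M", ], "MD%")
  vd <- ratio_mean(abs(se["V", ] - sc["V", ]), sc["V", ], "VD%")
  cr <- ratio_mean(sc["R", ], se["R", ], "CR%")
  vr <- ratio_mean(sc["CV", ], se["CV", ], "VR%")

  cov_t <- vapply(seq_along(nm), function(j) {
    tr <- schema[[j]]
    if (tr$kind == "qualitative") {
      de <- unique(stats::na.omit(ec$values[[j]]))
      dc <- unique(stats::na.omit(cc$values[[j]]))
      length(intersect(dc, de)) / length(de)
    } else {
      lab <- quant_labels[[tr$name]]
      if (is.null(lab)) return(NA_real_)
      de <- unique(lab[ec$ids])
      dc <- unique(lab[cc$ids])
      length(intersect(dc, de)) / length(de)
    }
  }, numeric(1))
  cov_quant <- 100 * mean(cov_t[kinds == "quantitative"])
  cov_qual <- if (any(kinds == "qualitative"))
    100 * mean(cov_t[kinds == "qualitative"]) else NA_real_
  coverage <- 100 * mean(cov_t, na.rm = FALSE)

  verdict <- !is.na(md) && !is.na(cr) && !is.na(coverage) &&
    md <= 20 && cr > 80 && coverage >= coverage_min
  structure(list(MD_pct = md, VD_pct = vd, CR_pct = cr, VR_pct = vr,
                 coverage_pct = coverage,
                 coverage_quant_pct = cov_quant,
                 coverage_qual_pct = cov_qual,
                 m_quant = length(quant), m_total = length(nm),
                 representative = verdict, coverage_min = coverage_min),
            class = "evaluation_indices")
}

#' @export
print.evaluation_indices <- function(x, ...) {
  cat(sprintf(
    "<evaluation_indices> MD%% %.2f | VD%% %.2f | CR%% %.2f | VR%% %.2f | Coverage%% %.2f\n",
    x$MD_pct, x$VD_pct, x$CR_pct, x$VR_pct, x$coverage_pct))
  cat("  representative:", x$representative, "\n")
  invisible(x)
}
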
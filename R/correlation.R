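#' Correlation between two mixed-type trait columns
#'
#' Method dispatch follows standard practice for mixed phenotype data:
#' two quantitative traits use Pearson's r; two qualitative traits use
#' Spearman's rho on the category codes (schema order); a dichotomous
#' qualitative trait against a quantitative trait uses the point-biserial
#' coefficient (Pearson on the 0/1 coding); a polytomous qualitative trait
#' against a quantitative trait uses Spearman's rho between the category
#' codes and the quantitative trait's optimal 1-D cluster labels (see
#' [per_trait_clusters()]). Only pairwise-complete cases enter; a pair with
#' fewer than 3 complete cases or zero variance in either column is
#' reported as unavailable.
#'
#' @param x,y Trait columns (numeric or character vectors).
#' @param kind_x,kind_y `"quantitative"` or `"qualitative"`.
#' @param categories_x,categories_y Category labels for qualitative columns.
#' @param quant_labels_x,quant_labels_y Optional per-accession cluster
#'   labels for a quantitative column, used in the polytomous-qualitative
#'   vs quantitative case; if absent they are computed on the fly.
#' @return A list with `r`, `p`, `method`, `n_pairs` and `available`.
#' @export
correlate_pair <- function(x, y, kind_x, kind_y,
                           categories_x = NULL, categories_y = NULL,
                           quant_labels_x = NULL, quant_labels_y = NULL) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  unavailable <- function(method)
    list(r = NA_real_, p = NA_real_, method = method, n_pairs = n,
         available = FALSE)
  code <- function(v, cats) as.numeric(match(v, cats))

  if (kind_x == "quantitative" && kind_y == "quantitative") {
    xx <- as.numeric(x)[ok]; yy <- as.numeric(y)[ok]
    method <- "pearson"
  } else if (kind_x == "qualitative" && kind_y == "qualitative") {
    xx <- code(x, categories_x)[ok]; yy <- code(y, categories_y)[ok]
    method <- "spearman"
  } else {
    # orient so x is the qualitative column
    if (kind_x == "quantitative") {
      tmp <- x; x <- y; y <- tmp
      categories_x <- categories_y
      quant_labels_y <- quant_labels_x
    }
    if (length(categories_x) == 2L) {
      xx <- code(x, categories_x)[ok] - 1
      yy <- as.numeric(y)[ok]
      method <- "point_biserial"
    } else {
      lab <- quant_labels_y
      if (is.null(lab)) {
        lab <- rep(NA_real_, length(y))
        obs <- !is.na(y)
        lab[obs] <- per_trait_clusters(as.numeric(y)[obs])$labels
      }
      xx <- code(x, categories_x)[ok]; yy <- as.numeric(lab)[ok]
      method <- "spearman"
    }
  }
  if (n < 3L || stats::sd(xx) == 0 || stats::sd(yy) == 0 ||
      is.na(stats::sd(xx)) || is.na(stats::sd(yy)))
    return(unavailable(method))
  r <- if (method == "spearman")
    stats::cor(xx, yy, method = "spearman")
  else stats::cor(xx, yy)
  # t approximation for the p-value of the chosen coefficient
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = r, p = p, method = method, n_pairs = n, available = TRUE)
}

#' Pairwise correlation matrix of a phenotype table
#'
#' @param table A [trait_table()].
#' @param quant_labels Optional named list of per-accession cluster labels
#'   for the quantitative traits (from [per_trait_clusters()] on the
#'   completed table); computed on the fly when absent.
#' @return An object of class `trait_correlations`: a list of m x m
#'   matrices `r`, `p`, `n_pairs`, `available` and a character matrix
#'   `method`.
#' @export
trait_correlations <- function(table, quant_labels = NULL) {
  schema <- table$schema
  nm <- schema_names(schema)
  kinds <- schema_kinds(schema)
  m <- length(nm)
  if (is.null(quant_labels)) {
    quant_labels <- list()
    for (j in which(kinds == "quantitative")) {
      v <- table$values[[j]]
      lab <- rep(NA_real_, length(v))
      obs <- !is.na(v)
      if (length(unique(v[obs])) >= 2L)
        lab[obs] <- per_trait_clusters(v[obs])$labels
      quant_labels[[nm[j]]] <- lab
    }
  }
  emp <- function(init) matrix(init, m, m, dimnames = list(nm, nm))
  R <- emp(NA_real_); P <- emp(NA_real_); N <- emp(0)
  A <- emp(FALSE); M <- emp(NA_character_)
  for (i in seq_len(m)) {
    R[i, i] <- 1; P[i, i] <- 0; A[i, i] <- TRUE
    N[i, i] <- sum(!is.na(table$values[[i]]))
    for (j in seq_len(i - 1L)) {
      e <- correlate_pair(
        table$values[[i]], table$values[[j]], kinds[i], kinds[j],
        categories_x = schema[[i]]$categories,
        categories_y = schema[[j]]$categories,
        quant_labels_x = quant_labels[[nm[i]]],
        quant_labels_y = quant_labels[[nm[j]]])
      R[i, j] <- R[j, i] <- e$r
      P[i, j] <- P[j, i] <- e$p
      N[i, j] <- N[j, i] <- e$n_pairs
      A[i, j] <- A[j, i] <- e$available
      M[i, j] <- M[j, i] <- e$method
    }
  }
  structure(list(r = R, p = P, n_pairs = N, available = A, method = M),
            class = "trait_correlations")
}

#' @export
print.trait_correlations <- function(x, ...) {
  up <- upper.tri(x$r)
  cat(sprintf("<trait_correlations> %d traits, %d pairs (%d unavailable)\n",
              nrow(x$r), sum(up), sum(!x$available[up])))
  invisible(x)
}

#' Summarize correlation strength over all trait pairs
#'
#' Percentages are taken over the `m(m-1)/2` distinct trait pairs.
#' Strength classes use configurable absolute-coefficient cutoffs
#' (defaults: strong `>= 0.5`, moderate `>= 0.3`, weak below); significance
#' is judged at `alpha`.
#'
#' @param corr A [trait_correlations()] object.
#' @param strong,moderate Absolute-coefficient cutoffs.
#' @param alpha Significance level.
#' @return A list with `pct_strong_or_moderate`, `pct_weak`,
#'   `pct_unavailable`, `pct_significant`, the cutoffs used and the pair
#'   count.
#' @export
correlation_summary <- function(corr, strong = 0.5, moderate = 0.3,
                                alpha = 0.05) {
  up <- upper.tri(corr$r)
  avail <- corr$available[up]
  r <- abs(corr$r[up])
  p <- corr$p[up]
  n_pairs <- sum(up)
  list(pct_strong_or_moderate = 100 * sum(avail & r >= moderate) / n_pairs,
       pct_weak = 100 * sum(avail & r < moderate) / n_pairs,
       pct_unavailable = 100 * sum(!avail) / n_pairs,
       pct_significant = 100 * sum(avail & p < alpha) / n_pairs,
       cutoffs = c(strong = strong, moderate = moderate, alpha = alpha),
       n_pairs = n_pairs)
}
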
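#' Encode a mixed-type table as a numeric matrix
#'
#' Quantitative traits are z-scored. Each qualitative trait is one-hot
#' encoded with every indicator scaled by `1/sqrt(2)`, so that a category
#' mismatch between two accessions contributes a squared distance of
#' exactly 1 for that trait -- commensurate with one standard deviation of
#' a quantitative trait. Clustering for population structure runs on
#' completed data; tables with missing cells are refused.
#'
#' @param table A fully observed [trait_table()].
#' @return An object of class `encoded_traits`: a list with the numeric
#'   matrix `X`, the integer map `trait_of_col`, trait `names` and `kinds`.
#' @export
encode_mixed <- function(table) {
  if (any(is.na(table$values)))
    stop("encode_mixed requires a fully observed table; impute first")
  schema <- table$schema
  nm <- schema_names(schema)
  pieces <- vector("list", length(nm))
  map <- integer(0)
  for (j in seq_along(nm)) {
    tr <- schema[[j]]
    if (tr$kind == "quantitative") {
      x <- as.numeric(table$values[[j]])
      s <- stats::sd(x)
      if (is.na(s) || s == 0) {
        warning("zero-variance quantitative trait '", tr$name,
                "' encoded as constant 0")
        col <- matrix(0, length(x), 1L)
      } else col <- matrix((x - mean(x)) / s, ncol = 1L)
    } else {
      cats <- tr$categories
      col <- matrix(0, n_accessions(table), length(cats))
      col[cbind(seq_len(nrow(col)), match(table$values[[j]], cats))] <- 1
      col <- col / sqrt(2)
    }
    pieces[[j]] <- col
    map <- c(map, rep(j, ncol(col)))
  }
  structure(list(X = do.call(cbind, pieces), trait_of_col = map,
                 names = nm, kinds = schema_kinds(schema),
                 ids = table$ids),
            class = "encoded_traits")
}

#' Entropy-weighted k-means on encoded mixed-type data
#'
#' Minimizes
#' `sum_c sum_{i in c} sum_t w_ct d2_t(x_i, z_c) + lambda * n * sum_c sum_t w_ct log(w_ct)`
#' by alternating (i) assignment of each accession to its nearest center
#' under the current per-cluster trait weights, (ii) center update (mean of
#' encoded columns per cluster), and (iii) the closed-form weight update
#' `w_ct proportional to exp(-D_ct / (lambda * n))`, with `D_ct` the
#' within-cluster dispersion (summed squared deviations) of cluster `c` on
#' trait `t`. The entropy penalty is expressed per accession, so `lambda`
#' is comparable across collection sizes: small values concentrate the
#' weights on low-dispersion traits within each cluster (0.5 by default),
#' while as `lambda` grows the weights tend to uniform and the procedure
#' approaches standard k-means on the encoded matrix. The best of `nstart`
#' k-means++-seeded runs by objective is returned; an empty cluster is
#' re-seeded at the point farthest from its current center. Clusters are
#' canonically renumbered by decreasing size (ties by smallest contained
#' accession index), so results are reproducible and label-stable.
#'
#' @param encoded An [encode_mixed()] object (or a plain numeric matrix,
#'   in which case every column is its own trait).
#' @param k Number of clusters (`1 <= k <= n`).
#' @param lambda Positive entropy-regularization parameter.
#' @param nstart Number of restarts.
#' @param max_iter Iteration cap per restart.
#' @param seed Integer seed.
#' @return An object of class `clustering_result`: a list with `k`,
#'   `assignments`, `centers`, `trait_weights` (k x traits, rows on the
#'   simplex), `variance_explained` (on the encoded matrix, unweighted),
#'   `objective` and the per-iteration `objective_trace` of the best run.
#' @export
weighted_kmeans <- function(encoded, k, lambda = 0.5, nstart = 100,
                            max_iter = 50, seed = 1) {
  if (!inherits(encoded, "encoded_traits")) {
    X <- as.matrix(encoded)
    encoded <- structure(list(X = X, trait_of_col = seq_len(ncol(X)),
                              names = paste0("V", seq_len(ncol(X))),
                              kinds = rep("quantitative", ncol(X)),
                              ids = rownames(X)),
                         class = "encoded_traits")
  }
  X <- encoded$X
  n <- nrow(X)
  stopifnot(k >= 1, k <= n, lambda > 0, nstart >= 1)
  tmap <- encoded$trait_of_col
  n_tr <- length(encoded$names)

  best <- NULL
  seeds <- derive_seeds(seed, nstart)
  for (s in seq_len(nstart)) {
    run <- with_seed(seeds[s], ewkm_once(X, k, lambda, tmap, n_tr, max_iter))
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  # canonical labels: decreasing size, ties by smallest accession index
  sizes <- tabulate(best$assign, k)
  first <- vapply(seq_len(k), function(c) {
    w <- which(best$assign == c)
    if (length(w)) min(w) else n + 1L
  }, integer(1))
  ord <- order(-sizes, first)
  relab <- integer(k); relab[ord] <- seq_len(k)
  assign <- relab[best$assign]
  centers <- best$centers[ord, , drop = FALSE]
  weights <- best$weights[ord, , drop = FALSE]
  colnames(weights) <- encoded$names

  mu <- colMeans(X)
  tss <- sum(sweep(X, 2L, mu)^2)
  wss <- sum((X - centers[assign, , drop = FALSE])^2)
  ve <- if (tss == 0) 0 else 1 - wss / tss
  names(assign) <- encoded$ids
  structure(list(k = k, assignments = assign, centers = centers,
                 trait_weights = weights,
                 variance_explained = ve, objective = best$objective,
                 objective_trace = best$trace, lambda = lambda),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf(
    "<clustering_result> k = %d, sizes = %s, variance explained = %.1f%%\n",
    x$k, paste(tabulate(x$assignments, x$k), collapse = "/"),
    100 * x$variance_explained))
  invisible(x)
}

ewkm_once <- function(X, k, lambda, tmap, n_tr, max_iter) {
  n <- nrow(X)
  centers <- X[kmeanspp_init(X, k), , drop = FALSE]
  weights <- matrix(1 / n_tr, k, n_tr)
  assign <- rep(1L, n)
  trace <- numeric(0)
  obj <- Inf
  for (it in seq_len(max_iter)) {
    wcol <- weights[, tmap, drop = FALSE]       # k x ncol(X)
    D <- vapply(seq_len(k), function(c) {
      as.numeric(sweep(X, 2L, centers[c, ])^2 %*% wcol[c, ])
    }, numeric(n))
    new_assign <- max.col(-D, ties.method = "first")
    # re-seed empty clusters at the farthest point from its center,
    # stealing only from clusters that keep at least one member
    for (c in which(tabulate(new_assign, k) == 0L)) {
      dself <- D[cbind(seq_len(n), new_assign)]
      cand <- which(tabulate(new_assign, k)[new_assign] > 1L)
      if (!length(cand)) next
      far <- cand[which.max(dself[cand])]
      centers[c, ] <- X[far, ]
      new_assign[far] <- c
    }
    assign <- new_assign
    for (c in seq_len(k)) {
      memb <- assign == c
      if (any(memb)) centers[c, ] <- colMeans(X[memb, , drop = FALSE])
    }
    # per-cluster per-trait dispersion and the entropy weight update
    disp <- matrix(0, k, n_tr)
    for (c in seq_len(k)) {
      memb <- assign == c
      d2 <- colSums(sweep(X[memb, , drop = FALSE], 2L, centers[c, ])^2)
      disp[c, ] <- as.numeric(rowsum(d2, tmap))
    }
    e <- exp(-(disp - apply(disp, 1L, min)) / (lambda * n))
    weights <- e / rowSums(e)
    new_obj <- ewkm_objective(X, centers, weights, assign, tmap, lambda)
    trace <- c(trace, new_obj)
    if (is.finite(obj) && obj - new_obj < 1e-10) { obj <- new_obj; break }
    obj <- new_obj
  }
  list(assign = assign, centers = centers, weights = weights,
       objective = obj, trace = trace)
}

ewkm_objective <- function(X, centers, weights, assign, tmap, lambda) {
  k <- nrow(centers)
  tot <- 0
  for (c in seq_len(k)) {
    memb <- assign == c
    if (!any(memb)) next
    d2 <- colSums(sweep(X[memb, , drop = FALSE], 2L, centers[c, ])^2)
    tot <- tot + sum(as.numeric(rowsum(d2, tmap)) * weights[c, ])
  }
  w <- weights[weights > 0]
  # entropy coefficient is per accession: total penalty lambda * n
  tot + lambda * nrow(X) * sum(w * log(w))
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  if (k == 1L) return(centers)
  d2 <- rowSums(sweep(X, 2L, X[centers[1L], ])^2)
  for (c in 2:k) {
    if (all(d2 == 0)) centers[c] <- sample.int(n, 1L)
    else centers[c] <- sample.int(n, 1L, prob = d2)
    d2 <- pmin(d2, rowSums(sweep(X, 2L, X[centers[c], ])^2))
  }
  centers
}

#' Search for the optimal number of clusters
#'
#' Runs [weighted_kmeans()] over `k_range` and applies the optimality
#' criteria used for germplasm structure analysis: high diversity richness
#' and evenness of the cluster-size distribution (Shannon-Weaver `> 0.90`,
#' Nei `> 0.80`) together with a large proportion of variance explained
#' (`> 0.75`). The smallest `k` satisfying all three is chosen; if none
#' does, the `k` satisfying the most criteria wins, with ties broken by
#' larger variance explained (the fallback is recorded in the report).
#'
#' @param table A fully observed [trait_table()], or an [encode_mixed()]
#'   object.
#' @param k_range Candidate cluster numbers.
#' @param lambda,nstart,seed Passed to [weighted_kmeans()].
#' @param h_min,nei_min,ve_min Criterion thresholds.
#' @return A list with `best` (the chosen `clustering_result`) and
#'   `report` (per-k data.frame with `H_prime`, `Nei`, `variance_explained`,
#'   per-criterion booleans, `chosen` flag and the `rule` applied).
#' @export
select_k <- function(table, k_range = 2:15, lambda = 0.5, nstart = 100,
                     seed = 1, h_min = 0.90, nei_min = 0.80,
                     ve_min = 0.75) {
  encoded <- if (inherits(table, "encoded_traits")) table
             else encode_mixed(table)
  k_range <- k_range[k_range <= nrow(encoded$X)]
  seeds <- derive_seeds(seed, length(k_range))
  fits <- vector("list", length(k_range))
  rows <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- weighted_kmeans(encoded, k, lambda = lambda, nstart = nstart,
                           seed = seeds[i])
    sizes <- tabulate(fit$assignments, k)
    h <- shannon_weaver(sizes); nei <- nei_index(sizes)
    rows[[i]] <- data.frame(
      k = k, H_prime = h, Nei = nei,
      variance_explained = fit$variance_explained,
      pass_H = h > h_min, pass_Nei = nei > nei_min,
      pass_VE = fit$variance_explained > ve_min)
    fits[[i]] <- fit
  }
  report <- do.call(rbind, rows)
  report$n_passed <- report$pass_H + report$pass_Nei + report$pass_VE
  all_pass <- which(report$n_passed == 3L)
  if (length(all_pass)) {
    pick <- all_pass[1L]                   # smallest k passing everything
    rule <- "smallest k satisfying all criteria"
  } else {
    cand <- which(report$n_passed == max(report$n_passed))
    pick <- cand[which.max(report$variance_explained[cand])]
    rule <- "no k satisfied all criteria; most criteria, then largest variance explained"
  }
  report$chosen <- seq_len(nrow(report)) == pick
  attr(report, "rule") <- rule
  list(best = fits[[pick]], report = report, rule = rule)
}

#' Optimal 1-D clustering of a single quantitative trait
#'
#' Applies the same weighted k-means machinery and optimality criteria to
#' one quantitative column, yielding the class labels used for per-trait
#' diversity and for the class-coverage index. Columns with fewer than 3
#' distinct values map each distinct value to its own class directly.
#'
#' @param values Numeric vector (no missing values).
#' @param k_range Candidate cluster numbers.
#' @param nstart,seed Passed to [weighted_kmeans()].
#' @return A list with `labels` (integer classes, canonically numbered) and
#'   `k`.
#' @export
per_trait_clusters <- function(values, k_range = 2:15, nstart = 10,
                               seed = 1, h_min = 0.90, nei_min = 0.80,
                               ve_min = 0.75) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("values must be fully observed")
  distinct <- sort(unique(values))
  if (length(distinct) < 3L)
    return(list(labels = match(values, distinct), k = length(distinct)))
  # with a single trait the per-cluster weights are degenerate (w = 1), so
  # the weighted algorithm reduces to plain k-means on the scaled column
  x <- as.numeric(scale(values))
  k_range <- k_range[k_range <= length(distinct)]
  rows <- vector("list", length(k_range))
  fits <- vector("list", length(k_range))
  with_seed(seed, {
    for (i in seq_along(k_range)) {
      k <- k_range[i]
      km <- tryCatch(
        suppressWarnings(stats::kmeans(x, k, nstart = nstart)),
        error = function(e) NULL)
      if (is.null(km)) next
      sizes <- km$size
      h <- shannon_weaver(sizes); nei <- nei_index(sizes)
      ve <- if (km$totss == 0) 0 else 1 - km$tot.withinss / km$totss
      rows[[i]] <- c(k = k, n_passed = (h > h_min) + (nei > nei_min) +
                       (ve > ve_min), ve = ve)
      fits[[i]] <- km
    }
  })
  ok <- !vapply(rows, is.null, logical(1))
  rep_mat <- do.call(rbind, rows[ok])
  fits <- fits[ok]
  all_pass <- which(rep_mat[, "n_passed"] == 3)
  pick <- if (length(all_pass)) all_pass[1L] else {
    cand <- which(rep_mat[, "n_passed"] == max(rep_mat[, "n_passed"]))
    cand[which.max(rep_mat[cand, "ve"])]
  }
  km <- fits[[pick]]
  # canonical labels: decreasing size, ties by smallest accession index
  first <- vapply(seq_len(length(km$size)), function(c)
    min(which(km$cluster == c)), integer(1))
  relab <- integer(length(km$size))
  relab[order(-km$size, first)] <- seq_along(km$size)
  list(labels = relab[km$cluster], k = length(km$size))
}
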
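#' Modified Roger's distance between phenotype vectors
#'
#' Accessions are encoded per trait so that the squared per-trait distance
#' between two fully observed accessions lies in \[0, 1\]: quantitative
#' traits are min-max scaled (collection-wide min/max), qualitative traits
#' one-hot encoded with indicators scaled by `1/sqrt(2)`. The distance is
#' `MRD(a, b) = sqrt(mean_t d2_t(a, b))`, a Euclidean-type normalized
#' distance with codomain \[0, 1\]. In `"raw"` mode a trait unobserved in
#' either accession contributes `d2_t = 0` while the divisor stays at the
#' full trait count -- the convention that reproduces the distance
#' shrinkage caused by unpaired phenotypes in incomplete data. In
#' `"complete"` mode missing cells are an error.
#'
#' @param table A [trait_table()].
#' @param mode `"complete"` or `"raw"`.
#' @param reference Optional [trait_table()] supplying the collection-wide
#'   min/max used for scaling (defaults to `table` itself); pass the entire
#'   collection when computing distances within a subset.
#' @return A symmetric n x n distance matrix with accession ids as
#'   dimnames.
#' @export
mrd_matrix <- function(table, mode = c("complete", "raw"),
                       reference = table) {
  mode <- match.arg(mode)
  if (mode == "complete" && any(is.na(table$values)))
    stop("complete mode requires a fully observed table")
  schema <- table$schema
  n <- n_accessions(table)
  m <- length(schema)
  acc <- matrix(0, n, n)
  for (j in seq_len(m)) {
    tr <- schema[[j]]
    v <- table$values[[j]]
    obs <- !is.na(v)
    if (tr$kind == "quantitative") {
      ref <- reference$values[[j]]
      lo <- min(ref, na.rm = TRUE); hi <- max(ref, na.rm = TRUE)
      x <- if (hi > lo) (as.numeric(v) - lo) / (hi - lo) else rep(0, n)
      x[!obs] <- 0
      d2 <- outer(x, x, function(a, b) (a - b)^2)
    } else {
      code <- match(v, tr$categories)
      code[!obs] <- 0L
      d2 <- outer(code, code, "!=") * 1
    }
    if (any(!obs)) {
      # unobserved in either accession: contributes 0 (raw-mode shrinkage)
      d2[!obs, ] <- 0
      d2[, !obs] <- 0
    }
    acc <- acc + d2
  }
  out <- sqrt(acc / m)
  dimnames(out) <- list(table$ids, table$ids)
  out
}

#' Distance of each accession to its cluster centroid
#'
#' The centroid of a cluster is encoded like an accession: per-trait mean
#' for quantitative traits (over the cluster's observed values) and modal
#' category for qualitative traits (ties broken by schema category order).
#' Distances use the same modified Roger's distance conventions as
#' [mrd_matrix()]; in `"raw"` mode, traits unobserved in the accession (or
#' with no observed value in its cluster) contribute 0, so added
#' missingness can never increase an accession's distance.
#'
#' @param table A [trait_table()].
#' @param assignments Integer cluster label per accession (e.g. from
#'   [weighted_kmeans()]).
#' @param mode `"complete"` or `"raw"`.
#' @param reference Scaling reference, as in [mrd_matrix()].
#' @return Named numeric vector of distances in \[0, 1\].
#' @export
centroid_distances <- function(table, assignments,
                               mode = c("complete", "raw"),
                               reference = table) {
  mode <- match.arg(mode)
  if (mode == "complete" && any(is.na(table$values)))
    stop("complete mode requires a fully observed table")
  stopifnot(length(assignments) == n_accessions(table))
  schema <- table$schema
  m <- length(schema)
  n <- n_accessions(table)
  acc <- numeric(n)
  for (j in seq_len(m)) {
    tr <- schema[[j]]
    v <- table$values[[j]]
    obs <- !is.na(v)
    if (tr$kind == "quantitative") {
      ref <- reference$values[[j]]
      lo <- min(ref, na.rm = TRUE); hi <- max(ref, na.rm = TRUE)
      x <- if (hi > lo) (as.numeric(v) - lo) / (hi - lo) else rep(0, n)
      cent <- tapply(x[obs], assignments[obs], mean)
      d2 <- (x - as.numeric(cent[as.character(assignments)]))^2
    } else {
      cent <- tapply(v[obs], assignments[obs], function(s) {
        cnt <- table(factor(s, levels = tr$categories))
        names(cnt)[which.max(cnt)]          # schema order breaks ties
      })
      d2 <- as.numeric(v != cent[as.character(assignments)])
    }
    d2[!obs | is.na(d2)] <- 0
    acc <- acc + d2
  }
  stats::setNames(sqrt(acc / m), table$ids)
}
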
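#' Sturges-rule classification of a quantitative column
#'
#' The number of classes is `K = ceiling(1 + log2(n))`, with `n` the number
#' of accessions observed for the trait. Bins are equal width over the
#' observed `[min, max]`, half-open `[lo, hi)` except for the last bin,
#' which is closed. A constant column yields a single class.
#'
#' @param values Numeric vector (may contain `NA`).
#' @param n Accession count entering Sturges' rule (default: number of
#'   non-missing values).
#' @param edges Optional externally fixed bin edges (length `K + 1`), used
#'   so that a core subset is binned on the entire collection's edges.
#' @return A list with `labels` (integer bin index per value, `NA` where
#'   missing), `edges` and `K`.
#' @export
sturges_bins <- function(values, n = sum(!is.na(values)), edges = NULL) {
  values <- as.numeric(values)
  obs <- values[!is.na(values)]
  if (!length(obs)) stop("sturges_bins needs at least one observed value")
  if (is.null(edges)) {
    if (min(obs) == max(obs))
      return(list(labels = ifelse(is.na(values), NA_integer_, 1L),
                  edges = c(min(obs), max(obs)), K = 1L))
    K <- ceiling(1 + log2(n))
    edges <- seq(min(obs), max(obs), length.out = K + 1L)
  }
  K <- length(edges) - 1L
  lab <- findInterval(values, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  lab[is.na(values)] <- NA_integer_
  list(labels = lab, edges = edges, K = K)
}

#' Build the trait-class grid for core selection
#'
#' Quantitative traits are classified by [sturges_bins()]; qualitative
#' traits by their observed categories. Missing cells map to no class and
#' the target class set of each trait is the set of classes with at least
#' one member.
#'
#' @param table A [trait_table()] (missing cells allowed).
#' @return An object of class `classification_grid`: a list with `classes`
#'   (n x m character matrix, `NA` for missing cells), `edges` (per
#'   quantitative trait), per-trait class `frequencies`, and `ids`.
#' @export
build_grid <- function(table) {
  schema <- table$schema
  nm <- schema_names(schema)
  n <- n_accessions(table)
  classes <- matrix(NA_character_, n, length(nm),
                    dimnames = list(table$ids, nm))
  edges <- list()
  for (j in seq_along(nm)) {
    tr <- schema[[j]]
    v <- table$values[[j]]
    if (tr$kind == "quantitative") {
      b <- sturges_bins(v)
      classes[, j] <- ifelse(is.na(b$labels), NA_character_,
                             paste0("bin", b$labels))
      edges[[tr$name]] <- b$edges
    } else {
      classes[, j] <- as.character(v)
    }
  }
  freqs <- lapply(seq_along(nm), function(j) table(classes[, j]))
  names(freqs) <- nm
  structure(list(classes = classes, edges = edges, frequencies = freqs,
                 ids = table$ids),
            class = "classification_grid")
}

#' @export
print.classification_grid <- function(x, ...) {
  cat(sprintf("<classification_grid> %d accessions x %d traits, %d target classes\n",
              nrow(x$classes), ncol(x$classes),
              sum(lengths(x$frequencies))))
  invisible(x)
}

# (trait, class) keys covered by each accession
grid_cover_sets <- function(grid) {
  nm <- colnames(grid$classes)
  apply(grid$classes, 1L, function(r) {
    obs <- !is.na(r)
    paste(nm[obs], r[obs], sep = "\r")
  }, simplify = FALSE)
}

#' Select a core collection by the maximization strategy
#'
#' A deterministic greedy realization of the advanced M (maximization)
#' strategy: maintain the set of still-uncovered trait classes; repeatedly
#' select the accession covering the most of them, breaking ties first in
#' favor of the accession whose newly covered classes are rarer (smaller
#' summed class frequency) and then by load order; stop when every class
#' with at least one member is covered. A reverse-order redundancy sweep
#' then removes any accession whose classes remain covered without it, so
#' the core has full class coverage with minimal redundancy.
#'
#' @param grid A [build_grid()] result.
#' @return An object of class `core_set`: a list with `ids` (selected
#'   accessions, in selection order after pruning), `trace` (one row per
#'   greedy step: accession and classes newly covered) and `coverage`
#'   (per-trait coverage fraction of the core, all 1 by construction).
#' @export
select_core <- function(grid) {
  covers <- grid_cover_sets(grid)
  all_classes <- unique(unlist(covers, use.names = FALSE))
  freq <- unlist(lapply(seq_along(grid$frequencies), function(j)
    stats::setNames(as.numeric(grid$frequencies[[j]]),
                    paste(names(grid$frequencies)[j],
                          names(grid$frequencies[[j]]), sep = "\r"))))
  uncovered <- all_classes
  chosen <- integer(0)
  trace <- list()
  n <- length(covers)
  while (length(uncovered)) {
    gain <- vapply(covers, function(s) sum(s %in% uncovered), numeric(1))
    gain[chosen] <- -1
    best_gain <- max(gain)
    cand <- which(gain == best_gain)
    if (length(cand) > 1L) {
      rarity <- vapply(cand, function(i)
        sum(freq[intersect(covers[[i]], uncovered)]), numeric(1))
      cand <- cand[rarity == min(rarity)]
    }
    pick <- cand[1L]                                # load order
    newly <- intersect(covers[[pick]], uncovered)
    chosen <- c(chosen, pick)
    trace[[length(trace) + 1L]] <- data.frame(
      step = length(chosen), accession = grid$ids[pick],
      new_classes = length(newly))
    uncovered <- setdiff(uncovered, newly)
  }
  # redundancy sweep, most recent picks first
  keep <- chosen
  for (acc in rev(chosen)) {
    rest <- setdiff(keep, acc)
    if (all(all_classes %in% unique(unlist(covers[rest], use.names = FALSE))))
      keep <- rest
  }
  ids <- grid$ids[keep]
  cov <- coverage_of(ids, grid)
  structure(list(ids = ids, trace = do.call(rbind, trace),
                 coverage = cov),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("<core_set> %d accessions, overall coverage %.1f%%\n",
              length(x$ids), x$coverage$overall))
  invisible(x)
}

#' Class coverage of a core subset
#'
#' Per trait, the ratio of classes present in the core to classes present
#' in the entire collection; the overall coverage is the mean of the
#' per-trait ratios, times 100.
#'
#' @param core Accession ids of the core (or a `core_set`).
#' @param grid The [build_grid()] of the entire collection.
#' @return A list with `per_trait` (named fractions in \[0,1\]) and
#'   `overall` (percent).
#' @export
coverage_of <- function(core, grid) {
  if (inherits(core, "core_set")) core <- core$ids
  idx <- match(core, grid$ids)
  if (anyNA(idx)) stop("core contains unknown accession id(s)")
  nm <- colnames(grid$classes)
  per <- vapply(seq_along(nm), function(j) {
    ec_classes <- names(grid$frequencies[[j]])
    if (!length(ec_classes)) return(NA_real_)
    cc <- unique(stats::na.omit(grid$classes[idx, j]))
    length(intersect(cc, ec_classes)) / length(ec_classes)
  }, numeric(1))
  names(per) <- nm
  list(per_trait = per, overall = 100 * mean(per, na.rm = TRUE))
}
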
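#' Shannon-Weaver and Nei phenotypic diversity indices
#'
#' Both indices operate on a vector of class or cluster counts. With
#' proportions `p_i = counts_i / sum(counts)` over the `S` non-empty
#' classes, the normalized Shannon-Weaver index is
#' `H' = -sum(p_i * ln(p_i)) / ln(S)` (in \[0, 1\], maximal at uniformity)
#' and Nei's index is `Nei = 1 - sum(p_i^2)` (in \[0, 1 - 1/S\]). Empty
#' classes are excluded from `S`; a single non-empty class gives `H' = 0`
#' by the limit convention.
#'
#' @param counts Non-negative class counts with a positive sum.
#' @return A scalar index value.
#' @examples
#' shannon_weaver(c(40, 29, 1, 17, 23, 45, 45))  # 0.90 to 2 dp
#' nei_index(c(40, 29, 1, 17, 23, 45, 45))       # 0.82 to 2 dp
#' @export
shannon_weaver <- function(counts) {
  p <- diversity_props(counts)
  if (length(p) == 1L) return(0)
  -sum(p * log(p)) / log(length(p))
}

#' @rdname shannon_weaver
#' @export
nei_index <- function(counts) {
  p <- diversity_props(counts)
  1 - sum(p^2)
}

diversity_props <- function(counts) {
  counts <- as.numeric(counts)
  if (!length(counts) || any(is.na(counts)) || any(counts < 0) ||
      sum(counts) <= 0)
    stop("counts must be non-negative with a positive sum")
  counts <- counts[counts > 0]
  counts / sum(counts)
}

#' Per-trait diversity of a collection
#'
#' Qualitative traits are scored on their category counts; quantitative
#' traits on counts over their optimal 1-D cluster labels (computed on the
#' accessions of `table` unless labels are supplied, so that a core subset
#' can be scored against classes defined on the entire collection).
#'
#' @param table A fully observed [trait_table()] (or any subset of one).
#' @param quant_labels Optional named list giving, for each quantitative
#'   trait, a per-accession label vector named by accession id (or aligned
#'   with `table$ids`).
#' @return A data.frame with columns `trait`, `kind`, `S` (non-empty
#'   classes), `H_prime` and `Nei`.
#' @export
trait_diversity <- function(table, quant_labels = NULL) {
  schema <- table$schema
  nm <- schema_names(schema)
  rows <- lapply(seq_along(nm), function(j) {
    tr <- schema[[j]]
    v <- table$values[[j]]
    v <- v[!is.na(v)]
    counts <- if (tr$kind == "qualitative") {
      as.numeric(table(factor(v, levels = tr$categories)))
    } else if (!is.null(quant_labels[[tr$name]])) {
      lab <- quant_labels[[tr$name]]
      if (!is.null(names(lab))) lab <- lab[table$ids]
      as.numeric(table(lab))
    } else if (length(unique(v)) < 2L) {
      length(v)
    } else {
      as.numeric(table(per_trait_clusters(v)$labels))
    }
    data.frame(trait = tr$name, kind = tr$kind,
               S = sum(counts > 0),
               H_prime = shannon_weaver(counts),
               Nei = nei_index(counts))
  })
  do.call(rbind, rows)
}

#' Diversity change between a collection and its core
#'
#' Per trait and per index, the relative change
#' `(core - entire) / entire * 100` (percent); non-negative change counts
#' as diversity retained, negative as lost. An entire-collection value of 0
#' leaves the change undefined (`NA`).
#'
#' @param ec_div,cc_div Data.frames from [trait_diversity()] on the entire
#'   and core collections (matched trait order).
#' @return A data.frame with per-trait percentage changes and
#'   retained/lost flags for both indices.
#' @export
diversity_change <- function(ec_div, cc_div) {
  stopifnot(identical(ec_div$trait, cc_div$trait))
  chg <- function(e, c) ifelse(e == 0, NA_real_, (c - e) / e * 100)
  h <- chg(ec_div$H_prime, cc_div$H_prime)
  n <- chg(ec_div$Nei, cc_div$Nei)
  data.frame(trait = ec_div$trait, kind = ec_div$kind,
             H_change_pct = h, H_status = status_of(h),
             Nei_change_pct = n, Nei_status = status_of(n))
}

status_of <- function(x)
  ifelse(is.na(x), NA_character_, ifelse(x >= 0, "retained", "lost"))
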
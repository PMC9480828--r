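#' Describe one phenotypic trait
#'
#' A trait schema records how a column of a phenotype table is to be
#' interpreted: as a quantitative measurement or as a qualitative character
#' with a fixed, ordered set of category labels. Qualitative traits that
#' originate from measurements (e.g. number of nodes on the main stem binned
#' into small/medium/large) may carry the numeric thresholds used to
#' categorize them.
#'
#' @param name Trait name (single string).
#' @param kind Either `"quantitative"` or `"qualitative"`.
#' @param unit Measurement unit, may be `""`.
#' @param categories Ordered character vector of category labels
#'   (qualitative traits only, at least two, unique).
#' @param thresholds Optional strictly increasing numeric cut points that map
#'   a measurement to `categories` (length `length(categories) - 1`).
#' @return An object of class `trait_schema`.
#' @examples
#' trait_schema("pod length", "qualitative", "cm",
#'              categories = c("short", "medium", "long"),
#'              thresholds = c(4.4, 5))
#' @export
trait_schema <- function(name, kind = c("quantitative", "qualitative"),
                         unit = "", categories = NULL, thresholds = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "qualitative") {
    if (is.null(categories) || length(categories) < 2L)
      stop("qualitative trait '", name, "' needs at least 2 categories")
    if (anyDuplicated(categories))
      stop("duplicate category labels in trait '", name, "'")
    categories <- as.character(categories)
  } else {
    if (!is.null(categories))
      stop("quantitative trait '", name, "' must not declare categories")
  }
  if (!is.null(thresholds)) {
    thresholds <- as.numeric(thresholds)
    if (is.unsorted(thresholds, strictly = TRUE))
      stop("thresholds for trait '", name, "' must be strictly increasing")
    if (kind == "qualitative" && length(thresholds) != length(categories) - 1L)
      stop("trait '", name, "': need length(categories) - 1 thresholds")
  }
  structure(list(name = name, kind = kind, unit = unit,
                 categories = categories, thresholds = thresholds),
            class = "trait_schema")
}

#' @export
print.trait_schema <- function(x, ...) {
  cat("<trait_schema> ", x$name, " [", x$kind, "]", sep = "")
  if (nzchar(x$unit %||% "")) cat(" (", x$unit, ")", sep = "")
  if (!is.null(x$categories))
    cat(": ", paste(x$categories, collapse = " < "), sep = "")
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_schema_list <- function(schema) {
  if (!is.list(schema) || !length(schema))
    stop("schema must be a non-empty list of trait_schema objects")
  ok <- vapply(schema, inherits, logical(1), "trait_schema")
  if (!all(ok)) stop("schema elements must be trait_schema objects")
  nm <- vapply(schema, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate trait names in schema")
  names(schema) <- nm
  schema
}

schema_names <- function(schema)
  unname(vapply(schema, `[[`, character(1), "name"))
schema_kinds <- function(schema)
  unname(vapply(schema, `[[`, character(1), "kind"))

#' Read or write a trait schema sidecar (JSON)
#'
#' The sidecar is a JSON array with one object per trait, holding `name`,
#' `kind`, optional `unit`, `categories` and `thresholds`. Trait order in the
#' file is the column order expected in the table.
#'
#' @param path File path.
#' @return `read_trait_schema()` returns a named list of [trait_schema()]
#'   objects; `write_trait_schema()` returns `path` invisibly.
#' @export
read_trait_schema <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  schema <- lapply(raw, function(tr) {
    trait_schema(name = tr$name, kind = tr$kind, unit = tr$unit %||% "",
                 categories = if (!is.null(tr$categories))
                   unlist(tr$categories, use.names = FALSE),
                 thresholds = if (!is.null(tr$thresholds))
                   unlist(tr$thresholds, use.names = FALSE))
  })
  validate_schema_list(schema)
}

#' @param schema Named list of [trait_schema()] objects.
#' @rdname read_trait_schema
#' @export
write_trait_schema <- function(schema, path) {
  schema <- validate_schema_list(schema)
  out <- lapply(unname(schema), function(tr) {
    x <- list(name = tr$name, kind = tr$kind)
    if (nzchar(tr$unit %||% "")) x$unit <- tr$unit
    if (!is.null(tr$categories)) x$categories <- tr$categories
    if (!is.null(tr$thresholds)) x$thresholds <- tr$thresholds
    x
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
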
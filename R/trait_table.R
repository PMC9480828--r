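#' Mixed-type phenotype table
#'
#' The central data container: accessions in rows, traits in columns.
#' Quantitative traits are stored as numeric columns, qualitative traits as
#' character columns restricted to their declared categories. `NA` marks a
#' missing cell. A parallel logical matrix records provenance: `FALSE` for
#' observed cells, `TRUE` for cells filled by imputation.
#'
#' @param values A data.frame of trait values, one column per schema entry,
#'   in schema order.
#' @param schema Named list of [trait_schema()] objects.
#' @param ids Character vector of unique accession identifiers (defaults to
#'   the row names of `values`).
#' @param imputed Optional logical matrix (same dimensions as `values`)
#'   marking completed cells; missing cells must not be marked.
#' @return An object of class `trait_table`.
#' @export
trait_table <- function(values, schema, ids = rownames(values),
                        imputed = NULL) {
  schema <- validate_schema_list(schema)
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  if (is.null(ids)) ids <- sprintf("acc%03d", seq_len(nrow(values)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate accession ids")
  if (length(ids) != nrow(values)) stop("ids/value row mismatch")
  nm <- schema_names(schema)
  if (!identical(colnames(values), nm)) {
    if (!all(nm %in% colnames(values)))
      stop("values missing traits: ",
           paste(setdiff(nm, colnames(values)), collapse = ", "))
    values <- values[nm]
  }
  for (tr in schema) {
    col <- values[[tr$name]]
    if (tr$kind == "quantitative") {
      if (!is.numeric(col)) {
        suppressWarnings(num <- as.numeric(col))
        if (any(is.na(num) & !is.na(col)))
          stop("non-numeric value in quantitative trait '", tr$name, "'")
        col <- num
      }
    } else {
      col <- as.character(col)
      bad <- !is.na(col) & !(col %in% tr$categories)
      if (any(bad))
        stop("trait '", tr$name, "': value(s) outside declared categories ",
             "at row(s) ", paste(which(bad), collapse = ", "), ": ",
             paste(unique(col[bad]), collapse = ", "))
    }
    values[[tr$name]] <- col
  }
  rownames(values) <- ids
  if (is.null(imputed)) {
    imputed <- matrix(FALSE, nrow(values), ncol(values),
                      dimnames = list(ids, nm))
  } else {
    imputed <- as.matrix(imputed)
    stopifnot(identical(dim(imputed), dim(as.matrix(values))))
    dimnames(imputed) <- list(ids, nm)
    if (any(imputed & as.matrix(is.na(values))))
      stop("missing cells cannot be marked as imputed")
  }
  structure(list(ids = ids, schema = schema, values = values,
                 imputed = imputed),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  k <- schema_kinds(x$schema)
  nmiss <- sum(is.na(x$values))
  cat(sprintf(
    "<trait_table> %d accessions x %d traits (%d quantitative, %d qualitative)\n",
    n_accessions(x), n_traits(x), sum(k == "quantitative"),
    sum(k == "qualitative")))
  cat(sprintf("  missing cells: %d (%.1f%%)   imputed cells: %d\n",
              nmiss, 100 * nmiss / prod(dim(x$values)), sum(x$imputed)))
  invisible(x)
}

#' Table dimensions and masks
#'
#' @param table A [trait_table()].
#' @return `n_accessions()`/`n_traits()` return counts; `missing_mask()`
#'   returns a logical matrix, `TRUE` where a cell is missing.
#' @export
n_accessions <- function(table) length(table$ids)

#' @rdname n_accessions
#' @export
n_traits <- function(table) length(table$schema)

#' @rdname n_accessions
#' @export
trait_names <- function(table) {
  if (inherits(table, "trait_table")) schema_names(table$schema)
  else schema_names(validate_schema_list(table))
}

#' @rdname n_accessions
#' @export
missing_mask <- function(table) {
  m <- as.matrix(is.na(table$values))
  dimnames(m) <- list(table$ids, schema_names(table$schema))
  m
}

#' Subset a trait table
#'
#' @param table A [trait_table()].
#' @param ids Accession ids to keep (order preserved as given).
#' @param traits Trait names to keep.
#' @return A [trait_table()] restricted to the requested rows/columns.
#' @export
subset_accessions <- function(table, ids) {
  idx <- match(ids, table$ids)
  if (anyNA(idx)) stop("unknown accession id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  trait_table(table$values[idx, , drop = FALSE], table$schema,
              ids = table$ids[idx],
              imputed = table$imputed[idx, , drop = FALSE])
}

#' @rdname subset_accessions
#' @export
subset_traits <- function(table, traits) {
  idx <- match(traits, schema_names(table$schema))
  if (anyNA(idx)) stop("unknown trait(s): ",
                       paste(traits[is.na(idx)], collapse = ", "))
  trait_table(table$values[, idx, drop = FALSE], table$schema[idx],
              ids = table$ids,
              imputed = table$imputed[, idx, drop = FALSE])
}

#' Read a phenotype table from delimited text
#'
#' Expects a header row of trait names with the accession identifier in the
#' first column, plus a JSON schema sidecar declaring every trait's kind and
#' categories. Cells equal to one of `missing_tokens` become missing.
#' Numeric parsing is locale-independent (dot decimal separator).
#'
#' @param path Path to the CSV/TSV file.
#' @param schema_path Path to the JSON schema sidecar, or a schema list.
#' @param sep Field separator (default `","`).
#' @param missing_tokens Strings mapped to missing (default empty and "NA").
#' @return A [trait_table()].
#' @export
read_trait_table <- function(path, schema_path, sep = ",",
                             missing_tokens = c("", "NA")) {
  schema <- if (is.character(schema_path)) read_trait_schema(schema_path)
            else validate_schema_list(schema_path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "", na.strings = NULL)
  if (ncol(df) < 2L) stop("table needs an id column plus at least one trait")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate accession id(s) in file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  df <- df[-1L]
  unknown <- setdiff(colnames(df), schema_names(schema))
  if (length(unknown))
    stop("unknown trait(s) in header: ", paste(unknown, collapse = ", "))
  absent <- setdiff(schema_names(schema), colnames(df))
  if (length(absent))
    stop("trait(s) declared in schema but absent from file: ",
         paste(absent, collapse = ", "))
  for (j in seq_along(df)) df[[j]][df[[j]] %in% missing_tokens] <- NA
  trait_table(df, schema, ids = ids)
}

#' Write a phenotype table to delimited text
#'
#' Missing cells are written as the first element of `missing_tokens` used
#' by [read_trait_table()] (the literal `NA`), so a write/read round trip
#' reproduces values, mask and ordering exactly.
#'
#' @param table A [trait_table()].
#' @param path Output file path.
#' @param schema_path Optional path for the JSON schema sidecar.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path, schema_path = NULL, sep = ",") {
  out <- data.frame(accession = table$ids, table$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, row.names = FALSE, na = "NA",
                     quote = TRUE)
  if (!is.null(schema_path)) write_trait_schema(table$schema, schema_path)
  invisible(path)
}

#' Remove duplicated accessions
#'
#' Accessions whose entire row of trait values -- including the pattern of
#' missing cells -- repeats an earlier accession's row are dropped; the first
#' occurrence is kept and accession order is otherwise preserved.
#'
#' @param table A [trait_table()].
#' @return A list with elements `table` (deduplicated) and `removed_ids`.
#' @export
dedupe_accessions <- function(table) {
  key <- apply(as.matrix(table$values), 1L, function(r)
    paste(ifelse(is.na(r), "\r<NA>\r", r), collapse = ""))
  dup <- duplicated(key)
  list(table = if (any(dup)) subset_accessions(table, table$ids[!dup])
               else table,
       removed_ids = table$ids[dup])
}

#' Remove invariant traits
#'
#' Traits whose non-missing values are all identical carry no information
#' for diversity or selection and are dropped. Constancy is judged on the
#' observed values only; missing cells do not rescue a constant trait.
#'
#' @param table A [trait_table()].
#' @return A list with elements `table` and `removed_traits`.
#' @export
drop_invariant_traits <- function(table) {
  const <- vapply(table$values, function(col) {
    obs <- col[!is.na(col)]
    length(unique(obs)) <= 1L
  }, logical(1))
  keep <- schema_names(table$schema)[!const]
  list(table = if (any(const)) subset_traits(table, keep) else table,
       removed_traits = schema_names(table$schema)[const])
}

#' Profile the missingness of a table
#'
#' Per-trait missing rates, the overall rate, and counts of traits in four
#' reporting strata: none (0%), low (0-30%], moderate (30-60%], and
#' high (60-100%].
#'
#' @param table A [trait_table()].
#' @return An object of class `missingness_profile`: a list with
#'   `per_trait` (named numeric vector of rates in \[0,1\]), `overall`, and
#'   `strata` (named integer vector summing to the number of traits).
#' @export
missingness_profile <- function(table) {
  mask <- missing_mask(table)
  per_trait <- colMeans(mask)
  strata <- c(none = sum(per_trait == 0),
              low = sum(per_trait > 0 & per_trait <= 0.30),
              moderate = sum(per_trait > 0.30 & per_trait <= 0.60),
              high = sum(per_trait > 0.60))
  structure(list(per_trait = per_trait, overall = mean(mask),
                 strata = strata),
            class = "missingness_profile")
}

#' @export
print.missingness_profile <- function(x, ...) {
  cat(sprintf("<missingness_profile> overall %.1f%%\n", 100 * x$overall))
  cat("  strata:", paste(names(x$strata), x$strata, sep = "=",
                         collapse = "  "), "\n")
  invisible(x)
}
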
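# OTU count tables travel as wide tibbles: first column `sample_id`, one
# column of non-negative integer counts per OTU. These helpers convert to and
# from the base matrix used for numerics, and validate the invariants.

#' Validate an OTU count table
#'
#' Checks the wide-tibble contract: a `sample_id` first column with unique
#' ids, unique OTU column names, and non-negative integer-valued counts.
#'
#' @param counts A data frame with a `sample_id` column and one numeric
#'   column per OTU.
#' @return The input, invisibly, if valid; otherwise an error describing the
#'   first violated invariant (duplicate ids, negative or fractional counts,
#'   with the offending cell named).
#' @export
validate_otu_table <- function(counts) {
  if (!is.data.frame(counts) || !"sample_id" %in% names(counts)) {
    abort("`counts` must be a data frame with a `sample_id` column.")
  }
  ids <- as.character(counts$sample_id)
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate sample ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  otus <- setdiff(names(counts), "sample_id")
  if (anyDuplicated(otus)) {
    abort(paste0("Duplicate OTU ids: ",
                 paste(unique(otus[duplicated(otus)]), collapse = ", ")))
  }
  for (o in otus) {
    v <- counts[[o]]
    if (!is.numeric(v)) abort(paste0("Counts for OTU '", o, "' are not numeric."))
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad)) {
      abort(paste0("Invalid count at sample '", ids[bad[1]], "', OTU '", o,
                   "': ", v[bad[1]],
                   " (counts must be non-negative integers)."))
    }
  }
  invisible(counts)
}

#' Convert an OTU table tibble to a count matrix
#'
#' @param counts Wide OTU tibble (see [validate_otu_table()]).
#' @return Integer-valued matrix, samples in rows (named by `sample_id`),
#'   OTUs in columns.
#' @export
otu_matrix <- function(counts) {
  validate_otu_table(counts)
  m <- as.matrix(counts[setdiff(names(counts), "sample_id")])
  rownames(m) <- as.character(counts$sample_id)
  storage.mode(m) <- "double"
  m
}

#' Convert a count matrix back to the wide-tibble form
#'
#' @param m Samples-by-OTU matrix with row names.
#' @return Tibble with a `sample_id` column followed by OTU columns.
#' @export
as_otu_table <- function(m) {
  ids <- rownames(m)
  if (is.null(ids)) {
    if (nrow(m) > 0) abort("Matrix must have row names (sample ids).")
    ids <- character(0)
  }
  dplyr::bind_cols(tibble(sample_id = ids),
                   as_tibble(m, .name_repair = "minimal"))
}

# Like otu_matrix() but for real-valued tables (e.g. Hellinger output).
wide_matrix <- function(x) {
  if (!is.data.frame(x) || !"sample_id" %in% names(x)) {
    abort("Expected a data frame with a `sample_id` column.")
  }
  m <- as.matrix(x[setdiff(names(x), "sample_id")])
  rownames(m) <- as.character(x$sample_id)
  m
}

sample_totals <- function(counts) {
  m <- otu_matrix(counts)
  setNames(rowSums(m), rownames(m))
}
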
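# Reading and writing the survey bundle: counts TSV (samples in rows, OTU
# ids in the header), metadata TSV, taxonomy TSV, hit and traits tables,
# truth JSON, filter-report JSON, and Newick trees. Writers order rows and
# columns lexicographically so outputs are byte-stable and diffable.

write_tsv_det <- function(x, path) {
  readr::write_tsv(x, path, na = "", progress = FALSE)
}

#' Write a survey bundle to a directory
#'
#' Writes `counts.tsv` (samples as rows, first column `sample_id`, OTU ids
#' as the remaining headers), `metadata.tsv`, and when present
#' `taxonomy.tsv` and `truth.json`. Rows and columns are sorted
#' lexicographically, so saving the same objects twice yields identical
#' bytes.
#'
#' @param survey A `fungal_survey` list (see [simulate_survey()]) or any
#'   list with at least `counts` and `metadata`.
#' @param dir Output directory; created if needed.
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cnt <- survey$counts
  validate_otu_table(cnt)
  cnt <- cnt[order(cnt$sample_id),
             c("sample_id", sort(setdiff(names(cnt), "sample_id")))]
  write_tsv_det(cnt, file.path(dir, "counts.tsv"))
  meta <- dplyr::arrange(survey$metadata, .data$sample_id)
  write_tsv_det(meta, file.path(dir, "metadata.tsv"))
  if (!is.null(survey$taxonomy)) {
    write_tsv_det(dplyr::arrange(survey$taxonomy, .data$otu_id),
                  file.path(dir, "taxonomy.tsv"))
  }
  if (!is.null(survey$truth_otus)) {
    jsonlite::write_json(
      list(truth_otus = dplyr::arrange(survey$truth_otus, .data$otu_id),
           truth_samples = dplyr::arrange(survey$truth_samples,
                                          .data$sample_id)),
      file.path(dir, "truth.json"),
      dataframe = "columns", na = "null", digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read a survey bundle from a directory
#'
#' Counterpart of [write_survey()]. Validates the counts table
#' (non-negative integers, unique ids) and checks that every sample in the
#' counts appears in the metadata; violations raise errors naming the
#' offending cells or ids.
#'
#' @param dir Directory containing `counts.tsv` and `metadata.tsv`
#'   (optionally `taxonomy.tsv`, `truth.json`).
#' @return A `fungal_survey`-shaped list with `counts`, `metadata` and,
#'   when present, `taxonomy`, `truth_otus`, `truth_samples`.
#' @export
read_survey <- function(dir) {
  counts <- readr::read_tsv(file.path(dir, "counts.tsv"),
                            show_col_types = FALSE, progress = FALSE)
  names(counts)[1] <- "sample_id"
  counts$sample_id <- as.character(counts$sample_id)
  validate_otu_table(counts)
  meta <- readr::read_tsv(file.path(dir, "metadata.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  meta$sample_id <- as.character(meta$sample_id)
  missing <- setdiff(counts$sample_id, meta$sample_id)
  if (length(missing)) {
    abort(paste0("Samples present in counts but absent from metadata: ",
                 paste(missing, collapse = ", ")))
  }
  out <- list(counts = counts, metadata = meta)
  tax_path <- file.path(dir, "taxonomy.tsv")
  if (file.exists(tax_path)) {
    out$taxonomy <- readr::read_tsv(tax_path, show_col_types = FALSE,
                                    progress = FALSE)
  }
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path)) {
    tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    out$truth_otus <- as_tibble(tr$truth_otus)
    out$truth_samples <- as_tibble(tr$truth_samples)
  }
  structure(out, class = "fungal_survey")
}

#' Read a reference-hit table
#'
#' Tab-separated with columns `otu_id`, `hit_order`, `similarity`,
#' `evalue`, `taxonomy`; the taxonomy path is pipe-joined
#' kingdom|phylum|class|order|family|genus with empty fields allowed.
#' Returns the long form used by [assign_taxonomy()].
#'
#' @param path Path to the TSV file.
#' @return Tibble `otu_id`, `hit_order`, `similarity`, `evalue` plus the
#'   six rank columns.
#' @export
read_hits <- function(path) {
  h <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("otu_id", "hit_order", "similarity", "evalue", "taxonomy")
  miss <- setdiff(need, names(h))
  if (length(miss)) {
    abort(paste0("Hit table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(h$similarity < 0 | h$similarity > 100)) {
    abort("Similarity values must lie in [0, 100].")
  }
  if (any(h$evalue < 0)) abort("E-values must be non-negative.")
  dup <- dplyr::count(h, .data$otu_id, .data$hit_order) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("Duplicate hit_order within OTU(s): ",
                 paste(unique(dup$otu_id), collapse = ", ")))
  }
  parts <- stringr::str_split_fixed(h$taxonomy, stringr::fixed("|"), 6)
  parts[parts == ""] <- NA_character_
  colnames(parts) <- rank_names()
  dplyr::bind_cols(dplyr::select(h, -"taxonomy"), as_tibble(parts))
}

#' Write a reference-hit table
#'
#' @param hits Long-form hit tibble (see [read_hits()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  tax <- apply(as.matrix(hits[rank_names()]), 1, function(r) {
    r[is.na(r)] <- ""
    paste(r, collapse = "|")
  })
  out <- dplyr::select(hits, "otu_id", "hit_order", "similarity", "evalue")
  out$taxonomy <- tax
  write_tsv_det(dplyr::arrange(out, .data$otu_id, .data$hit_order), path)
  invisible(path)
}

#' Read a traits lookup table
#'
#' @param path TSV with the columns documented in [synthetic_traits()].
#' @return Traits tibble.
#' @export
read_traits <- function(path) {
  tr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("genus", "species", "multi_lifestyle", "guild", "ecm_lineage",
            "exploration_type", "mold_group")
  miss <- setdiff(need, names(tr))
  if (length(miss)) {
    abort(paste0("Traits table lacks column(s): ",
                 paste(miss, collapse = ", ")))
  }
  tr
}

#' Read an ultrametric-capable phylogeny from a Newick file
#'
#' Requires branch lengths (phylogenetic distances are undefined without
#' them) and unique tip labels; polytomies are allowed.
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_survey_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) abort("Could not parse a tree from the file.")
  if (is.null(tr$edge.length)) {
    abort("Tree has no branch lengths; phylogenetic distances undefined.")
  }
  if (anyDuplicated(tr$tip.label)) {
    abort(paste0("Duplicate tip label(s): ",
                 paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                       collapse = ", ")))
  }
  tr
}

#' Serialize a filter report to JSON
#'
#' Stages are written in chain order with counts and removed ids.
#'
#' @param report A `filter_report` (see [apply_qc_chain()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  stages <- purrr::pmap(report, function(stage, n_samples, n_sequences,
                                         n_otus, removed) {
    list(stage = stage, n_samples = n_samples, n_sequences = n_sequences,
         n_otus = n_otus, removed = as.character(removed))
  })
  jsonlite::write_json(stages, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a filter report from JSON
#'
#' @param path JSON written by [write_filter_report()].
#' @return A `filter_report` tibble.
#' @export
read_filter_report <- function(path) {
  stages <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- purrr::map_dfr(stages, function(s) {
    tibble(stage = s$stage, n_samples = as.integer(s$n_samples),
           n_sequences = as.numeric(s$n_sequences),
           n_otus = as.integer(s$n_otus),
           removed = list(as.character(unlist(s$removed))))
  })
  class(out) <- c("filter_report", class(tibble()))
  out
}
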
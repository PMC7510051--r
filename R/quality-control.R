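# Pre-statistics sample/OTU quality control: control removal, depth
# filtering, OTU blocklisting, mold profiling and spoilage removal, with a
# full per-stage provenance report.

#' Quality-control thresholds
#'
#' The removal rule flags a sample as mold-spoiled when the relative
#' abundance of its single most abundant mold OTU exceeds 30 % for
#' Pezizomycotina molds, 15 % for Umbelopsidales or 15 % for
#' Mortierellales (strict inequalities). Mucorales are profiled but carry
#' no removal threshold. Samples with fewer than `min_reads` (default 500)
#' total reads are dropped, as are blocklisted OTUs (suspected
#' contamination / tag switching / non-target markers).
#'
#' @param min_reads Minimum total reads per sample.
#' @param pezizomycotina_max,umbelopsidales_max,mortierellales_max Maximum
#'   tolerated single-OTU relative abundance per mold group, in (0, 1].
#' @param otu_blocklist Character vector of OTU ids to exclude.
#' @param use_group_share If `TRUE`, also flag on the group's total share
#'   (off by default: the rule is defined on the per-sample maximum OTU).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_reads = 500, pezizomycotina_max = 0.30,
                          umbelopsidales_max = 0.15,
                          mortierellales_max = 0.15,
                          otu_blocklist = character(),
                          use_group_share = FALSE) {
  th <- c(pezizomycotina_max, umbelopsidales_max, mortierellales_max)
  if (any(th <= 0 | th > 1)) abort("Mold thresholds must lie in (0, 1].")
  if (min_reads < 1) abort("`min_reads` must be >= 1.")
  structure(list(min_reads = min_reads,
                 pezizomycotina_max = pezizomycotina_max,
                 umbelopsidales_max = umbelopsidales_max,
                 mortierellales_max = mortierellales_max,
                 otu_blocklist = as.character(otu_blocklist),
                 use_group_share = isTRUE(use_group_share)),
            class = "qc_thresholds")
}

#' Per-sample mold profiles
#'
#' For each sample and each mold group, the group's total share of the
#' sample's reads and the share of its single most abundant OTU. Shares
#' use the sample's total over *all* retained OTUs as denominator, so
#' `0 <= max_otu_share <= group_share <= 1`.
#'
#' @param counts Wide OTU tibble; all sample totals must be positive
#'   (depth-filter first).
#' @param assignments Assignment tibble with `otu_id` and `mold_group`.
#' @return Tibble `sample_id`, `mold_group`, `group_share`,
#'   `max_otu_share`, one row per sample x group (all four groups always
#'   present, zero shares when the group is absent).
#' @export
compute_mold_profiles <- function(counts, assignments) {
  m <- otu_matrix(counts)
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    abort(paste0("Zero-total sample(s): ",
                 paste(rownames(m)[tot <= 0], collapse = ", "),
                 ". Apply the depth filter first."))
  }
  grp_of <- setNames(assignments$mold_group, assignments$otu_id)
  purrr::map_dfr(mold_groups(), function(g) {
    otus <- intersect(colnames(m),
                      names(grp_of)[!is.na(grp_of) & grp_of == g])
    if (!length(otus)) {
      return(tibble(sample_id = rownames(m), mold_group = g,
                    group_share = 0, max_otu_share = 0))
    }
    sub <- m[, otus, drop = FALSE]
    tibble(sample_id = rownames(m), mold_group = g,
           group_share = unname(rowSums(sub) / tot),
           max_otu_share = unname(apply(sub, 1, max) / tot))
  }) |> dplyr::arrange(.data$sample_id)
}

#' Per-sample share of each global top mold OTU
#'
#' For every mold group, identifies the single most abundant mold OTU
#' across the whole table and reports its relative abundance in each
#' sample -- a covariate tracking the spread of the dominant mold, as
#' opposed to the per-sample maximum used by the removal rule.
#'
#' @inheritParams compute_mold_profiles
#' @return Tibble `sample_id`, `mold_group`, `top_otu`, `share`.
#' @export
global_top_mold_share <- function(counts, assignments) {
  m <- otu_matrix(counts)
  tot <- rowSums(m)
  grp_of <- setNames(assignments$mold_group, assignments$otu_id)
  purrr::map_dfr(mold_groups(), function(g) {
    otus <- intersect(colnames(m),
                      names(grp_of)[!is.na(grp_of) & grp_of == g])
    if (!length(otus)) return(tibble())
    top <- otus[which.max(colSums(m[, otus, drop = FALSE]))]
    tibble(sample_id = rownames(m), mold_group = g, top_otu = top,
           share = unname(m[, top] / tot))
  })
}

new_filter_report <- function() {
  structure(tibble(stage = character(), n_samples = integer(),
                   n_sequences = double(), n_otus = integer(),
                   removed = list()),
            class = c("filter_report", "tbl_df", "tbl", "data.frame"))
}

report_stage <- function(report, stage, m, removed = character()) {
  row <- tibble(stage = stage, n_samples = nrow(m),
                n_sequences = sum(m), n_otus = sum(colSums(m) > 0),
                removed = list(as.character(removed)))
  out <- dplyr::bind_rows(report, row)
  class(out) <- c("filter_report", class(tibble()))
  out
}

#' Apply the pre-statistics quality-control chain
#'
#' Stages, in order: (1) drop control samples; (2) drop samples with fewer
#' than `min_reads` total reads; (3) drop blocklisted OTUs; (4) recompute
#' totals and drop samples emptied by stage 3; (5) recompute mold profiles
#' and drop samples whose maximum mold-OTU share exceeds its group
#' threshold. Mold shares are computed *after* blocklist removal. The
#' returned report records sample/sequence/OTU counts and removed ids at
#' every stage; the chain is idempotent.
#'
#' @param counts Wide OTU tibble.
#' @param metadata Sample metadata with `sample_id` and logical
#'   `is_control`.
#' @param assignments Assignment tibble with `otu_id` and `mold_group`.
#' @param thresholds A [qc_thresholds()].
#' @return List with `counts` (filtered table) and `report`
#'   (a `filter_report` tibble).
#' @export
apply_qc_chain <- function(counts, metadata, assignments,
                           thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  m <- otu_matrix(counts)
  missing_meta <- setdiff(rownames(m), as.character(metadata$sample_id))
  if (length(missing_meta)) {
    abort(paste0("Samples absent from metadata: ",
                 paste(missing_meta, collapse = ", ")))
  }
  report <- report_stage(new_filter_report(), "input", m)

  is_ctl <- setNames(metadata$is_control %||% FALSE,
                     as.character(metadata$sample_id))
  ctl <- rownames(m)[is_ctl[rownames(m)] %in% TRUE]
  m <- m[setdiff(rownames(m), ctl), , drop = FALSE]
  report <- report_stage(report, "remove_controls", m, ctl)

  low <- rownames(m)[rowSums(m) < thresholds$min_reads]
  m <- m[setdiff(rownames(m), low), , drop = FALSE]
  report <- report_stage(report, "min_depth", m, low)

  block <- intersect(colnames(m), thresholds$otu_blocklist)
  m <- m[, setdiff(colnames(m), block), drop = FALSE]
  report <- report_stage(report, "otu_blocklist", m, block)

  empty <- rownames(m)[rowSums(m) == 0]
  m <- m[setdiff(rownames(m), empty), , drop = FALSE]
  report <- report_stage(report, "drop_empty", m, empty)

  if (nrow(m) == 0) abort("No samples survive QC.")
  prof <- compute_mold_profiles(as_otu_table(m), assignments)
  lim <- c(Mortierellales = thresholds$mortierellales_max,
           Umbelopsidales = thresholds$umbelopsidales_max,
           Pezizomycotina_mold = thresholds$pezizomycotina_max)
  prof <- dplyr::filter(prof, .data$mold_group %in% names(lim))
  stat <- if (thresholds$use_group_share) prof$group_share else
    prof$max_otu_share
  spoiled <- unique(prof$sample_id[stat > lim[prof$mold_group]])
  m <- m[setdiff(rownames(m), spoiled), , drop = FALSE]
  report <- report_stage(report, "mold_spoilage", m, spoiled)

  if (nrow(m) == 0) abort("No samples survive QC.")
  list(counts = as_otu_table(m), report = report)
}

#' Gate samples for per-guild analyses
#'
#' Community and richness analyses of a single guild exclude samples with
#' fewer than `min_otus` OTUs of that guild (default 20), and optionally
#' fewer than `min_sequences` reads of it (used with 100 for
#' ectomycorrhizal analyses).
#'
#' @param counts Wide OTU tibble (post-QC).
#' @param assignments Assignment tibble with `otu_id` and `guild`.
#' @param guild Guild label to gate on.
#' @param min_otus Minimum number of the guild's OTUs present.
#' @param min_sequences Optional minimum number of the guild's reads.
#' @return The counts table restricted to passing samples and the guild's
#'   OTU columns.
#' @export
guild_sample_gate <- function(counts, assignments, guild, min_otus = 20,
                              min_sequences = NULL) {
  m <- otu_matrix(counts)
  otus <- assignments$otu_id[!is.na(assignments$guild) &
                               assignments$guild == guild]
  otus <- intersect(colnames(m), otus)
  sub <- m[, otus, drop = FALSE]
  keep <- rowSums(sub > 0) >= min_otus
  if (!is.null(min_sequences)) keep <- keep & rowSums(sub) >= min_sequences
  as_otu_table(sub[keep, , drop = FALSE])
}
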
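# Taxonomic assignment from best-hit tables with rank-specific similarity /
# e-value thresholds and a conservative conflict rule, followed by
# functional annotation (guild, ectomycorrhizal lineage, exploration type,
# mold group) from a traits lookup table.

#' Rank-specific identification thresholds
#'
#' Minimum BLAST-style percent similarity and maximum e-value an alignment
#' hit must satisfy to support a label at each rank: kingdom > 70 %
#' similarity and e-value < 1e-20; phylum and class > 75 % and < 1e-50;
#' order, family and genus > 80 %, > 85 % and > 90 % respectively. The
#' class-level e-value bound is carried down to order/family/genus (only
#' similarity cut-offs are defined for those ranks); override via the
#' arguments if desired. Both comparisons are strict.
#'
#' @param min_similarity Named numeric vector of per-rank similarity floors.
#' @param max_evalue Named numeric vector of per-rank e-value ceilings.
#' @return Tibble with columns `rank`, `min_similarity`, `max_evalue`.
#' @export
rank_thresholds <- function(
    min_similarity = c(kingdom = 70, phylum = 75, class = 75,
                       order = 80, family = 85, genus = 90),
    max_evalue = c(kingdom = 1e-20, phylum = 1e-50, class = 1e-50,
                   order = 1e-50, family = 1e-50, genus = 1e-50)) {
  rk <- rank_names()
  stopifnot(all(rk %in% names(min_similarity)), all(rk %in% names(max_evalue)))
  tibble(rank = rk,
         min_similarity = as.numeric(min_similarity[rk]),
         max_evalue = as.numeric(max_evalue[rk]))
}

#' Assign one taxonomic rank from the best hits of one OTU
#'
#' Restricts the hits to those passing the rank's similarity and e-value
#' thresholds and carrying a non-empty label at that rank. An empty passing
#' set, or more than one distinct label among passing hits (conflicting
#' best matches), yields `NA` (unassigned) -- identification is
#' deliberately conservative.
#'
#' @param hits Tibble of reference hits for a single OTU: columns
#'   `similarity`, `evalue` and one column per rank.
#' @param rank One of kingdom, phylum, class, order, family, genus.
#' @param thresholds Output of [rank_thresholds()].
#' @return A single label, or `NA_character_`.
#' @export
assign_rank <- function(hits, rank, thresholds = rank_thresholds()) {
  rank <- match.arg(rank, rank_names())
  th <- thresholds[thresholds$rank == rank, ]
  lab <- hits[[rank]]
  ok <- !is.na(lab) & nzchar(lab) &
    hits$similarity > th$min_similarity & hits$evalue < th$max_evalue
  labs <- unique(lab[ok])
  if (length(labs) == 1) labs else NA_character_
}

#' Assign taxonomy for every OTU in a hit table
#'
#' Evaluates ranks from kingdom down to genus with [assign_rank()]; once a
#' rank is unassigned all deeper ranks are forced unassigned, so the
#' resulting paths are monotone. OTUs whose hits fail even the kingdom
#' thresholds (or that have no hits at all) are left fully unassigned --
#' unknown eukaryotes that drop out of fungal tallies.
#'
#' @param hits Tibble of reference hits, at most 10 per OTU, with columns
#'   `otu_id`, `hit_order`, `similarity`, `evalue` and the six rank
#'   columns.
#' @param thresholds Output of [rank_thresholds()].
#' @param otu_ids Optional full vector of OTU ids, so OTUs absent from the
#'   hit table still get (fully unassigned) rows.
#' @return Tibble with `otu_id` and the six rank columns (`NA` =
#'   unassigned).
#' @export
assign_taxonomy <- function(hits, thresholds = rank_thresholds(),
                            otu_ids = NULL) {
  need <- c("otu_id", "similarity", "evalue", rank_names())
  miss <- setdiff(need, names(hits))
  if (length(miss)) {
    abort(paste0("Hit table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  ids <- unique(c(as.character(hits$otu_id), otu_ids))
  no_hits <- setdiff(ids, hits$otu_id)
  if (length(no_hits)) {
    inform(paste0(length(no_hits), " OTU(s) without hits left unassigned."))
  }
  per_otu <- function(id) {
    h <- hits[hits$otu_id == id, , drop = FALSE]
    out <- setNames(rep(NA_character_, 6), rank_names())
    for (rk in rank_names()) {
      lab <- if (nrow(h)) assign_rank(h, rk, thresholds) else NA_character_
      if (is.na(lab)) break
      out[[rk]] <- lab
    }
    out
  }
  res <- purrr::map(ids, per_otu)
  dplyr::bind_cols(tibble(otu_id = ids),
                   as_tibble(do.call(rbind, res)))
}

#' Functional annotation from a traits lookup table
#'
#' Maps genus-level taxonomy onto functional categories: guild, and for
#' ectomycorrhizal fungi the lineage and exploration type, plus the mold
#' group for genera in the four mold clades. Genera flagged as having
#' multiple lifestyles need a species-level override row; without one (or
#' without a species-level identification) the guild stays unassigned.
#'
#' @param assignments Output of [assign_taxonomy()]; may carry an optional
#'   `species` column used to match species-level override rows.
#' @param traits Traits tibble with columns `genus`, `species` (`NA` for
#'   genus-level rows), `multi_lifestyle`, `guild`, `ecm_lineage`,
#'   `exploration_type`, `mold_group`. See [synthetic_traits()].
#' @return `assignments` with `guild`, `ecm_lineage`, `exploration_type`
#'   and `mold_group` columns filled (`NA` where unassignable).
#' @export
annotate_function <- function(assignments, traits) {
  need <- c("genus", "species", "multi_lifestyle", "guild", "ecm_lineage",
            "exploration_type", "mold_group")
  miss <- setdiff(need, names(traits))
  if (length(miss)) {
    abort(paste0("Traits table lacks column(s): ",
                 paste(miss, collapse = ", ")))
  }
  gen_rows <- dplyr::filter(traits, is.na(.data$species))
  sp_rows <- dplyr::filter(traits, !is.na(.data$species))
  out <- assignments
  if (!"species" %in% names(out)) out$species <- NA_character_
  out <- dplyr::left_join(
    out,
    dplyr::select(gen_rows, "genus", "multi_lifestyle", g_guild = "guild",
                  g_lin = "ecm_lineage", g_exp = "exploration_type",
                  g_mold = "mold_group"),
    by = "genus")
  out <- dplyr::left_join(
    out,
    dplyr::select(sp_rows, "genus", "species", s_guild = "guild",
                  s_lin = "ecm_lineage", s_exp = "exploration_type",
                  s_mold = "mold_group"),
    by = c("genus", "species"))
  out <- dplyr::mutate(
    out,
    multi = dplyr::coalesce(.data$multi_lifestyle, FALSE),
    guild = dplyr::if_else(.data$multi, .data$s_guild, .data$g_guild),
    ecm_lineage = dplyr::if_else(.data$multi, .data$s_lin, .data$g_lin),
    exploration_type = dplyr::if_else(.data$multi, .data$s_exp, .data$g_exp),
    mold_group = dplyr::coalesce(.data$s_mold, .data$g_mold))
  # lineage / exploration type only make sense for EcM fungi
  out <- dplyr::mutate(
    out,
    ecm_lineage = dplyr::if_else(!is.na(.data$guild) & .data$guild == "EcM",
                                 .data$ecm_lineage, NA_character_),
    exploration_type = dplyr::if_else(
      !is.na(.data$guild) & .data$guild == "EcM",
      .data$exploration_type, NA_character_))
  dplyr::select(out, -dplyr::any_of(c("multi", "multi_lifestyle", "g_guild",
                                      "g_lin", "g_exp", "g_mold", "s_guild",
                                      "s_lin", "s_exp", "s_mold")))
}
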
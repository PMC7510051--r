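# Diversity transforms: the anchored percentage log-ratio, the Hellinger
# transform, Shannon diversity, depth-residual richness and rarefaction.

#' Anchored log-ratio transform of a percentage
#'
#' Maps a relative abundance expressed in percent onto a symmetric
#' dimensionless scale: `log10((p + 0.01) / (100 - p + 0.01))`. The 0.01
#' percentage-point offset in both numerator and complement anchors the
#' scale at -4 (0 %), 0 (50 %) and 4 (100 %), and keeps the transform
#' finite at the boundaries. Used for ectomycorrhizal plant proportions,
#' tree basal-area shares, guild sequence proportions and per-OTU relative
#' abundances.
#'
#' @param p Numeric vector of percentages in `[0, 100]`.
#' @return Numeric vector of log-ratio scores; antisymmetric around 50 %
#'   (`logratio_pct(p) == -logratio_pct(100 - p)`).
#' @examples
#' logratio_pct(c(0, 50, 100))
#' @export
logratio_pct <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  bad <- which(is.finite(p) & (p < 0 | p > 100))
  if (length(bad)) {
    abort(paste0("Percentages outside [0, 100]: ", p[bad[1]], " at position ",
                 bad[1], "."))
  }
  log10((p + 0.01) / (100 - p + 0.01))
}

#' Hellinger transform of an OTU count table
#'
#' Each count is replaced by the square root of its within-sample relative
#' abundance, so every sample row has unit sum of squares. The standard
#' pre-treatment before Bray-Curtis / ordination, robust to double zeros.
#'
#' @param counts Wide OTU tibble (see [validate_otu_table()]); every sample
#'   must have a positive total.
#' @return Tibble of the same shape with real-valued entries.
#' @export
hellinger <- function(counts) {
  m <- otu_matrix(counts)
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    abort(paste0("Zero-total sample(s): ",
                 paste(rownames(m)[tot <= 0], collapse = ", "),
                 ". Depth-filter before transforming."))
  }
  as_otu_table(sqrt(m / tot))
}

#' Shannon diversity of one sample
#'
#' `H = -sum(p_i * log(p_i))` over OTUs with positive counts.
#'
#' @param x Non-negative count vector with a positive total.
#' @param base Logarithm base; natural log (nats) by default.
#' @return Shannon index, a single number.
#' @export
shannon <- function(x, base = exp(1)) {
  if (!is.numeric(x) || any(x < 0)) abort("`x` must be non-negative counts.")
  if (sum(x) <= 0) abort("Sample total must be positive.")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p, base = base))
}

#' Depth-residual richness
#'
#' Normalises observed OTU richness for unequal sequencing depth by fitting
#' two least-squares regressions of richness -- on the square root of depth
#' and on the natural log of depth -- and averaging their raw residuals.
#' Either single regression over- or under-corrects at the depth extremes;
#' the average behaves better across the whole depth range. When depths are
#' constant both slopes are undefined and the result falls back to simple
#' mean-centering.
#'
#' @param richness Numeric vector of observed OTU richness per sample.
#' @param depth Numeric vector of sequencing depths (reads), positive.
#' @return Numeric vector of residuals, same length and names as
#'   `richness`; sums to zero.
#' @export
residual_richness <- function(richness, depth) {
  if (length(richness) != length(depth)) {
    abort("`richness` and `depth` must have the same length.")
  }
  if (length(richness) < 3) abort("Need at least 3 samples.")
  if (any(depth <= 0)) abort("Depths must be positive.")
  if (sd(depth) == 0) {
    return(richness - mean(richness))
  }
  r1 <- resid(lm(richness ~ sqrt(depth)))
  r2 <- resid(lm(richness ~ log(depth)))
  out <- as.numeric((r1 + r2) / 2)
  names(out) <- names(richness)
  out
}

#' Add depth-residual richness per group to a metrics table
#'
#' Data-frame interface to [residual_richness()]: residuals are computed
#' within each group of rows (e.g. one fungal guild at a time), so that
#' every group's residuals sum to zero.
#'
#' @param data Data frame with one row per sample (x group).
#' @param richness,depth Unquoted column names holding richness and depth.
#' @param group Optional unquoted grouping column.
#' @return `data` with an added `residual` column.
#' @export
add_residual_richness <- function(data, richness, depth, group = NULL) {
  grp <- rlang::enquo(group)
  out <- if (rlang::quo_is_null(grp)) data else dplyr::group_by(data, !!grp)
  out <- dplyr::mutate(
    out,
    residual = residual_richness({{ richness }}, {{ depth }})
  )
  dplyr::ungroup(out)
}

#' Rarefied OTU accumulation curve
#'
#' Expected OTU richness at standardized numbers of reads, computed
#' analytically from the hypergeometric expectation
#' `E[S(m)] = S - sum_i C(N - N_i, m) / C(N, m)` (no resampling noise).
#' Sample-wise singletons -- OTUs with exactly one read in a sample, which
#' may represent index-switching artifacts -- can be excluded before
#' pooling.
#'
#' @param counts Wide OTU tibble.
#' @param depths Integer vector of read depths at which to evaluate the
#'   curve. Defaults to ~25 points spread over the available total.
#' @param mode `"pooled"` (default) treats all samples as one pooled
#'   community; `"per_sample"` returns one curve per sample (depths beyond
#'   a sample's total are dropped for that sample).
#' @param singleton_mode `"include"` (default) or `"exclude"` sample-wise
#'   singleton reads.
#' @return Tibble with columns `depth`, `expected_richness`, and
#'   `sample_id` when `mode = "per_sample"`; carries `singleton_mode`.
#' @export
rarefaction_curve <- function(counts, depths = NULL,
                              mode = c("pooled", "per_sample"),
                              singleton_mode = c("include", "exclude")) {
  mode <- match.arg(mode)
  singleton_mode <- match.arg(singleton_mode)
  m <- otu_matrix(counts)
  if (singleton_mode == "exclude") m[m == 1] <- 0
  if (mode == "pooled") {
    pooled <- colSums(m)
    n_tot <- sum(pooled)
    if (is.null(depths)) {
      depths <- unique(round(seq(1, n_tot, length.out = 25)))
    }
    if (any(depths < 1) || any(depths > n_tot)) {
      abort(paste0("Rarefaction depths must lie in [1, ", n_tot, "]."))
    }
    er <- as.numeric(suppressWarnings(vegan::rarefy(pooled, sample = depths)))
    out <- tibble(depth = depths, expected_richness = er)
  } else {
    tots <- rowSums(m)
    if (is.null(depths)) {
      depths <- unique(round(seq(1, max(tots), length.out = 25)))
    }
    out <- purrr::map_dfr(rownames(m), function(s) {
      d <- depths[depths >= 1 & depths <= tots[s]]
      if (!length(d)) return(tibble())
      tibble(sample_id = s, depth = d,
             expected_richness = as.numeric(
               suppressWarnings(vegan::rarefy(m[s, ], sample = d))))
    })
  }
  attr(out, "singleton_mode") <- singleton_mode
  out
}

#' Per-sample richness and sequence-proportion metrics by functional group
#'
#' Tallies, for every sample, OTU richness and sequence proportion within
#' each fungal guild, each taxonomic group (at a chosen rank) and each
#' ectomycorrhizal lineage, plus exploration-type sequence proportions.
#' Proportions are computed on the sample's total reads; the log-ratio
#' column applies [logratio_pct()] to the percentage.
#'
#' @param counts Wide OTU tibble.
#' @param assignments Taxon/function assignment tibble (one row per OTU)
#'   with columns `otu_id`, `guild`, `ecm_lineage`, `exploration_type` and
#'   the rank columns.
#' @param rank Taxonomic rank used for the "taxon" category
#'   (default `"order"`).
#' @return Long tibble: `sample_id`, `category` (guild / taxon / lineage /
#'   exploration), `group`, `richness`, `prop`, `prop_logratio`.
#' @export
group_metrics <- function(counts, assignments, rank = "order") {
  m <- otu_matrix(counts)
  tot <- rowSums(m)
  long <- as_tibble(as.table(m), .name_repair = "minimal")
  names(long) <- c("sample_id", "otu_id", "count")
  long <- dplyr::filter(long, .data$count > 0)
  key <- dplyr::select(assignments, "otu_id",
                       guild = "guild", taxon = dplyr::all_of(rank),
                       lineage = "ecm_lineage",
                       exploration = "exploration_type")
  long <- dplyr::left_join(long, key, by = "otu_id")
  one_cat <- function(col) {
    d <- dplyr::filter(long, !is.na(.data[[col]]))
    if (!nrow(d)) return(tibble())
    d |>
      dplyr::group_by(.data$sample_id, group = .data[[col]]) |>
      dplyr::summarise(richness = dplyr::n_distinct(.data$otu_id),
                       reads = sum(.data$count), .groups = "drop") |>
      dplyr::mutate(category = col,
                    prop = .data$reads / as.numeric(tot[.data$sample_id]),
                    prop_logratio = logratio_pct(100 * .data$prop)) |>
      dplyr::select("sample_id", "category", "group", "richness", "prop",
                    "prop_logratio")
  }
  dplyr::bind_rows(lapply(c("guild", "taxon", "lineage", "exploration"),
                          one_cat))
}

#' Number of distinct ectomycorrhizal lineages per sample
#'
#' A proxy for phylogenetic richness of the ectomycorrhizal community.
#'
#' @inheritParams group_metrics
#' @return Tibble `sample_id`, `n_lineages`.
#' @export
ecm_lineage_counts <- function(counts, assignments) {
  gm <- group_metrics(counts, assignments)
  lin <- dplyr::filter(gm, .data$category == "lineage")
  base <- tibble(sample_id = as.character(counts$sample_id))
  cnt <- dplyr::count(lin, .data$sample_id, name = "n_lineages")
  dplyr::left_join(base, cnt, by = "sample_id") |>
    dplyr::mutate(n_lineages = dplyr::coalesce(.data$n_lineages, 0L))
}
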
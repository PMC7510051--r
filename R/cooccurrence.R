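# Checkerboard C-score co-occurrence analysis with a fixed-fixed
# (margin-preserving) swap null model, as applied to complexes of closely
# related OTUs.

presence_matrix <- function(counts, min_count = 1) {
  m <- otu_matrix(counts)
  (m >= min_count) * 1
}

#' Checkerboard C-score for one OTU pair
#'
#' `C = (R_i - S) * (R_j - S)`, where `R_i` and `R_j` are the numbers of
#' samples occupied by each OTU and `S` the number of samples shared.
#' Zero when the two OTUs always co-occur; large when their occurrences
#' form a checkerboard. Symmetric in the pair.
#'
#' @param counts Wide OTU tibble (or binary presence matrix).
#' @param i,j OTU ids.
#' @param min_count Minimum count defining presence (default 1).
#' @return The C-score, a non-negative number.
#' @export
cscore_pair <- function(counts, i, j, min_count = 1) {
  pm <- if (is.data.frame(counts)) presence_matrix(counts, min_count) else
    (as.matrix(counts) >= min_count) * 1
  for (id in c(i, j)) {
    if (!id %in% colnames(pm)) abort(paste0("Unknown OTU: ", id))
  }
  ri <- sum(pm[, i])
  rj <- sum(pm[, j])
  s <- sum(pm[, i] * pm[, j])
  (ri - s) * (rj - s)
}

cscore_all_pairs <- function(pm, pairs) {
  vapply(seq_len(nrow(pairs)), function(r) {
    ri <- sum(pm[, pairs$otu_i[r]])
    rj <- sum(pm[, pairs$otu_j[r]])
    s <- sum(pm[, pairs$otu_i[r]] * pm[, pairs$otu_j[r]])
    (ri - s) * (rj - s)
  }, numeric(1))
}

#' Standardized C-scores against a fixed-fixed swap null model
#'
#' Null presence-absence matrices preserve both row (sample) and column
#' (OTU) occupancy totals; they are sampled by sequential trial swaps of
#' 2x2 checkerboard submatrices (the trial-swap chain, whose stationary
#' distribution is uniform over the margin-preserving set), with `burn_in`
#' trials before the first sample and `thin` trials between samples. For
#' each pair, `SES = (obs - null mean) / null sd`; positive SES means
#' segregation (avoidance), negative means aggregation. The two-tailed p
#' is `(count of |null - mean| >= |obs - mean| + 1) / (n_null + 1)`.
#' Degenerate margins that admit no swap leave the null distribution
#' constant; such pairs are flagged (`ses = NA`, `p_value = 1`).
#'
#' @param counts Wide OTU tibble.
#' @param pairs Tibble with columns `otu_i`, `otu_j`; default all pairs of
#'   OTUs present in the table.
#' @param otus Optional OTU subset from which to form all pairs (e.g. the
#'   members of one species complex).
#' @param n_null Number of null matrices (default 999).
#' @param burn_in Trial swaps before the first null sample (default
#'   30000).
#' @param thin Trial swaps between consecutive null samples (default
#'   1000).
#' @param seed Integer seed.
#' @param min_count Minimum count defining presence.
#' @param return_null If `TRUE`, the matrix of null C-scores (one row per
#'   null matrix, one column per pair) is attached as attribute
#'   `"null_scores"`.
#' @return Tibble per pair: `otu_i`, `otu_j`, `c_obs`, `null_mean`,
#'   `null_sd`, `ses`, `p_value`, `degenerate`.
#' @export
ses_cscore <- function(counts, pairs = NULL, otus = NULL, n_null = 999,
                       burn_in = 30000, thin = 1000, seed = 1L,
                       min_count = 1, return_null = FALSE) {
  pm <- presence_matrix(counts, min_count)
  if (nrow(pm) < 2 || ncol(pm) < 2) {
    abort("Need at least 2 samples and 2 OTUs.")
  }
  if (is.null(pairs)) {
    ids <- otus %||% colnames(pm)
    miss <- setdiff(ids, colnames(pm))
    if (length(miss)) {
      abort(paste0("Unknown OTU(s): ", paste(miss, collapse = ", ")))
    }
    cmb <- combn(ids, 2)
    pairs <- tibble(otu_i = cmb[1, ], otu_j = cmb[2, ])
  }
  obs <- cscore_all_pairs(pm, pairs)
  nm <- vegan::nullmodel(pm, "tswap")
  sims <- stats::simulate(nm, nsim = n_null, burnin = burn_in,
                          thin = thin, seed = seed)
  null_c <- matrix(NA_real_, n_null, nrow(pairs))
  for (r in seq_len(n_null)) {
    null_c[r, ] <- cscore_all_pairs(sims[, , r], pairs)
  }
  mu <- colMeans(null_c)
  sdv <- apply(null_c, 2, sd)
  degen <- sdv == 0
  ses <- ifelse(degen, NA_real_, (obs - mu) / sdv)
  p <- vapply(seq_len(nrow(pairs)), function(k) {
    if (degen[k]) return(1)
    (sum(abs(null_c[, k] - mu[k]) >= abs(obs[k] - mu[k]) - 1e-12) + 1) /
      (n_null + 1)
  }, numeric(1))
  out <- dplyr::bind_cols(pairs,
                          tibble(c_obs = obs, null_mean = mu,
                                 null_sd = sdv, ses = ses, p_value = p,
                                 degenerate = degen))
  if (return_null) attr(out, "null_scores") <- null_c
  out
}
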
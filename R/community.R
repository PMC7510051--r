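# Distance-based community structure: Bray-Curtis dissimilarity,
# PERMANOVA with sequential sums of squares on a Gower-centered distance
# matrix, Moran eigenvector maps (classical PCNM construction),
# plant-phylogeny community distances, NMDS and environmental vector
# fitting.

#' Bray-Curtis dissimilarity
#'
#' `d(a, b) = 1 - 2 * sum(min(x_a, x_b)) / (sum(x_a) + sum(x_b))` between
#' all sample pairs; typically applied to Hellinger-transformed
#' abundances.
#'
#' @param x Wide OTU tibble or numeric samples-by-feature matrix with
#'   non-negative entries and positive row totals.
#' @return A `dist` object labelled by sample id, entries in `[0, 1]`.
#' @export
bray_curtis <- function(x) {
  m <- if (is.data.frame(x)) wide_matrix(x) else as.matrix(x)
  if (any(m < 0)) abort("Entries must be non-negative.")
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    abort(paste0("Zero-total row(s): ",
                 paste(rownames(m)[tot <= 0], collapse = ", ")))
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  tm <- t(m)
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    mins <- colSums(pmin(tm[, js, drop = FALSE], m[i, ]))
    d[js, i] <- d[i, js] <- 1 - 2 * mins / (tot[i] + tot[js])
  }
  stats::as.dist(d)
}

# Gower-centered inner-product matrix from a distance matrix.
gower_center <- function(d) {
  a <- -0.5 * as.matrix(d)^2
  n <- nrow(a)
  j <- diag(n) - matrix(1 / n, n, n)
  j %*% a %*% j
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Partitions the total sum of squares of a distance matrix across model
#' terms fitted sequentially in the given order (type-I), using the
#' Gower-centered inner-product matrix and projection (hat) matrices of
#' the accumulated design. Significance of each term's pseudo-F comes from
#' free permutation of sample labels:
#' `p = (number of permuted F >= observed + 1) / (n_perm + 1)`.
#'
#' @param d A `dist` object (e.g. [bray_curtis()] on Hellinger-transformed
#'   counts).
#' @param data Data frame of design variables, rows matching the labels
#'   of `d` (matched by `sample_id` when present, else by order).
#' @param formula One-sided formula of terms, e.g. `~ pH + habitat`.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional integer seed for the permutation stream.
#' @param permutations Optional matrix of permutation indices (one
#'   permutation per row), overriding random generation; used e.g. for
#'   exhaustive enumeration on small n.
#' @return A `permanova` object; `tidy()` gives the per-term table (df,
#'   sums of squares, pseudo-F, R-squared in percent, permutation p).
#' @export
permanova <- function(d, data, formula, n_perm = 999, seed = NULL,
                      permutations = NULL) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if ("sample_id" %in% names(data) && !is.null(rownames(dm))) {
    idx <- match(rownames(dm), as.character(data$sample_id))
    if (anyNA(idx)) abort("Design rows do not match distance labels.")
    data <- data[idx, , drop = FALSE]
  }
  if (nrow(data) != n) abort("Design rows must match the distance matrix.")
  tl <- attr(stats::terms(formula), "term.labels")
  if (!length(tl)) abort("Formula must contain at least one term.")
  for (v in all.vars(formula)) {
    col <- data[[v]]
    if ((is.character(col) || is.factor(col)) &&
        length(unique(col)) < 2) {
      abort(paste0("Term '", v, "' has a single level."))
    }
  }
  g <- gower_center(dm)
  ss_total <- sum(diag(g))

  # hat matrix of the design accumulated up to each term
  hats <- vector("list", length(tl))
  dfs <- numeric(length(tl))
  prev_rank <- 1  # intercept
  for (k in seq_along(tl)) {
    f_k <- stats::as.formula(paste("~", paste(tl[seq_len(k)],
                                              collapse = " + ")))
    X <- model.matrix(f_k, data)
    qx <- qr(X)
    hats[[k]] <- tcrossprod(qr.Q(qx)[, seq_len(qx$rank), drop = FALSE])
    dfs[k] <- qx$rank - prev_rank
    prev_rank <- qx$rank
  }
  df_res <- n - prev_rank
  if (df_res <= 0) abort("No residual degrees of freedom.")

  stat <- function(gp) {
    tr <- vapply(hats, function(h) sum(h * gp), numeric(1))
    ss <- diff(c(0, tr))
    ss_res <- max(sum(diag(gp)) - tr[length(tr)], 0)
    (ss / dfs) / (ss_res / df_res)
  }
  f_obs <- stat(g)
  tr_obs <- vapply(hats, function(h) sum(h * g), numeric(1))
  ss_obs <- diff(c(0, tr_obs))
  ss_res <- max(ss_total - tr_obs[length(tr_obs)], 0)

  if (is.null(permutations)) {
    if (!is.null(seed)) set.seed(seed)
    permutations <- t(replicate(n_perm, sample.int(n)))
  }
  n_perm <- nrow(permutations)
  exceed <- numeric(length(tl))
  for (r in seq_len(n_perm)) {
    p <- permutations[r, ]
    exceed <- exceed + (stat(g[p, p]) >= f_obs - 1e-12)
  }
  p_val <- (exceed + 1) / (n_perm + 1)

  res <- tibble(
    term = c(tl, "Residual", "Total"),
    df = c(dfs, df_res, n - 1),
    sum_sq = c(ss_obs, ss_res, ss_total),
    pseudo_f = c(f_obs, NA, NA),
    r2 = 100 * c(ss_obs, ss_res, ss_total) / ss_total,
    p_value = c(p_val, NA, NA))
  structure(list(table = res, n_perm = n_perm, seed = seed),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (sequential SS, ", x$n_perm, " permutations)\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Tidy a PERMANOVA result
#'
#' @param x A `permanova` object.
#' @param ... Unused.
#' @return The per-term tibble (df, sum of squares, pseudo-F, R2 %,
#'   permutation p), with Residual and Total rows.
#' @method tidy permanova
#' @export
tidy.permanova <- function(x, ...) x$table

#' One-line summary of a PERMANOVA
#'
#' @param x A `permanova` object.
#' @param ... Unused.
#' @return Tibble with the strongest term, its R2, and permutation count.
#' @method glance permanova
#' @export
glance.permanova <- function(x, ...) {
  terms <- dplyr::filter(x$table, !.data$term %in% c("Residual", "Total"))
  best <- terms[which.max(terms$r2), ]
  tibble(n_terms = nrow(terms), best_term = best$term, best_r2 = best$r2,
         n_perm = x$n_perm)
}

#' Moran eigenvector maps from a distance matrix
#'
#' Classical PCNM/dbMEM construction: distances above the truncation
#' threshold (by default the longest edge of the minimum spanning tree)
#' are replaced by four times the threshold, the modified matrix is
#' Gower-centered, and eigenvectors with positive eigenvalues are
#' retained as spatial / temporal / phylogenetic covariates.
#'
#' @param d A `dist` object (geographic, temporal or phylogenetic
#'   community distances).
#' @param truncation Optional truncation threshold in the units of `d`.
#' @param source Tag recording the distance source: one of `"gMEM"`
#'   (geographic), `"tMEM"` (temporal), `"ntMEM"`, `"cdMEM"`, `"psMEM"`
#'   (phylogenetic community distances).
#' @return A `mem_basis` list: `vectors` (columns orthonormal, one per
#'   positive eigenvalue, named `MEM1`, `MEM2`, ...), `values`
#'   (descending), `truncation`, `source`. Empty basis (with a warning)
#'   when no positive eigenvalues exist.
#' @export
dbmem <- function(d, truncation = NULL,
                  source = c("gMEM", "tMEM", "ntMEM", "cdMEM", "psMEM")) {
  source <- match.arg(source)
  p <- if (is.null(truncation)) vegan::pcnm(d) else
    vegan::pcnm(d, threshold = truncation)
  pos <- p$values > sqrt(.Machine$double.eps)
  if (!any(pos)) {
    warn("No positive eigenvalues; empty eigenvector basis.")
    return(structure(list(vectors = matrix(numeric(0), nrow = attr(d, "Size"),
                                           ncol = 0),
                          values = numeric(0), truncation = p$threshold,
                          source = source), class = "mem_basis"))
  }
  vec <- p$vectors[, seq_len(sum(pos)), drop = FALSE]
  colnames(vec) <- paste0("MEM", seq_len(ncol(vec)))
  structure(list(vectors = vec, values = p$values[pos],
                 truncation = p$threshold, source = source),
            class = "mem_basis")
}

#' @export
print.mem_basis <- function(x, ...) {
  cat(x$source, "basis:", ncol(x$vectors), "eigenvectors, truncation",
      signif(x$truncation, 4), "\n")
  invisible(x)
}

#' Temporal distances for temporal eigenvector maps
#'
#' Absolute differences in days between sampling dates, after pooling
#' winter-adjacent months: February-April are mapped to March and
#' November-January to December (of the November year) before
#' differencing, reflecting that little fungal turnover is resolvable
#' within those pooled windows.
#'
#' @param dates `Date` vector.
#' @return A `dist` of absolute day differences.
#' @export
temporal_distances <- function(dates) {
  dates <- as.Date(dates)
  mo <- as.integer(format(dates, "%m"))
  yr <- as.integer(format(dates, "%Y"))
  adj <- dates
  pool_spring <- mo %in% 2:4
  adj[pool_spring] <- as.Date(sprintf("%d-03-15", yr[pool_spring]))
  adj[mo == 11] <- as.Date(sprintf("%d-12-15", yr[mo == 11]))
  adj[mo == 12] <- as.Date(sprintf("%d-12-15", yr[mo == 12]))
  adj[mo == 1] <- as.Date(sprintf("%d-12-15", yr[mo == 1] - 1L))
  stats::dist(as.numeric(adj))
}

#' Plant-phylogeny community distances between samples
#'
#' Three between-sample distances computed on the woody-plant phylogeny
#' from each sample's plant community: `comdist` (mean patristic distance
#' over all cross-community pairs), `comdistnt` (mean distance to the
#' nearest taxon in the other community, averaged both ways) and the
#' PhyloSor dissimilarity (1 - shared branch length / mean total branch
#' length).
#'
#' @param tree An `ape::phylo` with branch lengths (see
#'   [read_survey_tree()]).
#' @param comm Wide community tibble: `sample_id` plus one column per
#'   plant taxon (presence or abundance); taxa with any occurrence must be
#'   tree tips.
#' @return List of three `dist` objects: `comdist`, `comdistnt`,
#'   `phylosor` (dissimilarity scale).
#' @export
phylo_community_distances <- function(tree, comm) {
  m <- otu_matrix(comm)
  present <- colnames(m)[colSums(m) > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing)) {
    abort(paste0("Community member(s) not in the tree: ",
                 paste(missing, collapse = ", ")))
  }
  cd <- stats::cophenetic(tree)
  list(comdist = picante::comdist(m, cd, abundance.weighted = FALSE),
       comdistnt = picante::comdistnt(m, cd, abundance.weighted = FALSE),
       phylosor = 1 - picante::phylosor(m, tree))
}

#' Non-metric multidimensional scaling
#'
#' Minimises Kruskal stress-1 by monotone regression from multiple random
#' starts, keeping the best solution.
#'
#' @param d A `dist` of dissimilarities (finite).
#' @param k Number of ordination dimensions (default 2).
#' @param n_starts Number of random starts (default 20).
#' @param seed Integer seed.
#' @return An `nmds_fit`: `points` tibble (`sample_id`, `NMDS1`, ...),
#'   `stress` (0-1 scale), `converged` flag.
#' @export
nmds <- function(d, k = 2, n_starts = 20, seed = 1L) {
  if (any(!is.finite(as.vector(d)))) abort("Distances must be finite.")
  if (attr(d, "Size") < k + 2) abort("Need at least k + 2 points.")
  set.seed(seed)
  # near-zero stress is the expected outcome for cleanly embeddable
  # configurations, not a data problem worth a warning here
  fit <- withCallingHandlers(
    vegan::metaMDS(d, k = k, try = n_starts, trymax = n_starts,
                   autotransform = FALSE, wascores = FALSE, trace = 0),
    warning = function(w) {
      if (grepl("stress is (nearly) zero", conditionMessage(w),
                fixed = TRUE)) {
        invokeRestart("muffleWarning")
      }
    })
  pts <- as_tibble(fit$points, .name_repair = "minimal")
  names(pts) <- paste0("NMDS", seq_len(k))
  pts <- dplyr::bind_cols(tibble(sample_id = labels(d)), pts)
  structure(list(points = pts, stress = fit$stress,
                 converged = isTRUE(fit$converged)),
            class = "nmds_fit")
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat("NMDS: stress =", signif(x$stress, 4),
      if (x$converged) "(converged)" else "(no convergent solution)", "\n")
  invisible(x)
}

#' Fit environmental vectors onto an ordination
#'
#' Least-squares direction of each (numeric) environmental variable in
#' ordination space, with squared multiple correlation and a permutation
#' p-value. Constant variables are skipped with a warning.
#'
#' @param ordination An `nmds_fit` (or any object with a `points` tibble).
#' @param env Data frame of environmental variables, rows aligned with the
#'   ordination's samples (matched by `sample_id` when present).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return Tibble: `variable`, axis loadings (direction cosines), `r2`,
#'   `p_value`.
#' @export
envfit_vectors <- function(ordination, env, n_perm = 999, seed = 1L) {
  pts <- ordination$points
  coords <- as.matrix(pts[setdiff(names(pts), "sample_id")])
  rownames(coords) <- pts$sample_id
  if ("sample_id" %in% names(env)) {
    idx <- match(pts$sample_id, as.character(env$sample_id))
    if (anyNA(idx)) abort("`env` rows do not match the ordination samples.")
    env <- env[idx, setdiff(names(env), "sample_id"), drop = FALSE]
  }
  num <- env[vapply(env, is.numeric, logical(1))]
  const <- vapply(num, function(v) sd(v, na.rm = TRUE) == 0, logical(1))
  if (any(const)) {
    warn(paste0("Skipping constant variable(s): ",
                paste(names(num)[const], collapse = ", ")))
    num <- num[!const]
  }
  if (!ncol(num)) abort("No usable (non-constant numeric) variables.")
  set.seed(seed)
  ef <- vegan::envfit(coords, num, permutations = n_perm)
  arrows <- as_tibble(ef$vectors$arrows, .name_repair = "minimal")
  names(arrows) <- colnames(coords)
  dplyr::bind_cols(tibble(variable = rownames(ef$vectors$arrows)), arrows,
                   tibble(r2 = as.numeric(ef$vectors$r),
                          p_value = as.numeric(ef$vectors$pvals)))
}
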
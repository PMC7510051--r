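# Niche modelling of richness variables and per-OTU abundances along
# environmental gradients: random-forest predictor preselection against
# shuffled decoys, quadratic least-squares response fits, variance
# explained, and response-shape classification.

#' Select predictors by random-forest importance against shuffled decoys
#'
#' Fits one regression random forest (999 trees by default) on the
#' candidate predictors plus `n_decoys` label-shuffled decoy copies of
#' each. The decoys carry the marginal distribution of the real
#' predictors but no signal, so the largest decoy importance estimates
#' the noise floor -- including the level that the *best* spurious
#' in-sample association among many noise variables reaches. Candidates
#' are ranked by raw permutation importance (mean MSE increase) and
#' selected when it exceeds `max(0, largest decoy importance)`. A decoy
#' ensemble several times larger than the candidate set keeps the
#' family-wise false-selection rate on pure-noise responses low
#' (roughly `1 / (1 + n_decoys)`). `method = "top_k"` instead simply
#' keeps the `k` highest-ranked candidates.
#'
#' @param data Data frame holding response and predictors; rows with
#'   missing values among the used columns are dropped (with a message).
#' @param response Name of the response column (string).
#' @param predictors Character vector of candidate predictor columns;
#'   default: all numeric columns except the response.
#' @param n_trees Number of trees (default 999).
#' @param n_decoys Shuffled decoy copies appended per candidate
#'   (default 10).
#' @param seed Integer seed; the procedure is deterministic given it.
#' @param method `"decoy"` (default) or `"top_k"`.
#' @param k Number kept when `method = "top_k"`.
#' @return Tibble `predictor`, `importance`, `selected`, ranked by
#'   decreasing importance, with the decoy threshold as an attribute.
#' @export
select_predictors <- function(data, response, predictors = NULL,
                              n_trees = 999, n_decoys = 10, seed = 1L,
                              method = c("decoy", "top_k"), k = 5) {
  method <- match.arg(method)
  if (is.null(predictors)) {
    num <- names(data)[vapply(data, is.numeric, logical(1))]
    predictors <- setdiff(num, response)
  }
  used <- data[c(response, predictors)]
  ok <- complete.cases(used)
  if (!all(ok)) {
    inform(paste0("Dropped ", sum(!ok), " row(s) with missing values."))
    used <- used[ok, ]
  }
  if (nrow(used) < 30) abort("Need at least 30 complete rows.")
  y <- used[[response]]
  X <- as.data.frame(used[predictors])
  if (length(predictors) < 2) {
    return(tibble(predictor = predictors, importance = NA_real_,
                  selected = TRUE))
  }
  set.seed(seed)
  dec <- do.call(cbind, lapply(seq_len(n_decoys), function(r) {
    d <- as.data.frame(lapply(X, sample))
    names(d) <- paste0(".decoy", r, "_", names(X))
    d
  }))
  rf <- randomForest::randomForest(x = cbind(X, dec), y = y,
                                   ntree = n_trees, importance = TRUE)
  imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  thr <- max(0, imp[names(dec)])
  out <- tibble(predictor = predictors,
                importance = as.numeric(imp[predictors])) |>
    dplyr::arrange(dplyr::desc(.data$importance))
  out$selected <- if (method == "decoy") out$importance > thr else
    seq_len(nrow(out)) <= k
  attr(out, "decoy_threshold") <- thr
  attr(out, "n") <- nrow(used)
  out
}

#' Fit per-predictor quadratic response models
#'
#' Each selected predictor is standardized (mean 0, SD 1) and the response
#' regressed on it with linear and quadratic terms:
#' `y = b0 + b1 x + b2 x^2`. Per-predictor variance explained is the
#' model R-squared in percent; a combined additive model over all selected
#' predictors' linear + quadratic terms gives the combined R-squared.
#' Response shapes are classified with [classify_shape()] over the
#' predictor's observed 5th-95th percentile range.
#'
#' @param data Data frame holding response and predictors.
#' @param response Name of the response column.
#' @param predictors Character vector of selected predictors (non-empty).
#' @param importance Optional named importance scores carried into the
#'   result.
#' @return A `niche_model` object; see [tidy.niche_model()] and
#'   [glance.niche_model()].
#' @export
fit_quadratic_model <- function(data, response, predictors,
                                importance = NULL) {
  if (!length(predictors)) abort("`predictors` must be non-empty.")
  used <- data[c(response, predictors)]
  used <- used[complete.cases(used), ]
  y <- used[[response]]
  y_const <- sd(y) == 0
  per <- purrr::map_dfr(predictors, function(p) {
    x_raw <- used[[p]]
    if (sd(x_raw) == 0 || y_const) {
      return(tibble(predictor = p, b0 = mean(y), b1 = 0, b2 = 0,
                    r2 = 0, vertex = NA_real_, shape = "flat",
                    p_linear = NA_real_, p_quadratic = NA_real_))
    }
    x <- as.numeric(scale(x_raw))
    fit <- lm(y ~ x + I(x^2))
    cf <- coef(fit)
    sm <- summary(fit)
    ct <- sm$coefficients
    p_lin <- if ("x" %in% rownames(ct)) ct["x", 4] else NA_real_
    p_quad <- if ("I(x^2)" %in% rownames(ct)) ct["I(x^2)", 4] else NA_real_
    b1 <- unname(cf["x"] %||% 0)
    b2 <- unname(cf["I(x^2)"] %||% 0)
    if (is.na(b2)) { b2 <- 0; p_quad <- NA_real_; warn(
      paste0("Collinear quadratic term dropped for '", p, "'.")) }
    if (is.na(b1)) { b1 <- 0; p_lin <- NA_real_ }
    q <- quantile(x, c(0.05, 0.95), names = FALSE)
    shape <- classify_shape(b1, b2, p_lin, p_quad, q[1], q[2])
    vertex_std <- if (b2 != 0) -b1 / (2 * b2) else NA_real_
    # vertex back on the predictor's original scale
    vertex <- if (is.na(vertex_std)) NA_real_ else
      vertex_std * sd(x_raw) + mean(x_raw)
    tibble(predictor = p, b0 = unname(cf[1]), b1 = b1, b2 = b2,
           r2 = 100 * sm$r.squared, vertex = vertex, shape = shape,
           p_linear = p_lin, p_quadratic = p_quad)
  })
  if (!is.null(importance)) {
    per$importance <- as.numeric(importance[per$predictor])
  }
  Xs <- as.data.frame(lapply(used[predictors], function(v) {
    if (sd(v) == 0) v else as.numeric(scale(v))
  }))
  names(Xs) <- paste0("x", seq_along(predictors))
  terms <- paste(unlist(lapply(names(Xs), function(nm)
    c(nm, paste0("I(", nm, "^2)")))), collapse = " + ")
  comb_r2 <- if (y_const) 0 else {
    comb <- lm(stats::as.formula(paste("y ~", terms)),
               data = cbind(y = y, Xs))
    100 * summary(comb)$r.squared
  }
  structure(list(response = response, terms = per, combined_r2 = comb_r2,
                 n = nrow(used)),
            class = "niche_model")
}

#' Classify the shape of a quadratic response
#'
#' Encodes the directionality classes used to summarise niche models: if
#' the quadratic term is not significant (p >= 0.05), the shape is
#' `positive` or `negative` by the sign of a significant linear term, else
#' `flat`. With a significant negative quadratic term the fit is
#' `unimodal` when the vertex lies inside the observed 5th-95th percentile
#' range, `saturating` (rise then plateau) when the vertex lies above the
#' 95th percentile, and `negative` when it lies below the 5th. With a
#' significant positive quadratic term the mirror logic yields `U`,
#' `negative` and `positive` respectively.
#'
#' @param b1,b2 Linear and quadratic coefficients (standardized
#'   predictor).
#' @param p_linear,p_quadratic Their t-test p-values.
#' @param p5,p95 Observed 5th and 95th percentiles of the (standardized)
#'   predictor.
#' @param alpha Significance level (default 0.05).
#' @return One of `"positive"`, `"negative"`, `"unimodal"`, `"U"`,
#'   `"saturating"`, `"flat"`.
#' @export
classify_shape <- function(b1, b2, p_linear, p_quadratic, p5, p95,
                           alpha = 0.05) {
  sig_q <- !is.na(p_quadratic) && p_quadratic < alpha
  sig_l <- !is.na(p_linear) && p_linear < alpha
  if (!sig_q) {
    if (sig_l) return(if (b1 > 0) "positive" else "negative")
    return("flat")
  }
  vertex <- -b1 / (2 * b2)
  if (b2 < 0) {
    if (vertex >= p5 && vertex <= p95) return("unimodal")
    if (vertex > p95) return("saturating")
    return("negative")
  }
  if (vertex >= p5 && vertex <= p95) return("U")
  if (vertex < p5) return("positive")
  "negative"
}

#' Select predictors and fit the quadratic niche model in one step
#'
#' @inheritParams select_predictors
#' @return A `niche_model`, or `NULL` (with a message) when no predictor
#'   survives selection.
#' @export
niche_model <- function(data, response, predictors = NULL, n_trees = 999,
                        n_decoys = 10, seed = 1L,
                        method = c("decoy", "top_k"), k = 5) {
  sel <- select_predictors(data, response, predictors, n_trees = n_trees,
                           n_decoys = n_decoys, seed = seed,
                           method = method, k = k)
  kept <- sel$predictor[sel$selected]
  if (!length(kept)) {
    inform(paste0("No predictor selected for '", response, "'."))
    return(NULL)
  }
  fit <- fit_quadratic_model(data, response, kept,
                             importance = setNames(sel$importance,
                                                   sel$predictor))
  fit$selection <- sel
  fit
}

#' Niche model for one OTU's relative abundance
#'
#' The response is the anchored log-ratio of the OTU's within-sample
#' relative abundance in percent ([logratio_pct()]); predictor selection
#' and quadratic fitting proceed as for richness responses. OTUs present
#' in fewer than `min_prevalence` samples are skipped.
#'
#' @param counts Wide OTU tibble (post-QC).
#' @param metadata Sample metadata aligned by `sample_id`.
#' @param otu_id OTU column to model.
#' @param predictors Character vector of metadata predictor columns.
#' @param min_prevalence Minimum number of samples with the OTU present.
#' @inheritParams select_predictors
#' @return A `niche_model`, or `NULL` when skipped.
#' @export
otu_niche_model <- function(counts, metadata, otu_id, predictors,
                            min_prevalence = 20, n_trees = 999,
                            n_decoys = 10, seed = 1L) {
  m <- otu_matrix(counts)
  if (!otu_id %in% colnames(m)) abort(paste0("Unknown OTU: ", otu_id))
  prev <- sum(m[, otu_id] > 0)
  if (prev < min_prevalence) {
    inform(paste0("OTU '", otu_id, "' present in ", prev,
                  " samples (< ", min_prevalence, "); skipped."))
    return(NULL)
  }
  resp <- logratio_pct(100 * m[, otu_id] / rowSums(m))
  df <- dplyr::left_join(tibble(sample_id = rownames(m),
                                .otu_logratio = as.numeric(resp)),
                         metadata, by = "sample_id")
  niche_model(df, ".otu_logratio", predictors, n_trees = n_trees,
              n_decoys = n_decoys, seed = seed)
}

#' @export
print.niche_model <- function(x, ...) {
  cat("Niche model for '", x$response, "' (n = ", x$n, ")\n", sep = "")
  cat("Combined quadratic R2: ", round(x$combined_r2, 1), "%\n", sep = "")
  print(x$terms)
  invisible(x)
}

#' Tidy a niche model
#'
#' @param x A `niche_model`.
#' @param ... Unused.
#' @return One row per predictor: coefficients on the standardized scale,
#'   variance explained (%), the vertex on the original predictor scale,
#'   and the shape class.
#' @method tidy niche_model
#' @export
tidy.niche_model <- function(x, ...) {
  dplyr::mutate(x$terms, response = x$response, .before = 1)
}

#' One-line summary of a niche model
#'
#' @param x A `niche_model`.
#' @param ... Unused.
#' @return Tibble with response name, number of selected predictors,
#'   combined R-squared (%), and n.
#' @method glance niche_model
#' @export
glance.niche_model <- function(x, ...) {
  tibble(response = x$response, n_predictors = nrow(x$terms),
         combined_r2 = x$combined_r2, n = x$n)
}
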
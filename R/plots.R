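# ggplot2 displays for the main result types.

#' Plot rarefied OTU accumulation curves
#'
#' @param curve Output of [rarefaction_curve()] (optionally row-bound over
#'   several groups with a `group` column).
#' @return A ggplot.
#' @export
plot_rarefaction <- function(curve) {
  aes <- if ("sample_id" %in% names(curve)) {
    ggplot2::aes(.data$depth, .data$expected_richness,
                 group = .data$sample_id)
  } else if ("group" %in% names(curve)) {
    ggplot2::aes(.data$depth, .data$expected_richness,
                 colour = .data$group)
  } else {
    ggplot2::aes(.data$depth, .data$expected_richness)
  }
  ggplot2::ggplot(curve, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Reads", y = "Expected OTU richness") +
    ggplot2::theme_minimal()
}

#' Plot per-sample mold profiles
#'
#' Bars of the maximum single-OTU share per mold group, with the flagging
#' thresholds drawn as dashed lines.
#'
#' @param profiles Output of [compute_mold_profiles()].
#' @param thresholds A [qc_thresholds()].
#' @return A ggplot.
#' @export
plot_mold_profiles <- function(profiles, thresholds = qc_thresholds()) {
  lim <- tibble(
    mold_group = c("Mortierellales", "Umbelopsidales", "Pezizomycotina_mold"),
    limit = c(thresholds$mortierellales_max, thresholds$umbelopsidales_max,
              thresholds$pezizomycotina_max))
  ggplot2::ggplot(profiles,
                  ggplot2::aes(.data$sample_id, .data$max_otu_share)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(data = lim,
                        ggplot2::aes(yintercept = .data$limit),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~mold_group, ncol = 1) +
    ggplot2::labs(x = NULL, y = "Max OTU share of sample reads") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot fitted quadratic niche responses
#'
#' One panel per selected predictor, showing the fitted quadratic
#' response over the standardized predictor range with the shape class in
#' the strip label.
#'
#' @param object A `niche_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot niche_model
#' @export
autoplot.niche_model <- function(object, ...) {
  grid <- tidyr::expand_grid(predictor = object$terms$predictor,
                             x = seq(-2, 2, length.out = 101))
  grid <- dplyr::left_join(grid, object$terms, by = "predictor") |>
    dplyr::mutate(y = .data$b0 + .data$b1 * .data$x +
                    .data$b2 * .data$x^2,
                  panel = paste0(.data$predictor, " (", .data$shape, ", ",
                                 round(.data$r2, 1), "%)"))
  ggplot2::ggplot(grid, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "Standardized predictor", y = object$response) +
    ggplot2::theme_minimal()
}

#' Plot an NMDS ordination with fitted environmental vectors
#'
#' @param object An `nmds_fit`.
#' @param vectors Optional output of [envfit_vectors()] drawn as arrows.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nmds_fit
#' @export
autoplot.nmds_fit <- function(object, vectors = NULL, ...) {
  p <- ggplot2::ggplot(object$points,
                       ggplot2::aes(.data$NMDS1, .data$NMDS2)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(caption = paste0("stress = ",
                                   signif(object$stress, 3))) +
    ggplot2::theme_minimal()
  if (!is.null(vectors)) {
    sc <- 0.9 * max(abs(as.matrix(
      object$points[c("NMDS1", "NMDS2")])))
    p <- p +
      ggplot2::geom_segment(
        data = vectors,
        ggplot2::aes(x = 0, y = 0, xend = sc * sqrt(.data$r2) * .data$NMDS1,
                     yend = sc * sqrt(.data$r2) * .data$NMDS2),
        arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
        colour = "firebrick") +
      ggplot2::geom_text(
        data = vectors,
        ggplot2::aes(x = 1.05 * sc * sqrt(.data$r2) * .data$NMDS1,
                     y = 1.05 * sc * sqrt(.data$r2) * .data$NMDS2,
                     label = .data$variable),
        colour = "firebrick", size = 3)
  }
  p
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
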
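#' Tidy a multilevel foveal-curvature fit
#'
#' @param x A `fovea_fit` from [fit_multilevel()] or [linear_trend_test()].
#' @param ... Unused.
#' @return A tibble with one row per fixed-effect term: `term`, `estimate`
#'   (SD change in foveal curvature per stated increment), `std_error`, `df`
#'   (Satterthwaite), `statistic`, `p_value`, `ci_low`, `ci_high`, plus
#'   `model` and `stratum` identifiers.
#' @export
tidy.fovea_fit <- function(x, ...) {
  dplyr::mutate(x$coefs, model = x$spec$model_id, stratum = x$spec$stratum,
                .before = 1)
}

#' @rdname tidy.fovea_fit
#' @return For `glance()`: a one-row tibble with the variance components,
#'   sample sizes and convergence flags.
#' @export
glance.fovea_fit <- function(x, ...) {
  tibble::tibble(model = x$spec$model_id, stratum = x$spec$stratum,
                 sd_person = x$sd_person, sd_residual = x$sd_residual,
                 icc = x$sd_person^2 / (x$sd_person^2 + x$sd_residual^2),
                 n_eyes = x$n_eyes, n_persons = x$n_persons,
                 converged = x$converged, singular = x$singular)
}

#' Forest plot of a fitted model's coefficients
#'
#' @param object A `fovea_fit`.
#' @param drop_intercept Drop the intercept row? Default `TRUE`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fovea_fit <- function(object, drop_intercept = TRUE, ...) {
  d <- tidy(object)
  if (drop_intercept) d <- dplyr::filter(d, .data$term != "(Intercept)")
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(
      x = "SD change in foveal curvature (95% CI)", y = NULL,
      title = sprintf("Model %d, %s stratum (%d eyes / %d persons)",
                      object$spec$model_id, object$spec$stratum,
                      object$n_eyes, object$n_persons)) +
    ggplot2::theme_minimal()
}

#' Plot one B-scan with its segmented boundaries
#'
#' @param object An `oct_segmentation` from [astar_segment()].
#' @param bscan Optional intensity matrix to show underneath the traces.
#' @param ... Unused.
#' @return A ggplot (y-axis reversed: rows increase downward, as acquired).
#' @export
autoplot.oct_segmentation <- function(object, bscan = NULL, ...) {
  W <- ncol(object$mask)
  traces <- dplyr::bind_rows(
    tibble::tibble(column = seq_len(W), row = object$ilm, surface = "ILM"),
    tibble::tibble(column = seq_len(W), row = object$rpe, surface = "RPE"))
  p <- ggplot2::ggplot()
  if (!is.null(bscan)) {
    img <- tibble::tibble(
      column = rep(seq_len(ncol(bscan)), each = nrow(bscan)),
      row = rep(seq_len(nrow(bscan)), ncol(bscan)),
      intensity = as.vector(bscan))
    p <- p + ggplot2::geom_raster(
      data = img, ggplot2::aes(x = .data$column, y = .data$row,
                               fill = .data$intensity)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none")
  }
  p + ggplot2::geom_line(
      data = traces,
      ggplot2::aes(x = .data$column, y = .data$row, colour = .data$surface)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "A-scan (column)", y = "depth (row)",
                  subtitle = paste("qc:", object$qc)) +
    ggplot2::theme_minimal()
}

#' Thickness-map plot of a segmented volume
#'
#' @param seg An `oct_volume_segmentation` from [segment_volume()].
#' @param center Optional [locate_fovea_center()] result to mark.
#' @return A ggplot of the slice-by-column retinal thickness map.
#' @export
plot_thickness_map <- function(seg, center = NULL) {
  stopifnot(inherits(seg, "oct_volume_segmentation"))
  thick <- seg$rpe - seg$ilm
  d <- tibble::tibble(
    slice = rep(seq_len(nrow(thick)), ncol(thick)),
    column = rep(seq_len(ncol(thick)), each = nrow(thick)),
    thickness = as.vector(thick))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$column, y = .data$slice,
                                       fill = .data$thickness)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "thickness (px)") +
    ggplot2::labs(x = "A-scan (column)", y = "B-scan (slice)") +
    ggplot2::theme_minimal()
  if (!is.null(center))
    p <- p + ggplot2::annotate("point", x = center$column, y = center$slice,
                               colour = "red", shape = 3, size = 3)
  p
}
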
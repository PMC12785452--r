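# ggplot2 views of the result objects (diagnostic graphics, not analysis).

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Kaplan-Meier step curves
#'
#' @param object a `morpho_km`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.morpho_km <- function(object, ...) {
  cv <- dplyr::bind_rows(
    dplyr::transmute(
      dplyr::distinct(object$curves, .data$group),
      group = .data$group, time = 0, surv = 1),
    object$curves[, c("group", "time", "surv")])
  ggplot2::ggplot(cv, ggplot2::aes(.data$time, .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "days", y = "survival fraction",
                  colour = "attractor") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Cluster-validity indices across K
#'
#' @param object a `morpho_kscan`.
#' @param ... unused.
#' @return a ggplot (one panel per index).
#' @export
autoplot.morpho_kscan <- function(object, ...) {
  long <- tidyr::pivot_longer(object$indices, -"k",
                              names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$k, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected_k, linetype = 2) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Null distribution of the permuted silhouette
#'
#' @param object a `morpho_permtest`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.morpho_permtest <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$silhouette)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = object$observed_silhouette,
                        colour = "red") +
    ggplot2::labs(x = "null silhouette",
                  subtitle = sprintf("observed = %.3f, p = %.4g",
                                     object$observed_silhouette,
                                     object$p_value)) +
    ggplot2::theme_minimal()
}

#' Attractor basins in the PCA plane
#'
#' @param tbl embedding table.
#' @param model an `attractor_model`.
#' @return a ggplot of cases in PC1/PC2 coloured by attractor.
#' @export
plot_attractors <- function(tbl, model) {
  pc <- pca_diagnostics(tbl)
  df <- tibble::tibble(PC1 = pc$scores[, 1], PC2 = pc$scores[, 2],
                       attractor = factor(model$labels))
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data$attractor)) +
    ggplot2::geom_point() +
    ggplot2::theme_minimal()
}

#' Central-slice heat map of a sensitivity map
#'
#' @param object a `sensitivity_maps`.
#' @param field `"shift_heat"`, `"flip_heat"` or `"hit"`.
#' @param slice axial slice index (default: middle).
#' @param ... unused.
#' @return a ggplot raster.
#' @export
autoplot.sensitivity_maps <- function(object,
                                      field = c("shift_heat", "flip_heat",
                                                "hit"),
                                      slice = NULL, ...) {
  field <- match.arg(field)
  m <- object[[field]]
  if (is.null(slice)) slice <- dim(m)[3] %/% 2L
  sl <- m[, , slice]
  df <- expand.grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = paste(field, "slice", slice)) +
    ggplot2::theme_minimal()
}

#' Dynamic-attractor endpoints in their own PCA plane
#'
#' @param object a `dynamic_attractors`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dynamic_attractors <- function(object, ...) {
  ok <- !is.na(object$labels)
  pc <- stats::prcomp(object$endpoints[ok, , drop = FALSE])
  df <- tibble::tibble(PC1 = pc$x[, 1], PC2 = pc$x[, 2],
                       attr_dynamic = factor(object$labels[ok]),
                       converged = object$converged[ok])
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data$attr_dynamic,
                                   shape = .data$converged)) +
    ggplot2::geom_point() +
    ggplot2::theme_minimal()
}

#' Explained-variance curve of the latent PCA
#'
#' @param pca a [pca_diagnostics()] result.
#' @return a ggplot of the cumulative explained variance.
#' @export
plot_explained_variance <- function(pca) {
  ggplot2::ggplot(pca$explained,
                  ggplot2::aes(.data$component, .data$cumulative)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "cumulative explained variance") +
    ggplot2::theme_minimal()
}
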
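#' Plot a slice of a volume or fraction map
#'
#' A single axial (or other axis) slice as a ggplot raster, in world mm
#' coordinates.
#'
#' @param volume A [qct_volume()].
#' @param slice Slice index along `axis` (default: middle).
#' @param axis Slicing axis, 1-3.
#' @return A ggplot.
#' @export
plot_slice <- function(volume, slice = NULL, axis = 3L) {
  a <- as_array(volume)
  dm <- dim(a)
  if (is.null(slice)) slice <- ceiling(dm[axis] / 2)
  sl <- switch(axis, a[slice, , ], a[, slice, ], a[, , slice])
  sp <- if (inherits(volume, "qct_volume")) volume$spacing else c(1, 1, 1)
  ax <- setdiff(1:3, axis)
  df <- tidyr::expand_grid(j = (seq_len(ncol(sl)) - 1) * sp[ax[2]],
                           i = (seq_len(nrow(sl)) - 1) * sp[ax[1]])
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "mm", y = "mm", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot phantom_bundle
#' @export
autoplot.phantom_bundle <- function(object, slice = NULL, ...) {
  dm <- dim(object$tlc_volume)
  if (is.null(slice)) slice <- ceiling(dm[3] / 2)
  sp <- object$tlc_volume$spacing
  one <- function(v, label) {
    sl <- as_array(v)[, , slice]
    df <- tidyr::expand_grid(y = (seq_len(dm[2]) - 1) * sp[2],
                             x = (seq_len(dm[1]) - 1) * sp[1])
    df$hu <- as.vector(sl)
    df$scan <- label
    df
  }
  df <- dplyr::bind_rows(one(object$tlc_volume, "inspiration (TLC)"),
                         one(object$exp_volume, "expiration"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$hu)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~scan) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(-1000, 100)) +
    ggplot2::labs(x = "mm", y = "mm", fill = "HU") +
    ggplot2::theme_minimal()
}

#' @method autoplot qct_comparison
#' @export
autoplot.qct_comparison <- function(object, variables = NULL, ...) {
  s <- object$summaries
  s <- s[s$region != "demographics", ]
  if (!is.null(variables)) s <- s[s$variable %in% variables, ]
  region_order <- c(airway_regions(), lobe_labels(), "whole")
  s$region <- factor(s$region, levels = intersect(region_order,
                                                  unique(s$region)))
  s$group <- factor(s$group, levels = cohort_groups())
  ggplot2::ggplot(s, ggplot2::aes(x = .data$region, y = .data$mean,
                                  colour = .data$group)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$ci_half,
                   ymax = .data$mean + .data$ci_half),
      width = 0.3, position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~variable, scales = "free") +
    ggplot2::labs(x = NULL, y = "group mean (±95% CI)", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
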
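#' Plot a spatial profile
#'
#' @param object a `cotune_profile` (from [radial_profile()] or the
#'   feedforward profile functions).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cotune_profile <- function(object, ...) {
  pos <- if ("r" %in% names(object)) "r" else "x"
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[pos]], y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = paste0(pos, " (um)"), y = "value") +
    ggplot2::theme_minimal()
}

#' Spike raster arranged by radial distance
#'
#' Each spike is drawn at its cell's radial distance from the stimulus
#' center, the standard presentation of sheet activity.
#'
#' @param record a `sim_record`.
#' @param pop population to draw.
#' @return a ggplot.
#' @export
plot_raster <- function(record, pop = "P") {
  stopifnot(inherits(record, "sim_record"))
  df <- record$spikes[record$spikes$pop == pop, ]
  df$r <- sqrt((df$x - record$center[1])^2 + (df$y - record$center[2])^2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$r)) +
    ggplot2::geom_point(size = 0.1, alpha = 0.4) +
    ggplot2::labs(x = "time (ms)", y = "radial distance (um)",
                  title = paste0(pop, " cell raster")) +
    ggplot2::theme_minimal()
}

#' Plot a post-stimulus time histogram
#'
#' @param hist a [psth()] tibble.
#' @return a ggplot.
#' @export
plot_psth <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$t, y = .data$count)) +
    ggplot2::geom_col(width = diff(hist$t[1:2]) * 0.9) +
    ggplot2::labs(x = "time (ms)", y = "spikes / bin / sweep") +
    ggplot2::theme_minimal()
}

#' Plot a width-ratio or mean-rate surface
#'
#' Raster of a surface over the (input strength, input width) plane with the
#' co-tuning (`ratio = 1`) contour overlaid when available.
#'
#' @param surface a [ff_surface()] or [rate_surfaces()] tibble.
#' @param z column to draw (`"ratio"`, `"mean_rate"`, ...).
#' @return a ggplot.
#' @export
plot_surface <- function(surface, z = "ratio") {
  icol <- intersect(c("i_max_norm", "n_max"), names(surface))[1]
  scol <- intersect(c("sigma_norm", "sigma"), names(surface))[1]
  p <- ggplot2::ggplot(surface,
                       ggplot2::aes(x = .data[[scol]], y = .data[[icol]],
                                    fill = .data[[z]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme_minimal()
  if (z == "ratio" || "ratio" %in% names(surface)) {
    ct <- cotuning_contour(surface)
    if (nrow(ct)) {
      p <- p + ggplot2::geom_path(
        data = ct, ggplot2::aes(x = .data[[scol]], y = .data[[icol]]),
        inherit.aes = FALSE, color = "purple")
    }
  }
  p
}

#' Plot a rate-versus-intensity curve
#'
#' @param response an [intensity_response()] result.
#' @return a ggplot.
#' @export
plot_intensity_response <- function(response) {
  ggplot2::ggplot(response$curve,
                  ggplot2::aes(x = .data$intensity, y = .data$rate)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "stimulus intensity", y = "mean rate (Hz)",
                  subtitle = response$class) +
    ggplot2::theme_minimal()
}
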
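#' Plot a labelled point pattern
#'
#' Cases are drawn as red dots and controls as blue dots, with the window
#' outline; an optional exposure source is marked with a black cross.
#'
#' @param pattern A [point_pattern].
#' @param source Optional length-2 coordinates of the exposure point source.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_pattern <- function(pattern, source = NULL, title = NULL) {
  stopifnot(inherits(pattern, "point_pattern"))
  w <- pattern_window(pattern)
  df <- as.data.frame(pattern)
  p <- ggplot2::ggplot() +
    window_layer(w) +
    ggplot2::geom_point(
      data = df,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$group),
      size = 1) +
    ggplot2::scale_colour_manual(
      values = c(case = "red", control = "blue"), drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, colour = NULL) +
    ggplot2::theme_minimal()
  add_source(p, source)
}

#' Plot a power surface
#'
#' Two-class map of the sufficiently powered region: knots at or above the
#' power threshold are green, evaluable knots below it blue; knots outside
#' the window (or never evaluable) are blank.
#'
#' @param psurf A `power_surface`.
#' @param source Optional exposure-source coordinates (black cross).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_power <- function(psurf, source = NULL, title = NULL) {
  stopifnot(inherits(psurf, "power_surface"))
  df <- surface_df(psurf$grid, psurf$power)
  df$class <- factor(ifelse(df$value >= psurf$threshold,
                            "sufficiently powered", "insufficiently powered"),
                     levels = c("sufficiently powered",
                                "insufficiently powered"))
  df <- df[!is.na(df$value), , drop = FALSE]
  if (!nrow(df)) warning("power surface is entirely non-evaluable")
  p <- ggplot2::ggplot() +
    ggplot2::geom_tile(
      data = df,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$class),
      width = psurf$grid$xstep, height = psurf$grid$ystep) +
    ggplot2::scale_fill_manual(
      values = c("sufficiently powered" = "#2e8b57",
                 "insufficiently powered" = "#4169e1"), drop = FALSE) +
    window_layer(psurf$grid$window) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, fill = NULL) +
    ggplot2::theme_minimal()
  add_source(p, source)
}

#' Plot a risk-surface band
#'
#' Continuous map of one band of a tested risk surface (log relative risk
#' by default, or its z-score / p-value).
#'
#' @param risk A `risk_surface`.
#' @param band One of `"rho"`, `"zscore"`, `"pvalue"`, `"se"`.
#' @param source Optional exposure-source coordinates.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_risk <- function(risk, band = c("rho", "zscore", "pvalue", "se"),
                      source = NULL, title = NULL) {
  stopifnot(inherits(risk, "risk_surface"))
  band <- match.arg(band)
  vals <- risk[[band]]
  if (is.null(vals)) stop("band '", band, "' not computed", call. = FALSE)
  df <- surface_df(risk$grid, vals)
  df <- df[!is.na(df$value), , drop = FALSE]
  if (!nrow(df)) warning("risk surface is entirely non-evaluable")
  p <- ggplot2::ggplot() +
    ggplot2::geom_tile(
      data = df,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value),
      width = risk$grid$xstep, height = risk$grid$ystep) +
    ggplot2::scale_fill_viridis_c(name = band) +
    window_layer(risk$grid$window) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title) +
    ggplot2::theme_minimal()
  add_source(p, source)
}

#' Save a plot as PNG
#'
#' @param plot A ggplot object.
#' @param path Output path.
#' @param width,height,dpi Image size in inches and resolution.
#' @return The path, invisibly.
#' @export
save_plot_png <- function(plot, path, width = 6, height = 6, dpi = 150) {
  grDevices::png(path, width = width * dpi, height = height * dpi, res = dpi,
                 type = if (capabilities("cairo")) "cairo" else "Xlib")
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}

surface_df <- function(grid, values) {
  data.frame(x = rep(grid$x, times = grid$ny),
             y = rep(grid$y, each = grid$nx),
             value = as.vector(values))
}

window_layer <- function(w) {
  ring_df <- do.call(rbind, lapply(seq_along(w$rings), function(i) {
    r <- w$rings[[i]]
    data.frame(x = c(r[, 1], r[1, 1]), y = c(r[, 2], r[1, 2]), ring = i)
  }))
  ggplot2::geom_path(
    data = ring_df,
    ggplot2::aes(x = .data$x, y = .data$y, group = .data$ring),
    colour = "grey30", linewidth = 0.4)
}

add_source <- function(p, source) {
  if (is.null(source)) return(p)
  p + ggplot2::annotate("point", x = source[1], y = source[2],
                        shape = 4, size = 3, stroke = 1.2, colour = "black")
}
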
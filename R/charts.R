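#' Chart specification for a BMI-for-age graph
#'
#' Holds the layout options of a sex-specific BMI-for-age chart, mimicking
#' the CDC 2000 growth-chart layout: age in years on the x-axis over the
#' 2 to <20 year window, BMI (kg/m^2) on the y-axis with an expanded ceiling
#' (default 60 kg/m^2) so severe obesity is visible.
#'
#' @param sex `"female"` or `"male"` (any accepted code).
#' @param mode `"cross_sectional"` (one point per subject) or
#'   `"longitudinal"` (connected trajectories per subject).
#' @param y_max Upper y-axis limit, kg/m^2; default 60. Configurable for
#'   cohorts whose BMI range is narrower or wider.
#' @param y_min Lower y-axis limit, kg/m^2; default 10 (below the P5 curve's
#'   minimum).
#' @param x_range Age window in years; default `c(2, 20)`.
#' @param output_format `"pdf"` or `"eps"`.
#' @param point_colour,point_size,point_shape,point_alpha Symbol style for
#'   subjects. Keep `point_alpha = 1` for EPS output (the PostScript device
#'   has no semi-transparency).
#' @param curve_colour,curve_linewidth Style for the percentile curves.
#' @param colour_by_id Longitudinal charts only: cycle colours per child
#'   (default) or draw all trajectories in `point_colour` when `FALSE`.
#' @return An object of class `chart_spec`.
#' @export
chart_spec <- function(sex, mode = c("cross_sectional", "longitudinal"),
                       y_max = 60, y_min = 10, x_range = c(2, 20),
                       output_format = c("pdf", "eps"),
                       point_colour = "#2b4c7e", point_size = 1.4,
                       point_shape = 16, point_alpha = 1, curve_colour = "grey35",
                       curve_linewidth = 0.5, colour_by_id = TRUE) {
  mode <- match.arg(mode)
  output_format <- match.arg(output_format)
  stopifnot(is.numeric(y_max), length(y_max) == 1, y_max > y_min,
            is.numeric(x_range), length(x_range) == 2, x_range[1] < x_range[2])
  structure(list(
    sex = normalize_sex(sex), mode = mode, y_max = y_max, y_min = y_min,
    x_range = x_range, output_format = output_format,
    point_colour = point_colour, point_size = point_size,
    point_shape = point_shape, point_alpha = point_alpha,
    curve_colour = curve_colour,
    curve_linewidth = curve_linewidth, colour_by_id = colour_by_id
  ), class = "chart_spec")
}

#' Assemble a BMI-for-age chart scene
#'
#' Builds the chart's scene model — the exact point coordinates, per-child
#' trajectories, and curve arrays that will be drawn — so its content can be
#' inspected and tested without parsing EPS/PDF output. Every plotted point
#' is the subject's `(age_y, bmi_kgm2)` exactly; no jitter.
#'
#' @param results Scored rows for a single sex (from [compute_results()]);
#'   rows without a usable BMI are skipped with a warning.
#' @param curves A [`bmi_curveset`][build_curves] for the same sex.
#' @param spec A [chart_spec()]; its sex must match the data, and its mode
#'   must match [detect_mode()] of the plotted rows.
#' @return Object of class `bmi_chart`: list with `spec`, `points`
#'   (data.frame `id`, `age_y`, `bmi`), `curves` (long data.frame), and
#'   `n_clipped` (points above `y_max`, excluded with a warning, never
#'   silently).
#' @export
bmi_chart <- function(results, curves, spec) {
  stopifnot(inherits(curves, "bmi_curveset"), inherits(spec, "chart_spec"))
  if (nrow(results) == 0) stop("no rows to plot", call. = FALSE)
  sexes <- unique(stats::na.omit(results$sex))
  if (length(sexes) != 1 || sexes != spec$sex) {
    stop("results must contain exactly the spec's sex (", spec$sex, ")",
         call. = FALSE)
  }
  if (curves$sex != spec$sex) stop("curve set is for the wrong sex", call. = FALSE)
  crv <- as.data.frame(curves)
  if (spec$y_max <= max(curves$curves[["P95"]] %||% -Inf)) {
    stop("y_max must exceed the maximum of the P95 curve", call. = FALSE)
  }
  usable <- !is.na(results$bmi_kgm2) & !is.na(results$age_y)
  if (any(!usable)) {
    warning(sum(!usable), " row(s) without usable BMI/age skipped")
  }
  pts <- data.frame(id = results$id[usable], age_y = results$age_y[usable],
                    bmi = results$bmi_kgm2[usable], stringsAsFactors = FALSE)
  mode <- detect_mode(pts$id)
  if (mode != spec$mode) {
    stop("data are ", mode, " but the spec says ", spec$mode, call. = FALSE)
  }
  n_clipped <- sum(pts$bmi > spec$y_max)
  if (n_clipped > 0) {
    warning(n_clipped, " point(s) above y_max = ", spec$y_max,
            " kg/m^2 clipped from the chart")
    pts <- pts[pts$bmi <= spec$y_max, , drop = FALSE]
  }
  if (spec$mode == "longitudinal") {
    pts <- pts[order(pts$id, pts$age_y), , drop = FALSE]
    dup <- stats::ave(pts$age_y, pts$id, FUN = function(a) duplicated(a))
    if (any(dup == 1)) {
      stop("duplicate age within a child's trajectory (id ",
           paste(unique(pts$id[dup == 1]), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  rownames(pts) <- NULL
  structure(list(spec = spec, points = pts, curves = crv,
                 n_clipped = n_clipped),
            class = "bmi_chart")
}

#' @export
print.bmi_chart <- function(x, ...) {
  cat(sprintf("<bmi_chart> %s, %s: %d point(s), %d subject(s), %d curve(s)\n",
              x$spec$sex, x$spec$mode, nrow(x$points),
              length(unique(x$points$id)), length(unique(x$curves$curve))))
  invisible(x)
}

#' @export
plot.bmi_chart <- function(x, ...) {
  spec <- x$spec
  # label curves at the right-hand edge, just past the age window
  ends <- do.call(rbind, lapply(split(x$curves, x$curves$curve), function(d) {
    d[which.max(d$age_y), ]
  }))
  p <- ggplot2::ggplot() +
    ggplot2::geom_line(
      data = x$curves,
      ggplot2::aes(x = age_y, y = bmi, group = curve),
      colour = spec$curve_colour, linewidth = spec$curve_linewidth
    ) +
    ggplot2::geom_text(
      data = ends,
      ggplot2::aes(x = age_y + 0.15, y = bmi, label = curve),
      hjust = 0, size = 2.6, colour = spec$curve_colour
    )
  if (spec$mode == "cross_sectional") {
    p <- p + ggplot2::geom_point(
      data = x$points, ggplot2::aes(x = age_y, y = bmi),
      colour = spec$point_colour, size = spec$point_size,
      shape = spec$point_shape, alpha = spec$point_alpha
    )
  } else if (spec$colour_by_id) {
    p <- p +
      ggplot2::geom_line(
        data = x$points,
        ggplot2::aes(x = age_y, y = bmi, group = id,
                     colour = id),
        linewidth = 0.4, show.legend = FALSE
      ) +
      ggplot2::geom_point(
        data = x$points,
        ggplot2::aes(x = age_y, y = bmi, colour = id),
        shape = 1, size = spec$point_size, show.legend = FALSE
      )
  } else {
    p <- p +
      ggplot2::geom_line(
        data = x$points,
        ggplot2::aes(x = age_y, y = bmi, group = id),
        colour = spec$point_colour, linewidth = 0.4
      ) +
      ggplot2::geom_point(
        data = x$points, ggplot2::aes(x = age_y, y = bmi),
        colour = spec$point_colour, shape = 1, size = spec$point_size
      )
  }
  p +
    ggplot2::scale_x_continuous(
      breaks = seq(spec$x_range[1], spec$x_range[2], by = 1),
      limits = c(spec$x_range[1], spec$x_range[2] + 1.6)
    ) +
    ggplot2::coord_cartesian(ylim = c(spec$y_min, spec$y_max)) +
    ggplot2::labs(
      x = "Age (years)", y = expression(BMI ~ (kg/m^2)),
      title = sprintf("BMI-for-age, %ss (%s)", spec$sex,
                      sub("_", "-", spec$mode))
    ) +
    ggplot2::theme_classic(base_size = 10)
}

#' Render a chart to a vector-graphics file
#'
#' @param chart A [bmi_chart()].
#' @param path Output file; defaults to [default_output_name()] in `dir`.
#'   The extension (`.pdf` or `.eps`) selects the device.
#' @param dir Directory used when `path` is not given.
#' @param width,height Device size in inches.
#' @return The path written, invisibly.
#' @export
render_chart <- function(chart, path = NULL, dir = ".",
                         width = 7, height = 7) {
  stopifnot(inherits(chart, "bmi_chart"))
  if (is.null(path)) {
    path <- file.path(dir, default_output_name(chart$spec$sex,
                                               chart$spec$mode,
                                               chart$spec$output_format))
  }
  ext <- tolower(sub(".*\\.", "", path))
  if (!ext %in% c("pdf", "eps")) {
    stop("unsupported output format: ", ext, " (use pdf or eps)",
         call. = FALSE)
  }
  p <- plot(chart)
  if (ext == "pdf") {
    grDevices::pdf(path, width = width, height = height, onefile = FALSE)
  } else {
    grDevices::postscript(path, width = width, height = height,
                          horizontal = FALSE, onefile = FALSE,
                          paper = "special")
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}

#' Default chart file name
#'
#' Follows the `BMI_Graph_<sex>[_long].<ext>` pattern: e.g.
#' `BMI_Graph_females.pdf` for a female cross-sectional chart and
#' `BMI_Graph_males_long.eps` for a male longitudinal chart.
#'
#' @param sex,mode,format Chart enumerants.
#' @return File name (no directory).
#' @export
default_output_name <- function(sex, mode = c("cross_sectional", "longitudinal"),
                                format = c("pdf", "eps")) {
  sex <- normalize_sex(sex)
  mode <- match.arg(mode)
  format <- match.arg(format)
  sprintf("BMI_Graph_%ss%s.%s", sex,
          if (mode == "longitudinal") "_long" else "", format)
}
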
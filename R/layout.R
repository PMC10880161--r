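#' Style options for nomogram layout and rendering
#'
#' @param width,height Figure size in pixels (SVG/PNG) or 1/96 inch (PDF).
#'   `height = NULL` scales with the number of axis rows.
#' @param font_size Tick-label font size in px.
#' @param axis_color Stroke/label colour.
#' @param tick_target Desired tick count per axis before the nice-step
#'   policy adjusts it.
#' @param show_curve Draw the probability panel (default `TRUE`).
#' @param curve_samples Number of samples of the probability curve.
#' @param dash SVG dash pattern for categorical axes.
#' @return A `nomo_style` list.
#' @export
nomo_style <- function(width = 900, height = NULL, font_size = 11,
                       axis_color = "black", tick_target = 6,
                       show_curve = TRUE, curve_samples = 512,
                       dash = "6,4") {
  structure(list(width = width, height = height, font_size = font_size,
                 axis_color = axis_color, tick_target = tick_target,
                 show_curve = show_curve, curve_samples = curve_samples,
                 dash = dash),
            class = "nomo_style")
}

#' Nice tick values covering an interval
#'
#' Chooses a step from \{1, 2, 2.5, 5\} x 10^k giving between
#' `target_count / 2` and `2 * target_count` ticks over `[lo, hi]`
#' (closest achievable to `target_count`), and always includes both
#' endpoints. A span that is negligible relative to the endpoint
#' magnitudes yields the endpoints alone.
#'
#' @param lo,hi Interval bounds, `hi >= lo`.
#' @param target_count Desired number of ticks (>= 2).
#' @return Sorted numeric vector of tick values from `lo` to `hi`.
#' @examples
#' nice_ticks(0, 100, 11)
#' nice_ticks(0, 1, 6)
#' @export
nice_ticks <- function(lo, hi, target_count = 6) {
  stopifnot(hi >= lo, target_count >= 2)
  span <- hi - lo
  scale <- max(abs(lo), abs(hi), 1e-12)
  if (span <= 1e-12 || span / scale <= 1e-4) {
    return(unique(c(lo, hi)))
  }
  mantissas <- c(1, 2, 2.5, 5)
  k_range <- seq(floor(log10(span / (2 * target_count))),
                 ceiling(log10(span)))
  best <- NULL
  best_score <- Inf
  for (k in k_range) {
    for (m in mantissas) {
      step <- m * 10^k
      first <- ceiling(lo / step - 1e-9) * step
      if (first > hi + step * 1e-9) next
      inner <- seq(first, hi + step * 1e-9, by = step)
      inner <- inner[inner >= lo - step * 1e-9 & inner <= hi + step * 1e-9]
      ticks <- sort(c(lo, inner, hi))
      ticks <- ticks[c(TRUE, diff(ticks) > step * 1e-6)]
      n <- length(ticks)
      if (n < target_count / 2 || n > 2 * target_count) next
      score <- abs(n - target_count)
      if (score < best_score ||
          (score == best_score && !is.null(best) && n < length(best))) {
        best <- ticks
        best_score <- score
      }
    }
  }
  if (is.null(best)) unique(c(lo, hi)) else best
}

#' Compute nomogram geometry
#'
#' Lays out the chart in normalized coordinates: a points ruler spanning
#' `0..p_max` on top, one axis per predictor below it (one-hot levels of a
#' nominal variable merged onto a single axis, each level labelled at its
#' own point position), then the total-points ruler `0..total_max_points`
#' and the evenly scaled probability panel. Points on the shared ruler map
#' to horizontal position `points / p_max`; the total ruler has its own
#' scale `total / total_max_points`. Predictor tick labels are *values*,
#' placed at their point positions, on the side requested by each row's
#' `position`. The decision threshold, when present and attainable, gets a
#' vertical marker through the total ruler and the panel.
#'
#' @param model,scales,pm Model, scales and probability map, mutually
#'   consistent (as assembled by [nomogram()]).
#' @param style A [nomo_style()].
#' @return A `nomo_geometry` list: `axes` (tibble with columns `kind`,
#'   `name`, `style`, `label_side`, `row`, `x0`, `x1` and a `ticks`
#'   list-column of `(x, label, value)` tibbles), `curve`, `prob_ticks`,
#'   `threshold_x`, `threshold`, `p_max`, `total_max_points`, `style`.
#' @export
compute_layout <- function(model, scales, pm, style = nomo_style()) {
  p_max <- attr(scales, "p_max")
  tick_target <- style$tick_target

  points_ticks <- ruler_ticks(0, p_max, p_max, tick_target)
  axis_rows <- list(tibble::tibble(
    kind = "points_ruler", name = "Points", style = "solid",
    label_side = "up", x0 = 0, x1 = 1,
    ticks = list(points_ticks)
  ))

  done_groups <- character()
  for (i in seq_len(nrow(scales))) {
    grp <- scales$group[i]
    if (!is.na(grp)) {
      if (grp %in% done_groups) next
      done_groups <- c(done_groups, grp)
      members <- which(!is.na(scales$group) & scales$group == grp)
      ticks <- tibble::tibble(
        value = 1,
        x = scales$max_points[members] / p_max,
        label = sub("^.*::", "", scales$feature[members])
      )[, c("x", "label", "value")]
      axis_rows <- c(axis_rows, list(tibble::tibble(
        kind = "predictor", name = grp, style = "dashed",
        label_side = scales$position[members[1]],
        x0 = 0, x1 = max(scales$max_points[members]) / p_max,
        ticks = list(ticks)
      )))
    } else {
      axis_rows <- c(axis_rows, list(predictor_axis(scales, i, p_max,
                                                    tick_target)))
    }
  }

  total_ticks <- ruler_ticks(0, pm$total_max_points, pm$total_max_points,
                             tick_target + 2)
  axis_rows <- c(axis_rows, list(tibble::tibble(
    kind = "total_ruler", name = "Total points", style = "solid",
    label_side = "down", x0 = 0, x1 = 1,
    ticks = list(total_ticks)
  )))
  axis_rows <- c(axis_rows, list(tibble::tibble(
    kind = "probability_panel", name = "Probability", style = "solid",
    label_side = "down", x0 = 0, x1 = 1,
    ticks = list(tibble::tibble(x = numeric(), label = character(),
                                value = numeric()))
  )))
  axes <- dplyr::bind_rows(axis_rows)
  axes$row <- seq_len(nrow(axes))

  curve <- probability_curve(pm, style$curve_samples)
  curve$x <- curve$total_points / pm$total_max_points

  thr <- model_threshold(model)
  threshold_x <- NULL
  if (!is.null(thr)) {
    lo <- sigmoid(pm$min_value); hi <- sigmoid(pm$max_value)
    if (thr >= lo && thr <= hi) {
      threshold_x <- probability_to_total_points(pm, thr) /
        pm$total_max_points
    } else {
      warning("threshold ", thr, " is not attainable over the predictor ",
              "box; marker omitted", call. = FALSE)
    }
  }

  structure(
    list(axes = axes, curve = curve,
         prob_ticks = tibble::tibble(probability = seq(0, 1, by = 0.2)),
         threshold_x = threshold_x, threshold = thr,
         p_max = p_max, total_max_points = pm$total_max_points,
         style = style),
    class = "nomo_geometry"
  )
}

ruler_ticks <- function(lo, hi, denom, target) {
  vals <- nice_ticks(lo, hi, target)
  tibble::tibble(x = vals / denom, label = fmt_num(vals), value = vals)
}

predictor_axis <- function(scales, i, p_max, target) {
  sc <- scales[i, ]
  vals <- if (sc$type == "continuous") {
    nice_ticks(sc$min, sc$max, target)
  } else {
    lv <- seq(ceiling(sc$min), floor(sc$max))
    if (length(lv) >= 2 && length(lv) <= 25) {
      unique(sort(c(sc$min, lv, sc$max)))
    } else {
      nice_ticks(sc$min, sc$max, target)
    }
  }
  if (sc$max_points > 0) {
    pts <- value_axis_points(sc, vals)
    ticks <- tibble::tibble(x = pts / p_max, label = fmt_num(vals),
                            value = vals)
  } else {
    # uninformative axis: flat line, labelled once at 0
    ticks <- tibble::tibble(x = 0, label = fmt_num(sc$min), value = sc$min)
  }
  tibble::tibble(
    kind = "predictor", name = sc$feature,
    style = ifelse(sc$type == "continuous", "solid", "dashed"),
    label_side = sc$position,
    x0 = 0, x1 = sc$max_points / p_max,
    ticks = list(ticks)
  )
}

value_axis_points <- function(sc, vals) {
  pts <- sc$slope * vals + sc$offset
  pmin(pmax(pts, 0), sc$max_points)
}

fmt_num <- function(x) trimws(formatC(x, format = "g", digits = 8))

#' Render a nomogram to a figure file
#'
#' SVG output is written as structured XML: each axis is a `<g>` element
#' classed by kind and line style (`axis predictor dashed`, ...), the
#' probability curve a `<polyline class="probability-curve">`, the
#' threshold a classed marker line — so the drawing can be inspected
#' programmatically. PNG and PDF are rendered from the ggplot2 figure
#' returned by [autoplot.nomogram()].
#'
#' @param nomo A [nomogram()] (or a bare `nomo_geometry`).
#' @param path Output file; format inferred from the extension unless
#'   `format` is given.
#' @param format `"svg"`, `"png"`, or `"pdf"`.
#' @return `path`, invisibly.
#' @export
render_nomogram <- function(nomo, path,
                            format = c("auto", "svg", "png", "pdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("svg", "png", "pdf")) {
      stop("cannot infer format from '", path,
           "'; use format = \"svg\"/\"png\"/\"pdf\"", call. = FALSE)
    }
  }
  geom <- if (inherits(nomo, "nomogram")) nomo$geometry else nomo
  stopifnot(inherits(geom, "nomo_geometry"))
  if (format == "svg") {
    write_svg_nomogram(geom, path)
  } else {
    if (!inherits(nomo, "nomogram")) {
      stop("png/pdf rendering needs the full nomogram object", call. = FALSE)
    }
    p <- autoplot.nomogram(nomo)
    w_in <- geom$style$width / 96
    h_in <- svg_height(geom) / 96
    if (format == "png") {
      grDevices::png(path, width = geom$style$width,
                     height = svg_height(geom), res = 96)
    } else {
      grDevices::pdf(path, width = w_in, height = h_in)
    }
    on.exit(grDevices::dev.off())
    print(p)
  }
  invisible(path)
}

ROW_H <- 60
PANEL_ROWS <- 3
MARGIN <- c(left = 150, right = 50, top = 30, bottom = 20)

svg_height <- function(geom) {
  n_slots <- nrow(geom$axes) - 1 + PANEL_ROWS
  MARGIN["top"] + n_slots * ROW_H + MARGIN["bottom"]
}

svg_x <- function(geom, x) {
  MARGIN["left"] + x * (geom$style$width - MARGIN["left"] - MARGIN["right"])
}

svg_y <- function(row) MARGIN["top"] + (row - 0.5) * ROW_H

write_svg_nomogram <- function(geom, path) {
  st <- geom$style
  h <- svg_height(geom)
  doc <- xml2::xml_new_root(
    "svg", xmlns = "http://www.w3.org/2000/svg",
    width = fmt_px(st$width), height = fmt_px(h),
    viewBox = paste(0, 0, st$width, h)
  )
  for (i in seq_len(nrow(geom$axes))) {
    ax <- geom$axes[i, ]
    if (ax$kind == "probability_panel") {
      svg_panel(doc, geom, ax)
    } else {
      svg_axis(doc, geom, ax)
    }
  }
  if (!is.null(geom$threshold_x)) {
    total_row <- geom$axes$row[geom$axes$kind == "total_ruler"]
    x <- svg_x(geom, geom$threshold_x)
    g <- xml2::xml_add_child(doc, "g", class = "threshold-marker")
    xml2::xml_add_child(g, "line",
                        x1 = fmt_px(x), y1 = fmt_px(svg_y(total_row) - 12),
                        x2 = fmt_px(x),
                        y2 = fmt_px(svg_y(total_row) + PANEL_ROWS * ROW_H),
                        stroke = "red", `stroke-dasharray` = "3,3")
    txt <- xml2::xml_add_child(g, "text", x = fmt_px(x + 4),
                               y = fmt_px(svg_y(total_row) - 14),
                               `font-size` = fmt_px(st$font_size),
                               fill = "red")
    xml2::xml_text(txt) <- paste0("threshold = ", fmt_num(geom$threshold))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

svg_axis <- function(doc, geom, ax) {
  st <- geom$style
  y <- svg_y(ax$row)
  g <- xml2::xml_add_child(
    doc, "g", class = paste("axis", ax$kind, ax$style),
    `data-name` = ax$name, `data-row` = as.character(ax$row)
  )
  line <- xml2::xml_add_child(
    g, "line",
    x1 = fmt_px(svg_x(geom, ax$x0)), y1 = fmt_px(y),
    x2 = fmt_px(svg_x(geom, ax$x1)), y2 = fmt_px(y),
    stroke = st$axis_color, `stroke-width` = "1.5"
  )
  if (ax$style == "dashed") {
    xml2::xml_set_attr(line, "stroke-dasharray", st$dash)
  }
  name <- xml2::xml_add_child(g, "text",
                              x = fmt_px(MARGIN["left"] - 10),
                              y = fmt_px(y + st$font_size / 3),
                              `text-anchor` = "end",
                              `font-size` = fmt_px(st$font_size),
                              `font-weight` = "bold")
  xml2::xml_text(name) <- ax$name
  up <- identical(ax$label_side, "up")
  tick_dir <- if (up) -6 else 6
  label_y <- y + if (up) -10 else 10 + st$font_size * 0.8
  ticks <- ax$ticks[[1]]
  for (j in seq_len(nrow(ticks))) {
    x <- svg_x(geom, ticks$x[j])
    xml2::xml_add_child(g, "line", class = "tick",
                        x1 = fmt_px(x), y1 = fmt_px(y),
                        x2 = fmt_px(x), y2 = fmt_px(y + tick_dir),
                        stroke = st$axis_color)
    txt <- xml2::xml_add_child(g, "text", class = "tick-label",
                               x = fmt_px(x), y = fmt_px(label_y),
                               `text-anchor` = "middle",
                               `font-size` = fmt_px(st$font_size))
    xml2::xml_text(txt) <- ticks$label[j]
  }
  g
}

svg_panel <- function(doc, geom, ax) {
  st <- geom$style
  if (!st$show_curve) return(invisible(NULL))
  y_top <- svg_y(ax$row)
  y_bot <- y_top + (PANEL_ROWS - 1) * ROW_H
  g <- xml2::xml_add_child(doc, "g", class = "axis probability_panel solid",
                           `data-name` = ax$name,
                           `data-row` = as.character(ax$row))
  name <- xml2::xml_add_child(g, "text",
                              x = fmt_px(MARGIN["left"] - 10),
                              y = fmt_px((y_top + y_bot) / 2),
                              `text-anchor` = "end",
                              `font-size` = fmt_px(st$font_size),
                              `font-weight` = "bold")
  xml2::xml_text(name) <- ax$name
  # uniform probability gridlines: the panel's y axis is evenly scaled
  for (p in geom$prob_ticks$probability) {
    yy <- y_bot - p * (y_bot - y_top)
    xml2::xml_add_child(g, "line", class = "gridline",
                        x1 = fmt_px(svg_x(geom, 0)), y1 = fmt_px(yy),
                        x2 = fmt_px(svg_x(geom, 1)), y2 = fmt_px(yy),
                        stroke = "#cccccc", `stroke-width` = "0.5")
    lab <- xml2::xml_add_child(g, "text", class = "prob-label",
                               x = fmt_px(svg_x(geom, 0) - 6),
                               y = fmt_px(yy + st$font_size / 3),
                               `text-anchor` = "end",
                               `font-size` = fmt_px(st$font_size * 0.9))
    xml2::xml_text(lab) <- fmt_num(p)
  }
  pts <- paste(fmt_px(svg_x(geom, geom$curve$x)),
               fmt_px(y_bot - geom$curve$probability * (y_bot - y_top)),
               sep = ",", collapse = " ")
  xml2::xml_add_child(g, "polyline", class = "probability-curve",
                      points = pts, fill = "none",
                      stroke = "steelblue", `stroke-width` = "1.5")
  g
}

fmt_px <- function(x) sprintf("%.4f", x)

#' Plot a nomogram with ggplot2
#'
#' Draws the laid-out chart: one horizontal axis per row (dashed for
#' categorical predictors), value labels at their point positions, the
#' total ruler, the evenly scaled probability panel with the sigmoid
#' curve, and the threshold marker when present.
#'
#' @param object A [nomogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nomogram <- function(object, ...) {
  geom <- object$geometry
  axes <- geom$axes
  n_axes <- nrow(axes)
  panel_row <- axes$row[axes$kind == "probability_panel"]

  seg <- dplyr::filter(axes, .data$kind != "probability_panel")
  seg$y <- -seg$row
  ticks <- tidyr::unnest(
    dplyr::select(seg, "name", "row", "label_side", "ticks"),
    "ticks"
  )
  ticks$y <- -ticks$row
  ticks$yend <- ticks$y + ifelse(ticks$label_side == "up", 0.12, -0.12)
  ticks$ylab <- ticks$y + ifelse(ticks$label_side == "up", 0.28, -0.28)

  panel_top <- -panel_row
  panel_bot <- -(panel_row + PANEL_ROWS - 1)
  curve <- geom$curve
  curve$y <- panel_bot + curve$probability * (panel_top - panel_bot)

  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, xend = .data$x1, y = .data$y,
                   yend = .data$y, linetype = .data$style),
      linewidth = 0.6
    ) +
    ggplot2::geom_segment(
      data = ticks,
      ggplot2::aes(x = .data$x, xend = .data$x, y = .data$y,
                   yend = .data$yend),
      linewidth = 0.4
    ) +
    ggplot2::geom_text(
      data = ticks,
      ggplot2::aes(x = .data$x, y = .data$ylab, label = .data$label),
      size = geom$style$font_size / 3.2
    ) +
    ggplot2::geom_text(
      data = dplyr::mutate(seg, ylab = .data$y),
      ggplot2::aes(x = -0.02, y = .data$ylab, label = .data$name),
      hjust = 1, fontface = "bold", size = geom$style$font_size / 3
    ) +
    ggplot2::geom_line(
      data = curve, ggplot2::aes(x = .data$x, y = .data$y),
      colour = "steelblue", linewidth = 0.7
    ) +
    ggplot2::geom_text(
      data = data.frame(y = panel_bot +
                          geom$prob_ticks$probability *
                          (panel_top - panel_bot),
                        label = fmt_num(geom$prob_ticks$probability)),
      ggplot2::aes(x = -0.02, y = .data$y, label = .data$label),
      hjust = 1, size = geom$style$font_size / 3.6
    ) +
    ggplot2::scale_linetype_identity() +
    ggplot2::coord_cartesian(xlim = c(-0.25, 1.05)) +
    ggplot2::theme_void()

  if (!is.null(geom$threshold_x)) {
    total_row <- axes$row[axes$kind == "total_ruler"]
    p <- p + ggplot2::geom_segment(
      data = data.frame(x = geom$threshold_x, y = -total_row + 0.2,
                        yend = panel_bot),
      ggplot2::aes(x = .data$x, xend = .data$x, y = .data$y,
                   yend = .data$yend),
      colour = "red", linetype = "dashed", linewidth = 0.5
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
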
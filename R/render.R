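#' Style configuration for the SVG renderer
#'
#' The notation's visual grammar admits very few stylistic degrees of
#' freedom: a single stroke width shared by every element class (lines may
#' be of arbitrary thickness but proportional for all elements), black
#' strokes only, no fills, a monospace font for layer and region names, and
#' the dash patterns distinguishing dotted (layer/region delimiters) from
#' dashed (unit boxes) strokes.
#'
#' @param stroke_width Single stroke width for all elements.
#' @param font_family_labels Monospace family for layer/region names.
#' @param font_family_population Family for population and unit labels.
#' @param font_size Label font size.
#' @param dash_dotted,dash_dashed `stroke-dasharray` values for the dotted
#'   and dashed line classes.
#' @return An object of class `nns_style`.
#' @export
style_config <- function(stroke_width = 1,
                         font_family_labels = "monospace",
                         font_family_population = "sans-serif",
                         font_size = 12,
                         dash_dotted = "1,3", dash_dashed = "6,3") {
  if (!is.numeric(stroke_width) || length(stroke_width) != 1L || stroke_width <= 0) {
    abort_ns("stroke_width must be a single positive number", "nns_invalid_style")
  }
  structure(list(stroke_width = stroke_width,
                 font_family_labels = font_family_labels,
                 font_family_population = font_family_population,
                 font_size = font_size,
                 dash_dotted = dash_dotted, dash_dashed = dash_dashed),
            class = "nns_style")
}

svg_text_spans <- function(spans, x, y, family, size, anchor = "middle") {
  inner <- paste0(vapply(seq_len(nrow(spans)), function(i) {
    if (spans$style[i] == "italic") {
      sprintf('<tspan font-style="italic">%s</tspan>', xml_escape(spans$text[i]))
    } else {
      sprintf("<tspan>%s</tspan>", xml_escape(spans$text[i]))
    }
  }, ""), collapse = "")
  sprintf('<text x="%s" y="%s" font-family="%s" font-size="%s" text-anchor="%s" fill="black">%s</text>',
          fmt_len(x), fmt_len(y), xml_escape(family), fmt_num(size), anchor, inner)
}

svg_plain_text <- function(txt, x, y, family, size, anchor = "middle") {
  svg_text_spans(data.frame(text = txt, style = "normal"), x, y, family, size,
                 anchor)
}

#' Render a laid-out model to SVG
#'
#' Realizes the notation's visual grammar over a computed layout as an SVG
#' 1.1 document: one solid unfilled rectangle per population; one solid
#' polyline per projection with no arrowhead (direction is already fixed by
#' the side convention); an empty circle tangent to the target edge at the
#' terminus of every inhibitory projection and no terminator on excitatory
#' ones; dotted horizontal layer lines with uppercase roman labels at the
#' schematic's right edge; dotted vertical region delimiters with monospace
#' names above; dashed unit rectangles with their name; population labels
#' typeset per [display_label()] (morphological class in italics); and
#' density labels printed verbatim. Only black strokes on a transparent
#' background. Output is byte-identical across invocations on equal inputs.
#'
#' @param layout An `nns_layout` from [compute_layout()].
#' @param model The `nns_model` the layout was computed for.
#' @param style A [style_config()].
#' @param path Optional file path to also write the document to.
#' @return The SVG document as a single character string.
#' @export
render_svg <- function(layout, model, style = style_config(), path = NULL) {
  stopifnot(inherits(layout, "nns_layout"), inherits(model, "nns_model"))
  for (id in names(layout$population_boxes)) {
    if (!id %in% names(model$populations)) {
      abort_ns(sprintf("layout/model mismatch: box for unknown population '%s'", id),
               "nns_render_error")
    }
  }
  for (id in names(layout$projection_paths)) {
    if (!id %in% names(model$projections)) {
      abort_ns(sprintf("layout/model mismatch: path for unknown projection '%s'", id),
               "nns_render_error")
    }
  }
  sw <- fmt_num(style$stroke_width)
  cv <- layout$canvas
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'width="%s" height="%s" viewBox="%s %s %s %s">'),
            fmt_len(max(cv$w, 1)), fmt_len(max(cv$h, 1)),
            fmt_len(cv$x), fmt_len(cv$y),
            fmt_len(max(cv$w, 1)), fmt_len(max(cv$h, 1))),
    '<g class="nns-canvas">')

  ## layer and region delimiters (dotted)
  ll <- layout$layer_lines
  for (i in seq_len(nrow(ll))) {
    out <- c(out, sprintf(
      '<line class="nns-layer-line" x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="%s" stroke-dasharray="%s"/>',
      fmt_len(ll$x0[i]), fmt_len(ll$y[i]), fmt_len(ll$x1[i]), fmt_len(ll$y[i]),
      sw, style$dash_dotted))
  }
  lb <- layout$layer_labels
  for (i in seq_len(nrow(lb))) {
    out <- c(out, svg_plain_text(lb$layer[i], lb$x[i],
                                 lb$y[i] + style$font_size / 3,
                                 style$font_family_labels, style$font_size,
                                 anchor = "end"))
  }
  rl <- layout$region_lines
  for (i in seq_len(nrow(rl))) {
    out <- c(out, sprintf(
      '<line class="nns-region-line" x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="%s" stroke-dasharray="%s"/>',
      fmt_len(rl$x[i]), fmt_len(rl$y0[i]), fmt_len(rl$x[i]), fmt_len(rl$y1[i]),
      sw, style$dash_dotted))
  }
  rb <- layout$region_labels
  for (i in seq_len(nrow(rb))) {
    if (nzchar(rb$name[i])) {
      out <- c(out, svg_plain_text(rb$name[i], rb$x[i], rb$y[i],
                                   style$font_family_labels, style$font_size))
    }
  }

  ## unit boxes (dashed)
  for (uid in names(layout$unit_boxes)) {
    b <- layout$unit_boxes[[uid]]
    if (b$w <= 0 || b$h <= 0) next
    out <- c(out, sprintf(
      '<rect class="nns-unit" x="%s" y="%s" width="%s" height="%s" fill="none" stroke="black" stroke-width="%s" stroke-dasharray="%s"/>',
      fmt_len(b$x), fmt_len(b$y), fmt_len(b$w), fmt_len(b$h), sw,
      style$dash_dashed))
    out <- c(out, svg_plain_text(model$units[[uid]]$name, b$x + 4,
                                 b$y + style$font_size,
                                 style$font_family_population,
                                 style$font_size * 0.85, anchor = "start"))
  }

  ## projections (solid, no arrowheads) with inhibitory terminators
  tr <- layout$config$terminator_radius %||% 4.5
  for (pid in names(layout$projection_paths)) {
    p <- layout$projection_paths[[pid]]
    pts <- p$points
    pts_txt <- paste(sprintf("%s,%s", vapply(pts[, 1], fmt_len, ""),
                             vapply(pts[, 2], fmt_len, "")), collapse = " ")
    out <- c(out, sprintf(
      '<polyline class="nns-projection" points="%s" fill="none" stroke="black" stroke-width="%s"/>',
      pts_txt, sw))
    if (isTRUE(p$inhibitory)) {
      # empty circle tangent to the target edge at the terminus
      end <- pts[nrow(pts), ]
      prev <- pts[nrow(pts) - 1L, ]
      dirx <- sign(prev[1] - end[1])
      diry <- if (dirx == 0) sign(prev[2] - end[2]) else 0
      if (dirx == 0 && diry == 0) dirx <- -1
      out <- c(out, sprintf(
        '<circle class="nns-terminator" cx="%s" cy="%s" r="%s" fill="none" stroke="black" stroke-width="%s"/>',
        fmt_len(end[1] + dirx * tr), fmt_len(end[2] + diry * tr),
        fmt_len(tr), sw))
    }
  }

  ## population boxes and labels
  for (pid in names(layout$population_boxes)) {
    b <- layout$population_boxes[[pid]]
    out <- c(out, sprintf(
      '<rect class="nns-population" x="%s" y="%s" width="%s" height="%s" fill="none" stroke="black" stroke-width="%s"/>',
      fmt_len(b$x), fmt_len(b$y), fmt_len(b$w), fmt_len(b$h), sw))
    spans <- display_label(model$populations[[pid]]$label)
    out <- c(out, svg_text_spans(spans, b$x + b$w / 2,
                                 b$y + b$h / 2 + style$font_size / 3,
                                 style$font_family_population,
                                 style$font_size))
  }

  ## density labels
  dl <- layout$density_labels
  for (i in seq_len(nrow(dl))) {
    out <- c(out, svg_plain_text(dl$text[i], dl$x[i], dl$y[i],
                                 style$font_family_population,
                                 style$font_size * 0.85))
  }

  out <- c(out, "</g>", "</svg>")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "", useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}
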
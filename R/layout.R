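#' Layout configuration
#'
#' Metric parameters of the automatic layout, in abstract length units (they
#' become SVG user units unchanged). The notation fixes topology conventions
#' only — shapes are of arbitrary size and proportions — so all metrics are
#' tunable; every length must be strictly positive.
#'
#' @param box_min_w,box_min_h Minimum population box size; boxes widen to fit
#'   their label.
#' @param band_gap Vertical clearance between a box and its layer-band
#'   boundary.
#' @param column_gap Horizontal clearance between region strips and between
#'   boxes within a band.
#' @param channel_spacing Spacing between parallel routing tracks.
#' @param unit_margin Margin between a unit box and its members.
#' @param loop_margin Clearance of a self-projection above its box.
#' @param terminator_radius Radius of the inhibitory terminator circle.
#' @param char_width Estimated glyph advance used to size boxes around their
#'   labels (text metrics are character-count heuristics; no font files are
#'   consulted).
#' @return An object of class `nns_layout_config`.
#' @export
layout_config <- function(box_min_w = 60, box_min_h = 30, band_gap = 18,
                          column_gap = 40, channel_spacing = 8,
                          unit_margin = 10, loop_margin = 12,
                          terminator_radius = 4.5, char_width = 8) {
  cfg <- list(box_min_w = box_min_w, box_min_h = box_min_h,
              band_gap = band_gap, column_gap = column_gap,
              channel_spacing = channel_spacing, unit_margin = unit_margin,
              loop_margin = loop_margin, terminator_radius = terminator_radius,
              char_width = char_width)
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      abort_ns(sprintf("layout parameter '%s' must be a strictly positive length", nm),
               "nns_layout_infeasible")
    }
  }
  structure(cfg, class = "nns_layout_config")
}

rect <- function(x, y, w, h) list(x = x, y = y, w = w, h = h)

rects_overlap <- function(a, b) {
  a$x < b$x + b$w && b$x < a$x + a$w && a$y < b$y + b$h && b$y < a$y + a$h
}

# longest-path rank of each population over the cell-internal projection
# graph; sources rank 0, ties later broken by declaration order
longest_path_ranks <- function(ids, edges) {
  rank <- stats::setNames(rep(0L, length(ids)), ids)
  if (nrow(edges)) {
    for (pass in seq_len(length(ids) + 1L)) {
      changed <- FALSE
      for (i in seq_len(nrow(edges))) {
        s <- edges$source[i]; t <- edges$target[i]
        if (s != t && rank[[t]] < rank[[s]] + 1L &&
            rank[[s]] < length(ids)) {  # cap guards cycles
          rank[[t]] <- rank[[s]] + 1L
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  rank
}

#' Compute deterministic 2-D geometry for a model
#'
#' Places population boxes on a grid scaffold — one column per region in
#' display order (plus a trailing column for region-less populations), one
#' horizontal band per cortical layer ordered with the highest layer on top
#' (plus a bottom band for unlayered populations) — and routes every
#' projection orthogonally under the notation's side conventions: internal
#' projections leave the source box's right edge and arrive at the target's
#' left edge, inputs run from the canvas margin to the target's left edge,
#' outputs from the source's right edge to the margin, and self-projections
#' loop over the top of their box. Unit boxes are the bounding rectangles of
#' their members plus a margin. The result is a pure function of the model
#' and configuration.
#'
#' @param model An `nns_model`; it must validate without ERROR findings.
#' @param config A [layout_config()].
#' @return An object of class `nns_layout` with components
#'   `population_boxes` (id -> rect), `projection_paths` (id -> list with a
#'   two-column point `matrix`, `kind`, and terminator flag), `layer_lines`,
#'   `layer_labels`, `region_lines`, `region_labels`, `unit_boxes`,
#'   `density_labels`, `canvas`, and `warnings`.
#' @export
compute_layout <- function(model, config = layout_config()) {
  stopifnot(inherits(model, "nns_model"))
  diags <- validate_model(model)
  if (any(diags$severity == "ERROR")) {
    abort_ns(paste0("cannot lay out an invalid model:\n",
                    paste0("  ", format_diagnostics(diags), collapse = "\n")),
             "nns_validation_error")
  }
  cfg <- config
  pops <- model$populations
  projs <- model$projections
  empty <- list(
    population_boxes = list(), projection_paths = list(),
    layer_lines = empty_df(c("layer", "area", "y", "x0", "x1")),
    layer_labels = empty_df(c("layer", "x", "y")),
    region_lines = empty_df(c("x", "y0", "y1")),
    region_labels = empty_df(c("region", "name", "x", "y")),
    unit_boxes = list(),
    density_labels = empty_df(c("projection", "x", "y", "text")),
    canvas = rect(0, 0, 0, 0), warnings = character())
  if (length(pops) == 0L && length(model$regions) == 0L) {
    return(structure(empty, class = "nns_layout"))
  }

  ## -- grid scaffold --------------------------------------------------
  NOREG <- "\r<no-region>"    # trailing column for region-less populations
  NOLAY <- "\r<unlayered>"    # bottom band for unlayered populations
  regs <- model$regions[order(vapply(model$regions, `[[`, 1L, "display_order"),
                              names(model$regions), method = "radix")]
  col_ids <- vapply(regs, `[[`, "", "id")
  pop_region <- vapply(pops, function(p) p$region_ref %||% NOREG, "")
  if (any(pop_region == NOREG) || length(col_ids) == 0L) col_ids <- c(col_ids, NOREG)
  # rows: union of layer numerals over all areas, highest (smallest) on top
  numerals <- sort(unique(vapply(model$layers, `[[`, 1L, "order_index")))
  row_keys <- c(as.character(numerals), NOLAY)
  layer_by_id <- model$layers
  pop_row <- vapply(pops, function(p) {
    if (is.null(p$layer_ref)) NOLAY else
      as.character(layer_by_id[[p$layer_ref]]$order_index)
  }, "")

  ## -- box sizing ------------------------------------------------------
  label_text_len <- function(p) {
    spans <- display_label(p$label)
    sum(nchar(spans$text))
  }
  box_w <- vapply(pops, function(p) {
    max(cfg$box_min_w, label_text_len(p) * cfg$char_width + 16)
  }, 0)
  box_h <- rep(cfg$box_min_h, length(pops))
  names(box_h) <- names(box_w) <- names(pops)

  ## -- cell membership and intra-cell ordering ------------------------
  decl_order <- stats::setNames(seq_along(pops), names(pops))
  src <- vapply(projs, `[[`, "", "source")
  tgt <- vapply(projs, `[[`, "", "target")
  cell_key <- paste(pop_region, pop_row, sep = "\r")
  order_in_cell <- function(ids) {
    internal <- data.frame(source = src, target = tgt)[
      src %in% ids & tgt %in% ids, , drop = FALSE]
    rank <- longest_path_ranks(ids, internal)
    ids[order(rank[ids], decl_order[ids], method = "radix")]
  }

  ## -- band heights and column widths ----------------------------------
  band_h <- stats::setNames(rep(cfg$box_min_h + 2 * cfg$band_gap,
                                length(row_keys)), row_keys)
  col_w <- stats::setNames(rep(cfg$box_min_w + 2 * cfg$column_gap,
                               length(col_ids)), col_ids)
  cells <- list()
  for (ci in col_ids) for (ri in row_keys) {
    ids <- names(pops)[pop_region == ci & pop_row == ri]
    if (!length(ids)) next
    ids <- order_in_cell(ids)
    cells[[length(cells) + 1L]] <- list(ci = ci, ri = ri, ids = ids)
    need_w <- sum(box_w[ids]) + cfg$column_gap * (length(ids) + 1L)
    need_h <- max(box_h[ids]) + 2 * cfg$band_gap
    col_w[[ci]] <- max(col_w[[ci]], need_w)
    band_h[[ri]] <- max(band_h[[ri]], need_h)
  }
  # drop the unlayered band when nothing lives there and layers exist
  if (!any(pop_row == NOLAY) && length(numerals)) {
    row_keys <- setdiff(row_keys, NOLAY)
    band_h <- band_h[row_keys]
  }

  col_x <- cumsum(c(0, unname(col_w)))[seq_along(col_ids)]
  names(col_x) <- col_ids
  row_y <- cumsum(c(0, unname(band_h)))[seq_along(row_keys)]
  names(row_y) <- row_keys
  content_w <- sum(col_w)
  content_h <- sum(band_h)

  ## -- place boxes ------------------------------------------------------
  boxes <- list()
  for (cell in cells) {
    ci <- cell$ci; ri <- cell$ri
    ids <- cell$ids
    x <- col_x[[ci]] + cfg$column_gap
    for (id in ids) {
      y <- row_y[[ri]] + (band_h[[ri]] - box_h[[id]]) / 2
      boxes[[id]] <- rect(x, y, box_w[[id]], box_h[[id]])
      x <- x + box_w[[id]] + cfg$column_gap
    }
  }

  ## -- unit boxes (bottom-up over the membership forest) ---------------
  unit_boxes <- list()
  unit_box_of <- function(uid) {
    if (!is.null(unit_boxes[[uid]])) return(unit_boxes[[uid]])
    u <- model$units[[uid]]
    xs <- c(); ys <- c(); xe <- c(); ye <- c()
    for (m in u$members) {
      b <- if (m %in% names(model$units)) unit_box_of(m) else boxes[[m]]
      if (is.null(b)) next
      xs <- c(xs, b$x); ys <- c(ys, b$y)
      xe <- c(xe, b$x + b$w); ye <- c(ye, b$y + b$h)
    }
    b <- if (length(xs)) {
      rect(min(xs) - cfg$unit_margin, min(ys) - cfg$unit_margin,
           max(xe) - min(xs) + 2 * cfg$unit_margin,
           max(ye) - min(ys) + 2 * cfg$unit_margin)
    } else rect(0, 0, 0, 0)
    unit_boxes[[uid]] <<- b
    b
  }
  for (uid in names(model$units)) unit_box_of(uid)
  warnings <- character()
  parents <- unit_parents(model)
  uids <- names(model$units)
  if (length(uids) > 1L) {
    for (i in seq_len(length(uids) - 1L)) for (j in (i + 1L):length(uids)) {
      a <- uids[i]; b <- uids[j]
      nested <- identical(parents[a], stats::setNames(b, a)) ||
        identical(parents[b], stats::setNames(a, b))
      if (!nested && rects_overlap(unit_boxes[[a]], unit_boxes[[b]]) &&
          unit_boxes[[a]]$w > 0 && unit_boxes[[b]]$w > 0) {
        warnings <- c(warnings, sprintf(
          "unit boxes '%s' and '%s' overlap: their member regions interleave", a, b))
      }
    }
  }

  ## -- ports -------------------------------------------------------------
  parts <- classify_endpoints(model)
  proj_ids <- names(projs)
  in_ports <- list(); out_ports <- list()
  for (pid in names(pops)) {
    aff <- proj_ids[tgt[proj_ids] == pid]
    eff <- proj_ids[src[proj_ids] == pid]
    b <- boxes[[pid]]
    if (length(aff)) {
      ys <- b$y + b$h * seq_along(aff) / (length(aff) + 1L)
      in_ports[aff] <- as.list(ys)
    }
    if (length(eff)) {
      ys <- b$y + b$h * seq_along(eff) / (length(eff) + 1L)
      out_ports[eff] <- as.list(ys)
    }
  }

  ## -- routing -----------------------------------------------------------
  cs <- cfg$channel_spacing
  n_proj <- length(proj_ids)
  in_x <- -(cfg$column_gap + (n_proj + 2L) * cs)
  out_x <- content_w + cfg$column_gap + (n_proj + 2L) * cs
  paths <- list()
  density_rows <- list()
  k <- 0L  # greedy track counter, projection-id order
  for (pid in proj_ids) {
    pr <- projs[[pid]]
    k <- k + 1L
    if (pid %in% parts$inputs) {
      b <- boxes[[pr$target]]
      y <- in_ports[[pid]]
      pts <- rbind(c(in_x, y), c(b$x, y))
      kind <- "input"
    } else if (pid %in% parts$outputs) {
      b <- boxes[[pr$source]]
      y <- out_ports[[pid]]
      pts <- rbind(c(b$x + b$w, y), c(out_x, y))
      kind <- "output"
    } else if (identical(pr$source, pr$target)) {
      b <- boxes[[pr$source]]
      y0 <- out_ports[[pid]]; y1 <- in_ports[[pid]]
      top <- b$y - cfg$loop_margin - (k %% 4L) * cs
      pts <- rbind(c(b$x + b$w, y0),
                   c(b$x + b$w + cfg$loop_margin + (k %% 4L) * cs, y0),
                   c(b$x + b$w + cfg$loop_margin + (k %% 4L) * cs, top),
                   c(b$x - cfg$loop_margin - (k %% 4L) * cs, top),
                   c(b$x - cfg$loop_margin - (k %% 4L) * cs, y1),
                   c(b$x, y1))
      kind <- "self"
    } else {
      sb <- boxes[[pr$source]]; tb <- boxes[[pr$target]]
      y0 <- out_ports[[pid]]; y1 <- in_ports[[pid]]
      sx <- sb$x + sb$w; tx <- tb$x
      if (sx + 2 * cs < tx) {
        # forward: one vertical jog in the inter-column channel
        mx <- sx + ((k %% (n_proj + 1L)) + 1L) / (n_proj + 2L) * (tx - sx)
        pts <- rbind(c(sx, y0), c(mx, y0), c(mx, y1), c(tx, y1))
      } else {
        # backward or stacked: detour below the occupied bands
        dy <- content_h + cfg$band_gap + k * cs
        mx1 <- sx + cs * (1L + (k %% 4L))
        mx0 <- tx - cs * (1L + (k %% 4L))
        pts <- rbind(c(sx, y0), c(mx1, y0), c(mx1, dy), c(mx0, dy),
                     c(mx0, y1), c(tx, y1))
      }
      kind <- "internal"
    }
    paths[[pid]] <- list(points = pts, kind = kind,
                         inhibitory = identical(pr$excitation, "inhibitory"))
    if (!is.null(pr$density)) {
      seg <- max(1L, floor(nrow(pts) / 2))
      mx <- (pts[seg, 1] + pts[seg + 1L, 1]) / 2
      my <- (pts[seg, 2] + pts[seg + 1L, 2]) / 2
      density_rows[[pid]] <- data.frame(projection = pid, x = mx, y = my - 4,
                                        text = fmt_num(pr$density))
    }
  }

  ## -- layer and region annotation lines --------------------------------
  layer_rows <- list(); label_rows <- list()
  for (l in model$layers) {
    ri <- as.character(l$order_index)
    a <- l$area_ref
    layer_rows[[l$id]] <- data.frame(
      layer = l$name, area = a, y = row_y[[ri]] + band_h[[ri]],
      x0 = col_x[[a]], x1 = col_x[[a]] + col_w[[a]])
  }
  for (ri in as.character(numerals)) {
    nm <- names(roman_layers)[match(as.integer(ri), roman_layers)]
    label_rows[[ri]] <- data.frame(layer = nm, x = out_x,
                                   y = row_y[[ri]] + band_h[[ri]] / 2)
  }
  region_line_rows <- list(); region_label_rows <- list()
  reg_cols <- col_ids[col_ids != NOREG]
  for (i in seq_along(reg_cols)) {
    ci <- reg_cols[i]
    if (i > 1L) {
      region_line_rows[[ci]] <- data.frame(x = col_x[[ci]], y0 = 0,
                                           y1 = content_h)
    }
    region_label_rows[[ci]] <- data.frame(
      region = ci, name = model$regions[[ci]]$name,
      x = col_x[[ci]] + col_w[[ci]] / 2, y = -8)
  }

  ## -- canvas ------------------------------------------------------------
  ys <- c(0, content_h,
          unlist(lapply(paths, function(p) p$points[, 2])),
          unlist(lapply(unit_boxes, function(b) c(b$y, b$y + b$h))))
  y0 <- min(ys) - 2 * cfg$band_gap
  y1 <- max(ys) + 2 * cfg$band_gap
  canvas <- rect(in_x, y0, out_x - in_x, y1 - y0)

  structure(list(
    population_boxes = boxes,
    projection_paths = paths,
    layer_lines = bind_or_empty(layer_rows, c("layer", "area", "y", "x0", "x1")),
    layer_labels = bind_or_empty(label_rows, c("layer", "x", "y")),
    region_lines = bind_or_empty(region_line_rows, c("x", "y0", "y1")),
    region_labels = bind_or_empty(region_label_rows, c("region", "name", "x", "y")),
    unit_boxes = unit_boxes,
    density_labels = bind_or_empty(density_rows,
                                   c("projection", "x", "y", "text")),
    canvas = canvas, warnings = warnings, config = cfg), class = "nns_layout")
}

empty_df <- function(cols) {
  stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
}

bind_or_empty <- function(rows, cols) {
  if (length(rows)) do.call(rbind, unname(rows)) else empty_df(cols)
}
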
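# Independent oracles and fault injectors used across the suite.
# These deliberately re-derive properties by brute force rather than calling
# the code paths they check.

eps <- 1e-9

`%||%` <- function(x, y) if (is.null(x)) y else x

# brute-force endpoint partition: scan every projection record directly
brute_classify <- function(model) {
  internal <- inputs <- outputs <- character()
  for (pr in model$projections) {
    if (identical(pr$source, EXTERNAL)) inputs <- c(inputs, pr$id)
    else if (identical(pr$target, EXTERNAL)) outputs <- c(outputs, pr$id)
    else internal <- c(internal, pr$id)
  }
  list(internal = internal, inputs = inputs, outputs = outputs)
}

# brute-force pairwise box intersection count
count_box_overlaps <- function(boxes) {
  ids <- names(boxes)
  n <- 0L
  if (length(ids) < 2L) return(0L)
  for (i in 1:(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
    a <- boxes[[ids[i]]]; b <- boxes[[ids[j]]]
    if (a$x < b$x + b$w && b$x < a$x + a$w &&
        a$y < b$y + b$h && b$y < a$y + a$h) n <- n + 1L
  }
  n
}

on_right_edge <- function(pt, box) {
  abs(pt[1] - (box$x + box$w)) < eps &&
    pt[2] >= box$y - eps && pt[2] <= box$y + box$h + eps
}
on_left_edge <- function(pt, box) {
  abs(pt[1] - box$x) < eps &&
    pt[2] >= box$y - eps && pt[2] <= box$y + box$h + eps
}

# independent side-convention predicate for every routed projection
count_endpoint_violations <- function(model, lay) {
  cls <- brute_classify(model)
  bad <- 0L
  for (pid in names(lay$projection_paths)) {
    pts <- lay$projection_paths[[pid]]$points
    pr <- model$projections[[pid]]
    first <- pts[1, ]; last <- pts[nrow(pts), ]
    ok <- if (pid %in% cls$inputs) {
      abs(first[1] - lay$canvas$x) < eps &&
        on_left_edge(last, lay$population_boxes[[pr$target]])
    } else if (pid %in% cls$outputs) {
      on_right_edge(first, lay$population_boxes[[pr$source]]) &&
        abs(last[1] - (lay$canvas$x + lay$canvas$w)) < eps
    } else {
      on_right_edge(first, lay$population_boxes[[pr$source]]) &&
        on_left_edge(last, lay$population_boxes[[pr$target]])
    }
    if (!ok) bad <- bad + 1L
  }
  bad
}

# varied but deterministic generator settings for property sweeps
sweep_model <- function(s) {
  random_model(s, n_pop = 3 + s %% 10, n_proj = 5 + s %% 15,
               n_layers = s %% 5, n_regions = s %% 4 + (s %% 5 > 0),
               n_units = s %% 4, p_inhibitory = 0.3, p_external = 0.2)
}

# ---- single-fault injectors, one per rulebook rule ----------------------
# each takes a clean seeded model and corrupts exactly one rule by direct
# list surgery (bypassing the strict constructors)
injection_base <- function(seed) {
  random_model(seed, n_pop = 5, n_proj = 6, n_layers = 2, n_regions = 3,
               n_units = 2, p_inhibitory = 0.3, p_external = 0.1)
}

inject_violation <- function(rule, seed) {
  m <- injection_base(seed)
  switch(rule,
    "R-POP-LABEL" = {
      m$populations[[1L]]$label$ephys <- NULL
      m$populations[[1L]]$label$morph <- NULL
    },
    "R-PROJ-ENDPOINTS" = {
      m$projections[[1L]]$source <- EXTERNAL
      m$projections[[1L]]$target <- EXTERNAL
    },
    "R-PROJ-DENSITY" = {
      m$projections[[1L]]$density <- 1.5
    },
    "R-LAYER-NAME" = {
      m$layers[[1L]]$name <- "VII"
    },
    "R-LAYER-ORDER" = {
      m$layers[[1L]]$order_index <- m$layers[[1L]]$order_index + 1L
    },
    "R-NCR-NOLAYERS" = {
      m$regions[["zncr"]] <- region("zncr", "ncr", name = "Z", display_order = 99L)
      m$layers[["zlay"]] <- layer("zlay", "I", "zncr")
    },
    "R-UNIT-FOREST" = {
      m$units[["unit01"]]$members <- union(m$units[["unit01"]]$members, "unit02")
      m$units[["unit02"]]$members <- union(m$units[["unit02"]]$members, "unit01")
    },
    "R-REF-INTEGRITY" = {
      m$projections[[1L]]$target <- "no_such_population"
    },
    "R-NO-COLOR" = {
      m$populations[[1L]]$extra$color <- "red"
    },
    "R-NO-SCALING" = {
      m$projections[[1L]]$extra$scale_by <- "density"
    },
    stop("unknown rule ", rule))
  m
}

# ---- SVG introspection helpers (XML queries over the rendered document) --
svg_doc <- function(svg) {
  x <- xml2::read_xml(svg)
  xml2::xml_ns_strip(x)
  x
}

svg_count <- function(x, xpath) length(xml2::xml_find_all(x, xpath))

# every stroke/fill attribute in the document, for the no-color check
svg_paints <- function(x) {
  nodes <- xml2::xml_find_all(x, "//*[@stroke or @fill]")
  c(xml2::xml_attr(nodes, "stroke"), xml2::xml_attr(nodes, "fill"))
}

svg_dashed_classes <- function(x) {
  nodes <- xml2::xml_find_all(x, "//*[@stroke-dasharray]")
  sort(unique(xml2::xml_attr(nodes, "class")))
}

svg_italic_texts <- function(x) {
  xml2::xml_text(xml2::xml_find_all(x, "//tspan[@font-style='italic']"))
}

render_fixture <- function(fid) {
  m <- build_fixture(fid)
  list(model = m, svg = render_svg(compute_layout(m), m))
}
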
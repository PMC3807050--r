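DEFAULT_POP_SIZE <- 100L

py_ident <- function(id, prefix) {
  s <- gsub("[^A-Za-z0-9_]", "_", id)
  paste0(prefix, "_", s)
}

ann_json <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

py_num <- function(x) {
  # full-precision literal so densities survive the text round trip
  format(x, digits = 17, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}

#' Export a model to a constrained declarative PyNN script
#'
#' Emits a runnable PyNN-style script: one `Population` statement per
#' population (size taken from its `size` extra attribute, default 100) and
#' one `Projection` statement per internal projection, with the excitation
#' type as the receptor target and the connection density as the connector
#' probability. PyNN has no vocabulary for layers, areas, NCRs or units, so
#' that structure rides in `# @nns-...` comment annotations attached to the
#' corresponding statements; projections with an `EXTERNAL` endpoint are
#' emitted as annotated input/output declarations. A PyNN interpreter
#' unaware of neural schematics can run the script; [import_pynn()] reads
#' the annotations back. Output is deterministic (elements sorted by id).
#'
#' @param model An `nns_model` validating clean of ERRORs.
#' @param path Optional file path to also write the script to.
#' @return The script as a single character string.
#' @export
export_pynn <- function(model, path = NULL) {
  stopifnot(inherits(model, "nns_model"))
  diags <- validate_model(model)
  if (any(diags$severity == "ERROR")) {
    abort_ns(paste0("refusing to export an invalid model:\n",
                    paste0("  ", format_diagnostics(diags), collapse = "\n")),
             "nns_validation_error")
  }
  out <- c(
    "# Neural Schematic export: constrained declarative PyNN subset",
    sprintf("# @nns-meta %s", ann_json(list(format_version = NNSD_VERSION,
                                            metadata = model$metadata))),
    "import pyNN.neuron as sim", "", "sim.setup()", "")
  for (r in model$regions) {
    out <- c(out, sprintf("# @nns-region %s", ann_json(
      list(id = r$id, kind = r$kind, name = r$name,
           display_order = r$display_order))))
  }
  for (l in model$layers) {
    out <- c(out, sprintf("# @nns-layer %s", ann_json(
      list(id = l$id, name = l$name, area = l$area_ref))))
  }
  for (u in model$units) {
    out <- c(out, sprintf("# @nns-unit %s", ann_json(
      list(id = u$id, name = u$name, members = I(u$members)))))
  }
  if (length(model$regions) || length(model$layers) || length(model$units)) {
    out <- c(out, "")
  }
  for (p in model$populations) {
    size <- p$extra$size %||% DEFAULT_POP_SIZE
    ann <- drop_null(list(id = p$id, ephys = p$label$ephys,
                          morph = p$label$morph, layer = p$layer_ref,
                          region = p$region_ref,
                          extra = if (length(p$extra)) p$extra))
    out <- c(out, sprintf(
      '%s = sim.Population(%s, sim.IF_cond_exp(), label="%s")  # @nns-pop %s',
      py_ident(p$id, "pop"), py_num(size), p$id, ann_json(ann)))
  }
  out <- c(out, "")
  parts <- classify_endpoints(model)
  for (pr in model$projections) {
    ann <- drop_null(list(id = pr$id, source = pr$source, target = pr$target,
                          excitation = pr$excitation, density = pr$density,
                          extra = if (length(pr$extra)) pr$extra))
    if (pr$id %in% parts$internal) {
      conn <- if (is.null(pr$density)) "sim.AllToAllConnector()" else
        sprintf("sim.FixedProbabilityConnector(p_connect=%s)", py_num(pr$density))
      out <- c(out, sprintf(
        '%s = sim.Projection(%s, %s, %s, receptor_type="%s")  # @nns-proj %s',
        py_ident(pr$id, "prj"), py_ident(pr$source, "pop"),
        py_ident(pr$target, "pop"), conn, pr$excitation, ann_json(ann)))
    } else if (pr$id %in% parts$inputs) {
      out <- c(out, sprintf("# @nns-input %s", ann_json(ann)))
    } else {
      out <- c(out, sprintf("# @nns-output %s", ann_json(ann)))
    }
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

parse_ann <- function(line, tag) {
  payload <- sub(paste0("^.*# @nns-", tag, " "), "", line)
  tryCatch(jsonlite::fromJSON(payload, simplifyVector = FALSE),
           error = function(e) {
             abort_ns(sprintf("malformed @nns-%s annotation: %s", tag, line),
                      "nns_parse_error")
           })
}

pop_stmt_re <- paste0(
  '^[A-Za-z0-9_]+ = sim\\.Population\\([0-9]+, sim\\.[A-Za-z0-9_]+\\(\\), ',
  'label="[^"]*"\\)  # @nns-pop .*$')
proj_stmt_re <- paste0(
  '^[A-Za-z0-9_]+ = sim\\.Projection\\([A-Za-z0-9_]+, [A-Za-z0-9_]+, ',
  'sim\\.[A-Za-z0-9_]+\\((p_connect=[0-9.eE+-]+)?\\), ',
  'receptor_type="(excitatory|inhibitory)"\\)  # @nns-proj .*$')

#' Import a model from a constrained declarative PyNN script
#'
#' Reads back scripts of the declarative subset that [export_pynn()] emits:
#' literal arguments, no control flow. Scripts are parsed as source text and
#' never executed. Populations and internal projections are reconstructed
#' from their statements and `@nns` annotations; layers, areas, NCRs, units,
#' and external input/output projections are reconstructed from annotation
#' lines alone.
#'
#' @param x A file path or the script text itself (anything containing a
#'   newline is treated as text).
#' @return An `nns_model`.
#' @export
import_pynn <- function(x) {
  if (is_string(x) && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE, encoding = "UTF-8")
  } else {
    lines <- strsplit(paste(x, collapse = "\n"), "\n", fixed = TRUE)[[1L]]
  }
  meta <- list()
  regions <- list(); layers <- list(); units <- list()
  pops <- list(); projs <- list()
  allowed_plain <- c("", "import pyNN.neuron as sim", "sim.setup()")

  for (line in lines) {
    if (grepl("# @nns-meta ", line, fixed = TRUE)) {
      m <- parse_ann(line, "meta")
      meta <- lapply(m$metadata %||% list(), as_scalar)
    } else if (grepl("^# @nns-region ", line)) {
      r <- parse_ann(line, "region")
      regions[[length(regions) + 1L]] <-
        region(r$id, r$kind, name = r$name, display_order = r$display_order)
    } else if (grepl("^# @nns-layer ", line)) {
      l <- parse_ann(line, "layer")
      layers[[length(layers) + 1L]] <- layer(l$id, l$name, l$area)
    } else if (grepl("^# @nns-unit ", line)) {
      u <- parse_ann(line, "unit")
      units[[length(units) + 1L]] <-
        unit_group(u$id, name = u$name,
                   members = as.character(unlist(u$members %||% list())))
    } else if (grepl("# @nns-pop ", line, fixed = TRUE)) {
      if (!grepl(pop_stmt_re, line)) {
        abort_ns(paste0("unsupported construct in population statement: ", line),
                 "nns_unsupported_construct")
      }
      p <- parse_ann(line, "pop")
      pops[[length(pops) + 1L]] <-
        population(p$id, ephys = p$ephys, morph = p$morph, layer = p$layer,
                   region = p$region, extra = lapply(p$extra %||% list(),
                                                     as_scalar))
    } else if (grepl("# @nns-proj ", line, fixed = TRUE)) {
      if (!grepl(proj_stmt_re, line)) {
        abort_ns(paste0("unsupported construct in projection statement: ", line),
                 "nns_unsupported_construct")
      }
      pr <- parse_ann(line, "proj")
      projs[[length(projs) + 1L]] <-
        projection(pr$id, pr$source, pr$target, pr$excitation,
                   density = pr$density,
                   extra = lapply(pr$extra %||% list(), as_scalar))
    } else if (grepl("^# @nns-(input|output) ", line)) {
      tag <- if (grepl("^# @nns-input ", line)) "input" else "output"
      pr <- parse_ann(line, tag)
      projs[[length(projs) + 1L]] <-
        projection(pr$id, pr$source, pr$target, pr$excitation,
                   density = pr$density,
                   extra = lapply(pr$extra %||% list(), as_scalar))
    } else if (grepl("^#", line) || line %in% allowed_plain) {
      # plain comment or boilerplate: ignore
    } else {
      abort_ns(paste0("unsupported construct outside the declarative subset: ",
                      line), "nns_unsupported_construct")
    }
  }
  nns_model(populations = pops, projections = projs, layers = layers,
            regions = regions, units = units, metadata = meta, check = TRUE)
}
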
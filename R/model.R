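#' Reserved endpoint token for projections without an origin or terminus
#'
#' Projections whose source is `EXTERNAL` are inputs to the network structure;
#' projections whose target is `EXTERNAL` are outputs. `EXTERNAL` is a
#' sentinel, not a population identifier, and may never occupy both endpoints
#' of the same projection.
#'
#' @format A length-one character vector, `"EXTERNAL"`.
#' @export
EXTERNAL <- "EXTERNAL"

excitation_types <- c("excitatory", "inhibitory")

roman_layers <- c(I = 1L, II = 2L, III = 3L, IV = 4L, V = 5L, VI = 6L)

#' Construct a population label
#'
#' A population is named after the electrophysiological (or spiking-behaviour)
#' class of its neurons, typeset normal, and/or a morphological or other
#' descriptive class, typeset italic. At least one part must be present and
#' each part is an uppercase alphanumeric token.
#'
#' @param ephys Electrophysiological/spiking class token (e.g. `"RS"`,
#'   `"FS"`, `"POIS"`), or `NULL`.
#' @param morph Morphological or other descriptive class token (e.g. `"PYR"`,
#'   `"NPYR"`, `"TC"`, `"STIM"`), or `NULL`.
#' @return An object of class `nns_label`.
#' @examples
#' population_label("RS", "PYR")
#' population_label(morph = "TC")
#' @export
population_label <- function(ephys = NULL, morph = NULL) {
  if (is.null(ephys) && is.null(morph)) {
    abort_ns("invalid label: both the electrophysiological and the morphological class are absent",
             "nns_invalid_label")
  }
  for (tok in list(ephys, morph)) {
    if (!is.null(tok) && !is_class_token(tok)) {
      abort_ns(sprintf("invalid label token %s: must be uppercase alphanumeric with no whitespace",
                       deparse(tok)), "nns_invalid_label")
    }
  }
  structure(list(ephys = ephys, morph = morph), class = "nns_label")
}

#' Typeset a population label as styled spans
#'
#' Expands a label into an ordered list of text spans with a typeset style,
#' ready for a renderer: the electrophysiological class in normal typeset,
#' the morphological/other class in italic, joined by a normal-typeset
#' `"/"` when both are present.
#'
#' @param label An `nns_label`, or a population (its label is used).
#' @return A data frame with columns `text` and `style`
#'   (`"normal"` or `"italic"`), one row per span.
#' @examples
#' display_label(population_label("RS", "PYR"))
#' @export
display_label <- function(label) {
  if (inherits(label, "nns_population")) label <- label$label
  if (!inherits(label, "nns_label")) {
    label <- population_label(label$ephys, label$morph)  # revalidates
  }
  if (is.null(label$ephys) && is.null(label$morph)) {
    abort_ns("invalid label: no class token present", "nns_invalid_label")
  }
  spans <- list()
  if (!is.null(label$ephys)) spans[[length(spans) + 1L]] <- c(label$ephys, "normal")
  if (!is.null(label$ephys) && !is.null(label$morph)) spans[[length(spans) + 1L]] <- c("/", "normal")
  if (!is.null(label$morph)) spans[[length(spans) + 1L]] <- c(label$morph, "italic")
  data.frame(text = vapply(spans, `[`, "", 1L),
             style = vapply(spans, `[`, "", 2L))
}

check_id <- function(id, what) {
  if (!is_string(id) || !nzchar(id)) {
    abort_ns(sprintf("%s id must be a non-empty string", what), "nns_invalid_element")
  }
  if (identical(id, EXTERNAL)) {
    abort_ns(sprintf("%s id may not be the reserved token 'EXTERNAL'", what),
             "nns_invalid_element")
  }
  id
}

check_extra <- function(extra) {
  if (is.null(extra)) return(list())
  if (!is.list(extra) || (length(extra) > 0 && is.null(names(extra)))) {
    abort_ns("extra_attributes must be a named list", "nns_invalid_element")
  }
  extra
}

#' Construct a population
#'
#' The lowest-level node of a neural schematic: a compound of functionally
#' related neurons of one morphological/electrophysiological cell class.
#' Additional attributes (neuron model parameters, spatial distribution, ...)
#' are carried in `extra` but are never rendered and never influence geometry.
#'
#' @param id Unique identifier.
#' @param ephys,morph Label parts, see [population_label()]. Alternatively
#'   pass a ready-made label as `label`.
#' @param label An `nns_label`; overrides `ephys`/`morph` when given.
#' @param layer Optional layer identifier the population resides in. A
#'   population with a layer must live in an area (never a non-cortical
#'   region) that contains that layer.
#' @param region Optional area or non-cortical-region identifier.
#' @param extra Named list of additional, non-rendered attributes.
#' @return An object of class `nns_population`.
#' @export
population <- function(id, ephys = NULL, morph = NULL, label = NULL,
                       layer = NULL, region = NULL, extra = list()) {
  check_id(id, "population")
  if (is.null(label)) label <- population_label(ephys, morph)
  if (!inherits(label, "nns_label")) label <- population_label(label$ephys, label$morph)
  if (!is.null(layer) && !is_string(layer)) {
    abort_ns("layer reference must be a single string", "nns_invalid_element")
  }
  if (!is.null(region) && !is_string(region)) {
    abort_ns("region reference must be a single string", "nns_invalid_element")
  }
  structure(list(id = id, label = label, layer_ref = layer, region_ref = region,
                 extra = check_extra(extra)),
            class = "nns_population")
}

#' Construct a projection
#'
#' A directed bundle of same-excitation-type synaptic connections between two
#' populations. Projections do not branch or join: each has exactly one
#' source and one target. A projection with source `EXTERNAL` is an input to
#' the network; one with target `EXTERNAL` is an output; both endpoints may
#' not be `EXTERNAL`. A population may project onto itself.
#'
#' @param id Unique identifier.
#' @param source,target Population identifiers, or [EXTERNAL].
#' @param excitation `"excitatory"` or `"inhibitory"`.
#' @param density Optional relative connection density in `[0, 1]`.
#' @param extra Named list of additional, non-rendered attributes (weights,
#'   delays, plasticity, ...).
#' @return An object of class `nns_projection`.
#' @export
projection <- function(id, source, target, excitation = "excitatory",
                       density = NULL, extra = list()) {
  check_id(id, "projection")
  if (!is_string(source) || !is_string(target)) {
    abort_ns("projection endpoints must be single strings", "nns_invalid_element")
  }
  if (identical(source, EXTERNAL) && identical(target, EXTERNAL)) {
    abort_ns("projection endpoints may not both be EXTERNAL", "nns_invalid_element")
  }
  if (!is_string(excitation) || !excitation %in% excitation_types) {
    abort_ns("excitation must be 'excitatory' or 'inhibitory'", "nns_invalid_element")
  }
  if (!is.null(density)) {
    if (!is.numeric(density) || length(density) != 1L || is.na(density) ||
        density < 0 || density > 1) {
      abort_ns("connection density must be a single number in [0, 1]",
               "nns_invalid_element")
    }
    density <- as.numeric(density)
  }
  structure(list(id = id, source = source, target = target,
                 excitation = excitation, density = density,
                 extra = check_extra(extra)),
            class = "nns_projection")
}

#' Construct a cortical layer
#'
#' One of the cortical laminae I--VI, belonging to an area. Layers are named
#' with uppercase roman numerals and ordered with the highest cortical layer
#' (smallest numeral) on top.
#'
#' @param id Unique identifier.
#' @param name Roman numeral token, one of `"I"` ... `"VI"`.
#' @param area Identifier of the containing area.
#' @return An object of class `nns_layer` with a derived `order_index`.
#' @export
layer <- function(id, name, area) {
  check_id(id, "layer")
  if (!is_string(name) || !name %in% names(roman_layers)) {
    abort_ns(sprintf("layer name %s must be an uppercase roman numeral I..VI",
                     deparse(name)), "nns_invalid_element")
  }
  if (!is_string(area)) abort_ns("layer area reference must be a single string",
                                 "nns_invalid_element")
  structure(list(id = id, name = name, area_ref = area,
                 order_index = unname(roman_layers[[name]])),
            class = "nns_layer")
}

#' Construct a region (cortical area or non-cortical region)
#'
#' Areas partition the cortical surface and may contain layers; non-cortical
#' regions (NCRs) are any other brain region, rendered in the same visual
#' style as areas but never containing layer boundaries.
#'
#' @param id Unique identifier.
#' @param kind `"area"` or `"ncr"`.
#' @param name Free-text display name (may be empty).
#' @param display_order Integer ordering of region strips, left to right.
#' @return An object of class `nns_region`.
#' @export
region <- function(id, kind = c("area", "ncr"), name = id, display_order = 1L) {
  check_id(id, "region")
  kind <- match.arg(kind)
  if (!is_string(name)) abort_ns("region name must be a single string",
                                 "nns_invalid_element")
  if (!is_count(display_order)) abort_ns("display_order must be a non-negative integer",
                                         "nns_invalid_element")
  structure(list(id = id, kind = kind, name = name,
                 display_order = as.integer(display_order)),
            class = "nns_region")
}

#' Construct a functional unit
#'
#' A dashed-box grouping of functionally related elements (e.g. a cortical
#' column). A unit may house sub-units along with populations; unit
#' membership forms a forest (no unit is its own ancestor) and each
#' population belongs to at most one unit directly.
#'
#' @param id Unique identifier.
#' @param name Free-text, function-derived name.
#' @param members Character vector of population and/or sub-unit identifiers.
#' @return An object of class `nns_unit`.
#' @export
unit_group <- function(id, name = id, members = character()) {
  check_id(id, "unit")
  if (!is_string(name)) abort_ns("unit name must be a single string",
                                 "nns_invalid_element")
  if (length(members) && (!is.character(members) || anyNA(members))) {
    abort_ns("unit members must be a character vector of identifiers",
             "nns_invalid_element")
  }
  if (anyDuplicated(members)) {
    abort_ns("unit members must be unique", "nns_invalid_element")
  }
  structure(list(id = id, name = name, members = as.character(members)),
            class = "nns_unit")
}

as_elements <- function(x, class, what) {
  if (length(x) == 0L) return(structure(list(), names = character()))
  x <- unname(x)
  ok <- vapply(x, inherits, TRUE, class)
  if (!all(ok)) abort_ns(sprintf("all %s must be built with %s()", what,
                                 sub("^nns_", "", class)), "nns_invalid_element")
  ids <- vapply(x, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    abort_ns(sprintf("duplicate %s id: %s", what, ids[duplicated(ids)][1L]),
             "nns_invalid_element")
  }
  names(x) <- ids
  x[order(ids, method = "radix")]
}

#' Assemble a neural network structure model
#'
#' The complete schematic document: populations, projections, layers,
#' regions, and units, plus free-form metadata. By default the assembled
#' model is checked against the full notation rulebook and construction
#' fails on any ERROR-severity finding; pass `check = FALSE` to build a
#' model for later inspection with [validate_model()].
#'
#' @param populations,projections,layers,regions,units Lists of elements
#'   built with the respective constructors.
#' @param metadata Named list (title, provenance, ...).
#' @param check Validate on construction (default `TRUE`).
#' @return An object of class `nns_model`, with each collection stored as a
#'   list named and sorted by element id.
#' @export
nns_model <- function(populations = list(), projections = list(),
                      layers = list(), regions = list(), units = list(),
                      metadata = list(), check = TRUE) {
  m <- structure(list(
    populations = as_elements(populations, "nns_population", "populations"),
    projections = as_elements(projections, "nns_projection", "projections"),
    layers      = as_elements(layers, "nns_layer", "layers"),
    regions     = as_elements(regions, "nns_region", "regions"),
    units       = as_elements(units, "nns_unit", "units"),
    metadata    = check_extra(metadata)
  ), class = "nns_model")
  if (check) {
    d <- validate_model(m)
    bad <- d[d$severity == "ERROR", , drop = FALSE]
    if (nrow(bad)) {
      abort_ns(paste0("model violates the notation rulebook:\n",
                      paste0("  ", format_diagnostics(bad), collapse = "\n")),
               "nns_invalid_model")
    }
  }
  m
}

#' @export
print.nns_model <- function(x, ...) {
  cat(sprintf("<nns_model> %d populations, %d projections, %d layers, %d regions, %d units\n",
              length(x$populations), length(x$projections), length(x$layers),
              length(x$regions), length(x$units)))
  invisible(x)
}

#' Partition projections into internal, input, and output classes
#'
#' Projections that have no origin (source `EXTERNAL`) are inputs to the
#' network structure; projections that do not terminate (target `EXTERNAL`)
#' are outputs; all others are internal. The three sets are disjoint and
#' cover every projection.
#'
#' @param model An `nns_model` passing referential integrity.
#' @return A list with character-vector components `internal`, `inputs`,
#'   and `outputs` of projection ids.
#' @export
classify_endpoints <- function(model) {
  stopifnot(inherits(model, "nns_model"))
  ids <- names(model$projections)
  src <- vapply(model$projections, `[[`, "", "source")
  tgt <- vapply(model$projections, `[[`, "", "target")
  if (length(ids) == 0L) {
    return(list(internal = character(), inputs = character(), outputs = character()))
  }
  list(internal = unname(ids[src != EXTERNAL & tgt != EXTERNAL]),
       inputs   = unname(ids[src == EXTERNAL]),
       outputs  = unname(ids[tgt == EXTERNAL]))
}

# unit id -> parent unit id (units are members of at most one other unit)
unit_parents <- function(model) {
  parents <- character()
  for (u in model$units) {
    for (m in u$members) {
      if (m %in% names(model$units)) parents[[m]] <- u$id
    }
  }
  parents
}

#' Look up the unit a population directly belongs to
#'
#' @param model An `nns_model`.
#' @param pop_id Population identifier.
#' @return The unit id, or `NULL` when the population is in no unit.
#' @export
population_unit <- function(model, pop_id) {
  for (u in model$units) if (pop_id %in% u$members) return(u$id)
  NULL
}

#' Compare two models element-wise
#'
#' Equality of two models under the notation's data model: identical element
#' sets with identical field values, ignoring list storage order (collections
#' are canonically sorted by id on construction).
#'
#' @param a,b `nns_model` objects.
#' @return `TRUE` or `FALSE`.
#' @export
models_equal <- function(a, b) {
  norm <- function(m) {
    m <- unclass(m)
    m$metadata <- if (length(m$metadata)) {
      m$metadata[order(names(m$metadata), method = "radix")]
    } else NULL
    for (coll in c("populations", "projections", "layers", "regions", "units")) {
      m[[coll]] <- lapply(m[[coll]], function(e) {
        e <- unclass(e)
        e$extra <- if (length(e$extra)) {
          e$extra[order(names(e$extra), method = "radix")]
        } else NULL
        if (!is.null(e$label)) e$label <- unclass(e$label)
        if (!is.null(e$members)) e$members <- sort(e$members, method = "radix")
        e[!vapply(e, is.null, TRUE)]
      })
    }
    m
  }
  isTRUE(all.equal(norm(a), norm(b), tolerance = 0, check.attributes = TRUE))
}
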
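#' The notation rulebook
#'
#' Closed set of rule identifiers the validator can cite. Structural rules
#' carry ERROR severity; stylistic rules (requests for color or
#' attribute-scaled glyphs, which the notation forbids but which do not
#' corrupt the model) carry WARNING severity, as does a connection density
#' of exactly zero (renderable but semantically void).
#'
#' @format Character vector of rule ids.
#' @export
NNS_RULES <- c("R-POP-LABEL", "R-PROJ-ENDPOINTS", "R-PROJ-DENSITY",
               "R-LAYER-NAME", "R-LAYER-ORDER", "R-NCR-NOLAYERS",
               "R-UNIT-FOREST", "R-REF-INTEGRITY", "R-NO-COLOR",
               "R-NO-SCALING")

color_style_keys <- c("color", "colour", "fill", "stroke", "stroke_color",
                      "fill_color", "background")
scaling_style_keys <- c("scale_by", "size_by", "width_by", "scale_with",
                        "thickness_by", "line_width_by")

new_diag <- function(severity, rule_id, subject, message) {
  data.frame(severity = severity, rule_id = rule_id, subject = subject,
             message = message)
}

empty_diag <- function() {
  data.frame(severity = character(), rule_id = character(),
             subject = character(), message = character())
}

style_diags <- function(extra, subject) {
  d <- list()
  keys <- tolower(names(extra %||% list()))
  for (k in intersect(keys, color_style_keys)) {
    d[[length(d) + 1L]] <- new_diag("WARNING", "R-NO-COLOR", subject,
      sprintf("style attribute '%s' requests a color; colors are not applied in the notation", k))
  }
  for (k in intersect(keys, scaling_style_keys)) {
    d[[length(d) + 1L]] <- new_diag("WARNING", "R-NO-SCALING", subject,
      sprintf("style attribute '%s' requests attribute-scaled glyphs; element features are never scaled by attribute values", k))
  }
  d
}

#' Validate a model against the notation rulebook
#'
#' Checks every notation rule and returns machine-readable diagnostics
#' instead of raising conditions, so partially invalid models can be
#' inspected. A model conforms iff the returned list is empty; a model with
#' no ERROR-severity findings satisfies every structural invariant of the
#' data model.
#'
#' @param model An `nns_model` (possibly violating semantic rules; only
#'   structural parseability is assumed).
#' @return A data frame of diagnostics with columns `severity`
#'   (`"ERROR"`/`"WARNING"`), `rule_id` (one of [NNS_RULES]), `subject`
#'   (element identifier) and `message`, sorted by severity, rule id, and
#'   subject.
#' @seealso [format_diagnostics()] for the line-oriented report form.
#' @export
validate_model <- function(model) {
  d <- list()
  pops <- model$populations %||% list()
  projs <- model$projections %||% list()
  layers <- model$layers %||% list()
  regions <- model$regions %||% list()
  units <- model$units %||% list()

  pop_ids <- vapply(pops, function(p) p$id %||% "", "")
  layer_ids <- vapply(layers, function(l) l$id %||% "", "")
  region_ids <- vapply(regions, function(r) r$id %||% "", "")
  unit_ids <- vapply(units, function(u) u$id %||% "", "")
  all_ids <- c(pop_ids, layer_ids, region_ids, unit_ids,
               vapply(projs, function(p) p$id %||% "", ""))
  for (dup in unique(all_ids[duplicated(all_ids)])) {
    d[[length(d) + 1L]] <- new_diag("ERROR", "R-REF-INTEGRITY", dup,
      "duplicate identifier: every identifier must resolve to exactly one element")
  }
  region_kind <- stats::setNames(
    vapply(regions, function(r) r$kind %||% "", ""), region_ids)

  ## populations -------------------------------------------------------
  for (p in pops) {
    lab <- p$label %||% list()
    toks <- list(lab$ephys, lab$morph)
    if (is.null(toks[[1]]) && is.null(toks[[2]])) {
      d[[length(d) + 1L]] <- new_diag("ERROR", "R-POP-LABEL", p$id,
        "population label must carry an electrophysiological and/or a morphological class")
    } else {
      for (tok in toks) {
        if (!is.null(tok) && !is_class_token(tok)) {
          d[[length(d) + 1L]] <- new_diag("ERROR", "R-POP-LABEL", p$id,
            sprintf("label token %s is not an uppercase alphanumeric class name", deparse(tok)))
        }
      }
    }
    if (!is.null(p$region_ref) && !p$region_ref %in% region_ids) {
      d[[length(d) + 1L]] <- new_diag("ERROR", "R-REF-INTEGRITY", p$id,
        sprintf("region reference '%s' does not resolve", p$region_ref))
    }
    if (!is.null(p$layer_ref)) {
      if (!p$layer_ref %in% layer_ids) {
        d[[length(d) + 1L]] <- new_diag("ERROR", "R-REF-INTEGRITY", p$id,
          sprintf("layer reference '%s' does not resolve", p$layer_ref))
      } else {
        lay <- layers[[match(p$layer_ref, layer_ids)]]
        if (!is.null(p$region_ref) &&
            identical(region_kind[[p$region_ref]] %||% "", "ncr")) {
          d[[length(d) + 1L]] <- new_diag("ERROR", "R-NCR-NOLAYERS", p$id,
            "a layered population cannot reside in a non-cortical region: NCRs contain no layer boundaries")
        } else if (is.null(p$region_ref) ||
                   !identical(lay$area_ref %||% "", p$region_ref)) {
          d[[length(d) + 1L]] <- new_diag("ERROR", "R-REF-INTEGRITY", p$id,
            sprintf("population in layer '%s' must reside in the area containing that layer",
                    p$layer_ref))
        }
      }
    }
    d <- c(d, style_diags(p$extra, p$id))
  }

  ## projections -------------------------------------------------------
  for (pr in projs) {
    src <- pr$source %||% ""
    tgt <- pr$target %||% ""
    if (identical(src, EXTERNAL) && identical(tgt, EXTERNAL)) {
      d[[length(d) + 1L]] <- new_diag("ERROR", "R-PROJ-ENDPOINTS", pr$id,
        "projection endpoints may not both be EXTERNAL: projections do not branch or join and need at least one population endpoint")
    }
    for (ep in c(src, tgt)) {
      if (!identical(ep, EXTERNAL) && !ep %in% pop_ids) {
        d[[length(d) + 1L]] <- new_diag("ERROR", "R-REF-INTEGRITY", pr$id,
          sprintf("projection endpoint '%s' does not resolve to a population", ep))
      }
    }
    if (!is.null(pr$density)) {
      dens <- pr$density
      if (!is.numeric(dens) || length(dens) != 1L || is.na(dens) ||
          dens < 0 || dens > 1) {
        d[[length(d) + 1L]] <- new_diag("ERROR", "R-PROJ-DENSITY", pr$id,
          "connection density must be a relative number in [0, 1]")
      } else if (dens == 0) {
        d[[length(d) + 1L]] <- new_diag("WARNING", "R-PROJ-DENSITY", pr$id,
          "connection density of exactly 0 denotes a projection with no realized connections")
      }
    }
    d <- c(d, style_diags(pr$extra, pr$id))
  }

  ## layers ------------------------------------------------------------
  seen_pairs <- character()
  for (l in layers) {
    nm <- l$name %||% ""
    if (!is_string(nm) || !nm %in% names(roman_layers)) {
      d[[length(d) + 1L]] <- new_diag("ERROR", "R-LAYER-NAME", l$id,
        sprintf("layer name %s is not an uppercase roman numeral I..VI", deparse(nm)))
    } else {
      if (!identical(as.integer(l$order_index %||% -1L),
                     roman_layers[[nm]])) {
        d[[length(d) + 1L]] <- new_diag("ERROR", "R-LAYER-ORDER", l$id,
          sprintf("layer order index %s does not match numeral %s; layers stack with the highest cortical layer on top",
                  deparse(l$order_index), nm))
      }
      key <- paste0(l$area_ref %||% "", "\r", nm)
      if (key %in% seen_pairs) {
        d[[length(d) + 1L]] <- new_diag("ERROR", "R-LAYER-NAME", l$id,
          sprintf("duplicate layer %s within area '%s'", nm, l$area_ref %||% ""))
      }
      seen_pairs <- c(seen_pairs, key)
    }
    aref <- l$area_ref %||% ""
    if (!aref %in% region_ids) {
      d[[length(d) + 1L]] <- new_diag("ERROR", "R-REF-INTEGRITY", l$id,
        sprintf("area reference '%s' does not resolve", aref))
    } else if (identical(region_kind[[aref]], "ncr")) {
      d[[length(d) + 1L]] <- new_diag("ERROR", "R-NCR-NOLAYERS", l$id,
        sprintf("layer assigned to non-cortical region '%s': NCRs must not contain layer boundaries", aref))
    }
  }

  ## units -------------------------------------------------------------
  membership <- character()  # member id -> owning unit, to catch multi-membership
  for (u in units) {
    for (m in u$members %||% character()) {
      if (!m %in% c(pop_ids, unit_ids)) {
        d[[length(d) + 1L]] <- new_diag("ERROR", "R-REF-INTEGRITY", u$id,
          sprintf("unit member '%s' does not resolve to a population or unit", m))
      } else if (m %in% names(membership)) {
        d[[length(d) + 1L]] <- new_diag("ERROR", "R-UNIT-FOREST", m,
          sprintf("element belongs directly to units '%s' and '%s'; direct membership is exclusive",
                  membership[[m]], u$id))
      } else {
        membership[[m]] <- u$id
      }
    }
  }
  # cycle detection over unit -> sub-unit edges
  for (u in units) {
    seen <- character()
    cur <- u$id
    repeat {
      nxt <- membership[cur]
      if (is.na(nxt)) break
      nxt <- unname(nxt)
      if (nxt %in% c(seen, cur, u$id)) {
        if (identical(nxt, u$id)) {
          d[[length(d) + 1L]] <- new_diag("ERROR", "R-UNIT-FOREST", u$id,
            "unit membership contains a cycle: a unit may not be its own ancestor")
        }
        break
      }
      seen <- c(seen, cur)
      cur <- nxt
    }
  }

  ## metadata-level style requests ------------------------------------
  d <- c(d, style_diags(model$metadata, "<model>"))

  out <- if (length(d)) do.call(rbind, d) else empty_diag()
  out <- unique(out)
  out[order(out$severity, out$rule_id, out$subject, method = "radix"), ,
      drop = FALSE]
}

#' Format diagnostics as line-oriented text
#'
#' @param diags Data frame from [validate_model()].
#' @return Character vector, one `severity rule_id subject: message` line per
#'   finding.
#' @export
format_diagnostics <- function(diags) {
  if (nrow(diags) == 0L) return(character())
  sprintf("%s %s %s: %s", diags$severity, diags$rule_id, diags$subject,
          diags$message)
}

#' Serialize diagnostics as a JSON report
#'
#' @param diags Data frame from [validate_model()].
#' @return A JSON string (array of finding objects).
#' @export
diagnostics_json <- function(diags) {
  as.character(jsonlite::toJSON(diags, dataframe = "rows", auto_unbox = TRUE,
                                pretty = TRUE))
}
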
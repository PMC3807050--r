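NNSD_VERSION <- "1.0"

drop_null <- function(x) x[!vapply(x, is.null, TRUE)]

pop_to_list <- function(p) drop_null(list(
  id = p$id,
  label = drop_null(list(ephys = p$label$ephys, morph = p$label$morph)),
  layer = p$layer_ref, region = p$region_ref,
  extra = if (length(p$extra)) p$extra))

proj_to_list <- function(pr) drop_null(list(
  id = pr$id, source = pr$source, target = pr$target,
  excitation = pr$excitation, density = pr$density,
  extra = if (length(pr$extra)) pr$extra))

#' Serialize a model to the NNSD textual format
#'
#' NNSD is this package's JSON-dialect description format for neural
#' schematics (UTF-8, conventional extension `.nnsd.json`). Output is
#' deterministic: elements are emitted sorted by id with a stable key order,
#' so two invocations on equal models are byte-identical. Empty sections are
#' omitted; an empty model serializes to a document carrying only the format
#' version. Serialization refuses models that do not validate clean of
#' ERROR-severity findings.
#'
#' @param model An `nns_model`.
#' @param path Optional file path; when given the document is also written
#'   there.
#' @return The NNSD document as a single character string (invisibly when
#'   `path` is given).
#' @seealso [read_nnsd()]
#' @export
write_nnsd <- function(model, path = NULL) {
  stopifnot(inherits(model, "nns_model"))
  diags <- validate_model(model)
  if (any(diags$severity == "ERROR")) {
    abort_ns(paste0("refusing to serialize an invalid model:\n",
                    paste0("  ", format_diagnostics(diags), collapse = "\n")),
             "nns_validation_error")
  }
  doc <- list(format_version = NNSD_VERSION)
  if (length(model$metadata)) doc$metadata <- model$metadata
  if (length(model$regions)) doc$regions <- lapply(unname(model$regions),
    function(r) list(id = r$id, kind = r$kind, name = r$name,
                     display_order = r$display_order))
  if (length(model$layers)) doc$layers <- lapply(unname(model$layers),
    function(l) list(id = l$id, name = l$name, area = l$area_ref))
  if (length(model$populations))
    doc$populations <- lapply(unname(model$populations), pop_to_list)
  if (length(model$projections))
    doc$projections <- lapply(unname(model$projections), proj_to_list)
  if (length(model$units)) doc$units <- lapply(unname(model$units),
    function(u) list(id = u$id, name = u$name, members = I(u$members)))
  txt <- as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                       pretty = TRUE))
  txt <- paste0(txt, "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

take <- function(rec, known) rec[setdiff(names(rec), known)]

as_scalar <- function(x) if (is.list(x) && length(x) == 1L && is.null(names(x))) x[[1L]] else x

#' Read a model from the NNSD textual format
#'
#' Parses an NNSD document and reconstructs the model, enforcing every
#' notation invariant. Densities given in percent (key `density_percent`)
#' are converted to relative numbers by division by 100. Unknown keys on an
#' element are preserved in its extra attributes rather than dropped.
#'
#' @param x A file path, or the document text itself (anything containing a
#'   `{` or newline is treated as text).
#' @return An `nns_model`.
#' @seealso [write_nnsd()]
#' @export
read_nnsd <- function(x) {
  if (is_string(x) && !grepl("[{\n]", x)) {
    if (!file.exists(x)) abort_ns(sprintf("no such file: %s", x), "nns_parse_error")
    x <- paste(readLines(x, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  } else {
    x <- paste(x, collapse = "\n")
  }
  doc <- tryCatch(jsonlite::fromJSON(x, simplifyVector = FALSE),
                  error = function(e) {
                    abort_ns(paste0("NNSD parse error: ", conditionMessage(e)),
                             "nns_parse_error")
                  })
  if (!is.list(doc)) abort_ns("NNSD parse error: document is not an object",
                              "nns_parse_error")

  regions <- lapply(doc$regions %||% list(), function(r) {
    region(r[["id"]], r[["kind"]] %||% "area", name = r[["name"]] %||% r[["id"]],
           display_order = r[["display_order"]] %||% 1L)
  })
  layers <- lapply(doc$layers %||% list(), function(l) {
    layer(l[["id"]], l[["name"]], l[["area"]])
  })
  pops <- lapply(doc$populations %||% list(), function(p) {
    extra <- c(p[["extra"]] %||% list(),
               take(p, c("id", "label", "layer", "region", "extra")))
    population(p[["id"]], ephys = p[["label"]][["ephys"]],
               morph = p[["label"]][["morph"]],
               layer = p[["layer"]], region = p[["region"]],
               extra = lapply(extra, as_scalar))
  })
  projs <- lapply(doc$projections %||% list(), function(pr) {
    dens <- pr[["density"]]
    if (is.null(dens) && !is.null(pr[["density_percent"]])) {
      dens <- pr[["density_percent"]] / 100
    }
    extra <- c(pr[["extra"]] %||% list(),
               take(pr, c("id", "source", "target", "excitation", "density",
                          "density_percent", "extra")))
    projection(pr[["id"]], pr[["source"]], pr[["target"]],
               pr[["excitation"]] %||% "excitatory",
               density = dens, extra = lapply(extra, as_scalar))
  })
  units <- lapply(doc$units %||% list(), function(u) {
    unit_group(u[["id"]], name = u[["name"]] %||% u[["id"]],
               members = as.character(unlist(u[["members"]] %||% list())))
  })
  meta <- c(doc$metadata %||% list(),
            take(doc, c("format_version", "metadata", "regions", "layers",
                        "populations", "projections", "units")))
  nns_model(populations = pops, projections = projs, layers = layers,
            regions = regions, units = units,
            metadata = lapply(meta, as_scalar), check = TRUE)
}
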
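`%||%` <- function(x, y) if (is.null(x)) y else x

abort_ns <- function(msg, class) {
  stop(structure(
    class = c(class, "neuroschematics_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

# uppercase alphanumeric class tokens (RS, PYR, POIS, ...)
is_class_token <- function(x) is_string(x) && grepl("^[A-Z0-9]+$", x)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# deterministic coordinate formatting for serialized geometry
fmt_len <- function(x) {
  s <- sprintf("%.2f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

# densities and other model numbers are printed as stored, never rescaled
fmt_num <- function(x) format(x, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
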
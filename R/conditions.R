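# Classed error conditions so callers (and tests) can distinguish failure modes.

bioid_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "bioidflow_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = NULL)
  ))
}

format_error        <- function(msg, ...) bioid_error("bioid_format_error", msg, ...)
validation_error    <- function(msg, ...) bioid_error("bioid_validation_error", msg, ...)
config_error        <- function(msg, ...) bioid_error("bioid_config_error", msg, ...)
lookup_error        <- function(msg, ...) bioid_error("bioid_lookup_error", msg, ...)
normalization_error <- function(msg, ...) bioid_error("bioid_normalization_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# delimiter from file extension unless explicitly given
detect_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_delim_table <- function(path, sep = NULL, header = TRUE, comment.char = "") {
  utils::read.table(path,
    sep = detect_sep(path, sep), header = header,
    stringsAsFactors = FALSE, quote = "", comment.char = comment.char,
    check.names = FALSE
  )
}

write_delim_table <- function(x, path, sep = NULL) {
  utils::write.table(x, path,
    sep = detect_sep(path, sep), quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}
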
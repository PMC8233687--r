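# Internal helpers shared across modules.

# Two error families so the pipeline / CLI can map them to distinct exit
# codes: configuration problems (bad schema, bad arguments) vs data problems
# (malformed or inconsistent input files).
stop_config <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("mutdensity_config_error", "mutdensity_error",
                                "error", "condition")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("mutdensity_data_error", "mutdensity_error",
                                "error", "condition")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_tsv_strict <- function(path, ...) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE, ...)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Integer check tolerant of numeric storage ("60000" and 60000 both pass).
is_whole <- function(x) {
  is.numeric(x) & !is.na(x) & abs(x - round(x)) < 1e-8
}
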
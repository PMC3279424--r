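# internal helpers shared across modules

# Canonical key for an unordered protein pair; (A,B) and (B,A) collapse.
pair_key <- function(a, b) {
  swap <- b < a
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  paste(lo, hi, sep = "\t")
}

# sorted unique character set, never NA, never ""
as_charset <- function(x) {
  x <- as.character(x)
  x <- x[!is.na(x) & nzchar(x)]
  sort(unique(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hippie <- function(msg, class = "hippie_error", call. = FALSE) {
  stop(structure(
    class = c(class, "hippie_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

# condition class used by validators so callers (and the CLI) can
# distinguish bad data from missing files
stop_validation <- function(msg) stop_hippie(msg, class = "hippie_validation_error")

check_file_exists <- function(path) {
  if (!file.exists(path)) {
    stop_hippie(sprintf("input file not found: %s", path),
                class = "hippie_missing_input_error")
  }
  invisible(path)
}
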
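#' Technique reliability score tables
#'
#' PPI detection methods differ widely in how directly and reliably they
#' establish a physical interaction: structure determination (e.g. x-ray
#' crystallography) pins down a direct contact, affinity- and
#' complementation-based assays report binding with intermediate confidence,
#' while colocalization or cosedimentation only hint at association. A
#' technique score table maps each detection-method name -- and, where one
#' exists, its PSI-MI controlled-vocabulary code -- to a curated reliability
#' score between 0 ("no experiment assigned") and 10.
#'
#' Lookups resolve by PSI-MI code first and by normalized method name second.
#' Name normalization case-folds, collapses whitespace and strips hyphens and
#' slashes, so that spelling variants used by different source databases
#' ("Two-hybrid", "two hybrid") resolve to the same entry. On a conflicting
#' duplicate key the loader refuses the table.
#'
#' @param path Path to a tab-delimited table with a header line and columns
#'   `name`, `mi` (PSI-MI code `MI:nnnn`, may be empty) and `score` in
#'   \[0, 10\].
#' @return An object of class `technique_score_table`: a data frame with
#'   columns `name`, `norm_name`, `mi`, `score`.
#' @examples
#' tab <- default_technique_scores()
#' technique_score(tab, "x-ray crystallography")   # 10
#' technique_score(tab, mi = "MI:0254")            # genetic interference, 0
#' @export
load_technique_scores <- function(path) {
  check_file_exists(path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           na.strings = NULL)
  need <- c("name", "mi", "score")
  if (!all(need %in% names(raw))) {
    stop_validation(sprintf(
      "technique score table must have columns %s", paste(need, collapse = ", ")))
  }
  score <- suppressWarnings(as.numeric(raw$score))
  if (anyNA(score)) {
    stop_validation("technique score table: non-numeric score value")
  }
  if (any(score < 0 | score > 10)) {
    stop_validation("technique scores must lie in [0, 10]")
  }
  mi <- trimws(raw$mi)
  bad_mi <- nzchar(mi) & !grepl("^MI:[0-9]{4}$", mi)
  if (any(bad_mi)) {
    stop_validation(sprintf("malformed PSI-MI code(s): %s",
                            paste(unique(mi[bad_mi]), collapse = ", ")))
  }
  tab <- data.frame(
    name = trimws(raw$name),
    norm_name = normalize_technique(raw$name),
    mi = mi,
    score = score,
    stringsAsFactors = FALSE
  )
  # duplicate keys are allowed only when they agree on the score
  dup_conflict <- function(key, sc) {
    keep <- nzchar(key)
    any(vapply(split(sc[keep], key[keep]),
               function(s) length(unique(s)) > 1L, logical(1)))
  }
  if (dup_conflict(tab$mi, tab$score)) {
    stop_validation("conflicting scores for a duplicated PSI-MI code")
  }
  if (dup_conflict(tab$norm_name, tab$score)) {
    stop_validation("conflicting scores for a duplicated technique name")
  }
  class(tab) <- c("technique_score_table", "data.frame")
  tab
}

#' @rdname load_technique_scores
#' @export
default_technique_scores <- function() {
  load_technique_scores(
    system.file("extdata", "technique_scores.tsv", package = "hippie",
                mustWork = TRUE))
}

#' Normalize a detection-method name for lookup
#'
#' Case-folds, replaces hyphens and slashes by spaces, collapses runs of
#' whitespace and trims. Normalization is what makes "Two-hybrid",
#' "two hybrid" and "two  hybrid" the same key.
#'
#' @param x Character vector of method names.
#' @return Character vector of normalized keys.
#' @export
normalize_technique <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[-/]", " ", x)
  gsub("[[:space:]]+", " ", x)
}

#' Look up technique reliability scores
#'
#' Resolves by PSI-MI code when `mi` is given and found; otherwise by
#' normalized name. Unknown techniques score 0 and raise a warning: an
#' unrecognized method must never silently inflate a confidence score.
#'
#' @param table A `technique_score_table`.
#' @param name Character vector of method names (may be `NULL` if `mi` given).
#' @param mi Optional character vector of PSI-MI codes, same length as `name`
#'   (empty string / `NA` where absent).
#' @param warn Warn about unknown techniques (default `TRUE`).
#' @return Numeric vector of scores in \[0, 10\].
#' @export
technique_score <- function(table, name = NULL, mi = NULL, warn = TRUE) {
  stopifnot(inherits(table, "technique_score_table"))
  n <- max(length(name), length(mi))
  if (n == 0L) return(numeric(0))
  name <- if (is.null(name)) character(n) else as.character(name)
  mi <- if (is.null(mi)) character(n) else as.character(mi)
  mi[is.na(mi)] <- ""
  name[is.na(name)] <- ""

  out <- rep(NA_real_, n)
  has_mi <- nzchar(mi)
  if (any(has_mi)) {
    idx <- match(mi[has_mi], table$mi)
    out[has_mi] <- table$score[idx]
  }
  todo <- is.na(out)
  if (any(todo)) {
    idx <- match(normalize_technique(name[todo]), table$norm_name)
    out[todo] <- table$score[idx]
  }
  unknown <- is.na(out)
  if (any(unknown)) {
    if (warn) {
      shown <- unique(ifelse(nzchar(name[unknown]), name[unknown], mi[unknown]))
      warning(sprintf("unknown technique(s), scored 0: %s",
                      paste(shown, collapse = ", ")), call. = FALSE)
    }
    out[unknown] <- 0
  }
  out
}

# canonical storage key for a technique: the table's own name when the
# technique resolves, else the normalized raw name
technique_key <- function(table, name, mi = NULL) {
  n <- length(name)
  if (n == 0L) return(character(0))
  mi <- if (is.null(mi)) character(n) else as.character(mi)
  mi[is.na(mi)] <- ""
  key <- rep(NA_character_, n)
  has_mi <- nzchar(mi)
  if (any(has_mi)) key[has_mi] <- table$name[match(mi[has_mi], table$mi)]
  todo <- is.na(key)
  if (any(todo)) {
    key[todo] <- table$name[match(normalize_technique(name[todo]), table$norm_name)]
  }
  todo <- is.na(key)
  key[todo] <- normalize_technique(name[todo])
  key
}

#' @export
print.technique_score_table <- function(x, ...) {
  cat(sprintf("Technique score table: %d entries (%d with PSI-MI codes)\n",
              nrow(x), sum(nzchar(x$mi))))
  cat(sprintf("Score levels: %s\n",
              paste(sort(unique(x$score)), collapse = ", ")))
  invisible(x)
}
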
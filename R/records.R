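#' Source interaction records
#'
#' A set of raw interaction records as reported by one or more source
#' datasets, before identifier mapping and merging. Each record carries the
#' two interactor identifiers in their source namespace, the supporting
#' studies (PubMed IDs), the detection techniques (name plus PSI-MI code when
#' available), any PSI-MI interaction-type codes, the source dataset label,
#' and a flag marking genetic (as opposed to physical) interactions.
#'
#' @param ns_a,ns_b Identifier namespaces (e.g. `"uniprotkb"`).
#' @param id_a,id_b Source-namespace identifiers; must be non-empty.
#' @param pubmed_ids List of character vectors of PubMed IDs (may be empty,
#'   never blank strings).
#' @param tech_names,tech_mis Parallel lists: technique names and their PSI-MI
#'   codes (`""` where the source gave none).
#' @param interaction_types List of character vectors of PSI-MI
#'   interaction-type codes.
#' @param source_name Dataset label, recycled if scalar.
#' @param is_genetic Logical flag per record.
#' @return A `hippie_records` data frame, one row per record, with the set
#'   fields held as list columns (sorted, de-duplicated).
#' @export
hippie_records <- function(id_a, id_b, ns_a = "uniprotkb", ns_b = "uniprotkb",
                           pubmed_ids = NULL, tech_names = NULL,
                           tech_mis = NULL, interaction_types = NULL,
                           source_name = "unknown", is_genetic = FALSE) {
  n <- length(id_a)
  stopifnot(length(id_b) == n)
  if (n > 0L && (any(!nzchar(id_a)) || any(!nzchar(id_b)))) {
    stop_validation("interactor identifiers must be non-empty")
  }
  empty_list <- function(x) {
    if (is.null(x) || length(x) == 0L) return(rep(list(character(0)), n))
    if (!is.list(x)) x <- as.list(x)
    rep_len(x, n)
  }
  pubmed_ids <- lapply(empty_list(pubmed_ids), as_charset)
  interaction_types <- lapply(empty_list(interaction_types), as_charset)
  tech_names <- empty_list(tech_names)
  tech_mis <- if (is.null(tech_mis)) {
    lapply(tech_names, function(x) character(length(x)))
  } else {
    empty_list(tech_mis)
  }
  # de-duplicate technique (name, mi) pairs, keep name/mi aligned and sorted
  for (i in seq_len(n)) {
    nm <- as.character(tech_names[[i]])
    mi <- as.character(tech_mis[[i]])
    if (length(mi) != length(nm)) {
      stop_validation("tech_names and tech_mis must be parallel")
    }
    mi[is.na(mi)] <- ""
    keep <- !duplicated(paste(nm, mi)) & (nzchar(nm) | nzchar(mi))
    ord <- order(nm[keep], mi[keep])
    tech_names[[i]] <- nm[keep][ord]
    tech_mis[[i]] <- mi[keep][ord]
  }
  out <- data.frame(ns_a = rep_len(as.character(ns_a), n),
                    id_a = as.character(id_a),
                    ns_b = rep_len(as.character(ns_b), n),
                    id_b = as.character(id_b),
                    source_name = rep_len(as.character(source_name), n),
                    is_genetic = rep_len(as.logical(is_genetic), n),
                    stringsAsFactors = FALSE)
  out$pubmed_ids <- pubmed_ids
  out$tech_names <- tech_names
  out$tech_mis <- tech_mis
  out$interaction_types <- interaction_types
  class(out) <- c("hippie_records", "data.frame")
  out
}

#' @export
print.hippie_records <- function(x, ...) {
  cat(sprintf("%d source interaction record(s) from %d dataset(s)\n",
              nrow(x), length(unique(x$source_name))))
  if (any(x$is_genetic)) {
    cat(sprintf("  %d flagged genetic\n", sum(x$is_genetic)))
  }
  invisible(x)
}

#' Read a simple tab-delimited source dataset
#'
#' A minimal source dialect for datasets not distributed in PSI-MI TAB:
#' a header line and tab-separated columns `id_a`, `id_b`, `pmids`
#' (comma-separated), `methods` (pipe-separated entries, each a method name
#' optionally followed by ` [MI:nnnn]`), and optionally `source`, `genetic`
#' (0/1) and `types` (comma-separated PSI-MI codes).
#'
#' @param path File path.
#' @param source_name Dataset label used when the file has no `source` column.
#' @param namespace Identifier namespace of the `id_a`/`id_b` columns.
#' @return A [hippie_records] data frame.
#' @export
read_source_table <- function(path, source_name = basename(path),
                              namespace = "uniprotkb") {
  check_file_exists(path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           na.strings = NULL)
  need <- c("id_a", "id_b", "pmids", "methods")
  if (!all(need %in% names(raw))) {
    stop_hippie(sprintf("source table must have columns %s",
                        paste(need, collapse = ", ")),
                class = "hippie_format_error")
  }
  split_csv <- function(x) lapply(strsplit(x, ",", fixed = TRUE),
                                  function(v) as_charset(trimws(v)))
  methods <- strsplit(raw$methods, "|", fixed = TRUE)
  tech_names <- vector("list", nrow(raw))
  tech_mis <- vector("list", nrow(raw))
  for (i in seq_along(methods)) {
    entries <- trimws(methods[[i]])
    entries <- entries[nzchar(entries)]
    mi <- rep("", length(entries))
    has <- grepl("\\[MI:[0-9]{4}\\]$", entries)
    mi[has] <- sub("^.*\\[(MI:[0-9]{4})\\]$", "\\1", entries[has])
    nm <- trimws(sub("\\s*\\[MI:[0-9]{4}\\]$", "", entries))
    tech_names[[i]] <- nm
    tech_mis[[i]] <- mi
  }
  hippie_records(
    id_a = trimws(raw$id_a), id_b = trimws(raw$id_b),
    ns_a = namespace, ns_b = namespace,
    pubmed_ids = split_csv(raw$pmids),
    tech_names = tech_names, tech_mis = tech_mis,
    interaction_types = if ("types" %in% names(raw)) split_csv(raw$types),
    source_name = if ("source" %in% names(raw)) raw$source else source_name,
    is_genetic = if ("genetic" %in% names(raw)) raw$genetic %in% c("1", "TRUE", "true") else FALSE
  )
}
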
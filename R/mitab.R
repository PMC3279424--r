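#' Read and write PSI-MI TAB 2.5
#'
#' PSI-MI TAB 2.5 is the Proteomics Standards Initiative's 15-column
#' tab-delimited interchange format for molecular interactions: interactor
#' identifiers, aliases, detection methods and interaction types as
#' controlled-vocabulary cells of the form `psi-mi:"MI:nnnn"(label)`,
#' publications as `pubmed:<id>`, multi-valued cells pipe-separated and `-`
#' as the missing-value token. Files with more than 15 columns (later MITAB
#' versions) are accepted; the extra columns are ignored.
#'
#' `read_psimitab25` returns one [hippie_records] row per line. Malformed
#' cells are record-level problems: the offending value is skipped, parsing
#' continues, and all problems are collected in the `"problems"` attribute
#' (a data frame with `line` and `message`) and summarized in one warning.
#' A line with fewer than 15 columns is a hard format error.
#'
#' A record is flagged genetic when any of its interaction-type codes is in
#' `genetic_types` (default `MI:0208`, "genetic interaction").
#'
#' @param path File path.
#' @param genetic_types PSI-MI interaction-type codes treated as genetic.
#' @return A [hippie_records] data frame with attribute `"problems"`.
#' @export
read_psimitab25 <- function(path, genetic_types = "MI:0208") {
  check_file_exists(path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(hippie_records(character(0), character(0)))
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(cells)
  if (any(ncols < 15L)) {
    stop_hippie(sprintf(
      "PSI-MI TAB 2.5 requires 15 columns; line %d has %d",
      which(ncols < 15L)[1L], min(ncols)), class = "hippie_format_error")
  }

  problems <- list()
  note <- function(line, msg) {
    problems[[length(problems) + 1L]] <<- data.frame(
      line = line, message = msg, stringsAsFactors = FALSE)
  }

  n <- length(cells)
  ns_a <- id_a <- ns_b <- id_b <- src <- character(n)
  pmids <- tnames <- tmis <- itypes <- vector("list", n)
  ok <- rep(TRUE, n)

  for (i in seq_len(n)) {
    row <- cells[[i]]
    a <- parse_mitab_id(row[1L])
    b <- parse_mitab_id(row[2L])
    if (is.null(a) || is.null(b)) {
      note(i, "missing or malformed interactor identifier")
      ok[i] <- FALSE
      next
    }
    ns_a[i] <- a[1L]; id_a[i] <- a[2L]
    ns_b[i] <- b[1L]; id_b[i] <- b[2L]

    pub <- mitab_split(row[9L])
    is_pm <- grepl("^pubmed:", pub)
    if (length(pub) && !all(is_pm)) {
      note(i, sprintf("non-pubmed publication reference(s): %s",
                      paste(pub[!is_pm], collapse = "|")))
    }
    pm <- sub("^pubmed:", "", pub[is_pm])
    if (any(!nzchar(pm))) {
      note(i, "blank pubmed identifier")
      pm <- pm[nzchar(pm)]
    }
    pmids[[i]] <- pm

    det <- parse_cv_cell(row[7L])
    if (!is.null(det$bad) && length(det$bad)) {
      note(i, sprintf("malformed detection-method value(s): %s",
                      paste(det$bad, collapse = "|")))
    }
    tnames[[i]] <- det$name
    tmis[[i]] <- det$mi

    typ <- parse_cv_cell(row[12L])
    if (!is.null(typ$bad) && length(typ$bad)) {
      note(i, sprintf("malformed interaction-type value(s): %s",
                      paste(typ$bad, collapse = "|")))
    }
    # types are kept as codes; bare labels in the type column are ignored
    itypes[[i]] <- typ$mi[nzchar(typ$mi)]

    sdb <- parse_cv_cell(row[13L])
    src[i] <- if (length(sdb$name)) sdb$name[1L] else "unknown"
  }

  recs <- hippie_records(
    id_a = id_a[ok], id_b = id_b[ok], ns_a = ns_a[ok], ns_b = ns_b[ok],
    pubmed_ids = pmids[ok], tech_names = tnames[ok], tech_mis = tmis[ok],
    interaction_types = itypes[ok], source_name = src[ok],
    is_genetic = vapply(itypes[ok], function(t) any(t %in% genetic_types),
                        logical(1))
  )
  probs <- if (length(problems)) do.call(rbind, problems) else
    data.frame(line = integer(0), message = character(0))
  attr(recs, "problems") <- probs
  if (nrow(probs)) {
    warning(sprintf("%d problem(s) while parsing %s; see attr(., 'problems')",
                    nrow(probs), path), call. = FALSE)
  }
  recs
}

# "uniprotkb:P12345" -> c("uniprotkb", "P12345"); NULL when missing/malformed
parse_mitab_id <- function(cell) {
  first <- mitab_split(cell)
  if (!length(first)) return(NULL)
  x <- first[1L]
  sep <- regexpr(":", x, fixed = TRUE)
  if (sep < 1L || sep == nchar(x)) return(NULL)
  c(substr(x, 1L, sep - 1L), substring(x, sep + 1L))
}

mitab_split <- function(cell) {
  if (is.na(cell) || cell == "-" || !nzchar(cell)) return(character(0))
  strsplit(cell, "|", fixed = TRUE)[[1L]]
}

# controlled-vocabulary cell: entries psi-mi:"MI:nnnn"(label); entries not
# starting with psi-mi: are accepted as bare labels (sources without CV
# terms); psi-mi: entries that fail the grammar are reported as bad
parse_cv_cell <- function(cell) {
  vals <- mitab_split(cell)
  if (!length(vals)) return(list(name = character(0), mi = character(0),
                                 bad = character(0)))
  cv <- startsWith(vals, "psi-mi:")
  m <- regmatches(vals, regexec('^psi-mi:"(MI:[0-9]{4})"(?:\\((.*)\\))?$',
                                vals))
  name <- mi <- character(0)
  bad <- character(0)
  for (i in seq_along(vals)) {
    if (cv[i]) {
      if (length(m[[i]]) >= 2L) {
        mi <- c(mi, m[[i]][2L])
        lab <- if (length(m[[i]]) >= 3L) m[[i]][3L] else ""
        name <- c(name, lab)
      } else {
        bad <- c(bad, vals[i])
      }
    } else {
      name <- c(name, vals[i])
      mi <- c(mi, "")
    }
  }
  list(name = name, mi = mi, bad = bad)
}

# small label dictionary for codes we may need to print
mi_label <- function(code) {
  dict <- c("MI:0208" = "genetic interaction",
            "MI:0915" = "physical association",
            "MI:0407" = "direct interaction",
            "MI:0403" = "colocalization",
            "MI:0914" = "association")
  lab <- unname(dict[code])
  ifelse(is.na(lab), "unspecified", lab)
}

#' @rdname read_psimitab25
#'
#' @param records A [hippie_records] data frame.
#' @details `write_psimitab25` emits a deterministic file: records are sorted
#'   by canonical pair (then source and studies), set-valued cells are
#'   written in sorted order, techniques with a PSI-MI code as
#'   `psi-mi:"MI:nnnn"(name)` and code-less techniques as bare labels.
#'   A written file re-read with `read_psimitab25` yields the identical
#'   record list provided each record's genetic flag is consistent with its
#'   interaction-type codes (the flag travels in-band as type `MI:0208`).
#' @export
write_psimitab25 <- function(records, path) {
  stopifnot(inherits(records, "hippie_records"))
  n <- nrow(records)
  if (n == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  cv_or_label <- function(name, mi) {
    if (!length(name)) return("-")
    out <- ifelse(nzchar(mi), sprintf('psi-mi:"%s"(%s)', mi, name), name)
    paste(out[order(name, mi)], collapse = "|")
  }
  lines <- character(n)
  for (i in seq_len(n)) {
    pm <- records$pubmed_ids[[i]]
    ty <- records$interaction_types[[i]]
    lines[i] <- paste(c(
      paste0(records$ns_a[i], ":", records$id_a[i]),
      paste0(records$ns_b[i], ":", records$id_b[i]),
      "-", "-", "-", "-",
      cv_or_label(records$tech_names[[i]], records$tech_mis[[i]]),
      "-",
      if (length(pm)) paste0("pubmed:", pm, collapse = "|") else "-",
      "taxid:9606(human)", "taxid:9606(human)",
      if (length(ty)) paste(sprintf('psi-mi:"%s"(%s)', ty, mi_label(ty)),
                            collapse = "|") else "-",
      records$source_name[i],
      "-", "-"
    ), collapse = "\t")
  }
  ord <- order(pair_key(paste0(records$ns_a, ":", records$id_a),
                        paste0(records$ns_b, ":", records$id_b)),
               records$source_name,
               vapply(records$pubmed_ids, function(p)
                 paste(p, collapse = ","), character(1)))
  writeLines(lines[ord], path)
  invisible(path)
}
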
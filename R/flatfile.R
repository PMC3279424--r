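#' Read and write the six-column scored flat file
#'
#' The distribution format for a scored network: tab-separated columns
#' (1) protein identifier and (2) gene identifier of the first partner,
#' (3) protein identifier and (4) gene identifier of the second partner,
#' (5) confidence score and (6) an evidence comment. The comment encodes the
#' evidence ledger as semicolon-separated classes, each class a label
#' followed by a comma-separated value list:
#' `experiments:<names>;pmids:<ids>;sources:<labels>`.
#'
#' Two optional extension classes, `organisms:` and `types:`, carry
#' ortholog-organism evidence and PSI-MI interaction-type codes; they are
#' written only when non-empty so that files restricted to the three core
#' classes stay exactly in the core dialect. An unknown class label is
#' ignored with a warning.
#'
#' A protein mapping to several genes is expanded to one line per gene
#' combination: every line repeats the protein pair, score and comment and
#' varies only in the gene columns. `read_hippie_flat` reassembles those
#' lines into a single interaction.
#'
#' Scores are written rounded to 2 decimals (round-half-even); full precision
#' is an in-memory property. `write_hippie_flat` refuses unscored networks.
#'
#' @param path File path.
#' @return `read_hippie_flat`: a [hippie_network].
#' @export
read_hippie_flat <- function(path) {
  check_file_exists(path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(hippie_network(character(0), character(0)))
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(cells) != 6L)) {
    stop_hippie(sprintf("flat file requires 6 columns; line %d has %d",
                        which(lengths(cells) != 6L)[1L],
                        lengths(cells)[lengths(cells) != 6L][1L]),
                class = "hippie_format_error")
  }
  m <- do.call(rbind, cells)
  score <- suppressWarnings(as.numeric(m[, 5L]))
  if (anyNA(score)) {
    stop_validation("flat file: non-numeric score")
  }
  if (any(score < 0 | score > 1)) {
    stop_validation("flat file: score outside [0, 1]")
  }

  # canonicalize line orientation so grouping is order-independent
  swap <- m[, 3L] < m[, 1L]
  pa <- ifelse(swap, m[, 3L], m[, 1L])
  ga <- ifelse(swap, m[, 4L], m[, 2L])
  pb <- ifelse(swap, m[, 1L], m[, 3L])
  gb <- ifelse(swap, m[, 2L], m[, 4L])

  key <- paste(pa, pb, m[, 6L], m[, 5L], sep = "\r")
  groups <- split(seq_along(key), factor(key, levels = unique(key)))

  n <- length(groups)
  protein_a <- protein_b <- character(n)
  genes_a <- genes_b <- vector("list", n)
  studies <- techniques <- sources <- organisms <- itypes <- vector("list", n)
  sc <- numeric(n)
  for (g in seq_len(n)) {
    idx <- groups[[g]]
    protein_a[g] <- pa[idx[1L]]
    protein_b[g] <- pb[idx[1L]]
    genes_a[[g]] <- as_charset(setdiff(ga[idx], "-"))
    genes_b[[g]] <- as_charset(setdiff(gb[idx], "-"))
    sc[g] <- score[idx[1L]]
    ev <- parse_evidence_comment(m[idx[1L], 6L])
    techniques[[g]] <- ev$experiments
    studies[[g]] <- ev$pmids
    sources[[g]] <- ev$sources
    organisms[[g]] <- ev$organisms
    itypes[[g]] <- ev$types
  }
  hippie_network(protein_a, protein_b, genes_a, genes_b,
                 studies = studies, techniques = techniques,
                 sources = sources, organisms = organisms,
                 interaction_types = itypes, score = sc)
}

parse_evidence_comment <- function(comment) {
  out <- list(experiments = character(0), pmids = character(0),
              sources = character(0), organisms = character(0),
              types = character(0))
  if (!nzchar(comment) || comment == "-") return(out)
  classes <- strsplit(comment, ";", fixed = TRUE)[[1L]]
  for (cl in classes) {
    sep <- regexpr(":", cl, fixed = TRUE)
    if (sep < 1L) {
      warning(sprintf("malformed evidence class '%s' ignored", cl),
              call. = FALSE)
      next
    }
    label <- trimws(substr(cl, 1L, sep - 1L))
    vals <- as_charset(trimws(strsplit(substring(cl, sep + 1L), ",",
                                       fixed = TRUE)[[1L]]))
    if (label %in% names(out)) {
      out[[label]] <- vals
    } else {
      warning(sprintf("unknown evidence class '%s' ignored", label),
              call. = FALSE)
    }
  }
  out
}

format_evidence_comment <- function(techniques, studies, sources,
                                    organisms, types) {
  parts <- c(
    paste0("experiments:", paste(techniques, collapse = ",")),
    paste0("pmids:", paste(studies, collapse = ",")),
    paste0("sources:", paste(sources, collapse = ","))
  )
  if (length(organisms)) {
    parts <- c(parts, paste0("organisms:", paste(organisms, collapse = ",")))
  }
  if (length(types)) {
    parts <- c(parts, paste0("types:", paste(types, collapse = ",")))
  }
  paste(parts, collapse = ";")
}

#' @rdname read_hippie_flat
#' @param net A fully scored [hippie_network].
#' @export
write_hippie_flat <- function(net, path) {
  stopifnot(inherits(net, "hippie_network"))
  if (anyNA(net$score)) {
    stop_hippie("write_hippie_flat: network contains unscored interactions",
                class = "hippie_contract_error")
  }
  lines <- character(0)
  if (nrow(net)) {
    per <- vector("list", nrow(net))
    for (i in seq_len(nrow(net))) {
      ga <- net$genes_a[[i]]
      gb <- net$genes_b[[i]]
      if (!length(ga)) ga <- "-"
      if (!length(gb)) gb <- "-"
      combos <- expand.grid(gb = gb, ga = ga, stringsAsFactors = FALSE,
                            KEEP.OUT.ATTRS = FALSE)
      comment <- format_evidence_comment(
        net$techniques[[i]], net$studies[[i]], net$sources[[i]],
        net$organisms[[i]], net$interaction_types[[i]])
      per[[i]] <- sprintf("%s\t%s\t%s\t%s\t%s\t%s",
                          net$protein_a[i], combos$ga,
                          net$protein_b[i], combos$gb,
                          sprintf("%.2f", net$score[i]), comment)
    }
    lines <- unlist(per)
  }
  writeLines(lines, path)
  invisible(path)
}
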
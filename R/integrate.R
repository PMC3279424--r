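#' Default ortholog species
#'
#' The non-human model organisms in which ortholog evidence is accepted. An
#' interaction between the orthologs of a human protein pair observed in one
#' of these species raises the pair's organism count; evidence from a
#' species outside the configured list is a validation error. The list is
#' user-extensible via the `species` argument of [merge_sources()].
#'
#' @return Character vector of species names.
#' @export
default_ortholog_species <- function() {
  c("Bos taurus", "Caenorhabditis elegans", "Canis familiaris",
    "Drosophila melanogaster", "Gallus gallus", "Mus musculus",
    "Rattus norvegicus", "Saccharomyces cerevisiae", "Sus scrofa")
}

#' Read ortholog-evidence records
#'
#' Tab-delimited, no header: `protein_a`, `protein_b` (canonical human
#' protein identifiers) and `species`.
#'
#' @param path File path.
#' @return Data frame with columns `protein_a`, `protein_b`, `species`.
#' @export
read_ortholog_evidence <- function(path) {
  check_file_exists(path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      species = character(0), stringsAsFactors = FALSE))
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(cells) != 3L)) {
    stop_hippie("ortholog evidence file requires 3 tab-separated columns",
                class = "hippie_format_error")
  }
  m <- do.call(rbind, cells)
  data.frame(protein_a = m[, 1L], protein_b = m[, 2L], species = m[, 3L],
             stringsAsFactors = FALSE)
}

#' Merge source datasets into a non-redundant network
#'
#' The integration step: all records from all source datasets are mapped to
#' canonical protein and gene identifiers, genetic interactions and records
#' with unmappable endpoints are excluded, and records describing the same
#' canonical unordered pair are collapsed into one interaction whose
#' studies, techniques, sources and interaction types are the unions over
#' the contributing records. Technique names are canonicalized against the
#' technique score table, so spelling variants of one method count once.
#'
#' Ortholog evidence only ever strengthens an interaction that already has
#' human experimental support: organism annotations are attached to existing
#' pairs, and ortholog records for pairs with no human record are discarded
#' (their count is reported in the `"ortholog_only"` attribute). A species
#' outside `species` is a validation error.
#'
#' Merging is idempotent and order-independent: permuting or duplicating the
#' input datasets never changes the result.
#'
#' @param datasets A list of [hippie_records] data frames (or a single one).
#' @param mapping An [id_mapping_table].
#' @param orthologs Optional data frame from [read_ortholog_evidence()].
#' @param technique_table A `technique_score_table` used to canonicalize
#'   technique names.
#' @param species Allowed ortholog species.
#' @return A [hippie_network] (unscored). Attributes: `"drops"` (drop
#'   notices for unmappable records), `"n_genetic"` (genetic records
#'   excluded), `"ortholog_only"` (discarded ortholog-only pairs), and
#'   `"provenance"` (the per-record study/technique ledger needed for
#'   leave-one-study-out analysis).
#' @export
merge_sources <- function(datasets, mapping, orthologs = NULL,
                          technique_table = default_technique_scores(),
                          species = default_ortholog_species()) {
  if (inherits(datasets, "hippie_records")) datasets <- list(datasets)
  stopifnot(all(vapply(datasets, inherits, logical(1), "hippie_records")))
  recs <- do.call(rbind, lapply(datasets, as.data.frame))
  if (is.null(recs) || nrow(recs) == 0L) {
    net <- hippie_network(character(0), character(0))
    attr(net, "provenance") <- empty_provenance()
    attr(net, "drops") <- empty_drops()
    attr(net, "n_genetic") <- 0L
    attr(net, "ortholog_only") <- 0L
    return(net)
  }
  if (nrow(mapping) == 0L) {
    stop_hippie("empty identifier mapping table", class = "hippie_config_error")
  }

  n_genetic <- sum(recs$is_genetic)
  recs <- recs[!recs$is_genetic, , drop = FALSE]

  ia <- map_lookup(mapping, recs$ns_a, recs$id_a)
  ib <- map_lookup(mapping, recs$ns_b, recs$id_b)
  unmapped <- is.na(ia) | is.na(ib)
  drops <- empty_drops()
  if (any(unmapped)) {
    w <- which(unmapped)
    drops <- data.frame(
      source_name = recs$source_name[w],
      id_a = paste0(recs$ns_a[w], ":", recs$id_a[w]),
      id_b = paste0(recs$ns_b[w], ":", recs$id_b[w]),
      reason = ifelse(is.na(ia[w]) & is.na(ib[w]), "both endpoints unmappable",
                      ifelse(is.na(ia[w]), "first endpoint unmappable",
                             "second endpoint unmappable")),
      stringsAsFactors = FALSE)
    recs <- recs[!unmapped, , drop = FALSE]
    ia <- ia[!unmapped]
    ib <- ib[!unmapped]
  }

  if (nrow(recs) == 0L) {
    net <- hippie_network(character(0), character(0))
    attr(net, "provenance") <- empty_provenance()
    attr(net, "drops") <- drops
    attr(net, "n_genetic") <- n_genetic
    attr(net, "ortholog_only") <- 0L
    return(net)
  }

  pa <- mapping$protein_id[ia]
  pb <- mapping$protein_id[ib]
  ga <- mapping$genes[ia]
  gb <- mapping$genes[ib]
  swap <- pb < pa
  if (any(swap)) {
    tmp <- pa[swap]; pa[swap] <- pb[swap]; pb[swap] <- tmp
    gtmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- gtmp
  }
  key <- pair_key(pa, pb)
  tech_keys <- mapply(function(nm, mi) {
    as_charset(technique_key(technique_table, nm, mi))
  }, recs$tech_names, recs$tech_mis, SIMPLIFY = FALSE)

  groups <- split(seq_along(key), factor(key, levels = sort(unique(key))))
  m <- length(groups)
  protein_a <- protein_b <- character(m)
  genes_a <- genes_b <- studies <- techniques <- sources <- itypes <-
    vector("list", m)
  prov <- vector("list", m)
  for (g in seq_len(m)) {
    idx <- groups[[g]]
    protein_a[g] <- pa[idx[1L]]
    protein_b[g] <- pb[idx[1L]]
    genes_a[[g]] <- as_charset(unlist(ga[idx]))
    genes_b[[g]] <- as_charset(unlist(gb[idx]))
    studies[[g]] <- as_charset(unlist(recs$pubmed_ids[idx]))
    techniques[[g]] <- as_charset(unlist(tech_keys[idx]))
    sources[[g]] <- as_charset(recs$source_name[idx])
    itypes[[g]] <- as_charset(unlist(recs$interaction_types[idx]))
    # per-record ledger rows: each (study or "", technique or "") pairing
    prov[[g]] <- do.call(rbind, lapply(idx, function(i) {
      st <- recs$pubmed_ids[[i]]
      te <- tech_keys[[i]]
      if (!length(st)) st <- ""
      if (!length(te)) te <- ""
      expand.grid(pair = names(groups)[g], study = st, technique = te,
                  stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    }))
  }
  provenance <- unique(do.call(rbind, prov))
  provenance <- provenance[order(provenance$pair, provenance$study,
                                 provenance$technique), , drop = FALSE]
  rownames(provenance) <- NULL

  net <- hippie_network(protein_a, protein_b, genes_a, genes_b,
                        studies = studies, techniques = techniques,
                        sources = sources, interaction_types = itypes)

  ortholog_only <- 0L
  if (!is.null(orthologs) && nrow(orthologs)) {
    bad <- setdiff(unique(orthologs$species), species)
    if (length(bad)) {
      stop_validation(sprintf("ortholog species not in configured list: %s",
                              paste(bad, collapse = ", ")))
    }
    okey <- pair_key(orthologs$protein_a, orthologs$protein_b)
    keys <- network_keys(net)
    hit <- match(okey, keys)
    ortholog_only <- length(unique(okey[is.na(hit)]))
    for (i in which(!is.na(hit))) {
      r <- hit[i]
      net$organisms[[r]] <- as_charset(c(net$organisms[[r]],
                                         orthologs$species[i]))
    }
  }

  attr(net, "provenance") <- provenance
  attr(net, "drops") <- drops
  attr(net, "n_genetic") <- n_genetic
  attr(net, "ortholog_only") <- ortholog_only
  net
}

empty_drops <- function() {
  data.frame(source_name = character(0), id_a = character(0),
             id_b = character(0), reason = character(0),
             stringsAsFactors = FALSE)
}

empty_provenance <- function() {
  data.frame(pair = character(0), study = character(0),
             technique = character(0), stringsAsFactors = FALSE)
}
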
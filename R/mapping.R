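#' Identifier mapping tables
#'
#' Source databases report interactors in mixed namespaces. A mapping table
#' resolves each (namespace, source identifier) to one canonical protein
#' identifier -- the canonical representative, never a splice form -- plus a
#' non-empty set of gene identifiers. A protein encoded by duplicated
#' genomic loci legitimately maps to more than one gene; downstream, such
#' interactions are expanded over all gene combinations.
#'
#' File format: tab-delimited, no header, four columns
#' `namespace`, `source_id`, `protein_id`, `gene_ids` (comma-separated).
#'
#' @param path File path.
#' @return An object of class `id_mapping_table`.
#' @export
read_id_mapping <- function(path) {
  check_file_exists(path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(id_mapping_table(character(0), character(0), character(0), list()))
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(cells) != 4L)) {
    stop_hippie("id mapping table requires 4 tab-separated columns",
                class = "hippie_format_error")
  }
  m <- do.call(rbind, cells)
  id_mapping_table(
    namespace = m[, 1L], source_id = m[, 2L], protein_id = m[, 3L],
    genes = lapply(strsplit(m[, 4L], ",", fixed = TRUE),
                   function(g) as_charset(trimws(g)))
  )
}

#' @rdname read_id_mapping
#' @param namespace,source_id,protein_id Character vectors, one entry per
#'   mapped identifier.
#' @param genes List of non-empty gene-identifier vectors.
#' @export
id_mapping_table <- function(namespace, source_id, protein_id, genes) {
  n <- length(source_id)
  stopifnot(length(protein_id) == n, length(genes) == n)
  genes <- lapply(genes, as_charset)
  if (n > 0L && any(lengths(genes) == 0L)) {
    stop_validation("every mapped protein needs at least one gene identifier")
  }
  out <- data.frame(namespace = rep_len(as.character(namespace), n),
                    source_id = as.character(source_id),
                    protein_id = as.character(protein_id),
                    stringsAsFactors = FALSE)
  out$genes <- genes
  key <- paste(out$namespace, out$source_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop_validation("duplicate (namespace, source_id) in mapping table")
  }
  attr(out, "key") <- key
  class(out) <- c("id_mapping_table", "data.frame")
  out
}

#' @export
print.id_mapping_table <- function(x, ...) {
  cat(sprintf("Identifier mapping: %d source id(s) -> %d canonical protein(s)\n",
              nrow(x), length(unique(x$protein_id))))
  invisible(x)
}

# vectorized lookup; returns row indices into the table (NA = unmappable)
map_lookup <- function(table, namespace, source_id) {
  match(paste(namespace, source_id, sep = "\r"), attr(table, "key"))
}

#' Map one source record to canonical identifiers
#'
#' Resolves both endpoints of a record through the mapping table. When both
#' endpoints map, returns the interaction skeleton: the canonical unordered
#' pair, the per-endpoint gene sets (whose cross product is the set of gene
#' combinations), and the record's evidence. When either endpoint is not in
#' the table the record is excluded and a drop notice (reason and offending
#' identifier) is returned instead -- drops are data, not errors.
#'
#' @param rec A single-row [hippie_records].
#' @param table An [id_mapping_table].
#' @return A list with `mapped` (logical); on success `protein_a`,
#'   `protein_b`, `genes_a`, `genes_b`, `gene_combinations` (data frame of
#'   unordered gene pairs) and `record`; on failure `reason`.
#' @export
map_record <- function(rec, table) {
  stopifnot(inherits(rec, "hippie_records"), nrow(rec) == 1L)
  if (nrow(table) == 0L) {
    stop_hippie("empty identifier mapping table",
                class = "hippie_config_error")
  }
  ia <- map_lookup(table, rec$ns_a, rec$id_a)
  ib <- map_lookup(table, rec$ns_b, rec$id_b)
  if (is.na(ia) || is.na(ib)) {
    bad <- c(if (is.na(ia)) sprintf("%s:%s", rec$ns_a, rec$id_a),
             if (is.na(ib)) sprintf("%s:%s", rec$ns_b, rec$id_b))
    return(list(mapped = FALSE,
                reason = sprintf("unmappable endpoint(s): %s",
                                 paste(bad, collapse = ", "))))
  }
  pa <- table$protein_id[ia]
  pb <- table$protein_id[ib]
  ga <- table$genes[[ia]]
  gb <- table$genes[[ib]]
  if (pb < pa) {
    tmp <- pa; pa <- pb; pb <- tmp
    gtmp <- ga; ga <- gb; gb <- gtmp
  }
  combos <- expand.grid(gene_b = gb, gene_a = ga, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)[, c("gene_a", "gene_b")]
  list(mapped = TRUE, protein_a = pa, protein_b = pb,
       genes_a = ga, genes_b = gb, gene_combinations = combos,
       record = rec)
}
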
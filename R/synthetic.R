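#' Specification for synthetic fixture generation
#'
#' The synthetic generator emulates the *evidence structure* of an
#' integrated PPI collection -- not its topology: how often a pair is
#' re-reported across studies, which detection techniques support it, how
#' often orthologs interact in non-human species, identifier ambiguity, and
#' contamination with genetic interactions and unmappable identifiers.
#' That is exactly the structure the scoring and leave-one-study-out
#' machinery consume, so every module is testable with no download.
#'
#' Defaults reflect a realistic integrated collection: most interactions
#' are reported in a single study and replication across several studies is
#' the informative minority; replicate studies typically reuse the same
#' assay, so techniques are drawn once per pair and shared by its studies.
#'
#' @param n_proteins Number of distinct proteins.
#' @param n_interactions Number of distinct true interacting pairs.
#' @param study_multiplicity Named numeric vector: probability that a pair
#'   is reported by 1, 2, ... studies (names are the counts).
#' @param n_studies Size of the synthetic study pool (PubMed-like IDs
#'   disjoint from real PubMed ranges).
#' @param n_sources Number of source datasets the records are spread over.
#' @param techniques_per_pair Integer vector sampled uniformly for the
#'   number of distinct techniques per pair.
#' @param technique_pool Optional data frame (`name`, `mi`) to sample
#'   techniques from; defaults to the packaged technique table, so the
#'   sampled reliability scores follow the table's own composition (many
#'   mid-range assays, few top-tier ones).
#' @param organism_rate Per-species probability that ortholog evidence
#'   exists for a pair.
#' @param n_ortholog_only Ortholog records planted for pairs *without*
#'   human evidence (must be discarded by integration).
#' @param gene_ambiguity_rate Probability that a protein maps to 2 genes.
#' @param genetic_rate Per-record probability of being a genetic
#'   interaction record.
#' @param unmappable_rate Per-record probability that one endpoint is
#'   replaced by an identifier absent from the mapping table.
#' @param seed Integer seed; fixture generation is bit-reproducible under a
#'   fixed seed.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 80L,
                           n_interactions = 220L,
                           study_multiplicity = c("1" = 0.60, "2" = 0.20,
                                                  "3" = 0.12, "4" = 0.08),
                           n_studies = 14L,
                           n_sources = 3L,
                           techniques_per_pair = 1:2,
                           technique_pool = NULL,
                           organism_rate = 0.03,
                           n_ortholog_only = 3L,
                           gene_ambiguity_rate = 0.10,
                           genetic_rate = 0.05,
                           unmappable_rate = 0.03,
                           seed = 1L) {
  rates <- c(organism_rate, gene_ambiguity_rate, genetic_rate,
             unmappable_rate)
  if (any(rates < 0 | rates > 1)) {
    stop_validation("all rates must lie in [0, 1]")
  }
  if (abs(sum(study_multiplicity) - 1) > 1e-9 || any(study_multiplicity < 0)) {
    stop_validation("study_multiplicity must be a probability distribution")
  }
  if (is.null(names(study_multiplicity)) ||
      anyNA(suppressWarnings(as.integer(names(study_multiplicity))))) {
    stop_validation("study_multiplicity must be named by integer study counts")
  }
  if (max(as.integer(names(study_multiplicity))) > n_studies) {
    stop_validation("multiplicity exceeds the study pool size")
  }
  if (n_interactions > n_proteins * (n_proteins + 1) / 2) {
    stop_validation("more interactions requested than distinct pairs exist")
  }
  structure(list(
    n_proteins = as.integer(n_proteins),
    n_interactions = as.integer(n_interactions),
    study_multiplicity = study_multiplicity,
    n_studies = as.integer(n_studies),
    n_sources = as.integer(n_sources),
    techniques_per_pair = as.integer(techniques_per_pair),
    technique_pool = technique_pool,
    organism_rate = organism_rate,
    n_ortholog_only = as.integer(n_ortholog_only),
    gene_ambiguity_rate = gene_ambiguity_rate,
    genetic_rate = genetic_rate,
    unmappable_rate = unmappable_rate,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate synthetic source datasets with a known ground truth
#'
#' Produces everything the integration pipeline consumes -- source datasets
#' (as [hippie_records]), an identifier mapping table, ortholog-evidence
#' records -- plus a ground-truth ledger of the evidence counts the merged
#' network must reproduce. The ledger is computed by the generator's own
#' independent bookkeeping, so integration and scoring can be checked
#' against it end to end (conservation of evidence).
#'
#' Every pair's records carry explicit study associations, so the
#' leave-one-study-out optimizer runs on the merged result.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `datasets` (list of [hippie_records]), `mapping`
#'   (an `id_mapping_table`), `orthologs` (data frame), and `truth`: a list
#'   with per-pair expected evidence (`pairs`: protein pair, `n_studies`,
#'   `n_organisms`, technique names) and the planted contamination counts
#'   (`n_genetic_records`, `n_unmappable_records`, `n_ortholog_only`).
#' @export
generate_sources <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    np <- spec$n_proteins
    proteins <- sprintf("HP%04d", seq_len(np))
    source_ids <- sprintf("X%04d", seq_len(np))
    ambiguous <- stats::runif(np) < spec$gene_ambiguity_rate
    genes <- lapply(seq_len(np), function(i) {
      g <- sprintf("%d", 10000L + i)
      if (ambiguous[i]) c(g, sprintf("%d", 20000L + i)) else g
    })
    mapping <- id_mapping_table(namespace = "synthetic",
                                source_id = source_ids,
                                protein_id = proteins, genes = genes)

    # distinct unordered pairs (self-interactions excluded by construction
    # here; they are exercised by hand-built fixtures in the tests)
    n_all <- np * (np - 1L) / 2L
    pick <- sort(sample.int(n_all, spec$n_interactions))
    # row/col of the upper triangle by unranking
    b <- cumsum((np - 1L):1L)
    i_idx <- vapply(pick, function(p) which(p <= b)[1L], integer(1))
    j_off <- pick - c(0L, b)[i_idx]
    a_i <- i_idx
    b_i <- i_idx + j_off

    study_pool <- sprintf("%d", 900000000L + seq_len(spec$n_studies))
    mult <- as.integer(names(spec$study_multiplicity))
    m_per_pair <- sample(mult, spec$n_interactions, replace = TRUE,
                         prob = spec$study_multiplicity)

    pool <- spec$technique_pool %||% default_technique_scores()
    tech_rows <- lapply(seq_len(spec$n_interactions), function(k) {
      nt <- if (length(spec$techniques_per_pair) == 1L)
        spec$techniques_per_pair else sample(spec$techniques_per_pair, 1L)
      sample.int(nrow(pool), nt)
    })

    # one record per (pair, study), assigned to a source dataset
    rec_pair <- rep(seq_len(spec$n_interactions), m_per_pair)
    rec_study <- unlist(lapply(seq_len(spec$n_interactions), function(k) {
      sample(study_pool, m_per_pair[k])
    }))
    rec_source <- sprintf("SRC%d", sample.int(spec$n_sources,
                                              length(rec_pair),
                                              replace = TRUE))
    rec_genetic <- stats::runif(length(rec_pair)) < spec$genetic_rate
    rec_unmappable <- stats::runif(length(rec_pair)) < spec$unmappable_rate

    id_a <- source_ids[a_i[rec_pair]]
    id_b <- source_ids[b_i[rec_pair]]
    unk <- which(rec_unmappable)
    if (length(unk)) {
      id_a[unk] <- sprintf("UNK%04d", seq_along(unk))
    }

    recs <- hippie_records(
      id_a = id_a, id_b = id_b,
      ns_a = "synthetic", ns_b = "synthetic",
      pubmed_ids = as.list(rec_study),
      tech_names = lapply(tech_rows[rec_pair], function(r) pool$name[r]),
      tech_mis = lapply(tech_rows[rec_pair], function(r) pool$mi[r]),
      interaction_types = lapply(rec_genetic, function(g)
        if (g) "MI:0208" else "MI:0915"),
      source_name = rec_source,
      is_genetic = rec_genetic
    )
    datasets <- lapply(sort(unique(rec_source)), function(s) {
      d <- recs[recs$source_name == s, , drop = FALSE]
      rownames(d) <- NULL
      class(d) <- c("hippie_records", "data.frame")
      d
    })
    names(datasets) <- sort(unique(rec_source))

    # ortholog evidence for true pairs, plus planted ortholog-only pairs
    species <- default_ortholog_species()
    org <- expand.grid(pair = seq_len(spec$n_interactions),
                       species = species, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
    org <- org[stats::runif(nrow(org)) < spec$organism_rate, , drop = FALSE]
    orthologs <- data.frame(
      protein_a = proteins[a_i[org$pair]],
      protein_b = proteins[b_i[org$pair]],
      species = org$species, stringsAsFactors = FALSE)
    if (spec$n_ortholog_only > 0L) {
      free <- setdiff(seq_len(n_all), pick)
      extra <- sample(free, min(spec$n_ortholog_only, length(free)))
      e_i <- vapply(extra, function(p) which(p <= b)[1L], integer(1))
      e_j <- e_i + extra - c(0L, b)[e_i]
      orthologs <- rbind(orthologs, data.frame(
        protein_a = proteins[e_i], protein_b = proteins[e_j],
        species = sample(species, length(extra), replace = TRUE),
        stringsAsFactors = FALSE))
    }
    rownames(orthologs) <- NULL

    # ground truth from the generator's own bookkeeping: a surviving
    # (non-genetic, mappable) record contributes its study; techniques are
    # the pair techniques observed on surviving records
    surviving <- !rec_genetic & !rec_unmappable
    truth_pairs <- sort(unique(rec_pair[surviving]))
    truth <- data.frame(
      protein_a = proteins[a_i[truth_pairs]],
      protein_b = proteins[b_i[truth_pairs]],
      stringsAsFactors = FALSE)
    truth$n_studies <- vapply(truth_pairs, function(k)
      length(unique(rec_study[surviving & rec_pair == k])), integer(1))
    truth$techniques <- lapply(truth_pairs, function(k)
      as_charset(technique_key(pool, pool$name[tech_rows[[k]]],
                               pool$mi[tech_rows[[k]]])))
    okey <- pair_key(orthologs$protein_a, orthologs$protein_b)
    tkey <- pair_key(truth$protein_a, truth$protein_b)
    truth$n_organisms <- vapply(tkey, function(k)
      length(unique(orthologs$species[okey == k])), integer(1),
      USE.NAMES = FALSE)

    list(
      datasets = datasets,
      mapping = mapping,
      orthologs = orthologs,
      truth = list(
        pairs = truth,
        n_genetic_records = sum(rec_genetic),
        n_unmappable_records = sum(rec_unmappable & !rec_genetic),
        n_ortholog_only = length(unique(okey[!(okey %in% tkey)]))
      )
    )
  })
}

#' Generate an external screen with planted stratified recall
#'
#' Emulates the evaluation setting: a screen whose baits cover part of the
#' network and whose detected pairs recall the high-confidence stratum at
#' `high_recall` and the low-confidence stratum at `low_recall` (per
#' detectable pair, independently). With `high_recall > low_recall` the
#' expected one-sided Fisher direction is "high recalled better"; with
#' equal rates the test is null-calibrated.
#'
#' @param net A fully scored [hippie_network].
#' @param high_recall,low_recall Detection probabilities per detectable
#'   pair, `0 <= low_recall <= high_recall <= 1`.
#' @param threshold Score threshold separating the strata.
#' @param bait_fraction Fraction of the network's proteins used as baits.
#' @param seed Integer seed.
#' @return A `hippie_screen`.
#' @export
generate_screen <- function(net, high_recall, low_recall, threshold,
                            bait_fraction = 0.5, seed = 1L) {
  stopifnot(inherits(net, "hippie_network"))
  if (!(low_recall >= 0 && low_recall <= high_recall && high_recall <= 1)) {
    stop_validation("need 0 <= low_recall <= high_recall <= 1")
  }
  if (anyNA(net$score)) {
    stop_hippie("generate_screen requires a fully scored network",
                class = "hippie_contract_error")
  }
  with_seed(seed, {
    prots <- sort(unique(c(net$protein_a, net$protein_b)))
    n_baits <- max(1L, round(bait_fraction * length(prots)))
    baits <- sort(sample(prots, n_baits))
    detectable <- net$protein_a %in% baits | net$protein_b %in% baits
    rate <- ifelse(net$score >= threshold, high_recall, low_recall)
    hit <- detectable & stats::runif(nrow(net)) < rate
    external_screen(baits, net$protein_a[hit], net$protein_b[hit])
  })
}

#' Write a complete fixture directory
#'
#' Materializes a generated fixture on disk in the package's interchange
#' formats: one PSI-MI TAB 2.5 file per source dataset, the identifier
#' mapping table, the ortholog-evidence file, and an echo of the spec.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
write_fixture_dir <- function(spec, dir) {
  fx <- generate_sources(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(fx$datasets)) {
    p <- file.path(dir, paste0(nm, ".mitab25.txt"))
    write_psimitab25(fx$datasets[[nm]], p)
    paths <- c(paths, p)
  }
  map_path <- file.path(dir, "id_mapping.tsv")
  writeLines(sprintf("%s\t%s\t%s\t%s", fx$mapping$namespace,
                     fx$mapping$source_id, fx$mapping$protein_id,
                     vapply(fx$mapping$genes, paste, character(1),
                            collapse = ",")), map_path)
  ortho_path <- file.path(dir, "orthologs.tsv")
  writeLines(sprintf("%s\t%s\t%s", fx$orthologs$protein_a,
                     fx$orthologs$protein_b, fx$orthologs$species),
             ortho_path)
  spec_path <- file.path(dir, "spec_echo.dcf")
  flat <- spec
  flat$study_multiplicity <- paste(names(spec$study_multiplicity),
                                   spec$study_multiplicity,
                                   sep = "=", collapse = ",")
  flat$techniques_per_pair <- paste(spec$techniques_per_pair, collapse = ",")
  flat$technique_pool <- NULL
  write.dcf(as.data.frame(unclass(flat)[!vapply(unclass(flat), is.null,
                                                logical(1))]), spec_path)
  invisible(c(paths, map_path, ortho_path, spec_path))
}
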
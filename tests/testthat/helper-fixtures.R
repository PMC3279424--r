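# in-code fixtures shared across test files

# mapping table: source ids S1..Sn -> proteins P01..Pn, one gene each unless
# listed in `ambiguous` (then two genes)
tiny_mapping <- function(n = 6, ambiguous = integer(0)) {
  id_mapping_table(
    namespace = "test",
    source_id = sprintf("S%d", seq_len(n)),
    protein_id = sprintf("P%02d", seq_len(n)),
    genes = lapply(seq_len(n), function(i) {
      g <- sprintf("g%d", i)
      if (i %in% ambiguous) c(g, sprintf("g%d", 100 + i)) else g
    })
  )
}

tiny_records <- function(id_a, id_b, pmids = list(), techs = list(),
                         source = "DS", genetic = FALSE, types = NULL) {
  hippie_records(id_a = id_a, id_b = id_b, ns_a = "test", ns_b = "test",
                 pubmed_ids = pmids, tech_names = techs,
                 interaction_types = types,
                 source_name = source, is_genetic = genetic)
}

# a small scored network built directly (no merging)
tiny_scored_network <- function(scores,
                                proteins = NULL) {
  n <- length(scores)
  if (is.null(proteins)) {
    pa <- sprintf("A%03d", seq_len(n))
    pb <- sprintf("B%03d", seq_len(n))
  } else {
    pa <- proteins[[1]]
    pb <- proteins[[2]]
  }
  hippie_network(pa, pb,
                 genes_a = as.list(paste0("ga", seq_len(n))),
                 genes_b = as.list(paste0("gb", seq_len(n))),
                 studies = rep(list("900000001"), n),
                 techniques = rep(list("Two-hybrid"), n),
                 sources = rep(list("DS"), n),
                 score = scores)
}

# fixture with a strong planted study-reproducibility signal: multi-study
# PPIs are a minority, replicated deeply enough to stay multi-study after
# one holdout, and techniques are homogeneous mid-tier assays so the
# reproducibility signal lives in the studies
strong_signal_spec <- function(seed) {
  tab <- default_technique_scores()
  synthetic_spec(
    study_multiplicity = c("1" = 0.7, "3" = 0.15, "4" = 0.15),
    technique_pool = tab[tab$score == 5, c("name", "mi")],
    techniques_per_pair = 1:3,
    seed = seed
  )
}

merged_fixture <- function(seed = 1, spec = synthetic_spec(seed = seed)) {
  fx <- generate_sources(spec)
  net <- merge_sources(fx$datasets, fx$mapping, orthologs = fx$orthologs)
  list(fx = fx, net = net)
}

# independent brute-force oracle for the one-sided Fisher test: enumerate
# the hypergeometric pmf over the margins of [[kh, nh], [kl, nl]] with
# exact log-binomial coefficients
fisher_oracle <- function(kh, nh, kl, nl) {
  m <- kh + kl
  n <- nh + nl
  k <- kh + nh
  lo <- max(0, k - n)
  hi <- min(m, k)
  x <- lo:hi
  logp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  sum(exp(logp[x >= kh]))
}
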
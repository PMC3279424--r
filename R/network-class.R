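#' Scored interaction networks
#'
#' A `hippie_network` is the package's central container: one row per
#' non-redundant, unordered canonical protein pair, each carrying its full
#' evidence ledger and (once scored) a confidence score in \[0, 1). The
#' evidence ledger holds the supporting studies (PubMed IDs), the distinct
#' detection techniques (canonical names), the source datasets, the
#' non-human model organisms in which orthologs of the pair were seen to
#' interact, and any PSI-MI interaction-type codes. Each endpoint also
#' carries the gene identifiers its protein maps to; a protein encoded by
#' duplicated loci maps to more than one gene.
#'
#' Pairs are canonical: `protein_a <= protein_b` lexicographically, so
#' (A,B) and (B,A) are the same interaction. Self-interactions (A,A) are
#' permitted.
#'
#' @param protein_a,protein_b Canonical protein identifiers (any order;
#'   stored canonically).
#' @param genes_a,genes_b Lists of gene-identifier vectors per endpoint.
#' @param studies,techniques,sources,organisms,interaction_types Lists of
#'   character vectors (stored as sorted sets).
#' @param score Numeric scores in \[0, 1\], `NA` while unscored.
#' @return An object of class `hippie_network` (a data frame).
#' @export
hippie_network <- function(protein_a, protein_b,
                           genes_a = NULL, genes_b = NULL,
                           studies = NULL, techniques = NULL,
                           sources = NULL, organisms = NULL,
                           interaction_types = NULL, score = NA_real_) {
  n <- length(protein_a)
  stopifnot(length(protein_b) == n)
  protein_a <- as.character(protein_a)
  protein_b <- as.character(protein_b)
  if (n > 0L && (any(!nzchar(protein_a)) || any(!nzchar(protein_b)))) {
    stop_validation("protein identifiers must be non-empty")
  }
  listify <- function(x) {
    if (is.null(x)) rep(list(character(0)), n)
    else lapply(if (is.list(x)) x else as.list(x), as_charset)
  }
  genes_a <- listify(genes_a)
  genes_b <- listify(genes_b)
  swap <- protein_b < protein_a
  if (any(swap)) {
    tmp <- protein_a[swap]
    protein_a[swap] <- protein_b[swap]
    protein_b[swap] <- tmp
    gtmp <- genes_a[swap]
    genes_a[swap] <- genes_b[swap]
    genes_b[swap] <- gtmp
  }
  out <- data.frame(protein_a = protein_a, protein_b = protein_b,
                    stringsAsFactors = FALSE)
  out$genes_a <- genes_a
  out$genes_b <- genes_b
  out$studies <- listify(studies)
  out$techniques <- listify(techniques)
  out$sources <- listify(sources)
  out$organisms <- listify(organisms)
  out$interaction_types <- listify(interaction_types)
  out$score <- rep_len(as.numeric(score), max(n, 0L))[seq_len(n)]
  if (anyDuplicated(pair_key(out$protein_a, out$protein_b))) {
    stop_validation("duplicate canonical pair in network")
  }
  ord <- order(out$protein_a, out$protein_b)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hippie_network", "data.frame")
  out
}

network_keys <- function(net) pair_key(net$protein_a, net$protein_b)

# subset rows of a network, keeping class and trimming provenance
subset_network <- function(net, idx) {
  prov <- attr(net, "provenance")
  out <- net[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hippie_network", "data.frame")
  if (!is.null(prov)) {
    attr(out, "provenance") <- prov[prov$pair %in% network_keys(out), ,
                                    drop = FALSE]
  }
  out
}

#' @export
print.hippie_network <- function(x, ...) {
  scored <- sum(!is.na(x$score))
  cat(sprintf("Scored PPI network: %d interaction(s), %d protein(s)\n",
              nrow(x), length(unique(c(x$protein_a, x$protein_b)))))
  if (scored) {
    cat(sprintf("  scores: %d assigned, range [%.3f, %.3f]\n", scored,
                min(x$score, na.rm = TRUE), max(x$score, na.rm = TRUE)))
  } else if (nrow(x)) {
    cat("  unscored\n")
  }
  invisible(x)
}

#' @export
summary.hippie_network <- function(object, threshold = NULL, ...) {
  n <- nrow(object)
  res <- list(
    n_interactions = n,
    n_proteins = length(unique(c(object$protein_a, object$protein_b))),
    n_self = sum(object$protein_a == object$protein_b),
    n_multi_study = sum(lengths(object$studies) >= 2L),
    n_with_organisms = sum(lengths(object$organisms) > 0L),
    sources = sort(unique(unlist(object$sources)))
  )
  if (any(!is.na(object$score))) {
    s <- object$score[!is.na(object$score)]
    res$score_summary <- summary(s)
    if (length(s) >= 4L) {
      res$upper_quartile <- upper_quartile(s)
      thr <- threshold %||% res$upper_quartile
      res$threshold <- thr
      res$n_high <- sum(s >= thr)
    }
  }
  class(res) <- "summary.hippie_network"
  res
}

#' @export
print.summary.hippie_network <- function(x, ...) {
  cat(sprintf("PPI network: %d interactions among %d proteins\n",
              x$n_interactions, x$n_proteins))
  cat(sprintf("  self-interactions: %d; multi-study: %d; with ortholog evidence: %d\n",
              x$n_self, x$n_multi_study, x$n_with_organisms))
  if (length(x$sources)) {
    cat("  sources:", paste(x$sources, collapse = ", "), "\n")
  }
  if (!is.null(x$score_summary)) {
    cat("  score distribution:\n")
    print(x$score_summary)
    if (!is.null(x$upper_quartile)) {
      cat(sprintf("  upper quartile: %.4f; high-confidence (score >= %.4f): %d\n",
                  x$upper_quartile, x$threshold, x$n_high))
    }
  }
  invisible(x)
}

#' Plot the confidence-score distribution of a network
#'
#' Histogram of the per-interaction confidence scores with the
#' high-confidence threshold marked; interactions at or above the threshold
#' are the high-confidence stratum.
#'
#' @param x A scored `hippie_network`.
#' @param threshold High-confidence cut; defaults to the network's upper
#'   quartile.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.hippie_network <- function(x, threshold = NULL, ...) {
  s <- x$score[!is.na(x$score)]
  if (!length(s)) stop_hippie("network has no scores to plot")
  thr <- threshold %||% if (length(s) >= 4L) upper_quartile(s) else NULL
  graphics::hist(s, breaks = seq(0, 1, by = 0.05),
                 main = "Confidence score distribution",
                 xlab = "confidence score", col = "grey80", border = "white",
                 ...)
  if (!is.null(thr)) {
    graphics::abline(v = thr, lty = 2)
    graphics::mtext(sprintf("high-confidence ≥ %.2f", thr), side = 3,
                    adj = 1, cex = 0.8)
  }
  invisible(x)
}
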
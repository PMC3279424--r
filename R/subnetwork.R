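#' Extract a query-centered subnetwork at a confidence level
#'
#' Builds the network around a set of query proteins: at layer 0, only
#' interactions with *both* endpoints in the query set; at layer 1, every
#' interaction with at least one endpoint in the query set, which pulls in
#' the queries' direct partners (edges among the newly added partners are
#' not included). Interactions scoring below `min_score` are then dropped
#' (kept when `score >= min_score`, consistent with the high-confidence
#' convention), and, if an interaction-type filter is given, only
#' interactions annotated with at least one of the requested PSI-MI type
#' codes are kept -- note that interactions with *no* type annotation are
#' dropped whenever a filter is active, because their type is unknown, not
#' known-good.
#'
#' Query identifiers absent from the network are ignored with a warning; if
#' none are known the result is empty (with a message).
#'
#' @param net A scored [hippie_network].
#' @param proteins Non-empty character vector of canonical identifiers.
#' @param layer 0 or 1.
#' @param min_score Confidence threshold in \[0, 1\].
#' @param types Optional character vector of PSI-MI interaction-type codes.
#' @return The extracted [hippie_network], evidence preserved.
#' @export
extract_subnetwork <- function(net, proteins, layer = 0L, min_score = 0,
                               types = NULL) {
  stopifnot(inherits(net, "hippie_network"))
  proteins <- as_charset(proteins)
  if (!length(proteins)) stop_validation("query protein set is empty")
  if (!layer %in% c(0L, 1L)) stop_validation("layer must be 0 or 1")
  if (min_score < 0 || min_score > 1) {
    stop_validation("min_score must lie in [0, 1]")
  }
  known <- unique(c(net$protein_a, net$protein_b))
  unknown <- setdiff(proteins, known)
  if (length(unknown) == length(proteins)) {
    message("no query identifier found in the network; empty result")
  } else if (length(unknown)) {
    warning(sprintf("query identifier(s) not in network, ignored: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  in_a <- net$protein_a %in% proteins
  in_b <- net$protein_b %in% proteins
  keep <- if (layer == 0L) in_a & in_b else in_a | in_b
  keep <- keep & !is.na(net$score) & net$score >= min_score
  if (!is.null(types)) {
    keep <- keep & vapply(net$interaction_types,
                          function(t) any(t %in% types), logical(1))
  }
  subset_network(net, keep)
}

#' Iterated neighborhood expansion
#'
#' Applies layer-1 expansion repeatedly: starting from the seed proteins,
#' each round adds every interaction (at or above `min_score`) touching the
#' current protein set, then extends the set by the new partners. With
#' `layers = 1` this is exactly [extract_subnetwork()] at layer 1. The
#' number of layers is capped (default 3) because the reachable set grows
#' combinatorially in a dense interactome.
#'
#' @inheritParams extract_subnetwork
#' @param seed Seed protein identifiers.
#' @param layers Number of expansion rounds (>= 1).
#' @param max_layers Refusal cap.
#' @return The expanded [hippie_network].
#' @export
neighborhood_expand <- function(net, seed, layers = 1L, min_score = 0,
                                max_layers = 3L) {
  stopifnot(inherits(net, "hippie_network"))
  if (layers < 1L) stop_validation("layers must be >= 1")
  if (layers > max_layers) {
    stop_validation(sprintf(
      "layers = %d exceeds the cap of %d: neighborhoods grow combinatorially; raise max_layers only if you mean it",
      layers, max_layers))
  }
  current <- as_charset(seed)
  thr <- subset_network(net, !is.na(net$score) & net$score >= min_score)
  keep <- rep(FALSE, nrow(thr))
  for (i in seq_len(layers)) {
    touch <- thr$protein_a %in% current | thr$protein_b %in% current
    keep <- keep | touch
    current <- unique(c(current, thr$protein_a[touch], thr$protein_b[touch]))
  }
  subset_network(thr, keep)
}
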
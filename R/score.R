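#' Scoring parameters
#'
#' The confidence score has six free parameters: three saturation steepness
#' constants `a_s`, `a_o`, `a_t` (one per evidence component; dimensionless,
#' non-negative) and three weights `w_s`, `w_o`, `w_t` in \[0, 1\] that must
#' sum to 1 (within 1e-9). The packaged default is the published optimum of
#' the leave-one-study-out grid search:
#' `a_s = 2.3, a_o = 1.6, a_t = 0.2, w_s = 0.6, w_o = 0.1, w_t = 0.3`.
#'
#' @param a_s,a_o,a_t Saturation steepness for the study, organism and
#'   technique subscores.
#' @param w_s,w_o,w_t Subscore weights (simplex-constrained).
#' @return A named numeric vector of class `scoring_params`.
#' @examples
#' p <- scoring_params()          # published defaults
#' score_interaction(evidence_counts_values(1, 0, 5), p)   # ~0.7295
#' @export
scoring_params <- function(a_s = 2.3, a_o = 1.6, a_t = 0.2,
                           w_s = 0.6, w_o = 0.1, w_t = 0.3) {
  p <- c(a_s = a_s, a_o = a_o, a_t = a_t, w_s = w_s, w_o = w_o, w_t = w_t)
  if (any(!is.finite(p))) stop_validation("scoring parameters must be finite")
  if (any(p[1:3] < 0)) {
    stop_validation("steepness constants a_i must be non-negative")
  }
  if (any(p[4:6] < 0 | p[4:6] > 1)) {
    stop_validation("weights w_i must lie in [0, 1]")
  }
  if (abs(sum(p[4:6]) - 1) > 1e-9) {
    stop_validation("weights w_s + w_o + w_t must sum to 1 (within 1e-9)")
  }
  class(p) <- "scoring_params"
  p
}

#' @export
print.scoring_params <- function(x, ...) {
  cat("Scoring parameters:\n")
  cat(sprintf("  steepness  a_s = %.3g, a_o = %.3g, a_t = %.3g\n",
              x[["a_s"]], x[["a_o"]], x[["a_t"]]))
  cat(sprintf("  weights    w_s = %.3g, w_o = %.3g, w_t = %.3g\n",
              x[["w_s"]], x[["w_o"]], x[["w_t"]]))
  invisible(x)
}

#' Saturating evidence subscore
#'
#' Each evidence component enters the confidence score through the
#' saturating transform `s(n) = 1 - exp(-a * n)`: zero at `n = 0`,
#' approaching 1 as evidence accumulates, with `a` controlling how fast.
#' The first unit of evidence moves the subscore most; further corroboration
#' has diminishing returns, which is what keeps any finite evidence short
#' of certainty.
#'
#' @param n Non-negative evidence quantity (count or technique-score mass).
#' @param a Non-negative steepness constant.
#' @return Subscore in \[0, 1).
#' @export
subscore <- function(n, a) {
  if (any(n < 0) || any(a < 0)) {
    stop_hippie("subscore requires n >= 0 and a >= 0",
                class = "hippie_contract_error")
  }
  1 - exp(-a * n)
}

#' Evidence counts for scoring
#'
#' Reduces an interaction's evidence ledger to the three quantities the
#' score consumes: `n_studies` (distinct supporting PubMed IDs),
#' `n_organisms` (distinct non-human species with interacting orthologs)
#' and `technique_mass` (the sum of reliability scores over the *distinct*
#' techniques that verified the interaction -- a technique reused across
#' several studies counts once; the study count rewards the repetition).
#' Unknown techniques contribute 0 with a warning.
#'
#' @param net A [hippie_network].
#' @param table A `technique_score_table`.
#' @return A data frame with columns `n_studies`, `n_organisms`,
#'   `technique_mass`, one row per interaction.
#' @export
evidence_counts <- function(net, table = default_technique_scores()) {
  stopifnot(inherits(net, "hippie_network"))
  tm <- vapply(net$techniques, function(t) {
    if (!length(t)) 0 else sum(technique_score(table, t))
  }, numeric(1))
  data.frame(n_studies = lengths(net$studies),
             n_organisms = lengths(net$organisms),
             technique_mass = tm)
}

#' @rdname evidence_counts
#' @param n_studies,n_organisms,technique_mass Scalars or vectors; a direct
#'   way to build counts without a network (e.g. for what-if scoring).
#' @export
evidence_counts_values <- function(n_studies, n_organisms, technique_mass) {
  if (any(n_studies < 0) || any(n_organisms < 0) || any(technique_mass < 0)) {
    stop_hippie("evidence counts must be non-negative",
                class = "hippie_contract_error")
  }
  data.frame(n_studies = n_studies, n_organisms = n_organisms,
             technique_mass = technique_mass)
}

#' Confidence score of an interaction
#'
#' The total score is the weighted sum of the three saturating subscores:
#' `S = w_s * s(n_studies, a_s) + w_o * s(n_organisms, a_o) +
#' w_t * s(technique_mass, a_t)`. `S` lies in \[0, 1) for finite evidence
#' and is 0 exactly when all three evidence quantities are 0.
#'
#' @param counts A data frame from [evidence_counts()] /
#'   [evidence_counts_values()].
#' @param params A [scoring_params] object.
#' @return Numeric vector of scores.
#' @export
score_interaction <- function(counts, params = scoring_params()) {
  if (!inherits(params, "scoring_params")) {
    params <- do.call(scoring_params, as.list(params))
  }
  score_from_counts(counts$n_studies, counts$n_organisms,
                    counts$technique_mass, params)
}

# vectorized core, shared with the optimizer's hot loop
score_from_counts <- function(ns, no, tm, params) {
  params[["w_s"]] * (1 - exp(-params[["a_s"]] * ns)) +
    params[["w_o"]] * (1 - exp(-params[["a_o"]] * no)) +
    params[["w_t"]] * (1 - exp(-params[["a_t"]] * tm))
}

#' Score every interaction in a network
#'
#' Pure and deterministic: the same network, parameters and technique table
#' always produce the same scores, and rescoring is idempotent.
#'
#' @inheritParams evidence_counts
#' @param params A [scoring_params] object.
#' @return The network with its `score` column filled in.
#' @export
score_network <- function(net, params = scoring_params(),
                          table = default_technique_scores()) {
  stopifnot(inherits(net, "hippie_network"))
  if (!inherits(params, "scoring_params")) {
    params <- do.call(scoring_params, as.list(params))
  }
  cnt <- evidence_counts(net, table)
  net$score <- score_from_counts(cnt$n_studies, cnt$n_organisms,
                                 cnt$technique_mass, params)
  net
}

#' Upper quartile of a score distribution
#'
#' The 75th percentile by the nearest-rank convention: the
#' `ceiling(0.75 * n)`-th order statistic. Deterministic across platforms
#' and always an observed score. High-confidence membership uses
#' `score >= upper_quartile(...)`.
#'
#' @param x A scored [hippie_network] or a numeric score vector with at
#'   least 4 values.
#' @return The threshold score.
#' @export
upper_quartile <- function(x) {
  s <- if (inherits(x, "hippie_network")) x$score else as.numeric(x)
  s <- s[!is.na(s)]
  if (length(s) < 4L) {
    stop_hippie("upper_quartile needs at least 4 scores",
                class = "hippie_contract_error")
  }
  sort(s)[ceiling(0.75 * length(s))]
}

# nearest-rank interquartile range, same convention as upper_quartile
nearest_rank_iqr <- function(s) {
  n <- length(s)
  s <- sort(s)
  s[ceiling(0.75 * n)] - s[ceiling(0.25 * n)]
}
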
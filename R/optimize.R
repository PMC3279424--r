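#' Enumerate the parameter grid
#'
#' The six scoring parameters are selected by exhaustive search over a
#' regular grid: each steepness constant `a_i` on \[0, 3\] and each weight
#' `w_i` on \[0, 1\], with the weights constrained to the simplex
#' `w_s + w_o + w_t = 1`. At the default step of 0.1 this yields 31
#' values per steepness axis and 66 admissible weight triples --
#' 31^3 x 66 = 1,966,206 combinations in total. Coarser steps (e.g. 1.0 /
#' 0.2) give small grids suitable for testing and exploration.
#'
#' Rows are ordered lexicographically by `(a_s, a_o, a_t, w_s, w_o)`,
#' which also fixes the residual tie-break order of the search.
#'
#' @param a_step Step width for the steepness constants.
#' @param w_step Step width for the weights; `1/w_step` must be an integer.
#' @param a_max Upper bound of the steepness range.
#' @return A data frame with columns `a_s`, `a_o`, `a_t`, `w_s`, `w_o`,
#'   `w_t`; every row is an admissible parameter combination.
#' @export
enumerate_grid <- function(a_step = 0.1, w_step = 0.1, a_max = 3) {
  stopifnot(a_step > 0, w_step > 0, a_max >= 0)
  k <- round(1 / w_step)
  if (abs(k * w_step - 1) > 1e-9) {
    stop_validation("1/w_step must be an integer")
  }
  a_vals <- round(seq(0, a_max, by = a_step), 10)
  # admissible weight triples: compositions of k into three parts, lex order
  ij <- expand.grid(j = 0:k, i = 0:k, KEEP.OUT.ATTRS = FALSE)
  ij <- ij[ij$i + ij$j <= k, c("i", "j")]
  ij <- ij[order(ij$i, ij$j), , drop = FALSE]
  w <- data.frame(w_s = ij$i / k, w_o = ij$j / k, w_t = (k - ij$i - ij$j) / k)

  na <- length(a_vals)
  nw <- nrow(w)
  # steepness block lex-major, weights minor
  a_idx <- expand.grid(a_t = seq_len(na), a_o = seq_len(na),
                       a_s = seq_len(na), KEEP.OUT.ATTRS = FALSE)
  a_idx <- a_idx[order(a_idx$a_s, a_idx$a_o, a_idx$a_t), , drop = FALSE]
  grid <- data.frame(
    a_s = rep(a_vals[a_idx$a_s], each = nw),
    a_o = rep(a_vals[a_idx$a_o], each = nw),
    a_t = rep(a_vals[a_idx$a_t], each = nw),
    w_s = rep(w$w_s, times = na^3),
    w_o = rep(w$w_o, times = na^3),
    w_t = rep(w$w_t, times = na^3)
  )
  rownames(grid) <- NULL
  grid
}

# per-study leave-one-out structures, computed once per reference network
loso_precompute <- function(net, table, min_interactions = 10L,
                            min_multi = 2L) {
  prov <- attr(net, "provenance")
  if (is.null(prov) || !nrow(prov)) {
    stop_hippie(paste("reference network carries no study provenance;",
                      "build it with merge_sources()"),
                class = "hippie_contract_error")
  }
  keys <- network_keys(net)
  cnt <- evidence_counts(net, table)
  no_full <- cnt$n_organisms
  names(no_full) <- keys

  # technique score lookup for provenance rows (canonical keys)
  techs <- unique(prov$technique)
  techs <- techs[nzchar(techs)]
  tscore <- technique_score(table, techs, warn = FALSE)
  names(tscore) <- techs

  studies <- sort(unique(prov$study[nzchar(prov$study)]))
  multi_pair <- keys[lengths(net$studies) >= 2L]

  out <- list()
  for (j in studies) {
    in_study <- unique(prov$pair[prov$study == j])
    eligible <- length(in_study) >= min_interactions &&
      sum(in_study %in% multi_pair) > min_multi
    red <- prov[prov$study != j, , drop = FALSE]
    ns_red <- tapply(red$study, red$pair,
                     function(s) length(unique(s[nzchar(s)])))
    tm_red <- tapply(red$technique, red$pair, function(t) {
      t <- unique(t[nzchar(t)])
      if (!length(t)) 0 else sum(tscore[t])
    })
    pairs_red <- names(ns_red)
    keep <- ns_red > 0 | tm_red > 0
    pairs_red <- pairs_red[keep]
    overlap <- pairs_red %in% in_study
    out[[j]] <- list(
      study = j,
      eligible = eligible,
      n_in_study = length(in_study),
      ns = as.numeric(ns_red[keep]),
      no = as.numeric(no_full[pairs_red]),
      tm = as.numeric(tm_red[keep]),
      overlap = overlap,
      v = sum(overlap)
    )
  }
  out
}

#' Leave-one-study-out deviation for one held-out study
#'
#' Removes one study's evidence from the reference network (evidence
#' removal, not interaction removal: a PPI keeps its other studies and
#' techniques; a PPI left with no experimental evidence at all drops out),
#' rescores the reduced dataset, and measures how strongly the PPIs shared
#' between the held-out study and the reduced dataset are enriched among
#' the reduced dataset's top quartile. The deviation statistic is
#' `dev = (n_high + 0.5) / (0.25 * |overlap| + 0.5)`: the observed count of
#' overlap PPIs scoring at or above the reduced upper quartile `Q3`,
#' relative to the random expectation of one quarter, with 0.5 pseudocounts
#' keeping `log(dev)` finite at zero observed.
#'
#' A study is eligible when it contains at least `min_interactions`
#' interactions and more than `min_multi` PPIs found in multiple studies;
#' for an ineligible study a skip notice (`eligible = FALSE`) is returned,
#' not an error.
#'
#' @param reference A merged [hippie_network] with study provenance (from
#'   [merge_sources()]).
#' @param study A PubMed ID present in the reference.
#' @param params A [scoring_params] object.
#' @param table A `technique_score_table`.
#' @param min_interactions,min_multi Eligibility thresholds.
#' @return A list with `study`, `eligible`, and for eligible studies
#'   `overlap` (= `v`, the objective weight), `n_high`, `q3` and `dev`.
#' @export
loso_deviation <- function(reference, study, params = scoring_params(),
                           table = default_technique_scores(),
                           min_interactions = 10L, min_multi = 2L) {
  pre <- loso_precompute(reference, table, min_interactions, min_multi)
  h <- pre[[as.character(study)]]
  if (is.null(h)) {
    stop_validation(sprintf("study '%s' not present in the reference", study))
  }
  holdout_eval(h, params)
}

holdout_eval <- function(h, params) {
  if (!h$eligible) {
    return(list(study = h$study, eligible = FALSE,
                n_in_study = h$n_in_study))
  }
  s <- score_from_counts(h$ns, h$no, h$tm, params)
  q3 <- sort(s)[ceiling(0.75 * length(s))]
  n_high <- sum(s[h$overlap] >= q3)
  list(study = h$study, eligible = TRUE, overlap = h$v, n_high = n_high,
       q3 = q3, dev = (n_high + 0.5) / (0.25 * h$v + 0.5), v = h$v)
}

#' Reproducibility objective
#'
#' Aggregates the per-study deviations into one figure of merit: the
#' overlap-weighted geometric mean of the deviations,
#' `f = exp( sum(v_j log dev_j) / sum(v_j) )`. `f = 1` means the held-out
#' studies' PPIs land in the reduced top quartile exactly as often as
#' chance; `f > 1` means the score concentrates reproducible PPIs at the
#' top. `f` is invariant under uniform scaling of the weights and under
#' permutation of the studies.
#'
#' @param holdouts A list of holdout results (from [loso_deviation()]) or a
#'   data frame with columns `dev` and `v`.
#' @return The objective value.
#' @export
objective_f <- function(holdouts) {
  if (is.data.frame(holdouts)) {
    dev <- holdouts$dev
    v <- holdouts$v
  } else {
    holdouts <- Filter(function(h) isTRUE(h$eligible), holdouts)
    dev <- vapply(holdouts, `[[`, numeric(1), "dev")
    v <- vapply(holdouts, `[[`, numeric(1), "v")
  }
  if (!length(dev)) {
    stop_hippie("objective_f needs at least one eligible holdout",
                class = "hippie_contract_error")
  }
  if (any(dev <= 0) || any(v < 0)) {
    stop_hippie("deviations must be positive and weights non-negative",
                class = "hippie_contract_error")
  }
  exp(sum(v * log(dev)) / sum(v))
}

#' Fit the scoring parameters by leave-one-study-out grid search
#'
#' The estimator at the heart of the package. Every parameter combination
#' in the grid is evaluated on the reference network: combinations whose
#' induced score distribution has fewer than `min_distinct` distinct values
#' are excluded as degenerate (they cannot rank interactions usefully --
#' setting `w_t = 0` is the canonical way this happens, because the
#' technique scores provide most of the score's granularity); each
#' surviving combination gets the leave-one-study-out objective `f` (see
#' [objective_f()]) and, as a tie-break diagnostic, the nearest-rank
#' interquartile range of the full-reference score distribution. The winner
#' maximizes `f`; among `f`-maximizers the largest `iqr` wins (a wider
#' spread separates confidence classes better); residual ties go to the
#' lexicographically smallest parameter tuple.
#'
#' @param reference A merged [hippie_network] with study provenance and
#'   explicit study-interaction associations.
#' @param grid A parameter grid from [enumerate_grid()]. The full default
#'   grid is large; coarser grids fit in seconds.
#' @param table A `technique_score_table`.
#' @param min_distinct Degeneracy threshold on the number of distinct
#'   scores.
#' @param min_interactions,min_multi Study eligibility thresholds.
#' @return An object of class `hippie_fit` with components `winner`
#'   (a [scoring_params]), `report` (one row per combination: parameters,
#'   `f`, `iqr`, `degenerate`), `holdouts` (per-study diagnostics of the
#'   winner), `n_studies_used`, and the reference evidence counts.
#' @seealso [coef.hippie_fit()], [predict.hippie_fit()]
#' @export
fit_scoring_params <- function(reference,
                               grid = enumerate_grid(a_step = 0.5,
                                                     w_step = 0.1),
                               table = default_technique_scores(),
                               min_distinct = 20L,
                               min_interactions = 10L, min_multi = 2L) {
  stopifnot(inherits(reference, "hippie_network"))
  cnt <- evidence_counts(reference, table)
  pre <- loso_precompute(reference, table, min_interactions, min_multi)
  pre <- Filter(function(h) h$eligible, pre)
  if (!length(pre)) {
    stop_validation("no eligible studies in the reference network")
  }

  # tall arrays across holdouts for the vectorized inner loop
  ns_t <- unlist(lapply(pre, `[[`, "ns"), use.names = FALSE)
  no_t <- unlist(lapply(pre, `[[`, "no"), use.names = FALSE)
  tm_t <- unlist(lapply(pre, `[[`, "tm"), use.names = FALSE)
  sizes <- vapply(pre, function(h) length(h$ns), integer(1))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  overlap_t <- lapply(seq_along(pre),
                      function(k) which(pre[[k]]$overlap) + starts[k] - 1L)
  v <- vapply(pre, `[[`, numeric(1), "v")
  q3rank <- ceiling(0.75 * sizes)
  nh_exp <- 0.25 * v + 0.5

  ngrid <- nrow(grid)
  f <- iqr <- rep(NA_real_, ngrid)
  degenerate <- rep(FALSE, ngrid)
  ns_full <- cnt$n_studies
  no_full <- cnt$n_organisms
  tm_full <- cnt$technique_mass

  for (i in seq_len(ngrid)) {
    ws <- grid$w_s[i]; wo <- grid$w_o[i]; wt <- grid$w_t[i]
    as_ <- grid$a_s[i]; ao <- grid$a_o[i]; at <- grid$a_t[i]
    s_full <- ws * (1 - exp(-as_ * ns_full)) +
      wo * (1 - exp(-ao * no_full)) + wt * (1 - exp(-at * tm_full))
    if (length(unique(round(s_full, 9))) < min_distinct) {
      degenerate[i] <- TRUE
      next
    }
    iqr[i] <- nearest_rank_iqr(s_full)
    s_tall <- ws * (1 - exp(-as_ * ns_t)) +
      wo * (1 - exp(-ao * no_t)) + wt * (1 - exp(-at * tm_t))
    num <- 0
    for (k in seq_along(pre)) {
      sg <- s_tall[starts[k]:ends[k]]
      q3 <- sort(sg)[q3rank[k]]
      nh <- sum(s_tall[overlap_t[[k]]] >= q3)
      num <- num + v[k] * log((nh + 0.5) / nh_exp[k])
    }
    f[i] <- exp(num / sum(v))
  }

  if (all(is.na(f))) {
    stop_validation(paste("all parameter combinations are degenerate on this",
                          "reference; lower min_distinct or enrich the data"))
  }
  fmax <- max(f, na.rm = TRUE)
  cand <- which(!is.na(f) & f >= fmax - 1e-9)
  iqr_max <- max(iqr[cand])
  cand <- cand[iqr[cand] >= iqr_max - 1e-9]
  cand <- cand[order(grid$a_s[cand], grid$a_o[cand], grid$a_t[cand],
                     grid$w_s[cand], grid$w_o[cand], grid$w_t[cand])]
  best <- cand[1L]

  winner <- scoring_params(grid$a_s[best], grid$a_o[best], grid$a_t[best],
                           grid$w_s[best], grid$w_o[best], grid$w_t[best])
  hl <- lapply(pre, holdout_eval, params = winner)
  holdouts <- data.frame(
    study = vapply(hl, `[[`, character(1), "study"),
    overlap = vapply(hl, `[[`, numeric(1), "overlap"),
    n_high = vapply(hl, `[[`, numeric(1), "n_high"),
    q3 = vapply(hl, `[[`, numeric(1), "q3"),
    dev = vapply(hl, `[[`, numeric(1), "dev"),
    v = vapply(hl, `[[`, numeric(1), "v"),
    stringsAsFactors = FALSE)
  rownames(holdouts) <- NULL

  report <- cbind(grid, f = f, iqr = iqr, degenerate = degenerate)
  structure(list(
    winner = winner,
    f = f[best],
    iqr = iqr[best],
    report = report,
    holdouts = holdouts,
    n_studies_used = length(pre),
    counts = cnt,
    table = table,
    min_distinct = min_distinct
  ), class = "hippie_fit")
}

#' @export
print.hippie_fit <- function(x, ...) {
  cat("Leave-one-study-out parameter fit\n")
  cat(sprintf("  %d parameter combination(s) evaluated, %d degenerate\n",
              nrow(x$report), sum(x$report$degenerate)))
  cat(sprintf("  %d eligible held-out studies\n", x$n_studies_used))
  cat(sprintf("  objective f = %.4f, score iqr = %.4f\n", x$f, x$iqr))
  cat("  winner:\n")
  print(x$winner)
  invisible(x)
}

#' @export
summary.hippie_fit <- function(object, ...) {
  r <- object$report[!object$report$degenerate, , drop = FALSE]
  r <- r[order(-r$f, -r$iqr), , drop = FALSE]
  cat("Top parameter combinations by objective f:\n")
  print(utils::head(r, 10), row.names = FALSE, digits = 4)
  cat("\nPer-study diagnostics of the winner:\n")
  print(object$holdouts, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.hippie_fit <- function(object, ...) {
  p <- unclass(object$winner)
  attributes(p) <- list(names = names(p))
  p
}

#' Score a network with fitted parameters
#'
#' @param object A `hippie_fit`.
#' @param newdata A [hippie_network] to score.
#' @param ... Unused.
#' @return The scored network.
#' @export
predict.hippie_fit <- function(object, newdata, ...) {
  score_network(newdata, params = object$winner, table = object$table)
}
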
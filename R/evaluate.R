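#' External interaction screens
#'
#' An external screen is described by its bait proteins and the interacting
#' pairs it detected. A screen can only detect network PPIs that touch one
#' of its baits, so recall must be computed against the detectable subset,
#' not the whole network. Every detected pair must contain at least one
#' bait.
#'
#' @param baits Character vector of protein identifiers.
#' @param detected_a,detected_b Endpoints of the detected pairs (any
#'   order; stored canonically).
#' @return An object of class `hippie_screen`.
#' @export
external_screen <- function(baits, detected_a = character(0),
                            detected_b = character(0)) {
  baits <- as_charset(baits)
  stopifnot(length(detected_a) == length(detected_b))
  detected_a <- as.character(detected_a)
  detected_b <- as.character(detected_b)
  touches_bait <- detected_a %in% baits | detected_b %in% baits
  if (any(!touches_bait)) {
    stop_validation(sprintf(
      "%d detected pair(s) contain no bait; screens detect via baits",
      sum(!touches_bait)))
  }
  swap <- detected_b < detected_a
  pa <- ifelse(swap, detected_b, detected_a)
  pb <- ifelse(swap, detected_a, detected_b)
  keep <- !duplicated(pair_key(pa, pb))
  structure(list(
    baits = baits,
    detected = data.frame(protein_a = pa[keep], protein_b = pb[keep],
                          stringsAsFactors = FALSE)
  ), class = "hippie_screen")
}

#' @export
print.hippie_screen <- function(x, ...) {
  cat(sprintf("External screen: %d bait(s), %d detected pair(s)\n",
              length(x$baits), nrow(x$detected)))
  invisible(x)
}

#' Read an external screen from two files
#'
#' `baits_path`: one protein identifier per line. `pairs_path`:
#' tab-delimited, no header, two columns per detected pair.
#'
#' @param baits_path,pairs_path File paths.
#' @return A `hippie_screen`.
#' @export
read_screen <- function(baits_path, pairs_path) {
  check_file_exists(baits_path)
  check_file_exists(pairs_path)
  baits <- readLines(baits_path)
  baits <- trimws(baits[nzchar(trimws(baits))])
  lines <- readLines(pairs_path)
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    cells <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(cells) < 2L)) {
      stop_hippie("screen pair file requires 2 tab-separated columns",
                  class = "hippie_format_error")
    }
    m <- do.call(rbind, lapply(cells, `[`, 1:2))
    external_screen(baits, m[, 1L], m[, 2L])
  } else {
    external_screen(baits)
  }
}

#' Detectable subset of a network under a screen
#'
#' Exactly the interactions with at least one endpoint among the screen's
#' baits (a self-interaction of a bait is detectable). An empty bait set is
#' an error: nothing would be detectable.
#'
#' @param net A [hippie_network].
#' @param screen A [external_screen()].
#' @return The detectable sub-network.
#' @export
detectable_subset <- function(net, screen) {
  stopifnot(inherits(net, "hippie_network"), inherits(screen, "hippie_screen"))
  if (!length(screen$baits)) {
    stop_validation("screen has no baits; nothing is detectable")
  }
  subset_network(net, net$protein_a %in% screen$baits |
                   net$protein_b %in% screen$baits)
}

#' One-sided Fisher's exact test on stratified recall counts
#'
#' Tests whether the high-confidence stratum is recalled by the screen more
#' often than the low-confidence stratum. The 2x2 table pairs each
#' stratum's overlap count with its detectable count --
#' `[[k_high, n_high], [k_low, n_low]]` -- and the p-value is the exact
#' hypergeometric tail probability of an overlap split at least as extreme
#' as observed, at fixed margins (alternative: greater recall in the high
#' stratum).
#'
#' @param k_high,k_low Overlap counts per stratum.
#' @param n_high,n_low Detectable counts per stratum.
#' @return The one-sided p-value.
#' @examples
#' fisher_one_sided(75, 2239, 45, 5760)   # 6.40e-15
#' fisher_one_sided(41, 322, 32, 806)     # 1.75e-06
#' @export
fisher_one_sided <- function(k_high, n_high, k_low, n_low) {
  counts <- c(k_high, n_high, k_low, n_low)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_hippie("counts must be non-negative integers",
                class = "hippie_contract_error")
  }
  # margins of [[k_high, n_high], [k_low, n_low]]
  m <- k_high + k_low          # first-column total
  n <- n_high + n_low          # second-column total
  k <- k_high + n_high         # first-row total
  stats::phyper(k_high - 1, m, n, k, lower.tail = FALSE)
}

#' Stratified recall of a scored network by an external screen
#'
#' The evaluation protocol for a confidence threshold: split the scored
#' network into a high stratum (`score >= threshold`) and a low stratum
#' (`score < threshold`), restrict each to the PPIs detectable by the
#' screen, count how many detectable PPIs the screen actually found
#' (overlap), and report per-stratum recall. When both strata have
#' detectable PPIs, a one-sided Fisher's exact test ([fisher_one_sided()])
#' assesses whether recall is greater in the high stratum. A stratum with
#' no detectable PPIs has undefined recall and is reported as `NA`.
#'
#' @param net A fully scored [hippie_network].
#' @param screen A [external_screen()].
#' @param threshold Score threshold in \[0, 1\].
#' @return An object of class `recall_report`: a data frame with one row
#'   per stratum (`stratum`, `size`, `detectable`, `overlap`, `recall`,
#'   `recall_pct` at 1 decimal) and attribute `fisher_p`.
#' @export
stratified_recall <- function(net, screen, threshold) {
  stopifnot(inherits(net, "hippie_network"), inherits(screen, "hippie_screen"))
  if (threshold < 0 || threshold > 1) {
    stop_validation("threshold must lie in [0, 1]")
  }
  if (anyNA(net$score)) {
    stop_hippie("stratified_recall requires a fully scored network",
                class = "hippie_contract_error")
  }
  det_keys <- pair_key(screen$detected$protein_a, screen$detected$protein_b)
  det <- detectable_subset(net, screen)
  det_high <- det$score >= threshold
  hit <- network_keys(det) %in% det_keys

  size <- c(sum(net$score >= threshold), sum(net$score < threshold))
  detectable <- c(sum(det_high), sum(!det_high))
  overlap <- c(sum(hit & det_high), sum(hit & !det_high))
  recall <- ifelse(detectable > 0, overlap / detectable, NA_real_)

  report <- data.frame(
    stratum = c(sprintf("score >= %.2f", threshold),
                sprintf("score < %.2f", threshold)),
    size = size,
    detectable = detectable,
    overlap = overlap,
    recall = recall,
    recall_pct = round(100 * recall, 1),
    stringsAsFactors = FALSE)
  fisher_p <- if (all(detectable > 0)) {
    fisher_one_sided(overlap[1L], detectable[1L], overlap[2L], detectable[2L])
  } else {
    NA_real_
  }
  attr(report, "fisher_p") <- fisher_p
  attr(report, "threshold") <- threshold
  class(report) <- c("recall_report", "data.frame")
  report
}

#' @export
print.recall_report <- function(x, ...) {
  cat("Coverage of the network by the external screen\n")
  df <- as.data.frame(x)
  df$recall <- NULL
  df$`overlap (recall)` <- ifelse(
    is.na(df$recall_pct), sprintf("%d (recall undefined)", df$overlap),
    sprintf("%d (%.1f%%)", df$overlap, df$recall_pct))
  df$overlap <- df$recall_pct <- NULL
  print(df, row.names = FALSE)
  p <- attr(x, "fisher_p")
  if (!is.na(p)) {
    cat(sprintf("one-sided Fisher's exact test: p = %.2e\n", p))
  }
  invisible(x)
}
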
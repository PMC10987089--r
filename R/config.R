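#' Default size-rank bin edges
#'
#' Lower bin edges (cm) for size ranks 2 through 8, plus the upper bound of
#' the rank-8 bin. Ranks categorize an object's real-world bounding-box
#' diagonal on a logarithmic scale. Bins are half-open, `[lower, upper)`, so a
#' diagonal exactly on an edge belongs to the higher rank. Edges for ranks 4,
#' 5 and 7 sit on the published per-rank mean sizes (77, 146 and 577 cm);
#' the remaining edges interpolate between them on the log scale.
#'
#' @return Named numeric vector: lower edges for ranks `"2"` .. `"8"` and the
#'   overall upper bound `"cap"`.
#' @seealso [assign_rank()]
#' @export
default_rank_edges <- function() {
  c("2" = 9.5, "3" = 38, "4" = 77, "5" = 146, "6" = 290, "7" = 577,
    "8" = 1752, cap = 16000)
}

#' Analysis configuration
#'
#' Bundles every tunable of the boundary analysis: rank binning, animate
#' exclusion, permutation-test settings, confidence level and the normal
#' priors of the Bayes-factor comparison.
#'
#' @param rank_bin_edges Strictly increasing numeric vector of bin edges in
#'   cm; the first `length - 1` entries are lower edges of consecutive ranks
#'   starting at `min_rank`, the last entry is the upper bound.
#' @param min_rank Integer rank labeled by the first bin (default 2).
#' @param exclude_animate Drop animate objects before analysis? Default TRUE.
#' @param trough_site Optional fixed rank pair `c(i, i + 1)` at which the
#'   trough statistic is evaluated; when `NULL` the site is detected as the
#'   interior maximizer of the trough value.
#' @param n_permutations Number of label permutations for the trough test.
#' @param alpha One-tailed significance level (default 0.05).
#' @param ci_level Confidence level for intervals (default 0.95).
#' @param h1_prior_mean,h1_prior_sd Normal prior on the Fisher-z effect under
#'   H1 for the Bayes factor (defaults 2 and 1). H0 is standard normal.
#' @param permute Permutation exchange unit: `"ranks"` shuffles object-to-rank
#'   labels (default); `"actions"` independently shuffles each object's
#'   affordance vector across actions.
#' @param p_smoothing Use the (count + 1) / (N + 1) permutation p estimator
#'   instead of the raw count / N (default FALSE).
#' @param seed Integer seed for every random step downstream.
#' @return An object of class `aff_config` (a list).
#' @export
analysis_config <- function(rank_bin_edges = default_rank_edges(),
                            min_rank = 2L,
                            exclude_animate = TRUE,
                            trough_site = NULL,
                            n_permutations = 5000L,
                            alpha = 0.05,
                            ci_level = 0.95,
                            h1_prior_mean = 2,
                            h1_prior_sd = 1,
                            permute = c("ranks", "actions"),
                            p_smoothing = FALSE,
                            seed = 1L) {
  if (!is.numeric(rank_bin_edges) || length(rank_bin_edges) < 3L ||
      any(diff(rank_bin_edges) <= 0))
    aff_stop("`rank_bin_edges` must be a strictly increasing numeric vector of length >= 3",
             "value_error")
  check_scalar_in(min_rank, "min_rank", 0, 100)
  check_scalar_in(n_permutations, "n_permutations", 1, Inf)
  check_scalar_in(alpha, "alpha", 0, 1, open_lo = TRUE, open_hi = TRUE)
  check_scalar_in(ci_level, "ci_level", 0, 1, open_lo = TRUE, open_hi = TRUE)
  check_scalar_in(h1_prior_mean, "h1_prior_mean")
  check_scalar_in(h1_prior_sd, "h1_prior_sd", 0, Inf, open_lo = TRUE)
  if (!is.null(trough_site)) {
    if (length(trough_site) == 1L) trough_site <- c(trough_site, trough_site + 1L)
    if (length(trough_site) != 2L || trough_site[2] != trough_site[1] + 1L)
      aff_stop("`trough_site` must be a neighboring rank pair c(i, i + 1)",
               "value_error")
    trough_site <- as.integer(trough_site)
  }
  structure(list(
    rank_bin_edges = unname(as.numeric(rank_bin_edges)),
    min_rank = as.integer(min_rank),
    exclude_animate = isTRUE(exclude_animate),
    trough_site = trough_site,
    n_permutations = as.integer(n_permutations),
    alpha = alpha,
    ci_level = ci_level,
    h1_prior_mean = h1_prior_mean,
    h1_prior_sd = h1_prior_sd,
    permute = match.arg(permute),
    p_smoothing = isTRUE(p_smoothing),
    seed = as.integer(seed)
  ), class = "aff_config")
}

#' @export
print.aff_config <- function(x, ...) {
  ranks <- seq(x$min_rank, length.out = length(x$rank_bin_edges) - 1L)
  cat("<aff_config>\n")
  cat("  ranks", min(ranks), "..", max(ranks), " edges(cm):",
      paste(format(x$rank_bin_edges, trim = TRUE), collapse = ", "), "\n")
  cat("  permutations:", x$n_permutations, " alpha:", x$alpha,
      " permute:", x$permute, " seed:", x$seed, "\n")
  cat("  trough site:",
      if (is.null(x$trough_site)) "auto-detected"
      else paste(x$trough_site, collapse = "-"), "\n")
  invisible(x)
}

#' Map an object size to its size rank
#'
#' Assigns the integer size rank of a real-world bounding-box diagonal under
#' half-open logarithmic bins: a diagonal exactly on a bin edge goes to the
#' higher rank. The map is monotone non-decreasing in the diagonal.
#'
#' @param diagonal_cm Positive numeric vector of diagonals in cm.
#' @param config An [analysis_config()] supplying the bin edges.
#' @return Integer vector of ranks.
#' @examples
#' assign_rank(c(17, 77, 146, 577, 5317))
#' @export
assign_rank <- function(diagonal_cm, config = analysis_config()) {
  if (!is.numeric(diagonal_cm) || any(!is.finite(diagonal_cm)) ||
      any(diagonal_cm <= 0))
    aff_stop("`diagonal_cm` must be positive and finite", "domain_error")
  edges <- config$rank_bin_edges
  idx <- findInterval(diagonal_cm, edges)
  out_of_range <- idx == 0L | idx == length(edges)
  if (any(out_of_range))
    aff_stop(sprintf(
      "diagonal size(s) %s outside the covered range [%g, %g) cm",
      paste(format(diagonal_cm[out_of_range]), collapse = ", "),
      edges[1], edges[length(edges)]), "range_error")
  as.integer(idx + config$min_rank - 1L)
}
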
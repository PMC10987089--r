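# Boundary statistics: rank-wise similarity curve, trough value, permutation
# test, dependent-correlation comparisons and object-level boundary
# localization.

#' Mean affordance vector per size rank
#'
#' Unweighted mean of the member objects' affordance vectors within each size
#' rank.
#'
#' @param aff An `affordance_matrix`.
#' @return Numeric matrix, rank x action, rownames = rank labels (ascending).
#' @export
rank_mean_vectors <- function(aff) {
  stopifnot(inherits(aff, "affordance_matrix"))
  ranks <- aff$objects$rank
  rng <- range(ranks)
  missing_ranks <- setdiff(seq(rng[1], rng[2]), unique(ranks))
  if (length(missing_ranks))
    aff_stop(sprintf("no objects in rank(s) %s inside the analyzed range %d..%d",
                     paste(missing_ranks, collapse = ", "), rng[1], rng[2]),
             "coverage_error")
  sums <- rowsum(aff$probs, group = ranks) # rows ordered by sorted rank
  counts <- as.vector(table(ranks))
  sums / counts
}

#' Affordance similarity between neighboring size ranks
#'
#' Pearson correlation between the mean affordance vectors of each pair of
#' neighboring size ranks, with the standard error
#' `sqrt((1 - r^2) / (n - 2))` where `n` is the number of actions.
#'
#' @param rank_means Rank x action matrix from [rank_mean_vectors()].
#' @return A `rank_curve`: data frame with columns `lo`, `hi` (the rank
#'   pair), `r`, `se`; attribute `n_actions`.
#' @export
neighbor_similarity_curve <- function(rank_means) {
  if (!is.matrix(rank_means) || nrow(rank_means) < 2L)
    aff_stop("need mean vectors for at least 2 ranks", "insufficient_data")
  ranks <- as.integer(rownames(rank_means))
  n_act <- ncol(rank_means)
  r <- row_cor_adjacent(rank_means)
  if (anyNA(r))
    aff_warn("constant rank mean vector: correlation undefined for some pair(s)",
             "zero_variance")
  curve <- data.frame(lo = ranks[-length(ranks)], hi = ranks[-1L], r = r,
                      se = sqrt((1 - r^2) / (n_act - 2)))
  attr(curve, "n_actions") <- n_act
  class(curve) <- c("rank_curve", "data.frame")
  curve
}

.site_index <- function(curve, site) {
  if (length(site) == 1L) site <- c(site, site + 1L)
  j <- which(curve$lo == site[1] & curve$hi == site[2])
  if (!length(j))
    aff_stop(sprintf("rank pair (%d, %d) is not on the curve",
                     site[1], site[2]), "value_error")
  j
}

#' Trough value at a rank pair
#'
#' How far the similarity at `site` dips below the mean of its two banks
#' (the neighboring points of the curve):
#' `T = (r[site - 1] + r[site + 1]) / 2 - r[site]`. Larger is a deeper
#' trough; a bump yields a negative value.
#'
#' @param curve A `rank_curve`.
#' @param site Rank pair `c(i, i + 1)` (or the scalar `i`).
#' @return The trough value, a scalar.
#' @export
trough_value <- function(curve, site) {
  j <- .site_index(curve, site)
  if (j == 1L || j == nrow(curve))
    aff_stop("site has no bank on one side; the trough value needs both neighbors",
             "no_banks")
  (curve$r[j - 1L] + curve$r[j + 1L]) / 2 - curve$r[j]
}

#' Detect the trough site
#'
#' The interior rank pair maximizing the trough value; ties go to the smaller
#' rank. A fixed `trough_site` in `config` overrides detection.
#'
#' @param curve A `rank_curve`.
#' @param config Optional [analysis_config()]; its `trough_site`, when set,
#'   is returned after validation.
#' @return Integer rank pair `c(i, i + 1)`.
#' @export
detect_trough <- function(curve, config = NULL) {
  if (!is.null(config) && !is.null(config$trough_site)) {
    .site_index(curve, config$trough_site)
    return(config$trough_site)
  }
  if (nrow(curve) < 3L)
    aff_stop("need at least 3 curve points to detect an interior trough",
             "insufficient_curve")
  interior <- 2:(nrow(curve) - 1L)
  tv <- (curve$r[interior - 1L] + curve$r[interior + 1L]) / 2 -
    curve$r[interior]
  if (all(is.na(tv)))
    aff_stop("trough value undefined at every interior site", "zero_variance")
  j <- interior[which.max(tv)] # which.max: first maximum = smaller rank
  c(curve$lo[j], curve$hi[j])
}

# Trough value at curve position j for a rank-labeled affordance matrix.
# probs: object x action; labels: integer ranks; counts: per sorted rank.
.trough_at <- function(probs, labels, counts, j) {
  means <- rowsum(probs, group = labels) / counts
  rows <- (j - 1L):(j + 2L) # the four rank means feeding banks + trough
  r3 <- row_cor_adjacent(means[rows, , drop = FALSE])
  (r3[1] + r3[3]) / 2 - r3[2]
}

#' Permutation test of the trough value
#'
#' Tests whether the trough at `site` is larger than expected when object
#' sizes carry no information: each permutation shuffles the object-to-rank
#' assignment (per-rank object counts preserved), recomputes the
#' neighboring-rank similarity curve and evaluates the trough value at the
#' same site. The p-value is the plain permutation fraction
#' `p = (1/N) * sum(T_i >= T_obs)` (optionally the smoothed
#' `(count + 1) / (N + 1)` variant via `config$p_smoothing`).
#'
#' @param aff An `affordance_matrix` (objects carry ranks).
#' @param site Rank pair `c(i, i + 1)`; `NULL` detects it via
#'   [detect_trough()].
#' @param config An [analysis_config()]: permutation count, seed, exchange
#'   unit, smoothing.
#' @return A `trough_result`: list with `site`, `t_obs`, `null_values`,
#'   `p_value`, `n_permutations`, `seed`, `curve`.
#' @export
permutation_test_trough <- function(aff, site = NULL,
                                    config = analysis_config()) {
  stopifnot(inherits(aff, "affordance_matrix"))
  curve <- neighbor_similarity_curve(rank_mean_vectors(aff))
  if (is.null(site)) site <- detect_trough(curve, config)
  j <- .site_index(curve, site)
  if (j == 1L || j == nrow(curve))
    aff_stop("site has no bank on one side; choose an interior rank pair",
             "no_banks")
  t_obs <- trough_value(curve, site)

  labels <- aff$objects$rank
  counts <- as.vector(table(labels))
  if (all(counts == 1L))
    aff_warn("every rank holds a single object; permutations only relabel objects",
             "degenerate_permutation")
  probs <- aff$probs
  n_perm <- config$n_permutations
  null_values <- with_seed(config$seed, {
    vapply(seq_len(n_perm), function(i) {
      if (config$permute == "ranks") {
        .trough_at(probs, sample(labels), counts, j)
      } else {
        shuffled <- t(apply(probs, 1L, sample))
        .trough_at(shuffled, labels, counts, j)
      }
    }, numeric(1))
  })
  count <- sum(null_values >= t_obs, na.rm = TRUE)
  p <- if (config$p_smoothing) (count + 1) / (n_perm + 1) else count / n_perm
  structure(list(site = as.integer(site), t_obs = t_obs,
                 null_values = null_values, p_value = p,
                 n_permutations = n_perm, seed = config$seed, curve = curve),
            class = "trough_result")
}

#' @export
print.trough_result <- function(x, ...) {
  cat(sprintf("<trough_result> site ranks %d-%d: T_obs = %.4f, p = %.4g (N = %d permutations)\n",
              x$site[1], x$site[2], x$t_obs, x$p_value, x$n_permutations))
  invisible(x)
}

#' Compare two neighboring-rank similarities
#'
#' Tests whether the affordance similarity of rank pair `pair_a` differs from
#' that of `pair_b`, where the two pairs share a rank (dependent overlapping
#' correlations over the action dimension). Reports Steiger's Z with its
#' one-tailed p (positive Z when `pair_a`'s similarity is larger), Zou's
#' interval for the difference, and a Bayes factor for the Fisher-z
#' difference under the configured normal priors (H0 standard normal, H1
#' `N(h1_prior_mean, h1_prior_sd^2)`), with the Fisher-z standard error
#' `1 / sqrt(n_actions - 3)`.
#'
#' @param rank_means Rank x action matrix from [rank_mean_vectors()].
#' @param pair_a,pair_b Neighboring rank pairs sharing one rank, e.g.
#'   `c(3, 4)` and `c(4, 5)`.
#' @param config An [analysis_config()] (priors, ci_level).
#' @return List: `r_a`, `r_b`, `r_cross`, `Z`, `p_one_tailed`, `bf10`,
#'   `zou_ci`, `n_actions`.
#' @export
compare_neighbor_correlations <- function(rank_means, pair_a, pair_b,
                                          config = analysis_config()) {
  shared <- intersect(pair_a, pair_b)
  if (length(shared) != 1L)
    aff_stop("`pair_a` and `pair_b` must share exactly one rank",
             "value_error")
  n_act <- ncol(rank_means)
  if (n_act < 4L) aff_stop("need at least 4 actions", "insufficient_data")
  v <- function(rank) {
    i <- match(as.character(rank), rownames(rank_means))
    if (is.na(i)) aff_stop(sprintf("rank %s has no mean vector", rank),
                           "value_error")
    rank_means[i, ]
  }
  k <- shared
  jj <- setdiff(pair_a, k); hh <- setdiff(pair_b, k)
  r_a <- stats::cor(v(k), v(jj))
  r_b <- stats::cor(v(k), v(hh))
  r_cross <- stats::cor(v(jj), v(hh))
  st <- steiger_z(r_a, r_b, r_cross, n_act)
  z_diff <- fisher_z(r_a) - fisher_z(r_b)
  bf <- bayes_factor_normal(z_diff, se = 1 / sqrt(n_act - 3),
                            h1_mean = config$h1_prior_mean,
                            h1_sd = config$h1_prior_sd)
  list(pair_a = pair_a, pair_b = pair_b, r_a = r_a, r_b = r_b,
       r_cross = r_cross, Z = st$Z, p_one_tailed = st$p_one_tailed,
       bf10 = bf, zou_ci = zou_ci(r_a, r_b, r_cross, n_act,
                                  level = config$ci_level),
       n_actions = n_act)
}

#' Object-level boundary scan
#'
#' Traverses every object pair from the same or adjacent size ranks inside
#' `rank_window`, recording the pair's affordance similarity and mean
#' real-world size. Pairs are grouped by rank composition ((i,i) or
#' (i,i+1)); the boundary location is estimated as the mean pair size of the
#' composition with the lowest mean similarity, with a seeded percentile
#' bootstrap CI over that composition's pairs (normal-approximation CIs are
#' reported per composition as well, masked when a composition has a single
#' pair).
#'
#' @param aff An `affordance_matrix`.
#' @param rank_window Inclusive rank range to scan (default `c(3, 6)`).
#' @param config An [analysis_config()] (ci_level, seed).
#' @param n_boot Bootstrap resamples for the boundary CI (default 1000).
#' @return A `pair_scan`: list with `pairs` (one row per admissible pair),
#'   `compositions` (per-composition aggregates), `boundary_estimate_cm`,
#'   `boundary_ci`, `boundary_composition`.
#' @export
pairwise_boundary_scan <- function(aff, rank_window = c(3L, 6L),
                                   config = analysis_config(),
                                   n_boot = 1000L) {
  stopifnot(inherits(aff, "affordance_matrix"))
  keep <- aff$objects$rank >= rank_window[1] & aff$objects$rank <= rank_window[2]
  if (sum(keep) < 2L)
    aff_stop("fewer than 2 objects inside the rank window", "insufficient_data")
  obj <- aff$objects[keep, , drop = FALSE]
  sim <- similarity_matrix(aff)
  r_all <- sim$r[keep, keep, drop = FALSE]

  idx <- utils::combn(nrow(obj), 2L)
  ra <- obj$rank[idx[1, ]]; rb <- obj$rank[idx[2, ]]
  adm <- abs(ra - rb) <= 1L
  idx <- idx[, adm, drop = FALSE]
  pairs <- data.frame(
    object_a = obj$object[idx[1, ]],
    object_b = obj$object[idx[2, ]],
    rank_a = pmin(obj$rank[idx[1, ]], obj$rank[idx[2, ]]),
    rank_b = pmax(obj$rank[idx[1, ]], obj$rank[idx[2, ]]),
    mean_size_cm = (obj$diagonal_cm[idx[1, ]] + obj$diagonal_cm[idx[2, ]]) / 2,
    r = r_all[t(idx)],
    stringsAsFactors = FALSE)
  pairs$composition <- sprintf("(%d,%d)", pairs$rank_a, pairs$rank_b)

  q <- stats::qnorm(1 - (1 - config$ci_level) / 2)
  agg <- do.call(rbind, lapply(split(pairs, pairs$composition), function(g) {
    n <- nrow(g)
    sem_r <- if (n >= 2L) stats::sd(g$r) / sqrt(n) else NA_real_
    sem_s <- if (n >= 2L) stats::sd(g$mean_size_cm) / sqrt(n) else NA_real_
    data.frame(composition = g$composition[1], rank_a = g$rank_a[1],
               rank_b = g$rank_b[1], n_pairs = n,
               mean_r = mean(g$r), r_ci_lo = mean(g$r) - q * sem_r,
               r_ci_hi = mean(g$r) + q * sem_r,
               mean_size_cm = mean(g$mean_size_cm),
               size_ci_lo = mean(g$mean_size_cm) - q * sem_s,
               size_ci_hi = mean(g$mean_size_cm) + q * sem_s,
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$rank_a + agg$rank_b, agg$rank_a), , drop = FALSE]
  rownames(agg) <- NULL

  i_min <- which.min(agg$mean_r)
  min_comp <- agg$composition[i_min]
  comp_sizes <- pairs$mean_size_cm[pairs$composition == min_comp]
  boundary_ci <- if (length(comp_sizes) >= 2L)
    percentile_bootstrap_ci(comp_sizes, level = config$ci_level,
                            n_boot = n_boot, seed = config$seed)
  else c(lower = NA_real_, upper = NA_real_)

  structure(list(pairs = pairs, compositions = agg,
                 boundary_estimate_cm = agg$mean_size_cm[i_min],
                 boundary_ci = boundary_ci,
                 boundary_composition = c(agg$rank_a[i_min], agg$rank_b[i_min]),
                 rank_window = as.integer(rank_window)),
            class = "pair_scan")
}

#' @export
print.pair_scan <- function(x, ...) {
  cat(sprintf("<pair_scan> %d pairs, ranks %d..%d; lowest-similarity composition (%d,%d)\n",
              nrow(x$pairs), x$rank_window[1], x$rank_window[2],
              x$boundary_composition[1], x$boundary_composition[2]))
  cat(sprintf("  boundary estimate %.1f cm (%.0f%% CI %.1f-%.1f)\n",
              x$boundary_estimate_cm, 95,
              x$boundary_ci[1], x$boundary_ci[2]))
  invisible(x)
}

#' Write the rank curve as CSV
#' @param curve A `rank_curve`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rank_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Write a trough result as JSON
#' @param trough A `trough_result`.
#' @param path Output path.
#' @param include_null Also store the permuted null values? Default FALSE.
#' @return Invisibly, `path`.
#' @export
write_trough_json <- function(trough, path, include_null = FALSE) {
  out <- list(site = trough$site, t_obs = trough$t_obs,
              p_value = trough$p_value,
              n_permutations = trough$n_permutations, seed = trough$seed)
  if (include_null) out$null_values <- trough$null_values
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a pair scan as CSV
#' @param scan A `pair_scan`.
#' @param path Output path for the per-pair records.
#' @return Invisibly, `path`.
#' @export
write_pair_scan_csv <- function(scan, path) {
  utils::write.csv(scan$pairs, path, row.names = FALSE)
  invisible(path)
}
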
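# End-to-end orchestration: tensor -> affordance vectors -> RSM/clusters ->
# rank curve -> trough + permutation test -> neighboring-pair comparisons ->
# size-similarity control curve -> object-level boundary scan.

#' Real-world size similarity between two sizes
#'
#' `1 - (d_j - d_i) / d_i`: relative size similarity of the (larger-rank)
#' size `d_j` to the reference size `d_i`. Equals 1 when the sizes match,
#' reaches 0 when `d_j` doubles `d_i`, and is deliberately asymmetric (the
#' reference is the smaller rank).
#'
#' @param d_i Reference diagonal in cm (> 0), the smaller rank's mean size.
#' @param d_j Comparison diagonal in cm.
#' @return Numeric size similarity.
#' @export
size_similarity <- function(d_i, d_j) {
  if (any(!is.finite(d_i)) || any(d_i <= 0))
    aff_stop("`d_i` must be positive and finite", "domain_error")
  1 - (d_j - d_i) / d_i
}

#' Size-similarity curve across neighboring ranks
#'
#' [size_similarity()] between the mean object diagonals of each pair of
#' neighboring size ranks — the control curve showing that real-world size
#' changes smoothly across ranks.
#'
#' @param objects Object data frame with `diagonal_cm` and `rank`.
#' @return Data frame with columns `lo`, `hi`, `size_lo_cm`, `size_hi_cm`,
#'   `size_similarity`.
#' @export
size_similarity_curve <- function(objects) {
  objects <- validate_objects(objects)
  mean_sizes <- tapply(objects$diagonal_cm, objects$rank, mean)
  ranks <- as.integer(names(mean_sizes))
  m <- length(ranks)
  if (m < 2L) aff_stop("need at least 2 ranks", "insufficient_data")
  data.frame(lo = ranks[-m], hi = ranks[-1L],
             size_lo_cm = unname(mean_sizes[-m]),
             size_hi_cm = unname(mean_sizes[-1L]),
             size_similarity = size_similarity(unname(mean_sizes[-m]),
                                               unname(mean_sizes[-1L])))
}

#' Run the full affordance-boundary analysis
#'
#' Sequences every stage of the pipeline on a validated response tensor and
#' collects the results in a versioned report: affordance vectors, the
#' representational similarity matrix and its 2-cluster cut, the
#' neighboring-rank similarity curve, the permutation-tested trough, Z / p /
#' BF10 comparisons between consecutive neighboring-rank similarities, the
#' size-similarity control curve, and the object-level boundary scan.
#'
#' @param tensor A [response_tensor()].
#' @param config An [analysis_config()].
#' @param rank_window Rank window for the object-level scan; `NULL` (default)
#'   uses `c(3, 6)` clipped to the available ranks.
#' @param group_by Optional participant metadata column (e.g. `"group"`):
#'   adds per-group rank curves (descriptive only, no inference).
#' @return An `aff_report` (list; see Details), printable and serializable
#'   via [write_report()].
#' @export
run_analysis <- function(tensor, config = analysis_config(),
                         rank_window = NULL, group_by = NULL) {
  stopifnot(inherits(tensor, "response_tensor"))
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  d <- dim(tensor$data)
  note("input: %d participants x %d actions x %d objects", d[1], d[2], d[3])

  if (config$exclude_animate && any(tensor$objects$animate)) {
    n_anim <- sum(tensor$objects$animate)
    tensor <- filter_animate(tensor)
    note("excluded %d animate object(s); %d retained", n_anim,
         nrow(tensor$objects))
  }

  aff <- affordance_vectors(tensor)
  sim <- withCallingHandlers(
    similarity_matrix(aff),
    affbound_zero_variance = function(w) {
      note("masked cells: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  clusters <- cluster_similarity(sim, k = min(2L, nrow(aff$probs)))
  rank_means <- rank_mean_vectors(aff)
  curve <- neighbor_similarity_curve(rank_means)
  site <- detect_trough(curve, config)
  note("trough site: ranks %d-%d (%s)", site[1], site[2],
       if (is.null(config$trough_site)) "detected" else "fixed by config")
  trough <- permutation_test_trough(aff, site, config)

  comparisons <- NULL
  if (nrow(curve) >= 2L) {
    comparisons <- do.call(rbind, lapply(seq_len(nrow(curve) - 1L), function(i) {
      cmp <- compare_neighbor_correlations(
        rank_means, c(curve$lo[i], curve$hi[i]),
        c(curve$lo[i + 1L], curve$hi[i + 1L]), config)
      data.frame(pair_a = sprintf("(%d,%d)", curve$lo[i], curve$hi[i]),
                 pair_b = sprintf("(%d,%d)", curve$lo[i + 1], curve$hi[i + 1]),
                 r_a = cmp$r_a, r_b = cmp$r_b, Z = cmp$Z,
                 p_one_tailed = cmp$p_one_tailed, bf10 = cmp$bf10,
                 zou_lower = unname(cmp$zou_ci[1]),
                 zou_upper = unname(cmp$zou_ci[2]),
                 stringsAsFactors = FALSE)
    }))
    rownames(comparisons) <- NULL
  }

  size_curve <- size_similarity_curve(tensor$objects)

  ranks_present <- sort(unique(tensor$objects$rank))
  if (is.null(rank_window))
    rank_window <- c(max(3L, min(ranks_present)), min(6L, max(ranks_present)))
  scan <- NULL
  if (rank_window[1] < rank_window[2]) {
    scan <- pairwise_boundary_scan(aff, rank_window, config)
    note("boundary estimate: %.1f cm at composition (%d,%d)",
         scan$boundary_estimate_cm, scan$boundary_composition[1],
         scan$boundary_composition[2])
  } else note("rank window degenerate; object-level scan skipped")

  group_curves <- NULL
  if (!is.null(group_by)) {
    groups <- tensor$participants[[group_by]]
    group_curves <- lapply(split(seq_len(d[1]), groups), function(ix) {
      sub <- response_tensor(tensor$data[ix, , , drop = FALSE],
                             tensor$participants[ix, , drop = FALSE],
                             tensor$actions, tensor$objects)
      neighbor_similarity_curve(rank_mean_vectors(affordance_vectors(sub)))
    })
    note("group-stratified curves: %s",
         paste(names(group_curves), collapse = ", "))
  }

  structure(list(
    schema_version = "1.0",
    config = config,
    affordance = aff,
    similarity = sim,
    clusters = clusters,
    rank_curve = curve,
    trough = trough,
    comparisons = comparisons,
    size_curve = size_curve,
    pair_scan = scan,
    group_curves = group_curves,
    log = log
  ), class = "aff_report")
}

#' @export
print.aff_report <- function(x, ...) {
  cat("<aff_report> affordance-boundary analysis\n")
  cat(sprintf("  %d objects x %d actions, n = %d participants\n",
              nrow(x$affordance$probs), ncol(x$affordance$probs),
              x$affordance$n_participants))
  cat("  neighboring-rank similarity curve:\n")
  with(x$rank_curve, cat(sprintf("    r(%d,%d) = %+.3f (se %.3f)\n",
                                 lo, hi, r, se), sep = ""))
  cat(sprintf("  trough at ranks %d-%d: T_obs = %.3f, permutation p = %.4g (N = %d)\n",
              x$trough$site[1], x$trough$site[2], x$trough$t_obs,
              x$trough$p_value, x$trough$n_permutations))
  if (!is.null(x$pair_scan))
    cat(sprintf("  object-level boundary: %.1f cm (composition (%d,%d))\n",
                x$pair_scan$boundary_estimate_cm,
                x$pair_scan$boundary_composition[1],
                x$pair_scan$boundary_composition[2]))
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Writes `report.json` plus the CSV/JSON artifacts of the upstream stages
#' (affordance matrix, similarity matrix, clusters, rank curve, trough,
#' comparisons, pair scan) into `dir`.
#'
#' @param report An `aff_report`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "aff_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_affordance_csv(report$affordance, file.path(dir, "affordance_matrix.csv"))
  write_similarity_csv(report$similarity, file.path(dir, "similarity_matrix.csv"))
  write_clusters_json(report$clusters, file.path(dir, "clusters.json"))
  write_rank_curve_csv(report$rank_curve, file.path(dir, "rank_curve.csv"))
  write_trough_json(report$trough, file.path(dir, "trough.json"))
  if (!is.null(report$comparisons))
    utils::write.csv(report$comparisons, file.path(dir, "comparisons.csv"),
                     row.names = FALSE)
  if (!is.null(report$pair_scan))
    write_pair_scan_csv(report$pair_scan, file.path(dir, "pair_scan.csv"))

  main <- list(
    schema_version = report$schema_version,
    seed = report$config$seed,
    n_participants = report$affordance$n_participants,
    n_objects = nrow(report$affordance$probs),
    n_actions = ncol(report$affordance$probs),
    rank_curve = as.data.frame(report$rank_curve),
    trough = list(site = report$trough$site, t_obs = report$trough$t_obs,
                  p_value = report$trough$p_value,
                  n_permutations = report$trough$n_permutations),
    size_curve = report$size_curve,
    boundary_estimate_cm = if (!is.null(report$pair_scan))
      report$pair_scan$boundary_estimate_cm,
    boundary_ci = if (!is.null(report$pair_scan))
      unname(report$pair_scan$boundary_ci),
    log = report$log)
  jsonlite::write_json(main, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(dir)
}
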
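# Affordance vectors, the object-by-object representational similarity
# matrix (RSM), and its hierarchical clustering.

#' Affordance vectors from a response tensor
#'
#' For each object, the fraction of participants endorsing each action: the
#' object's affordance vector (one dimension per action).
#'
#' @param tensor A [response_tensor()].
#' @return An `affordance_matrix`: list with `probs` (object x action matrix
#'   of proportions in `[0, 1]`), `objects`, `actions`, `n_participants`.
#' @export
affordance_vectors <- function(tensor) {
  stopifnot(inherits(tensor, "response_tensor"))
  n_p <- dim(tensor$data)[1]
  if (n_p == 0L) aff_stop("tensor has zero participants", "empty_input")
  probs <- t(colMeans(tensor$data, dims = 1L)) # -> object x action
  structure(list(probs = probs, objects = tensor$objects,
                 actions = tensor$actions, n_participants = n_p),
            class = "affordance_matrix")
}

#' @export
print.affordance_matrix <- function(x, ...) {
  cat(sprintf("<affordance_matrix> %d objects x %d actions (n = %d participants)\n",
              nrow(x$probs), ncol(x$probs), x$n_participants))
  invisible(x)
}

#' Affordance similarity matrix
#'
#' Object-by-object Pearson correlations between affordance vectors, the
#' representational similarity matrix of perceived affordance. Cells
#' involving a zero-variance affordance vector are undefined (`NA`) and
#' flagged in `valid`, never silently zero.
#'
#' @param aff An `affordance_matrix`.
#' @return A `similarity_matrix`: list with `r` (symmetric object x object
#'   matrix, unit diagonal where defined), `valid` (per-object flag),
#'   `objects`.
#' @export
similarity_matrix <- function(aff) {
  stopifnot(inherits(aff, "affordance_matrix"))
  if (ncol(aff$probs) < 2L)
    aff_stop("need at least 2 actions to correlate affordance vectors",
             "insufficient_data")
  sds <- apply(aff$probs, 1L, stats::sd)
  valid <- sds > 0
  r <- suppressWarnings(stats::cor(t(aff$probs)))
  r[!valid, ] <- NA_real_
  r[, !valid] <- NA_real_
  diag(r)[valid] <- 1
  if (any(!valid))
    aff_warn(sprintf("zero-variance affordance vector(s): %s (cells masked)",
                     paste(aff$objects$object[!valid], collapse = ", ")),
             "zero_variance")
  structure(list(r = r, valid = valid, objects = aff$objects),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d objects (%d masked); off-diagonal range %.3f .. %.3f\n",
              nrow(x$r), sum(!x$valid),
              min(x$r[upper.tri(x$r)], na.rm = TRUE),
              max(x$r[upper.tri(x$r)], na.rm = TRUE)))
  invisible(x)
}

#' Hierarchical clustering of the similarity matrix
#'
#' Agglomerative clustering of the matrix rows (each object's similarity
#' profile) under Euclidean distance and complete linkage, cut at `k`
#' clusters. Objects with masked (zero-variance) profiles are dropped with a
#' warning. `stats::hclust` resolves merge ties deterministically given the
#' input order, so results are reproducible.
#'
#' @param sim A `similarity_matrix`.
#' @param k Number of clusters (default 2).
#' @return List with `labels` (named integer vector), `tree`
#'   (an `hclust` object), `k`.
#' @export
cluster_similarity <- function(sim, k = 2L) {
  stopifnot(inherits(sim, "similarity_matrix"))
  keep <- sim$valid
  if (any(!keep))
    aff_warn(sprintf("dropping %d masked object(s) before clustering",
                     sum(!keep)), "masked_dropped")
  m <- sim$r[keep, keep, drop = FALSE]
  if (k > nrow(m))
    aff_stop(sprintf("k = %d exceeds the %d clusterable objects", k, nrow(m)),
             "parameter_error")
  tree <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "complete")
  labels <- stats::cutree(tree, k = k)
  list(labels = labels, tree = tree, k = as.integer(k))
}

#' Write the affordance matrix as CSV
#' @param aff An `affordance_matrix`.
#' @param path Output CSV path (objects in rows, actions in columns).
#' @return Invisibly, `path`.
#' @export
write_affordance_csv <- function(aff, path) {
  df <- data.frame(object = aff$objects$object, aff$probs,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the similarity matrix as CSV
#' @param sim A `similarity_matrix`.
#' @param path Output CSV path (square object x object layout).
#' @return Invisibly, `path`.
#' @export
write_similarity_csv <- function(sim, path) {
  df <- data.frame(object = sim$objects$object, sim$r,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1] <- sim$objects$object
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write cluster labels and merge tree as JSON
#' @param clusters Result of [cluster_similarity()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_clusters_json <- function(clusters, path) {
  out <- list(
    k = clusters$k,
    labels = as.list(clusters$labels),
    merge = clusters$tree$merge,
    height = clusters$tree$height,
    order = clusters$tree$order,
    leaf_labels = clusters$tree$labels)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
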
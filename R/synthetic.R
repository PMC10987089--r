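# Synthetic judgment generator: Bernoulli responses under a logistic
# body-size boundary. Objects smaller than the agent attract manipulation
# endorsements (grasp, hold, throw, ...); objects larger attract whole-body
# endorsements (sit, stand, ...). The latent boundary is the agent's own
# diagonal size.

#' Generator configuration
#'
#' Parameters of the synthetic judgment model. For an object of diagonal `d`
#' and an action of class `s` (-1 manipulation, +1 whole-body) the
#' endorsement probability is
#' `p = lapse/2 + (1 - lapse) * gain * plogis(s * beta * log2(d / B))`,
#' with `B = agent_size_cm` the latent boundary. Each participant's response
#' is an independent Bernoulli draw at `p` (optionally shifted by a
#' per-participant logit offset).
#'
#' @param n_participants Number of simulated raters (default 528, the scale
#'   of the emulated study sample).
#' @param objects_per_rank Objects generated per size rank: a scalar or a
#'   vector along `rank_range`. Default `c(3, 4, 4, 4, 4, 3, 2)` over ranks
#'   2..8 (24 objects, concentrated at mid ranks like the emulated stimulus
#'   set).
#' @param rank_range Inclusive integer range of size ranks (default 2..8).
#' @param agent_size_cm Latent boundary B, the agent's body diagonal in cm:
#'   about 150 for an adult human, 77 for a cat, 577 for an elephant.
#' @param sharpness_beta Logistic slope per log2 size-ratio unit; 0 removes
#'   the boundary entirely (null model). Default 4.
#' @param lapse_rate Probability of a stimulus-independent random response,
#'   in [0, 1). Default 0.05.
#' @param action_gain Per-action ceiling in (0, 1]: scalar or one value per
#'   action. Default 1.
#' @param participant_sd SD of an optional per-participant logit offset
#'   (default 0 = homogeneous participants).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_participants = 528L,
                             objects_per_rank = c(3L, 4L, 4L, 4L, 4L, 3L, 2L),
                             rank_range = c(2L, 8L),
                             agent_size_cm = 150,
                             sharpness_beta = 4,
                             lapse_rate = 0.05,
                             action_gain = 1,
                             participant_sd = 0,
                             seed = 1L) {
  check_scalar_in(n_participants, "n_participants", 1, Inf)
  check_scalar_in(agent_size_cm, "agent_size_cm", 0, Inf, open_lo = TRUE)
  check_scalar_in(sharpness_beta, "sharpness_beta", 0, Inf)
  check_scalar_in(lapse_rate, "lapse_rate", 0, 1, open_hi = TRUE)
  check_scalar_in(participant_sd, "participant_sd", 0, Inf)
  if (length(rank_range) != 2L || rank_range[1] > rank_range[2])
    aff_stop("`rank_range` must be c(lo, hi) with lo <= hi", "value_error")
  ranks <- seq(rank_range[1], rank_range[2])
  if (!all(ranks %in% 2:8))
    aff_stop("`rank_range` must lie within 2..8", "value_error")
  opr <- as.integer(rep_len(objects_per_rank, length(ranks)))
  if (any(opr < 1L))
    aff_stop("`objects_per_rank` must be positive", "value_error")
  if (any(action_gain <= 0) || any(action_gain > 1))
    aff_stop("`action_gain` must lie in (0, 1]", "value_error")
  structure(list(
    n_participants = as.integer(n_participants),
    objects_per_rank = opr,
    rank_range = as.integer(rank_range),
    agent_size_cm = agent_size_cm,
    sharpness_beta = sharpness_beta,
    lapse_rate = lapse_rate,
    action_gain = as.numeric(action_gain),
    participant_sd = participant_sd,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  %d participants; ranks %d..%d with %s objects/rank\n",
              x$n_participants, x$rank_range[1], x$rank_range[2],
              paste(x$objects_per_rank, collapse = ",")))
  cat(sprintf("  agent %g cm; beta %g; lapse %g; seed %d\n",
              x$agent_size_cm, x$sharpness_beta, x$lapse_rate, x$seed))
  invisible(x)
}

#' Default action set
#'
#' Fourteen everyday actions: seven hand-scale manipulations and seven
#' whole-body actions.
#'
#' @return Data frame with columns `action`, `action_class`.
#' @export
default_actions <- function() {
  data.frame(
    action = c("grasp", "hold", "throw", "lift", "carry", "push", "pull",
               "sit", "stand", "lie", "climb", "enter", "lean", "walk"),
    action_class = rep(c("manipulation", "whole_body"), each = 7L),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic object set
#'
#' Samples `objects_per_rank` inanimate objects per size rank, with diagonals
#' drawn log-uniformly within each rank's bin, so generated objects are
#' consistent with [assign_rank()] by construction.
#'
#' @param config A [generator_config()].
#' @param analysis [analysis_config()] supplying the rank-bin edges.
#' @return Object data frame (columns object, diagonal_cm, rank, animate).
#' @export
generate_object_set <- function(config, analysis = analysis_config()) {
  stopifnot(inherits(config, "generator_config"))
  edges <- analysis$rank_bin_edges
  ranks <- seq(config$rank_range[1], config$rank_range[2])
  idx <- ranks - analysis$min_rank + 1L
  if (any(idx < 1L) || any(idx + 1L > length(edges)))
    aff_stop("`rank_range` not covered by the configured bin edges",
             "range_error")
  with_seed(config$seed, {
    rows <- do.call(rbind, lapply(seq_along(ranks), function(k) {
      m <- config$objects_per_rank[k]
      lo <- log(edges[idx[k]]); hi <- log(edges[idx[k] + 1L])
      data.frame(
        object = sprintf("obj_r%d_%02d", ranks[k], seq_len(m)),
        diagonal_cm = exp(sort(stats::runif(m, lo, hi))),
        rank = ranks[k],
        animate = FALSE,
        stringsAsFactors = FALSE)
    }))
    rownames(rows) <- NULL
    rows
  })
}

#' Endorsement probability under the boundary model
#'
#' The probability that a participant endorses `action` for `object`:
#' a logistic function of the log2 ratio between object size and agent size,
#' decreasing for manipulation actions and increasing for whole-body actions,
#' attenuated by the action gain and mixed with a symmetric lapse.
#'
#' @param object Object data frame (or a numeric vector of diagonals in cm).
#' @param action Action data frame row(s) (or a character vector of action
#'   classes).
#' @param config A [generator_config()].
#' @return Numeric matrix, object x action, of probabilities in
#'   `[lapse/2, 1 - lapse/2]`.
#' @export
endorsement_probability <- function(object, action, config) {
  stopifnot(inherits(config, "generator_config"))
  d <- if (is.data.frame(object)) object$diagonal_cm else as.numeric(object)
  cls <- if (is.data.frame(action)) action$action_class else as.character(action)
  if (any(!cls %in% c("manipulation", "whole_body")))
    aff_stop("action_class must be 'manipulation' or 'whole_body'",
             "value_error")
  if (any(d <= 0)) aff_stop("object diagonal must be positive", "domain_error")
  gain <- rep_len(config$action_gain, length(cls))
  s <- ifelse(cls == "manipulation", -1, 1)
  x <- log2(d / config$agent_size_cm)
  core <- stats::plogis(outer(x, s * config$sharpness_beta))
  p <- config$lapse_rate / 2 +
    (1 - config$lapse_rate) * sweep(core, 2L, gain, `*`)
  dimnames(p) <- list(
    if (is.data.frame(object)) object$object else NULL,
    if (is.data.frame(action)) action$action else NULL)
  p
}

#' Generate a synthetic response tensor
#'
#' Independent Bernoulli draws at [endorsement_probability()] for every
#' participant, action and object; deterministic given the configured seed.
#' Participants are assigned alternating group labels `"g1"`/`"g2"` so that
#' group-stratified analyses can be exercised.
#'
#' @param objects Object data frame (e.g. from [generate_object_set()]).
#' @param actions Action data frame (e.g. [default_actions()]).
#' @param config A [generator_config()].
#' @return A validated [response_tensor()].
#' @export
generate_responses <- function(objects, actions, config) {
  stopifnot(inherits(config, "generator_config"))
  objects <- validate_objects(objects)
  actions <- validate_actions(actions)
  if (!nrow(objects) || !nrow(actions))
    aff_stop("need at least one object and one action", "empty_input")
  p_oa <- endorsement_probability(objects, actions, config) # object x action
  n_p <- config$n_participants
  n_a <- nrow(actions); n_o <- nrow(objects)
  with_seed(config$seed + 1L, {
    # participant-major layout matches array(dim = c(n_p, n_a, n_o))
    p_full <- rep(as.numeric(t(p_oa)), each = n_p)
    if (config$participant_sd > 0) {
      off <- stats::rnorm(n_p, 0, config$participant_sd)
      p_full <- stats::plogis(stats::qlogis(pmin(pmax(p_full, 1e-12),
                                                 1 - 1e-12)) + off)
    }
    draws <- stats::rbinom(length(p_full), 1L, p_full)
    data <- array(draws, dim = c(n_p, n_a, n_o))
    participants <- data.frame(
      participant = sprintf("p%04d", seq_len(n_p)),
      group = rep_len(c("g1", "g2"), n_p),
      stringsAsFactors = FALSE)
    response_tensor(data, participants, actions, objects)
  })
}

#' Simulate a complete judgment study
#'
#' Convenience wrapper: generates the object set, takes the default 14-action
#' list and draws the response tensor.
#'
#' @param config A [generator_config()].
#' @param analysis [analysis_config()] supplying the rank-bin edges.
#' @return A `response_tensor` carrying its objects and actions.
#' @export
simulate_judgments <- function(config = generator_config(),
                               analysis = analysis_config()) {
  objects <- generate_object_set(config, analysis)
  generate_responses(objects, default_actions(), config)
}
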
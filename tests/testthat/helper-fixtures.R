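# Small builders used across test files.

# A tiny fully-specified tensor: 2 participants x 2 actions x 2 objects.
tiny_tensor <- function(values = rep(1L, 8L)) {
  data <- array(values, dim = c(2L, 2L, 2L))
  response_tensor(
    data,
    participants = data.frame(participant = c("p1", "p2")),
    actions = data.frame(action = c("grasp", "sit"),
                         action_class = c("manipulation", "whole_body")),
    objects = data.frame(object = c("cup", "bench"),
                         diagonal_cm = c(20, 200)))
}

# Build an affordance_matrix directly from a probs matrix and object ranks,
# bypassing the tensor stage (for boundary-statistics tests).
make_aff <- function(probs, ranks, diagonal_cm = NULL, n_participants = 100L) {
  n_obj <- nrow(probs)
  if (is.null(diagonal_cm)) diagonal_cm <- 10 * 2^ranks
  actions <- data.frame(
    action = sprintf("a%02d", seq_len(ncol(probs))),
    action_class = rep_len(c("manipulation", "whole_body"), ncol(probs)))
  objects <- data.frame(object = sprintf("o%02d", seq_len(n_obj)),
                        diagonal_cm = diagonal_cm, rank = as.integer(ranks),
                        animate = FALSE)
  structure(list(probs = `dimnames<-`(probs, list(objects$object, actions$action)),
                 objects = objects, actions = actions,
                 n_participants = n_participants),
            class = "affordance_matrix")
}

# A rank_curve data frame from raw r values over contiguous pairs.
make_curve <- function(r, lo_start = 2L, n_actions = 14L) {
  lo <- seq(lo_start, length.out = length(r))
  curve <- data.frame(lo = lo, hi = lo + 1L, r = r,
                      se = sqrt(pmax(1 - r^2, 0) / (n_actions - 2)))
  attr(curve, "n_actions") <- n_actions
  class(curve) <- c("rank_curve", "data.frame")
  curve
}
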
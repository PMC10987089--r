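# Response tensor: participant x action x object binary judgments, plus the
# object/action metadata the rest of the pipeline keys on.

#' Construct a response tensor
#'
#' @param data Binary array, participant x action x object.
#' @param participants Data frame with columns `participant` and optionally
#'   `group`; one row per participant, order matching `dim(data)[1]`.
#' @param actions Data frame with columns `action` and `action_class`
#'   (`"manipulation"` or `"whole_body"`), order matching `dim(data)[2]`.
#' @param objects Data frame with columns `object`, `diagonal_cm`, `rank` and
#'   `animate`, order matching `dim(data)[3]`.
#' @return An object of class `response_tensor`.
#' @export
response_tensor <- function(data, participants, actions, objects) {
  participants <- validate_participants(participants)
  actions <- validate_actions(actions)
  objects <- validate_objects(objects)
  if (!is.array(data) || length(dim(data)) != 3L)
    aff_stop("`data` must be a 3-d array (participant x action x object)",
             "format_error")
  d <- dim(data)
  if (d[1] != nrow(participants) || d[2] != nrow(actions) ||
      d[3] != nrow(objects))
    aff_stop(sprintf(
      "tensor dims %s do not match metadata (%d participants, %d actions, %d objects)",
      paste(d, collapse = "x"), nrow(participants), nrow(actions),
      nrow(objects)), "format_error")
  if (anyNA(data))
    aff_stop("response tensor has missing cells; every (participant, action, object) must be judged",
             "value_error")
  if (!all(data %in% c(0L, 1L)))
    aff_stop("responses must be 0 or 1", "value_error")
  storage.mode(data) <- "integer"
  dimnames(data) <- list(participants$participant, actions$action,
                         objects$object)
  structure(list(data = data, participants = participants, actions = actions,
                 objects = objects), class = "response_tensor")
}

#' @export
print.response_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<response_tensor> %d participants x %d actions x %d objects\n",
              d[1], d[2], d[3]))
  cat(sprintf("  objects: ranks %s; %d animate\n",
              paste(range(x$objects$rank), collapse = "-"),
              sum(x$objects$animate)))
  cat(sprintf("  endorsement rate: %.3f\n", mean(x$data)))
  invisible(x)
}

validate_participants <- function(participants) {
  if (is.character(participants))
    participants <- data.frame(participant = participants)
  if (!is.data.frame(participants) || !"participant" %in% names(participants))
    aff_stop("`participants` needs a `participant` column", "format_error")
  participants$participant <- as.character(participants$participant)
  if (anyDuplicated(participants$participant))
    aff_stop("duplicate participant ids", "value_error")
  if (!"group" %in% names(participants))
    participants[["group"]] <- rep(NA_character_, nrow(participants))
  participants[c("participant", "group")]
}

validate_actions <- function(actions) {
  if (!is.data.frame(actions) ||
      !all(c("action", "action_class") %in% names(actions)))
    aff_stop("`actions` needs columns `action` and `action_class`",
             "format_error")
  actions$action <- as.character(actions$action)
  if (anyDuplicated(actions$action))
    aff_stop("duplicate action names", "value_error")
  bad <- !actions$action_class %in% c("manipulation", "whole_body")
  if (any(bad))
    aff_stop(sprintf("unknown action_class for: %s",
                     paste(actions$action[bad], collapse = ", ")),
             "value_error")
  actions[c("action", "action_class")]
}

validate_objects <- function(objects, config = analysis_config()) {
  if (!is.data.frame(objects) ||
      !all(c("object", "diagonal_cm") %in% names(objects)))
    aff_stop("`objects` needs columns `object` and `diagonal_cm`",
             "format_error")
  objects$object <- as.character(objects$object)
  if (anyDuplicated(objects$object))
    aff_stop("duplicate object names", "value_error")
  if (any(!is.finite(objects$diagonal_cm)) || any(objects$diagonal_cm <= 0))
    aff_stop("`diagonal_cm` must be positive and finite", "domain_error")
  if (!"animate" %in% names(objects)) objects$animate <- FALSE
  objects$animate <- as.logical(objects$animate)
  if (!"rank" %in% names(objects) || all(is.na(objects$rank))) {
    objects$rank <- assign_rank(objects$diagonal_cm, config)
  } else {
    objects$rank <- as.integer(objects$rank)
    if (anyNA(objects$rank))
      aff_stop("`rank` must be all present or all absent", "value_error")
  }
  objects[c("object", "diagonal_cm", "rank", "animate")]
}

#' Read object metadata
#'
#' Expects columns `object`, `diagonal_cm`, optional `rank` and `animate`
#' (0/1). A missing `rank` column is derived from `diagonal_cm` via
#' [assign_rank()].
#'
#' @param path CSV file path.
#' @param config [analysis_config()] used when ranks must be derived.
#' @return Data frame with columns object, diagonal_cm, rank, animate.
#' @export
read_objects <- function(path, config = analysis_config()) {
  validate_objects(utils::read.csv(path, stringsAsFactors = FALSE), config)
}

#' Read action metadata
#'
#' Expects columns `action` and `action_class` where the class is
#' `"manipulation"` (hand-scale actions such as grasping or throwing) or
#' `"whole_body"` (actions such as sitting or standing).
#'
#' @param path CSV file path.
#' @return Data frame with columns action, action_class.
#' @export
read_actions <- function(path) {
  validate_actions(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read binary object-action judgments
#'
#' Reads a long-format judgment table (columns `participant`, `action`,
#' `object`, `response`, optional `group`) against object and action metadata
#' files and assembles a validated [response_tensor()]. Coverage must be
#' complete: every participant judges every object-action combination exactly
#' once.
#'
#' @param path Judgments CSV.
#' @param objects_path,actions_path Metadata CSVs (see [read_objects()],
#'   [read_actions()]).
#' @param config [analysis_config()] used when object ranks must be derived.
#' @return A `response_tensor`.
#' @export
read_responses <- function(path, objects_path, actions_path,
                           config = analysis_config()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "action", "object", "response")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    aff_stop(paste("judgment file lacks column(s):",
                   paste(missing_cols, collapse = ", ")), "format_error")
  objects <- read_objects(objects_path, config)
  actions <- read_actions(actions_path)

  bad <- which(!df$response %in% c(0, 1))
  if (length(bad))
    aff_stop(sprintf("response outside {0,1} at row(s) %s (first value: %s)",
                     paste(utils::head(bad, 5L), collapse = ", "),
                     df$response[bad[1]]), "value_error")
  unknown_obj <- setdiff(unique(df$object), objects$object)
  if (length(unknown_obj))
    aff_stop(paste("unknown object name(s):",
                   paste(unknown_obj, collapse = ", ")), "reference_error")
  unknown_act <- setdiff(unique(df$action), actions$action)
  if (length(unknown_act))
    aff_stop(paste("unknown action name(s):",
                   paste(unknown_act, collapse = ", ")), "reference_error")

  pid <- unique(df$participant)
  pi_ <- match(df$participant, pid)
  ai <- match(df$action, actions$action)
  oi <- match(df$object, objects$object)
  key <- (pi_ - 1L) * nrow(actions) * nrow(objects) +
    (ai - 1L) * nrow(objects) + oi
  if (anyDuplicated(key)) {
    first_dup <- which(duplicated(key))[1]
    aff_stop(sprintf(
      "duplicate judgment: participant %s, action %s, object %s (row %d)",
      df$participant[first_dup], df$action[first_dup], df$object[first_dup],
      first_dup), "value_error")
  }
  n_expected <- length(pid) * nrow(actions) * nrow(objects)
  if (nrow(df) != n_expected)
    aff_stop(sprintf(
      "incomplete coverage: %d judgments, expected %d (%d participants x %d actions x %d objects)",
      nrow(df), n_expected, length(pid), nrow(actions), nrow(objects)),
      "value_error")

  data <- array(NA_integer_, dim = c(length(pid), nrow(actions), nrow(objects)))
  data[cbind(pi_, ai, oi)] <- as.integer(df$response)

  groups <- if ("group" %in% names(df))
    as.character(df$group[match(pid, df$participant)]) else NA_character_
  participants <- data.frame(participant = as.character(pid), group = groups,
                             stringsAsFactors = FALSE)
  tensor <- response_tensor(data, participants, actions, objects)
  message(sprintf("read_responses: %d participants, %d actions, %d objects (%d judgments)",
                  length(pid), nrow(actions), nrow(objects), nrow(df)))
  tensor
}

#' Write a response tensor to CSV files
#'
#' Writes `responses.csv` (long format), `objects.csv` and `actions.csv` into
#' `dir`; the inverse of [read_responses()].
#'
#' @param tensor A `response_tensor`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_responses <- function(tensor, dir) {
  stopifnot(inherits(tensor, "response_tensor"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(tensor$data)
  long <- data.frame(
    participant = rep(tensor$participants$participant, times = d[2] * d[3]),
    group = rep(tensor$participants$group, times = d[2] * d[3]),
    action = rep(rep(tensor$actions$action, each = d[1]), times = d[3]),
    object = rep(tensor$objects$object, each = d[1] * d[2]),
    response = as.integer(tensor$data),
    stringsAsFactors = FALSE)
  paths <- file.path(dir, c("responses.csv", "objects.csv", "actions.csv"))
  utils::write.csv(long, paths[1], row.names = FALSE)
  obj <- tensor$objects
  obj$animate <- as.integer(obj$animate)
  utils::write.csv(obj, paths[2], row.names = FALSE)
  utils::write.csv(tensor$actions, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Drop animate objects
#'
#' Restricts a tensor to inanimate objects (animate and inanimate things are
#' processed differently and their affordances are not comparable, so the
#' analysis runs on inanimate objects only). Participant and action axes are
#' unchanged.
#'
#' @param tensor A `response_tensor`.
#' @return The filtered `response_tensor`.
#' @export
filter_animate <- function(tensor) {
  stopifnot(inherits(tensor, "response_tensor"))
  keep <- !tensor$objects$animate
  if (!any(keep))
    aff_stop("all objects are animate; nothing left to analyze",
             "empty_result")
  if (all(keep)) return(tensor)
  response_tensor(tensor$data[, , keep, drop = FALSE], tensor$participants,
                  tensor$actions, tensor$objects[keep, , drop = FALSE])
}
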
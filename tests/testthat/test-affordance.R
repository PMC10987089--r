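# Affordance vectors, the RSM and its clustering.

test_that("affordance proportions are exact participant fractions", {
  # 7 of 8 participants endorse -> 0.875 exactly
  data <- array(0L, dim = c(8L, 2L, 1L))
  data[1:7, 1, 1] <- 1L
  data[, 2, 1] <- 1L
  tens <- response_tensor(
    data, data.frame(participant = sprintf("p%d", 1:8)),
    data.frame(action = c("grasp", "hold"),
               action_class = c("manipulation", "manipulation")),
    data.frame(object = "hammer", diagonal_cm = 30))
  aff <- affordance_vectors(tens)
  expect_identical(unname(aff$probs[1, ]), c(0.875, 1))

  # 88 of 100 -> 0.88
  data <- array(rep(c(rep(1L, 88), rep(0L, 12)), 2), dim = c(100L, 2L, 1L))
  tens <- response_tensor(
    data, data.frame(participant = sprintf("p%d", 1:100)),
    tens$actions, tens$objects)
  expect_equal(unname(affordance_vectors(tens)$probs[1, 1]), 0.88)
})

test_that("zero-participant input is refused", {
  data <- array(integer(0), dim = c(0L, 2L, 2L))
  tens <- response_tensor(
    data, data.frame(participant = character(0)),
    data.frame(action = c("grasp", "sit"),
               action_class = c("manipulation", "whole_body")),
    data.frame(object = c("cup", "bench"), diagonal_cm = c(20, 200)))
  expect_error(affordance_vectors(tens), class = "affbound_empty_input")
})

test_that("similarity matches the textbook Pearson formula and its identities", {
  set.seed(1203)
  probs <- matrix(runif(6 * 14), nrow = 6)
  aff <- make_aff(probs, ranks = rep(2:4, each = 2L))
  sim <- similarity_matrix(aff)

  # independent covariance/sd oracle
  oracle <- matrix(NA_real_, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    x <- probs[i, ]; y <- probs[j, ]
    oracle[i, j] <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  diag(oracle) <- 1
  expect_equal(unname(sim$r), oracle, tolerance = 1e-12)
  expect_identical(sim$r, t(sim$r))
  expect_true(all(abs(sim$r) <= 1 + 1e-12))

  # identical vectors correlate at 1; a reflection correlates at -1
  probs2 <- rbind(probs[1, ], probs[1, ], 1 - probs[1, ])
  sim2 <- similarity_matrix(make_aff(probs2, ranks = c(2L, 2L, 3L)))
  expect_equal(sim2$r[1, 2], 1, tolerance = 1e-12)
  expect_equal(sim2$r[1, 3], -1, tolerance = 1e-12)
})

test_that("zero-variance affordance vectors are masked, not zeroed", {
  probs <- rbind(runif(5), rep(0.4, 5), runif(5))
  expect_warning(sim <- similarity_matrix(make_aff(probs, ranks = 2:4)),
                 class = "affbound_zero_variance")
  expect_true(all(is.na(sim$r[2, ])))
  expect_true(all(is.na(sim$r[, 2])))
  expect_false(anyNA(sim$r[c(1, 3), c(1, 3)]))
  expect_identical(unname(sim$valid), c(TRUE, FALSE, TRUE))
})

test_that("fewer than two actions cannot support a similarity matrix", {
  probs <- matrix(runif(3), ncol = 1)
  expect_error(similarity_matrix(make_aff(probs, ranks = 2:4)),
               class = "affbound_insufficient_data")
})

test_that("similarity is invariant to participant and object relabeling", {
  cfg <- analysis_config()
  gen <- generator_config(n_participants = 40L, objects_per_rank = 1L,
                          seed = 77)
  tens <- simulate_judgments(gen, cfg)
  sim <- similarity_matrix(affordance_vectors(tens))

  # shuffling participants leaves the matrix untouched
  perm <- sample(dim(tens$data)[1])
  tens_p <- response_tensor(tens$data[perm, , , drop = FALSE],
                            tens$participants[perm, , drop = FALSE],
                            tens$actions, tens$objects)
  expect_equal(similarity_matrix(affordance_vectors(tens_p))$r, sim$r,
               tolerance = 1e-12)

  # permuting objects permutes rows and columns consistently
  operm <- sample(dim(tens$data)[3])
  tens_o <- response_tensor(tens$data[, , operm, drop = FALSE],
                            tens$participants, tens$actions,
                            tens$objects[operm, , drop = FALSE])
  sim_o <- similarity_matrix(affordance_vectors(tens_o))
  expect_equal(unname(sim_o$r), unname(sim$r[operm, operm]),
               tolerance = 1e-12)
})

test_that("clustering recovers planted blocks and handles degenerate cuts", {
  # two perfect blocks of affordance profiles
  v1 <- c(rep(0.9, 7), rep(0.1, 7)); v2 <- rev(v1)
  probs <- rbind(v1, v1 + 0.01, v1 - 0.01, v2, v2 + 0.01, v2 - 0.01)
  aff <- make_aff(probs, ranks = c(2L, 2L, 3L, 5L, 5L, 6L))
  sim <- similarity_matrix(aff)
  cl <- cluster_similarity(sim, k = 2L)
  expect_identical(unname(cl$labels[1:3]), rep(cl$labels[[1]], 3))
  expect_identical(unname(cl$labels[4:6]), rep(cl$labels[[4]], 3))
  expect_false(cl$labels[[1]] == cl$labels[[4]])

  expect_identical(unname(cluster_similarity(sim, k = 1L)$labels),
                   rep(1L, 6L))
  expect_error(cluster_similarity(sim, k = 7L),
               class = "affbound_parameter_error")
})

test_that("clustering drops masked objects with a warning", {
  probs <- rbind(matrix(runif(4 * 6), 4), rep(0.5, 6))
  suppressWarnings(sim <- similarity_matrix(make_aff(probs, ranks = c(2:5, 5L))))
  expect_warning(cl <- cluster_similarity(sim, k = 2L),
                 class = "affbound_masked_dropped")
  expect_identical(length(cl$labels), 4L)
})

test_that("cluster artifacts serialize to JSON and back", {
  probs <- matrix(runif(5 * 8), 5)
  sim <- similarity_matrix(make_aff(probs, ranks = c(2L, 2L, 3L, 3L, 4L)))
  cl <- cluster_similarity(sim, k = 2L)
  path <- withr::local_tempfile(fileext = ".json")
  write_clusters_json(cl, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(back$k, 2L)
  expect_identical(unlist(back$labels), cl$labels)
  expect_equal(back$height, cl$tree$height, tolerance = 1e-12)
})
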
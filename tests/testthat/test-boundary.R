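# Rank curve, trough statistic, permutation test, dependent-correlation
# comparison and the object-level boundary scan.

test_that("rank mean vectors are plain unweighted member averages", {
  v1 <- runif(14); v2 <- runif(14); v3 <- runif(14)
  aff <- make_aff(rbind(v1, v2, v3), ranks = c(2L, 2L, 3L))
  m <- rank_mean_vectors(aff)
  expect_equal(unname(m["2", ]), (v1 + v2) / 2, tolerance = 1e-12)
  expect_equal(unname(m["3", ]), v3, tolerance = 1e-12)

  # two identical members leave the mean unchanged
  aff_id <- make_aff(rbind(v1, v1), ranks = c(2L, 2L))
  expect_equal(unname(rank_mean_vectors(aff_id)["2", ]), v1,
               tolerance = 1e-12)

  # a hole in the analyzed rank range is an error
  aff_gap <- make_aff(rbind(v1, v2), ranks = c(2L, 4L))
  expect_error(rank_mean_vectors(aff_gap), class = "affbound_coverage_error")
})

test_that("the neighboring-rank curve reproduces correlation identities and its SE", {
  v <- runif(14)
  m_same <- rbind(v, v + 0.1, v - 0.2)
  rownames(m_same) <- 2:4
  curve <- neighbor_similarity_curve(m_same)
  expect_equal(curve$r, c(1, 1), tolerance = 1e-12)

  m_alt <- rbind(v, 1 - v, v, 1 - v)
  rownames(m_alt) <- 2:5
  expect_equal(neighbor_similarity_curve(m_alt)$r, rep(-1, 3),
               tolerance = 1e-12)

  # closed-form SE at r = 0 with 14 actions
  curve0 <- make_curve(0)
  expect_equal(curve0$se, sqrt(1 / 12), tolerance = 1e-12)
  se_of <- function(r, n) sqrt((1 - r^2) / (n - 2))
  expect_equal(neighbor_similarity_curve(m_same)$se,
               se_of(c(1, 1), 14), tolerance = 1e-12)

  m_const <- rbind(v, rep(0.3, 14))
  rownames(m_const) <- 2:3
  expect_warning(curve_c <- neighbor_similarity_curve(m_const),
                 class = "affbound_zero_variance")
  expect_true(is.na(curve_c$r[1]))
})

test_that("the trough value is exact bank-minus-trough arithmetic", {
  expect_equal(trough_value(make_curve(c(0.46, 0.02, 0.52)), c(3, 4)), 0.47,
               tolerance = 1e-15)
  expect_equal(trough_value(make_curve(rep(0.6, 5)), c(4, 5)), 0)
  # a bump, not a trough, is negative
  expect_true(trough_value(make_curve(c(0.1, 0.8, 0.1)), c(3, 4)) < 0)
  expect_error(trough_value(make_curve(c(0.4, 0.2, 0.6)), c(2, 3)),
               class = "affbound_no_banks")
  expect_error(trough_value(make_curve(c(0.4, 0.2)), c(5, 6)),
               class = "affbound_value_error")
})

test_that("trough value is linear under scaling and invariant under shifts", {
  set.seed(88)
  for (i in 1:20) {
    r <- runif(6, -0.9, 0.9)
    site <- c(sample(3:6, 1))
    site <- c(site, site + 1)
    t0 <- trough_value(make_curve(r), site)
    expect_equal(trough_value(make_curve(0.37 * r), site), 0.37 * t0,
                 tolerance = 1e-12)
    shifted <- make_curve(r)
    shifted$r <- shifted$r + 0.05
    expect_equal(trough_value(shifted, site), t0, tolerance = 1e-12)
  }
})

test_that("trough detection maximizes the trough value with smaller-rank ties", {
  expect_identical(detect_trough(make_curve(c(0.8, 0.1, 0.7, 0.75, 0.8, 0.78))),
                   c(3L, 4L))
  # two equally deep troughs: the smaller rank wins
  expect_identical(detect_trough(make_curve(c(0.8, 0.1, 0.8, 0.1, 0.8))),
                   c(3L, 4L))
  expect_error(detect_trough(make_curve(c(0.5, 0.1))),
               class = "affbound_insufficient_curve")
  # a fixed site in the config overrides detection
  cfg <- analysis_config(trough_site = c(5, 6))
  expect_identical(detect_trough(make_curve(c(0.8, 0.1, 0.7, 0.75, 0.8)), cfg),
                   c(5L, 6L))
})

test_that("permutation p equals the plain exceedance fraction, smoothed on request", {
  set.seed(31)
  aff <- make_aff(matrix(runif(8 * 6), 8), ranks = rep(2:5, each = 2L))
  cfg <- analysis_config(n_permutations = 200, seed = 12)
  res <- permutation_test_trough(aff, c(3, 4), cfg)
  expect_identical(res$p_value,
                   mean(res$null_values >= res$t_obs))
  cfg_s <- analysis_config(n_permutations = 200, seed = 12,
                           p_smoothing = TRUE)
  res_s <- permutation_test_trough(aff, c(3, 4), cfg_s)
  expect_identical(res_s$p_value,
                   (sum(res$null_values >= res$t_obs) + 1) / 201)
  # identical seeds reproduce the null draws exactly
  res2 <- permutation_test_trough(aff, c(3, 4), cfg)
  expect_identical(res2$null_values, res$null_values)
})

test_that("permutation p matches exhaustive enumeration on a six-object toy", {
  set.seed(99)
  probs <- matrix(runif(6 * 5), nrow = 6)
  labels <- c(1L, 1L, 2L, 2L, 3L, 4L)
  aff <- make_aff(probs, ranks = labels)

  # independent oracle: curve and trough via plain loops over cor()
  oracle_trough <- function(lbl) {
    rk <- sort(unique(lbl))
    means <- t(vapply(rk, function(r) colMeans(probs[lbl == r, , drop = FALSE]),
                      numeric(ncol(probs))))
    rs <- vapply(seq_len(nrow(means) - 1),
                 function(i) cor(means[i, ], means[i + 1, ]), numeric(1))
    (rs[1] + rs[3]) / 2 - rs[2] # site (2,3): pair index 2
  }
  t_obs <- oracle_trough(labels)
  all_perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(all_perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  null_all <- vapply(all_perms(labels), oracle_trough, numeric(1))
  p_exact <- mean(null_all >= t_obs) # all 720 orderings, equally weighted

  cfg <- analysis_config(n_permutations = 4000, seed = 4)
  res <- permutation_test_trough(aff, c(2, 3), cfg)
  expect_equal(res$t_obs, t_obs, tolerance = 1e-12)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 0.01)
})

test_that("permutation p is invariant to object relabeling", {
  set.seed(14)
  probs <- matrix(runif(10 * 8), 10)
  ranks <- rep(2:6, each = 2L)
  cfg <- analysis_config(n_permutations = 300, seed = 21)
  res_a <- permutation_test_trough(make_aff(probs, ranks), c(4, 5), cfg)
  perm <- sample(10)
  res_b <- permutation_test_trough(make_aff(probs[perm, ], ranks[perm]),
                                   c(4, 5), cfg)
  expect_equal(res_a$t_obs, res_b$t_obs, tolerance = 1e-12)
  # same exchangeable null distribution: identical p under the shared seed
  expect_equal(res_a$p_value, res_b$p_value, tolerance = 0.05)
})

test_that("the action-shuffle null is available and degrades the trough", {
  cfg_h <- analysis_config(n_permutations = 300, seed = 3,
                           permute = "actions")
  gen <- generator_config(n_participants = 100L, seed = 4)
  aff <- affordance_vectors(simulate_judgments(gen))
  res <- permutation_test_trough(aff, c(4, 5), cfg_h)
  expect_lt(res$p_value, 0.05)
})

test_that("neighboring-correlation comparison wires Steiger, Zou and the Bayes factor", {
  set.seed(7)
  m <- matrix(runif(4 * 14), nrow = 4, dimnames = list(3:6, NULL))
  cfg <- analysis_config()
  cmp <- compare_neighbor_correlations(m, c(3, 4), c(4, 5), cfg)
  r_a <- cor(m["4", ], m["3", ])
  r_b <- cor(m["4", ], m["5", ])
  r_x <- cor(m["3", ], m["5", ])
  st <- steiger_z(r_a, r_b, r_x, 14)
  expect_equal(cmp$Z, st$Z, tolerance = 1e-12)
  expect_equal(cmp$p_one_tailed, st$p_one_tailed, tolerance = 1e-12)
  expect_equal(cmp$bf10,
               bayes_factor_normal(fisher_z(r_a) - fisher_z(r_b),
                                   se = 1 / sqrt(11)),
               tolerance = 1e-12)
  expect_equal(cmp$zou_ci, zou_ci(r_a, r_b, r_x, 14), tolerance = 1e-12)
  # swapping the two pairs flips the Z sign
  cmp_rev <- compare_neighbor_correlations(m, c(4, 5), c(3, 4), cfg)
  expect_equal(cmp_rev$Z, -cmp$Z, tolerance = 1e-12)
  expect_error(compare_neighbor_correlations(m, c(3, 4), c(5, 6), cfg),
               class = "affbound_value_error")
})

test_that("the pair scan enumerates exactly the admissible pairs", {
  # 2 objects in one rank: a single same-rank record
  aff2 <- make_aff(matrix(runif(2 * 6), 2), ranks = c(4L, 4L))
  scan2 <- pairwise_boundary_scan(aff2, c(3, 6))
  expect_identical(nrow(scan2$pairs), 1L)
  expect_identical(scan2$pairs$composition, "(4,4)")

  # 3 objects per rank over ranks 3..6: closed-form pair count
  set.seed(5)
  aff <- make_aff(matrix(runif(12 * 8), 12), ranks = rep(3:6, each = 3L))
  scan <- pairwise_boundary_scan(aff, c(3, 6))
  m <- 3
  expect_identical(nrow(scan$pairs), as.integer(4 * choose(m, 2) + 3 * m^2))
  expect_identical(scan$compositions$composition,
                   c("(3,3)", "(3,4)", "(4,4)", "(4,5)", "(5,5)", "(5,6)",
                     "(6,6)"))
  # brute-force count of admissible pairs
  cnt <- 0L
  rk <- aff$objects$rank
  for (i in 1:11) for (j in (i + 1):12)
    if (abs(rk[i] - rk[j]) <= 1) cnt <- cnt + 1L
  expect_identical(nrow(scan$pairs), cnt)
  expect_false(anyDuplicated(paste(scan$pairs$object_a,
                                   scan$pairs$object_b)) > 0)
})

test_that("the scan localizes a planted boundary at the lowest-similarity composition", {
  set.seed(10)
  v <- c(rep(0.9, 7), rep(0.1, 7))
  small <- ranks <- rep(3:6, each = 3L)
  probs <- t(vapply(seq_along(ranks), function(i) {
    base <- if (ranks[i] <= 4) v else 1 - v
    pmin(pmax(base + rnorm(14, 0, 0.03), 0), 1)
  }, numeric(14)))
  sizes <- c(runif(3, 40, 75), runif(3, 80, 140), runif(3, 150, 280),
             runif(3, 300, 550))
  aff <- make_aff(probs, ranks = ranks, diagonal_cm = sizes)
  scan <- pairwise_boundary_scan(aff, c(3, 6))
  expect_identical(scan$boundary_composition, c(4L, 5L))
  sizes45 <- scan$pairs$mean_size_cm[scan$pairs$composition == "(4,5)"]
  expect_equal(scan$boundary_estimate_cm, mean(sizes45), tolerance = 1e-12)
  expect_true(scan$boundary_ci[1] <= scan$boundary_estimate_cm)
  expect_true(scan$boundary_ci[2] >= scan$boundary_estimate_cm)
})

test_that("singleton compositions keep their record but mask the CI", {
  aff <- make_aff(matrix(runif(3 * 6), 3), ranks = c(3L, 3L, 4L),
                  diagonal_cm = c(30, 40, 80))
  scan <- pairwise_boundary_scan(aff, c(3, 4))
  comp33 <- scan$compositions[scan$compositions$composition == "(3,3)", ]
  expect_identical(comp33$n_pairs, 1L)
  expect_true(is.na(comp33$r_ci_lo))
})
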
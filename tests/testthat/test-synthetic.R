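# Synthetic study generator: design invariants, reproducibility and
# parameter recovery.

test_that("the default design reproduces the study's shape", {
  design <- experiment_design(master_seed = 8)
  records <- generate_judgments(design)
  # 200 participants, one judgment per coin each
  expect_equal(nrow(records), 200 * 20)
  expect_equal(length(unique(records$participant_id)), 200)
  expect_true(all(table(records$participant_id) == 20))
  # between subjects: no participant appears in two contexts
  expect_true(all(rowSums(table(records$participant_id, records$context) > 0) == 1))
  # 10 female then 10 male coins
  expect_equal(unique(records$gender_group[records$coin_id <= 10]), "F")
  expect_equal(unique(records$gender_group[records$coin_id > 10]), "M")
})

test_that("counterbalancing splits presentation side evenly in every cell", {
  for (n_pp in c(6, 7)) {
    design <- experiment_design(n_participants_per_context = n_pp,
                                master_seed = 3)
    records <- if (n_pp %% 2 == 1) {
      expect_message(generate_judgments(design), "floor/ceil")
      suppressMessages(generate_judgments(design))
    } else {
      generate_judgments(design)
    }
    swaps <- tapply(records$position_swapped,
                    list(records$coin_id, records$context), sum)
    expect_true(all(abs(swaps - (n_pp - swaps)) <= 1))
  }
})

test_that("generation is deterministic given the master seed", {
  d1 <- experiment_design(n_participants_per_context = 12, master_seed = 77)
  expect_identical(generate_judgments(d1), generate_judgments(d1))
  d2 <- experiment_design(n_participants_per_context = 12, master_seed = 78)
  expect_false(identical(generate_judgments(d1), generate_judgments(d2)))
  # generation does not disturb the caller's RNG stream
  set.seed(5); before <- runif(1)
  set.seed(5); invisible(generate_judgments(d1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("degenerate true marginals generate saturated tallies", {
  tm <- data.frame(coin_id = 1:2, p0 = 1, p1 = 1, p2 = 1, p3 = 1)
  design <- experiment_design(n_participants_per_context = 8,
                              true_marginals = tm, master_seed = 1)
  counts <- tally_judgments(generate_judgments(design))
  expect_true(all(counts$k == counts$n))
})

test_that("tallied frequencies are unbiased for the design marginals", {
  # coin 1, context C0 at p0 = 0.56: mean of k/n over many seeds
  tm <- face_study_marginals()[1, ]
  freqs <- vapply(1:200, function(s) {
    d <- experiment_design(n_participants_per_context = 50,
                           true_marginals = tm, master_seed = s)
    counts <- tally_judgments(generate_judgments(d))
    counts$k[counts$context == "C0"] / 50
  }, numeric(1))
  # standard error of the mean over 200 seeds is ~0.005
  expect_lt(abs(mean(freqs) - 0.56), 0.016)
})

test_that("marginals and disturbance are recovered at large n", {
  tm <- face_study_marginals()[c(1, 4), ]
  design <- experiment_design(n_participants_per_context = 20000,
                              true_marginals = tm, master_seed = 9)
  rec <- recover_marginals(generate_judgments(design))
  truth <- as.matrix(tm[, paste0("p", 0:3)])
  est <- as.matrix(rec[, paste0("p", 0:3)])
  expect_true(all(abs(est - truth) < 0.015))
  expect_equal(disturbance_delta(est[2, ]), 1.32, tolerance = 0.03)
})

test_that("parameter recovery stays within binomial error bars across seeds", {
  tm <- face_study_marginals()[c(3, 13), ]
  n <- 40
  hits <- 0L
  trials <- 0L
  for (s in 1:60) {
    d <- experiment_design(n_participants_per_context = n,
                           true_marginals = tm, master_seed = 1000 + s)
    rec <- recover_marginals(generate_judgments(d))
    est <- as.matrix(rec[, paste0("p", 0:3)])
    truth <- as.matrix(tm[, paste0("p", 0:3)])
    inside <- abs(est - truth) <= 3 * sqrt(truth * (1 - truth) / n) + 1e-12
    hits <- hits + sum(inside)
    trials <- trials + length(inside)
  }
  expect_gte(hits / trials, 0.99)
})

test_that("generate -> tally -> analyse closes end to end", {
  design <- experiment_design(n_participants_per_context = 30, master_seed = 6)
  fit <- cbd_analysis(generate_judgments(design), n_boot = 200, seed = 2)
  expect_s3_class(fit, "cbd_analysis")
  expect_equal(nrow(fit$results), 20)
  expect_equal(fit$results$cbd, 1 - fit$results$delta)
  expect_false(is.null(fit$accuracy))
})
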
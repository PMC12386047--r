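# Core cyclic-system statistics: disturbance, correlations, s_odd, the
# contextuality criterion and Boole's condition.

test_that("disturbance matches hand-verified study rows and basic identities", {
  expect_equal(disturbance_delta(c(0.56, 0.46, 0.42, 0.46)), 0.28)
  expect_equal(disturbance_delta(c(0.32, 0.78, 0.36, 0.12)), 1.32)
  expect_equal(disturbance_delta(c(0.16, 0.34, 0.26, 0.18)), 0.36)
  # equal marginals are nondisturbing regardless of level
  for (c0 in c(0, 0.17, 0.5, 1)) {
    expect_equal(disturbance_delta(rep(c0, 4)), 0)
  }
  # matrix input vectorises over rows
  m <- rbind(c(0.56, 0.46, 0.42, 0.46), c(0.3, 0.3, 0.3, 0.3))
  expect_equal(disturbance_delta(m), c(0.28, 0))
  expect_error(disturbance_delta(c(0.2, 1.4, 0.3, 0.1)), "\\[0, 1\\]")
})

test_that("disturbance is bounded by [0, 4] and invariant under cycle reflection", {
  set.seed(101)
  for (i in 1:500) {
    p <- runif(4)
    d <- disturbance_delta(p)
    expect_gte(d, 0)
    expect_lte(d, 4)
    expect_equal(disturbance_delta(rev(p)), d)
  }
})

test_that("context correlation codes forced choice as perfect anticorrelation", {
  for (a in c(0, 0.25, 0.5, 1)) {
    expect_equal(context_correlation(c(0, a, 1 - a, 0)), -1)
  }
  expect_equal(context_correlation(c(0.5, 0, 0, 0.5)), 1)
  expect_equal(context_correlation(rep(0.25, 4)), 0)
  expect_error(context_correlation(c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})

test_that("study-convention s_odd gives 3 for four perfect anticorrelations", {
  expect_equal(s_odd(rep(-1, 4)), 3)
  expect_equal(s_odd(rep(-1, 4), "study"), 3)
  # and matches its subset-enumeration oracle on random inputs
  set.seed(7)
  for (n in 3:7) {
    for (i in 1:40) {
      cc <- runif(n, -1, 1)
      expect_equal(s_odd(cc, "study"), s_odd_subsets(cc))
    }
  }
})

test_that("canonical s_odd equals exhaustive odd-sign enumeration", {
  expect_equal(s_odd(rep(-1, 4), "canonical"), s_odd_enumerate(rep(-1, 4)))
  expect_equal(s_odd(rep(-1, 4), "canonical"), 2)
  expect_equal(s_odd(c(1, 1, 1, -1), "canonical"), s_odd_enumerate(c(1, 1, 1, -1)))
  expect_equal(s_odd(c(1, 1, 1, -1), "canonical"), 4)
  set.seed(11)
  for (n in 3:8) {
    for (i in 1:40) {
      cc <- runif(n, -1, 1)
      expect_equal(s_odd(cc, "canonical"), s_odd_enumerate(cc))
    }
    # zeros and ties exercise the sign-flip edge case
    cc <- sample(c(-1, 0, 0.5, 1), n, replace = TRUE)
    expect_equal(s_odd(cc, "canonical"), s_odd_enumerate(cc))
  }
  expect_error(s_odd(c(-1, 1)), "at least 3")
})

test_that("the contextuality criterion reproduces the ideal-coin evaluation", {
  expect_identical(cbd_statistic(3, 4, 0), 1)
  expect_equal(cbd_statistic(3, 4, 0.28), 0.72)
  expect_equal(cbd_statistic(3, 4, 1.32), -0.32)
  expect_error(cbd_statistic(3, 4, -0.1), "nonnegative")
  expect_error(cbd_statistic(3, 2, 0), ">= 3")
})

test_that("forced-choice identity: study-convention statistic is 1 - disturbance", {
  set.seed(23)
  s <- s_odd(rep(-1, 4), "study")
  for (i in 1:2000) {
    p <- runif(4)
    d <- disturbance_delta(p)
    expect_identical(cbd_statistic(s, 4, d), 1 - d)
  }
})

test_that("Boole condition flags the ideal coin and accepts explicit joints", {
  b <- boole_lhs(rep(0.5, 4), rep(0, 6))
  expect_equal(b$value, 2)
  expect_false(b$satisfied)
  b0 <- boole_lhs(rep(0, 4), rep(0, 6))
  expect_equal(b0$value, 0)
  expect_true(b0$satisfied)
  # four independent fair coins admit a joint distribution
  bi <- boole_lhs(rep(0.5, 4), rep(0.25, 6))
  expect_equal(bi$value, 0.5)
  expect_true(bi$satisfied)
  # named pairwise input is reordered by name
  names_q <- c(p23 = 0.25, p01 = 0.25, p02 = 0.25, p03 = 0.25, p12 = 0.25,
               p13 = 0.25)
  expect_equal(boole_lhs(rep(0.5, 4), names_q)$value, 0.5)
  expect_error(boole_lhs(rep(0.5, 4), rep(0, 5)), "6 pairwise")
})

test_that("any behavior with an explicit joint distribution satisfies Boole", {
  set.seed(31)
  for (i in 1:200) {
    jt <- random_joint4()
    inp <- joint4_boole_inputs(jt)
    expect_true(boole_lhs(inp$single, inp$pairwise)$satisfied)
  }
})

test_that("marginals are recovered from context tallies in context order", {
  counts <- data.frame(coin_id = 1, context = paste0("C", 0:3), n = 50,
                       k = c(28, 23, 21, 23))
  m <- marginals_from_counts(counts)
  expect_equal(unlist(m[, paste0("p", 0:3)], use.names = FALSE),
               c(0.56, 0.46, 0.42, 0.46))
  saturated <- data.frame(coin_id = 2, context = 0:3, n = 50, k = 50)
  expect_equal(unlist(marginals_from_counts(saturated)[, paste0("p", 0:3)],
                      use.names = FALSE), rep(1, 4))
  coin13 <- data.frame(coin_id = 13, context = paste0("C", 0:3), n = 50,
                       k = c(8, 17, 13, 9))
  expect_equal(unlist(marginals_from_counts(coin13)[, paste0("p", 0:3)],
                      use.names = FALSE), c(0.16, 0.34, 0.26, 0.18))
  expect_error(marginals_from_counts(counts[-2, ]), "missing context")
  dup <- rbind(counts, counts[1, ])
  expect_error(marginals_from_counts(dup), "duplicate")
  zero_n <- transform(counts, n = c(50, 0, 50, 50))
  expect_error(marginals_from_counts(zero_n), "n > 0")
})

test_that("designated outcomes and context pairs follow the 4-cycle design", {
  expect_identical(designated_outcome("C0"), 0L)
  expect_identical(designated_outcome("C1"), 2L)
  expect_identical(designated_outcome("C2"), 2L)
  expect_identical(designated_outcome("C3"), 0L)
  expect_identical(designated_outcome(0:3), c(0L, 2L, 2L, 0L))
  expect_equal(context_facets("C3"), c(3L, 0L))
  expect_equal(context_facets(1), c(1L, 2L))
  expect_error(designated_outcome("C4"), "invalid context")
  expect_error(designated_outcome(5), "0..3")
  roles <- facet_roles()
  expect_equal(roles$role, c("fake", "real", "fake", "real"))
  expect_equal(roles$label, c("F0", "R1", "F2", "R3"))
})
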
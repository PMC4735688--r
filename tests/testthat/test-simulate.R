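test_that("pair coalescence times have the exponential mean", {
  # n=2, lambda=1: per-rep total length = 2 * T2, E[T2] = 1
  or <- oracle_pattern_length(one_pop(2), reps = 2e4, seed = 1)
  tl <- attr(or, "total_length")
  expect_lt(abs(tl[["mean"]] / 2 - 1) / (tl[["se"]] / 2), 3)
  # and the singleton-subtending length is 2.0
  expect_lt(abs(or$mean[or$A == 1] - 2) / or$se[or$A == 1], 3)
})

test_that("the 1/i law holds in the simulator (n = 10)", {
  or <- oracle_pattern_length(one_pop(10), reps = 5e4, seed = 2)
  r <- or$mean[or$A == 1] / or$mean[or$A == 2]
  se_r <- r * sqrt((or$se[or$A == 1] / or$mean[or$A == 1])^2 +
                   (or$se[or$A == 2] / or$mean[or$A == 2])^2)
  expect_lt(abs(r - 2) / se_r, 3)
})

test_that("simulation is reproducible from (config, seed) and seeds differ", {
  m <- two_pop()
  h1 <- sim_histogram(m, 1e4, seed = 9)
  h2 <- sim_histogram(m, 1e4, seed = 9)
  expect_identical(h1$counts, h2$counts)
  expect_identical(h1$monomorphic, h2$monomorphic)
  h3 <- sim_histogram(m, 1e4, seed = 10)
  expect_false(identical(h1$counts, h3$counts) &&
                 h1$monomorphic == h3$monomorphic)
  g1 <- sim_genealogy(m, seed = 5)
  g2 <- sim_genealogy(m, seed = 5)
  expect_equal(g1$branches, g2$branches)
})

test_that("theta -> 0 gives an all-monomorphic histogram", {
  m <- two_pop()
  h <- sim_histogram(m, 1000, scale = unit_scale(mu = 1e-20), seed = 1)
  expect_equal(h$monomorphic, 1000)
  expect_equal(nrow(h$counts), 0)
})

test_that("per-class frequencies match engine probabilities on a 2-pop model", {
  m <- two_pop()
  u <- unit_scale()
  n_sites <- 4e5
  h <- sim_histogram(m, n_sites, seed = 12)
  pats <- raretree:::tracked_patterns(c(4, 4), 4)
  p <- pattern_probability(m, pats, u)$prob
  obs <- rep(0, nrow(pats))
  idx <- match(raretree:::config_keys(raretree:::pattern_matrix(h), 5),
               raretree:::config_keys(pats, 5))
  obs[idx] <- h$counts$sites
  z <- (obs - n_sites * p) / sqrt(n_sites * p)
  expect_lt(max(abs(z)), 4)
  p0 <- 1 - u$theta * total_tree_length(m)
  z0 <- (h$monomorphic - n_sites * p0) / sqrt(n_sites * p0 * (1 - p0))
  # the simulator's Poisson multi-hits inflate the monomorphic class by
  # O(theta^2); allow that analytic excess on top of 4 sigma
  excess <- n_sites * u$theta^2 * 60 # ~ theta^2 E[L^2] / 2 upper bound
  expect_lt(abs(h$monomorphic - n_sites * p0) - excess,
            4 * sqrt(n_sites * p0 * (1 - p0)))
})

test_that("label exchangeability: permuting identical populations permutes patterns", {
  mk <- function(nm) demography(
    tibble::tibble(name = nm, lambda = c(1, 1), sample_size = c(4, 4)),
    tibble::tibble(time = 0.002, into = nm[1], from = nm[2],
                   lambda_after = 1))
  h1 <- sim_histogram(mk(c("X", "Y")), 5e4, seed = 33)
  h2 <- sim_histogram(mk(c("X", "Y")), 5e4, seed = 33)
  expect_identical(h1$counts, h2$counts) # determinism baseline
  # seed-matched: swapping which branch is 'into' only relabels columns
  pp1 <- pattern_probability(mk(c("X", "Y")), rbind(c(1, 2)))$prob
  pp2 <- pattern_probability(mk(c("X", "Y")), rbind(c(2, 1)))$prob
  expect_equal(pp1, pp2, tolerance = 1e-9)
})

test_that("ancient samples never coalesce before their age", {
  m <- demography(
    tibble::tibble(name = c("A", "B"), lambda = c(1, 1), sample_size = c(4, 3),
                   sample_age = c(0, 0.05)),
    tibble::tibble(time = 0.2, into = "A", from = "B", lambda_after = 1))
  for (s in 1:20) {
    g <- sim_genealogy(m, seed = 400 + s)
    br <- g$branches
    # every branch holding a B lineage is born at or after B's age, and
    # B tips are born exactly at the age
    b_branches <- br[br$B > 0, , drop = FALSE]
    expect_true(all(b_branches$birth >= 0.05 - 1e-12))
    tip_b <- b_branches[b_branches$A == 0 & b_branches$B == 1, ]
    expect_true(all(abs(tip_b$birth - 0.05) < 1e-12))
  }
})

test_that("the sharing fixture is seed-reproducible with sane structure", {
  fx1 <- sim_sharing_fixture(alpha = 0.4, n_sites = 2e4, seed = 77)
  fx2 <- sim_sharing_fixture(alpha = 0.4, n_sites = 2e4, seed = 77)
  expect_identical(fx1$panel, fx2$panel)
  expect_identical(fx1$reads, fx2$reads)
  expect_true(all(fx1$panel$total >= 1 & fx1$panel$total <= 9))
  expect_setequal(unique(fx1$truth$alpha), c(0, 0.4, 1))
})
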
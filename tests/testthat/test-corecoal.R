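# Closed-form oracles for the likelihood engine. Expected values are
# exact coalescent results:
#  - E[total length of branches subtending exactly i of n leaves] = 2/i
#    (lambda = 1), independent of n;
#  - with two lineages, P(no coalescence by tau) = exp(-tau/lambda);
#  - a lone derived lineage facing b non-derived ones accumulates
#    expected time 2 lambda / (b + 1) before being absorbed;
#  - E[total tree length] = 2 lambda H_{n-1}.

test_that("single-branch evolution matches the pure-death closed form", {
  # two derived lineages, no non-derived: P(still 2 at tau) = exp(-tau)
  sys <- list(list(amax = 2L, bmax = 0L, lambda = 1, active = TRUE,
                   dist = raretree:::delta_dist(2L, 0L, 2L, 0L)))
  pv <- matrix(0L, 1, 1)
  for (tau in c(0.3, 1, 2)) {
    st <- raretree:::cpp_branch_epoch(sys, pv, 0, 0, tau, 0.02, 1)
    expect_equal(st$dist[[1]][3, 1], exp(-tau), tolerance = 1e-6)
    expect_equal(st$dist[[1]][2, 1], 1 - exp(-tau), tolerance = 1e-6)
  }
  # dt = 0 leaves the state unchanged
  st0 <- raretree:::cpp_branch_epoch(sys, pv, 0, 0, 0, 0.1, 1)
  expect_equal(st0$dist[[1]], sys[[1]]$dist)
})

test_that("a lone derived lineage accumulates the exponential mean", {
  # a=1 vs b=1, lambda=1: acc(infinity) = E[absorption time] = 1
  m <- one_pop(n = 2)
  expect_equal(pattern_probability(m, 1)$acc, 2, tolerance = 1e-8) # C(2,1)*1
  # and the closed-form table gives h(1,b) = 2 lambda / (b+1)
  hm <- raretree:::cpp_h_table(1, 9, 1.5)
  expect_equal(hm[2, 2:10], 2 * 1.5 / (2:10), tolerance = 1e-12)
})

test_that("single-population pattern probabilities follow the 1/i law", {
  m <- one_pop(n = 10)
  pp <- pattern_probability(m, matrix(1:4, ncol = 1), unit_scale())
  expect_equal(pp$acc, 2 / (1:4), tolerance = 1e-6)
  expect_equal(pp$prob[1] / pp$prob[2], 2, tolerance = 0.01)
  # theta scaling: prob = theta * acc
  expect_equal(pp$prob, unit_scale()$theta * pp$acc)
})

test_that("degenerate patterns are rejected", {
  m <- one_pop(n = 4)
  expect_error(pattern_probability(m, 0), "monomorphic")
  expect_error(pattern_probability(m, 5), "larger than sample size")
  expect_error(pattern_probability(m, 4), "every sampled lineage")
})

test_that("joining two populations at (almost) zero equals the merged population", {
  mj <- demography(
    tibble::tibble(name = c("A", "B"), lambda = c(1, 1), sample_size = c(3, 3)),
    tibble::tibble(time = 1e-9, into = "A", from = "B", lambda_after = 1))
  mm <- one_pop(n = 6)
  for (tot in 1:4) {
    merged <- pattern_probability(mm, tot)$prob
    split <- expand.grid(a = 0:tot, b = 0:tot)
    split <- split[split$a + split$b == tot & split$a <= 3 & split$b <= 3, ]
    pj <- pattern_probability(mj, as.matrix(split))$prob
    expect_equal(sum(pj), merged, tolerance = 1e-5)
  }
})

test_that("total tree length matches harmonic closed forms and scaling", {
  expect_equal(total_tree_length(one_pop(2)), 2, tolerance = 1e-4)
  expect_equal(total_tree_length(one_pop(3)), 3, tolerance = 1e-4)
  expect_equal(total_tree_length(one_pop(10)), 2 * sum(1 / (1:9)),
               tolerance = 1e-4)
  # doubling lambda doubles the length
  expect_equal(total_tree_length(one_pop(7, lambda = 2)),
               2 * total_tree_length(one_pop(7, lambda = 1)),
               tolerance = 1e-8)
})

test_that("histogram log-likelihood assembles the multinomial classes", {
  m <- two_pop()
  u <- unit_scale()
  h <- rare_histogram(c("A", "B"), c(4, 4),
                      tibble::tibble(A = 1L, B = 0L, sites = 5),
                      monomorphic = 1000, overflow = 3)
  p_x <- pattern_probability(m, matrix(c(1, 0), 1), u)$prob
  pats <- raretree:::tracked_patterns(c(4, 4), 4)
  p_all <- pattern_probability(m, pats, u)$prob
  p0 <- 1 - u$theta * total_tree_length(m)
  p_over <- 1 - p0 - sum(p_all)
  manual <- 5 * log(p_x) + 1000 * log(p0) + 3 * log(p_over)
  expect_equal(histogram_loglik(m, h, u), manual, tolerance = 1e-10)

  # permutation symmetry: an exchangeable model is invariant under
  # permuting populations together with the histogram patterns
  ms <- demography(
    tibble::tibble(name = c("A", "B"), lambda = c(1, 1), sample_size = c(4, 4)),
    tibble::tibble(time = 0.002, into = "A", from = "B", lambda_after = 1))
  h1 <- rare_histogram(c("A", "B"), c(4, 4),
                       tibble::tibble(A = c(1L, 2L), B = c(0L, 1L),
                                      sites = c(7, 9)), monomorphic = 500)
  h2 <- rare_histogram(c("A", "B"), c(4, 4),
                       tibble::tibble(A = c(0L, 1L), B = c(1L, 2L),
                                      sites = c(7, 9)), monomorphic = 500)
  expect_equal(histogram_loglik(ms, h1, u), histogram_loglik(ms, h2, u),
               tolerance = 1e-8)

  # adding an all-zero-count pattern class changes nothing
  h3 <- rare_histogram(c("A", "B"), c(4, 4),
                       tibble::tibble(A = c(1L, 3L), B = c(0L, 1L),
                                      sites = c(5, 0)),
                       monomorphic = 1000, overflow = 3)
  expect_equal(histogram_loglik(m, h3, u), histogram_loglik(m, h, u))
})

test_that("probabilities are conserved, non-negative and grid-stable", {
  m <- three_pop()
  pats <- raretree:::tracked_patterns(c(4, 4, 2), 4)
  pp <- pattern_probability(m, pats)
  expect_true(all(pp$prob >= 0))
  # total polymorphic probability below theta * total tree length
  expect_lt(sum(pp$prob), unit_scale()$theta * total_tree_length(m))
  # halving the step-size controls changes nothing beyond 0.1%
  fine <- pattern_probability(m, pats, grid = time_grid(delta = 5e-5,
                                                        substep = 0.05))
  expect_lt(max(abs(fine$prob / pp$prob - 1)), 0.001)
})

test_that("freezing an ancient branch delays its participation", {
  # age 0 is identical to an unfrozen branch; a positive age lengthens
  # the query's private-singleton branch by exactly the age
  m0 <- demography(
    tibble::tibble(name = c("A", "Q"), lambda = c(1, 1), sample_size = c(4, 2),
                   sample_age = c(0, 0)),
    tibble::tibble(time = 0.01, into = "A", from = "Q", lambda_after = 1))
  m1 <- demography(
    tibble::tibble(name = c("A", "Q"), lambda = c(1, 1), sample_size = c(4, 2),
                   sample_age = c(0, 0.004)),
    tibble::tibble(time = 0.01, into = "A", from = "Q", lambda_after = 1))
  pats <- rbind(c(0, 1), c(1, 1), c(2, 1))
  p0 <- pattern_probability(m0, pats)
  p1 <- pattern_probability(m1, pats)
  # freezing removes the query lineage's pre-age segment, so the
  # query-private singleton loses expected subtending length (shared
  # patterns can gain: the frozen lineage is also protected from
  # absorption, so no blanket monotonicity is asserted)
  expect_lt(p1$acc[1], p0$acc[1])
  # and the frozen computation agrees with the Monte-Carlo oracle
  or <- oracle_pattern_length(m1, reps = 5e4, seed = 31, patterns = pats)
  z <- (p1$acc - or$mean) / or$se
  expect_lt(max(abs(z)), 4)
})
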
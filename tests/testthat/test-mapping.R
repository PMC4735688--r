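# mapping fixtures: a 3-population reference tree plus a held-out query
# diploid simulated from inside a tip (or as an outgroup), encoded as
# carrier calls (2 haploids, derived count 0/1)

map_tree <- function() {
  demography(
    tibble::tibble(name = c("A", "B", "C"), lambda = c(1, 0.8, 1.2),
                   sample_size = c(10L, 10L, 10L)),
    tibble::tibble(time = c(0.003, 0.006), into = c("A", "A"),
                   from = c("B", "C"), lambda_after = c(1.5, 1)))
}

# simulate a histogram including a query branch attached at `where`
sim_query_hist <- function(attach, t_attach, n_sites, seed, age = 0) {
  m <- map_tree()
  mq <- demography(
    dplyr::bind_rows(m$branches,
                     tibble::tibble(name = "Q", lambda = 1, sample_size = 2L,
                                    sample_age = age)),
    dplyr::bind_rows(m$joins,
                     tibble::tibble(time = t_attach, into = attach,
                                    from = "Q", lambda_after = NA_real_)))
  sim_histogram(mq, n_sites, seed = seed)
}

test_that("merge scans cover every branch with a well-formed surface", {
  m <- map_tree()
  h <- sim_query_hist("B", 1e-5, 1e5, seed = 601)
  sc <- merge_scan(m, h, "Q", points_per_segment = 6)
  e <- sc$entries
  # every branch of the tree is scanned, sorted by decreasing likelihood
  expect_setequal(unique(e$branch), c("A", "B", "C"))
  expect_true(all(diff(e$loglik) <= 1e-12))
  expect_equal(max(e$rel_lik), 1)
  expect_true(all(e$rel_lik > 0 & e$rel_lik <= 1))
  # merge times stay within each branch's lifetime
  expect_true(all(e$time[e$branch == "B"] <= 0.003))
  expect_true(all(e$time[e$branch == "C"] <= 0.006))
  # the conditional flag changes the surface (different composite)
  su <- merge_scan(m, h, "Q", points_per_segment = 6, conditional = FALSE)
  expect_false(isTRUE(all.equal(sc$entries$loglik, su$entries$loglik)))
  # placement power itself is exercised by the acceptance suite
})

test_that("an age-0 scan equals the unfrozen scan exactly; age excludes younger points", {
  m <- map_tree()
  h <- sim_query_hist("B", 1e-5, 1e5, seed = 88)
  s0 <- merge_scan(m, h, "Q", query_age = 0, points_per_segment = 5)
  s0b <- merge_scan(m, h, "Q", points_per_segment = 5)
  expect_identical(s0$entries, s0b$entries) # same code path, same surface
  s1 <- merge_scan(m, h, "Q", query_age = 0.002, points_per_segment = 5)
  expect_true(all(s1$entries$time >= 0.002))
  # at shared merge times the frozen surface is a valid likelihood
  expect_true(all(is.finite(s1$entries$loglik)))
  expect_error(merge_scan(m, h, "Q", query_age = 0.02), "query age exceeds")
})

test_that("query-private singletons do not change the scan", {
  m <- map_tree()
  h <- sim_query_hist("B", 1e-5, 1e5, seed = 92)
  s1 <- merge_scan(m, h, "Q", points_per_segment = 5)
  # inject private query singletons; restrict_to_shared must drop them
  hq <- encode_query_het(h, "Q")
  extra <- rare_histogram(hq$pops, hq$n,
                          tibble::tibble(A = 0L, B = 0L, C = 0L, Q = 1L,
                                         sites = 5000), hq$max_m)
  h2 <- merge_histograms(hq, extra)
  s2 <- merge_scan(m, h2, "Q", points_per_segment = 5)
  expect_equal(s1$entries$loglik, s2$entries$loglik, tolerance = 1e-12)
})

test_that("best_merge breaks ties toward the older time and flags them", {
  s <- structure(list(entries = tibble::tibble(
    branch = c("A", "A", "B"), time = c(0.001, 0.004, 0.002),
    time_years = c(1, 4, 2), loglik = c(-10, -10, -12),
    rel_lik = c(1, 1, exp(-2))), query = "Q", query_age = 0,
    max_loglik = -10), class = "merge_scan")
  b <- best_merge(s)
  expect_equal(b$time, 0.004)
  expect_true(b$tie)
  expect_error(best_merge(structure(list(entries = tibble::tibble()),
                                    class = "merge_scan")), "empty")
})

test_that("surface export is exp(logL - max) with 1 at the maximum", {
  s <- structure(list(entries = tibble::tibble(
    branch = c("A", "B"), time = c(0.001, 0.002), time_years = c(1, 2),
    loglik = c(-5, -7), rel_lik = c(1, exp(-2)))), class = "merge_scan")
  se <- surface_export(s)
  expect_equal(se$rel_lik, c(1, exp(-2)))
  # all-equal surface -> all 1
  s$entries$loglik <- c(-3, -3)
  expect_equal(surface_export(s)$rel_lik, c(1, 1))
})
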
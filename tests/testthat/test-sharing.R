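toy_panel <- function() {
  tibble::tibble(chrom = "1", pos = c(10L, 20L, 30L, 40L),
                 ref = "A", alt = "C",
                 NED = c(2L, 0L, 3L, 1L), IBS = c(0L, 1L, 2L, 0L),
                 total = c(2L, 1L, 5L, 1L))
}

test_that("carrier calling applies the minimum-support rule monotonically", {
  panel <- toy_panel()
  reads <- tibble::tibble(chrom = "1", pos = c(10L, 20L, 30L, 99L),
                          rare_reads = c(2L, 1L, 5L, 4L),
                          total_reads = c(7L, 9L, 6L, 8L))
  calls <- call_carriers(reads, panel, min_support = 2)
  expect_equal(calls$pos, c(10L, 30L)) # >=2 reads; site 99 off-panel
  expect_equal(attr(calls, "ignored"), 1)
  # raising the threshold never adds carriers
  for (ms in 3:5) {
    higher <- call_carriers(reads, panel, min_support = ms)
    expect_true(all(higher$pos %in% calls$pos))
  }
  expect_equal(nrow(call_carriers(reads[0, ], panel)), 0)
  expect_error(call_carriers(dplyr::mutate(reads, rare_reads = -1), panel),
               "non-negative")
})

test_that("sharing tables accumulate per-population counts by stratum", {
  panel <- toy_panel()
  calls <- tibble::tibble(sample = "S", chrom = "1", pos = c(10L, 30L))
  t <- build_sharing(calls, panel)
  # site 10: NED=2 total=2 -> NED stratum 2 += 2; site 30: total 5
  expect_equal(t$shared[t$population == "NED" & t$stratum == 2], 2)
  expect_equal(t$shared[t$population == "NED" & t$stratum == 5], 3)
  expect_equal(t$shared[t$population == "IBS" & t$stratum == 5], 2)
  expect_equal(t$shared[t$population == "IBS" & t$stratum == 2], 0)
  # no calls -> all-zero table; additivity of two sites in one stratum
  t0 <- build_sharing(calls[0, ], panel)
  expect_true(all(t0$shared == 0))
  calls2 <- tibble::tibble(sample = "S", chrom = "1", pos = c(10L, 40L))
  t2 <- build_sharing(calls2, panel)
  expect_equal(t2$shared[t2$population == "NED" & t2$stratum %in% c(1, 2)],
               c(1, 2)[order(c(1, 2))])
})

test_that("ratio curves use sqrt-count error propagation and omit zero denominators", {
  t <- tibble::tibble(sample = "S",
                      population = rep(c("NED", "IBS"), each = 3),
                      stratum = rep(1:3, 2),
                      shared = c(100, 50, 7, 50, 50, 0))
  rc <- ratio_curve(t, "NED", "IBS")
  expect_equal(rc$ratio[rc$stratum == 1], 2)
  expect_equal(rc$se[rc$stratum == 1], 2 * sqrt(1 / 100 + 1 / 50))
  expect_equal(rc$ratio[rc$stratum == 2], 1)
  expect_false(3 %in% rc$stratum) # zero denominator stratum omitted
  expect_equal(attr(rc, "omitted")$stratum, 3)
})

test_that("the projection and ancestry fraction follow their defining arithmetic", {
  t <- tibble::tibble(sample = "S",
                      population = rep(c("NED", "IBS"), each = 6),
                      stratum = rep(1:6, 2),
                      shared = c(100, 100, 50, 30, 20, 999,
                                 40, 30, 20, 5, 5, 999))
  pr <- sharing_projection(t, "NED", "IBS", max_stratum = 5)
  expect_equal(pr$num_shared, 300)
  expect_equal(pr$den_shared, 100)
  expect_equal(pr$f, 0.75)
  expect_equal(pr$se, sqrt(0.75 * 0.25 / 400))
  # symmetric counts give f = 1/2; zero total errors
  ts <- dplyr::mutate(t, shared = 10)
  expect_equal(sharing_projection(ts, "NED", "IBS")$f, 0.5)
  tz <- dplyr::mutate(t, shared = 0)
  expect_error(sharing_projection(tz, "NED", "IBS"), "zero total")

  expect_equal(ancestry_fraction(0.5, 0.4, 0.6)$fraction, 50)
  expect_equal(ancestry_fraction(0.4, 0.4, 0.6)$fraction, 0)
  expect_equal(ancestry_fraction(0.6, 0.4, 0.6)$fraction, 100)
  # no clipping outside the anchors
  expect_equal(ancestry_fraction(0.7, 0.4, 0.6)$fraction, 150)
  expect_error(ancestry_fraction(0.5, 0.4, 0.4), "anchor")
})

test_that("group summaries average non-excluded samples with min-max spread", {
  fr <- tibble::tibble(sample = c("a", "b", "c"), fraction = c(30, 40, 50))
  g <- group_summary(fr)
  expect_equal(g$mean, 40)
  expect_equal(c(g$spread_lo, g$spread_hi), c(30, 50))
  g2 <- group_summary(fr, exclude = "c")
  expect_equal(g2$mean, 35)
  expect_equal(g2$n_used, 2)
  expect_error(group_summary(fr, exclude = c("a", "b", "c")), "no samples")
})

test_that("haploid resampling matches its binomial expectation", {
  set.seed(2)
  panel <- tibble::tibble(chrom = "1", pos = 1:400, ref = "A", alt = "C",
                          NED = rbinom(400, 9, 0.3), IBS = 0L)
  panel$total <- panel$NED + panel$IBS
  panel <- panel[panel$total >= 1, ]
  f <- panel$NED / 100
  draws <- vapply(1:30, function(s)
    nrow(resample_haploid(panel, "NED", 100, seed = s)), numeric(1))
  mu <- sum(f); sdev <- sqrt(sum(f * (1 - f)))
  expect_lt(abs(mean(draws) - mu), 3 * sdev / sqrt(30))
  # boundary cases
  p0 <- dplyr::mutate(panel, NED = 0L)
  expect_equal(nrow(resample_haploid(p0, "NED", 100, seed = 1)), 0)
  p1 <- dplyr::mutate(panel, NED = 100L)
  expect_equal(nrow(resample_haploid(p1, "NED", 100, seed = 1)), nrow(panel))
})

test_that("pseudo-individuals from distinct panels order the projection correctly", {
  # sources with rare alleles young relative to the split, so the two
  # panels have distinct sharing structure
  fx <- sim_sharing_fixture(alpha = 0, split_time = 0.03,
                            lambda = c(0.3, 0.3), n_panel = 30,
                            n_sites = 3e5, seed = 123)
  pan <- fx$panel
  cn <- resample_haploid(pan, "A", fx$panel_sizes[["A"]], seed = 5,
                         sample_id = "pseudoA")
  cs <- resample_haploid(pan, "B", fx$panel_sizes[["B"]], seed = 6,
                         sample_id = "pseudoB")
  tab <- build_sharing(dplyr::bind_rows(cn, cs), pan)
  pr <- sharing_projection(tab, "A", "B")
  expect_gt(pr$f[pr$sample == "pseudoA"], pr$f[pr$sample == "pseudoB"])
})
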
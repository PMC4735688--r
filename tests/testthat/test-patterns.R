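test_that("histogram construction enforces class conservation", {
  h <- toy_histogram()
  expect_equal(h$monomorphic + h$overflow + sum(h$counts$sites), h$total_sites)
  expect_error(rare_histogram("A", 4, tibble::tibble(A = 5L, sites = 1)),
               "m_k <= n_k")
  expect_error(rare_histogram("A", 4, tibble::tibble(A = 0L, sites = 1)),
               "1 <= sum")
})

test_that("histogram text format round-trips and validates arity", {
  h <- toy_histogram()
  h2 <- read_histogram(text = paste(write_histogram(h), collapse = "\n"))
  expect_equal(h2$counts, h$counts)
  expect_equal(h2$n, h$n)
  expect_equal(h2$monomorphic, h$monomorphic)
  expect_equal(h2$overflow, h$overflow)
  expect_equal(h2$total_sites, h$total_sites)

  # empty histogram (all monomorphic) round-trips
  he <- rare_histogram(c("A", "B"), c(2, 2), NULL, monomorphic = 100)
  he2 <- read_histogram(text = paste(write_histogram(he), collapse = "\n"))
  expect_equal(he2$total_sites, 100)
  expect_equal(nrow(he2$counts), 0)

  # five-population histogram round-trips with deterministic ordering
  set.seed(1)
  pats <- raretree:::tracked_patterns(rep(4, 5), 4)
  keep <- sample(nrow(pats), 20)
  counts <- tibble::as_tibble(as.data.frame(pats[keep, ])) |>
    stats::setNames(paste0("P", 1:5))
  counts$sites <- sample(1:100, 20)
  h5 <- rare_histogram(paste0("P", 1:5), rep(4, 5), counts, 4,
                       monomorphic = 1e5)
  h5b <- read_histogram(text = paste(write_histogram(h5), collapse = "\n"))
  expect_equal(h5b$counts, h5$counts)

  # arity mismatch with the N= header is an error
  bad <- "N=4,4\nMAX_M=4\nTOTAL_SITES=100\nMONOMORPHIC 99\n1,0,0 1"
  expect_error(read_histogram(text = bad), "arity")
  expect_error(read_histogram(text = "N=2\nMAX_M=4\nTOTAL_SITES=5\nbogus line"),
               "malformed")
})

test_that("merging histograms is associative with the empty identity", {
  h <- toy_histogram()
  he <- rare_histogram(c("A", "B"), c(4, 4), NULL, 4)
  expect_equal(merge_histograms(h, he)$counts, h$counts)
  h2 <- rare_histogram(c("A", "B"), c(4, 4),
                       tibble::tibble(A = 1L, B = 0L, sites = 3),
                       monomorphic = 10)
  m1 <- merge_histograms(merge_histograms(h, h2), h)
  m2 <- merge_histograms(h, merge_histograms(h2, h))
  expect_equal(m1$counts, m2$counts)
  expect_equal(m1$total_sites, 2 * h$total_sites + h2$total_sites)
  # mismatched configurations refuse to merge
  hx <- rare_histogram(c("B", "A"), c(4, 4), NULL, 4)
  expect_error(merge_histograms(h, hx), "mismatch")
})

test_that("restriction to shared patterns drops query-private variants", {
  h <- rare_histogram(
    c("Q", "A", "B"), c(2, 4, 4),
    tibble::tibble(Q = c(1L, 1L, 0L), A = c(0L, 2L, 1L), B = c(0L, 0L, 2L),
                   sites = c(100, 20, 30)),
    monomorphic = 500, overflow = 7)
  r <- restrict_to_shared(h, "Q")
  expect_true(r$restricted)
  # (1,0,0) is query-private -> dropped; (0,1,2) lacks the query -> dropped
  expect_equal(nrow(r$counts), 1)
  expect_equal(r$counts$sites, 20)
  expect_equal(r$monomorphic + r$overflow, 0)
  expect_equal(r$total_sites, 20)
  expect_error(restrict_to_shared(h, "Z"), "unknown population")
  # degenerate: nothing shared -> empty histogram, no error
  h0 <- rare_histogram(c("Q", "A"), c(2, 4),
                       tibble::tibble(Q = 1L, A = 0L, sites = 5),
                       monomorphic = 10)
  expect_equal(nrow(restrict_to_shared(h0, "Q")$counts), 0)
})

test_that("query recoding collapses counts to heterozygous carrier calls", {
  h <- rare_histogram(
    c("Q", "A"), c(2, 4),
    tibble::tibble(Q = c(2L, 1L, 0L), A = c(1L, 1L, 1L), sites = c(5, 7, 9)),
    monomorphic = 100)
  r <- encode_query_het(h, "Q")
  expect_equal(sort(r$counts$sites), sort(c(12, 9))) # (1,1): 5+7, (0,1): 9
  expect_equal(r$total_sites, h$total_sites)
})

test_that("VCF + mask + population table produce the expected histogram", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"AA\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3", "s4"), collapse = "\t"),
    "1\t5\t.\tA\tC\t.\tPASS\tAA=A\tGT\t0|1\t0|0\t0|0\t0|0",   # (1,0)
    "1\t7\t.\tG\tT\t.\tPASS\tAA=T\tGT\t0|0\t0|0\t0|0\t0|0",   # AA=ALT: flips to (2,2)... all ref = all derived? see below
    "1\t9\t.\tA\tC\t.\tPASS\tAA=A\tGT\t1|1\t1|0\t1|0\t1|1",   # 6 copies > max_m -> overflow
    "1\t12\t.\tA\tAT\t.\tPASS\tAA=A\tGT\t0|1\t0|0\t0|0\t0|0", # indel: skipped
    "1\t40\t.\tA\tC\t.\tPASS\tAA=A\tGT\t0|1\t1|0\t0|0\t0|0",  # (1,1)
    "1\t100\t.\tA\tC\t.\tPASS\tAA=A\tGT\t0|1\t0|0\t0|0\t0|0"  # outside mask
  ), vcf)
  mask <- file.path(dir, "mask.bed")
  writeLines(c("1\t0\t50"), mask) # 0-based half-open: positions 1..50
  pops <- tibble::tibble(sample = c("s1", "s2", "s3", "s4"),
                         population = c("X", "X", "Y", "Y"))

  h <- vcf_to_histogram(vcf, pops, mask, max_m = 4)
  expect_equal(h$pops, c("X", "Y"))
  expect_equal(unname(h$n), c(4L, 4L))
  # REF polarization: site 5 -> (1,0); site 40 -> (2,0); site 7 monomorphic
  cm <- as.data.frame(h$counts)
  expect_equal(cm$sites[cm$X == 1 & cm$Y == 0], 1)
  expect_equal(cm$sites[cm$X == 2 & cm$Y == 0], 1)
  expect_equal(h$overflow, 1)
  # indel skipped and removed from the denominator: 50 - 1 skipped
  expect_equal(h$total_sites, 49)
  expect_equal(h$monomorphic, 49 - 2 - 1)

  # ancestral-tag polarization flips site 7 to all-derived (overflow)
  h2 <- vcf_to_histogram(vcf, pops, mask, max_m = 4,
                         polarize = "ancestral-tag")
  expect_equal(h2$overflow, 2)

  # sample missing from the VCF is an error
  expect_error(vcf_to_histogram(vcf, tibble::tibble(sample = "nope",
                                                    population = "X"), mask),
               "missing from VCF")
})

test_that("class conservation holds after every operation", {
  set.seed(4)
  m <- two_pop()
  h <- sim_histogram(m, 5e4, seed = 8)
  ops <- list(
    function(x) merge_histograms(x, x),
    function(x) read_histogram(text = paste(write_histogram(x), collapse = "\n")),
    function(x) encode_query_het(x, "A"))
  for (op in ops) {
    h2 <- op(h)
    expect_equal(h2$monomorphic + h2$overflow + sum(h2$counts$sites),
                 h2$total_sites)
  }
  r <- restrict_to_shared(h, "A")
  expect_equal(r$monomorphic + r$overflow + sum(r$counts$sites),
               r$total_sites)
})

test_that("the simulator's VCF export reproduces its histogram through the VCF path", {
  m <- three_pop(n = c(4, 4, 2))
  fx <- sim_vcf_fixture(m, 2000, seed = 21, dir = withr::local_tempdir())
  h <- vcf_to_histogram(fx$vcf, fx$pops_table, fx$mask, max_m = 4)
  expect_equal(h$pops, fx$histogram$pops)
  expect_equal(h$counts, fx$histogram$counts)
  expect_equal(h$monomorphic, fx$histogram$monomorphic)
  expect_equal(h$overflow, fx$histogram$overflow)
  expect_equal(h$total_sites, fx$histogram$total_sites)
})
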
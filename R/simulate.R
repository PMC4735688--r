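# Structured-coalescent Monte-Carlo simulation: synthetic data generator
# for the inference/mapping/sharing pipelines and brute-force oracle for
# the likelihood engine. Sites are unlinked (one independent genealogy
# per site); rare-allele pattern frequencies depend only on marginal
# genealogies, so linkage is irrelevant for everything computed here.

model_to_cargs <- function(m) {
  v <- validate_demography(m)
  if (length(v)) stop("invalid model: ", paste(v, collapse = "; "))
  b <- m$branches
  j <- m$joins[order(m$joins$time), , drop = FALSE]
  jm <- cbind(time = j$time,
              into = match(j$into, b$name) - 1L,
              from = match(j$from, b$name) - 1L,
              lambda_after = ifelse(is.na(j$lambda_after), NA_real_,
                                    j$lambda_after))
  if (!nrow(j)) jm <- matrix(numeric(), 0, 4)
  list(n = as.integer(b$sample_size), age = as.numeric(b$sample_age),
       lambda = as.numeric(b$lambda), joins = jm)
}

#' Simulate one genealogy under a demographic model
#'
#' Exact stochastic simulation of the structured coalescent: within each
#' branch of scaled size lambda every lineage pair coalesces at rate
#' `1/lambda` per scaled time unit; lineages move at joins; ancient
#' samples enter at their `sample_age`.
#'
#' @param m A `demography`.
#' @param seed Optional integer seed.
#' @return A list with `branches` (tibble: per-branch subtended leaf
#'   counts per population, `length`, and a `leaves` list-column of
#'   0-based haploid leaf ids in population-major order),
#'   `total_length` and `tmrca` (scaled times).
#' @export
sim_genealogy <- function(m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- model_to_cargs(m)
  g <- cpp_simulate(a$n, a$age, a$lambda, a$joins, 1L, 0, 4L, 0L, integer())
  br <- tibble::as_tibble(as.data.frame(g$desc)) |>
    stats::setNames(m$branches$name)
  br$length <- as.numeric(g$length)
  br$birth <- as.numeric(g$birth)
  br$leaves <- g$leaves
  list(branches = br, total_length = g$total_length, tmrca = g$tmrca)
}

#' Monte-Carlo oracle for expected pattern-subtending lengths
#'
#' For each tracked pattern, estimates by brute force the expected total
#' length of genealogy branches whose subtended leaf counts match the
#' pattern exactly (summed over qualifying branches per genealogy).
#' `pattern_probability()$acc` approximates exactly this quantity, and
#' the per-site probability is `theta` times it.
#'
#' @param m A `demography`.
#' @param reps Number of independent genealogies.
#' @param seed Optional integer seed.
#' @param max_m Maximum tracked total derived count. Default 4.
#' @param patterns Optional pattern matrix (rows; columns = model
#'   branches). Default: every tracked pattern.
#' @return Tibble with pattern columns, `mean`, `se` (Monte-Carlo
#'   standard error from replicate variance). The attribute
#'   `total_length` holds the mean and s.e. of the total genealogy
#'   length.
#' @export
oracle_pattern_length <- function(m, reps = 1e5, seed = NULL, max_m = 4,
                                  patterns = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- model_to_cargs(m)
  if (is.null(patterns)) patterns <- tracked_patterns(a$n, max_m)
  patterns <- matrix(as.integer(patterns), ncol = length(a$n))
  keys <- config_keys(patterns, max_m + 1L)
  r <- cpp_simulate(a$n, a$age, a$lambda, a$joins, as.integer(reps), 0,
                    3L, as.integer(max_m), as.integer(keys))
  mean_ <- r$sumL / r$reps
  var_ <- pmax(r$sumL2 / r$reps - mean_^2, 0)
  out <- tibble::as_tibble(as.data.frame(patterns)) |>
    stats::setNames(m$branches$name)
  out$mean <- mean_
  out$se <- sqrt(var_ / r$reps)
  tl_mean <- r$total_sumL / r$reps
  tl_var <- max(r$total_sumL2 / r$reps - tl_mean^2, 0)
  attr(out, "total_length") <- c(mean = tl_mean, se = sqrt(tl_var / r$reps))
  out
}

#' Simulate a site-pattern histogram of unlinked sites
#'
#' Drops `Poisson(theta * L)` mutations on each site's genealogy
#' (`theta = 2 n_ref mu`); a mutated site's pattern is the subtended
#' leaf-count vector of a length-proportionally chosen branch (sites
#' with several mutations keep the first, matching the biallelic view).
#'
#' @param m A `demography`.
#' @param n_sites Number of unlinked sites (callable genome length).
#' @param scale A [unit_scale()].
#' @param seed Optional integer seed.
#' @param max_m Maximum tracked total derived count. Default 4.
#' @return A `rare_histogram` over the populations with samples.
#' @export
sim_histogram <- function(m, n_sites, scale = unit_scale(), seed = NULL,
                          max_m = 4) {
  if (!is.null(seed)) set.seed(seed)
  a <- model_to_cargs(m)
  r <- cpp_simulate(a$n, a$age, a$lambda, a$joins, as.integer(n_sites),
                    scale$theta, 0L, as.integer(max_m), integer())
  K <- length(a$n)
  base <- max_m + 1
  pm <- matrix(0L, length(r$key), K)
  key <- r$key
  for (k in seq_len(K)) {
    pm[, k] <- as.integer(key %% base)
    key <- key %/% base
  }
  keep <- a$n > 0
  pops <- m$branches$name[keep]
  counts <- tibble::as_tibble(as.data.frame(pm[, keep, drop = FALSE])) |>
    stats::setNames(pops)
  counts$sites <- r$count
  rare_histogram(pops, a$n[keep], counts, max_m,
                 monomorphic = r$monomorphic, overflow = r$overflow)
}

#' Simulate unlinked sites with carrier identities and export VCF
#'
#' Like [sim_histogram()] but tracks which haploid leaves carry the
#' derived allele at each polymorphic site, writes a VCF of diploid
#' genotypes (consecutive haploid pairs), a BED mappability mask
#' covering the whole simulated region, and a population-assignment
#' table. Used for pipeline-consistency tests: running
#' [vcf_to_histogram()] on the export reproduces the returned histogram
#' exactly.
#'
#' @inheritParams sim_histogram
#' @param dir Output directory for `sites.vcf`, `mask.bed`, `pops.tsv`.
#' @return List: `histogram`, file paths `vcf`, `mask`, `pops`, and the
#'   population table.
#' @export
sim_vcf_fixture <- function(m, n_sites, scale = unit_scale(), seed = NULL,
                            max_m = 4, dir = tempfile("simvcf")) {
  if (!is.null(seed)) set.seed(seed)
  a <- model_to_cargs(m)
  if (any(a$n %% 2 != 0))
    stop("VCF export needs even haploid sample sizes (diploid individuals)")
  if (sum(a$n) > 64) stop("VCF export supports at most 64 haploids")
  r <- cpp_simulate(a$n, a$age, a$lambda, a$joins, as.integer(n_sites),
                    scale$theta, 2L, as.integer(max_m), integer())
  K <- length(a$n)
  keep <- which(a$n > 0)
  pops <- m$branches$name[keep]

  # histogram from the same per-site data
  desc <- r$desc
  tot <- rowSums(desc)
  tracked <- tot <= max_m
  counts <- tibble::as_tibble(as.data.frame(desc[tracked, keep, drop = FALSE])) |>
    stats::setNames(pops) |>
    dplyr::mutate(.sites = 1) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(pops))) |>
    dplyr::summarise(sites = sum(.data$.sites), .groups = "drop")
  h <- rare_histogram(pops, a$n[keep], counts, max_m,
                      monomorphic = n_sites - length(r$pos),
                      overflow = sum(!tracked))

  # diploid individuals: consecutive haploid pairs, population-major
  ids <- unlist(lapply(seq_along(keep), function(i)
    paste0(pops[i], "_", seq_len(a$n[keep[i]] / 2))))
  pop_of <- rep(pops, a$n[keep] / 2)
  hap_pop_offsets <- c(0, cumsum(a$n))[seq_len(K)]

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, "sites.vcf")
  mask <- file.path(dir, "mask.bed")
  popf <- file.path(dir, "pops.tsv")

  gts <- vapply(seq_along(r$pos), function(i) {
    carriers <- r$leaves[[i]]
    al <- integer(sum(a$n))
    al[carriers + 1L] <- 1L
    paste(paste0(al[c(TRUE, FALSE)], "|", al[c(FALSE, TRUE)]),
          collapse = "\t")
  }, "")
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=1>",
              "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  body <- sprintf("1\t%d\t.\tA\tC\t.\tPASS\tAA=A\tGT\t%s", r$pos, gts)
  writeLines(c(header, body), vcf)
  writeLines(sprintf("1\t0\t%d", n_sites), mask)
  pops_tbl <- tibble::tibble(sample = ids, population = pop_of)
  utils::write.table(pops_tbl, popf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(histogram = h, vcf = vcf, mask = mask, pops = popf,
       pops_table = pops_tbl)
}

#' Random valid demographic model (for property tests)
#'
#' Draws a random rooted topology by repeatedly joining two surviving
#' branches at increasing times, with log-normal branch sizes and
#' occasional ancient sampling ages.
#'
#' @param n_pops Number of populations.
#' @param seed Optional integer seed.
#' @param p_ancient Probability a tip carries an ancient sample age.
#' @return A `demography`.
#' @export
sim_random_model <- function(n_pops, seed = NULL, p_ancient = 0.2) {
  if (!is.null(seed)) set.seed(seed)
  nm <- paste0("P", seq_len(n_pops))
  br <- tibble::tibble(name = nm,
                       lambda = exp(stats::rnorm(n_pops, 0, 0.5)),
                       sample_size = sample(2:10, n_pops, replace = TRUE),
                       sample_age = 0)
  alive <- nm
  t <- 0
  joins <- list()
  while (length(alive) > 1) {
    t <- t + stats::rexp(1, rate = 1 / 0.003)
    pair <- sample(alive, 2)
    joins[[length(joins) + 1]] <- tibble::tibble(
      time = t, into = pair[1], from = pair[2],
      lambda_after = exp(stats::rnorm(1, 0, 0.5)))
    alive <- setdiff(alive, pair[2])
  }
  joins <- dplyr::bind_rows(joins)
  first_join <- vapply(nm, function(b)
    min(joins$time[joins$into == b | joins$from == b]), 0)
  anc <- stats::runif(n_pops) < p_ancient
  br$sample_age[anc] <- stats::runif(sum(anc), 0, 0.9) * first_join[anc]
  demography(br, joins)
}

#' Synthetic fixture for the rare-allele-sharing ancestry pipeline
#'
#' Simulates two source populations (panels) that split `split_time`
#' ago, plus diploid query individuals: `n_pure` pure descendants of
#' each source (the anchor groups) and one admixed individual whose
#' ancestry at each unlinked site is drawn from source A with
#' probability `alpha`. Panel sites are all variants with total panel
#' allele count in `1..max_count`; per-site read counts for every query
#' are drawn at the stated coverage with a symmetric per-read error.
#'
#' @param alpha Admixture fraction(s) (source A ancestry). A vector
#'   produces one admixed query per value (`admixed1`, `admixed2`, ...)
#'   from the same simulated sites, with independent per-site ancestry
#'   draws.
#' @param split_time Scaled split time of the two sources. Default 0.006
#'   (about 7,000 years at default scaling).
#' @param lambda Scaled sizes of the two source branches (ancestral size
#'   1). Default c(1, 1): the symmetric design keeps total sharing equal
#'   between sources in expectation, so the sharing projection is linear
#'   in `alpha`.
#' @param n_panel Haploid panel size per source. Default 100.
#' @param n_pure Pure anchor individuals per source. Default 3.
#' @param coverage Mean sequencing depth of the queries. Default 6.
#' @param error Per-read symmetric error rate. Default 0.001.
#' @param n_sites Number of unlinked sites. Default 2e5.
#' @param max_count Maximum panel allele count retained. Default 9.
#' @param scale A [unit_scale()].
#' @param seed Optional integer seed.
#' @param dir Optional directory; if given, writes `panel.tsv`,
#'   `reads_<sample>.tsv` and `truth.tsv`.
#' @return List: `panel` tibble (chrom, pos, ref, alt, A, B, total),
#'   `reads` (long tibble: sample, chrom, pos, rare_reads, total_reads),
#'   `truth` tibble, `panel_sizes`, and file paths when `dir` is given.
#' @export
sim_sharing_fixture <- function(alpha, split_time = 0.006, lambda = c(1, 1),
                                n_panel = 100, n_pure = 3, coverage = 6,
                                error = 0.001, n_sites = 2e5,
                                max_count = 9, scale = unit_scale(),
                                seed = NULL, dir = NULL) {
  stopifnot(all(alpha >= 0), all(alpha <= 1))
  if (!is.null(seed)) set.seed(seed)
  qa <- paste0("pureA", seq_len(n_pure))
  qb <- paste0("pureB", seq_len(n_pure))
  qnames <- c(qa, qb, "admixA", "admixB")
  qside <- c(rep("A", n_pure), rep("B", n_pure), "A", "B")
  eps <- 1e-6 * seq_along(qnames)
  br <- tibble::tibble(
    name = c("A", "B", qnames),
    lambda = c(lambda, rep(1, length(qnames))),
    sample_size = c(n_panel, n_panel, rep(2, length(qnames))),
    sample_age = 0)
  joins <- dplyr::bind_rows(
    tibble::tibble(time = eps, into = qside, from = qnames,
                   lambda_after = NA_real_),
    tibble::tibble(time = split_time, into = "A", from = "B",
                   lambda_after = 1))
  m <- demography(br, joins)
  a <- model_to_cargs(m)
  r <- cpp_simulate(a$n, a$age, a$lambda, a$joins, as.integer(n_sites),
                    scale$theta, 1L, 0L, integer())
  desc <- r$desc
  colnames(desc) <- m$branches$name
  total <- desc[, "A"] + desc[, "B"]
  keep <- total >= 1 & total <= max_count
  desc <- desc[keep, , drop = FALSE]
  panel <- tibble::tibble(chrom = "1", pos = r$pos[keep], ref = "A",
                          alt = "C", A = desc[, "A"], B = desc[, "B"],
                          total = total[keep])
  ns <- nrow(panel)

  # admixed genotypes: per-site ancestry draws between the two dedicated
  # admixture-source individuals
  adm <- vapply(alpha, function(al) {
    anc_a <- stats::runif(ns) < al
    ifelse(anc_a, desc[, "admixA"], desc[, "admixB"])
  }, numeric(ns))
  colnames(adm) <- if (length(alpha) == 1) "admixed" else
    paste0("admixed", seq_along(alpha))
  geno <- cbind(desc[, c(qa, qb), drop = FALSE], adm)

  reads <- purrr::map_dfr(colnames(geno), function(s) {
    g <- geno[, s]
    tot <- stats::rpois(ns, coverage)
    p <- ifelse(g == 0, error, ifelse(g == 1, 0.5, 1 - error))
    tibble::tibble(sample = s, chrom = "1", pos = panel$pos,
                   rare_reads = stats::rbinom(ns, tot, p), total_reads = tot)
  })
  truth <- tibble::tibble(sample = colnames(geno),
                          alpha = c(rep(1, n_pure), rep(0, n_pure), alpha))
  out <- list(panel = panel, reads = reads, truth = truth,
              panel_sizes = c(A = n_panel, B = n_panel), model = m)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(panel, file.path(dir, "panel.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(reads, file.path(dir, "reads.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$files <- file.path(dir, c("panel.tsv", "reads.tsv", "truth.tsv"))
  }
  out
}

#' Simulate unlinked sites as a per-site pattern table
#'
#' Returns the polymorphic sites themselves (derived-allele counts per
#' population) instead of an aggregated histogram, so that several
#' analyses -- e.g. per-query histograms for mapping several held-out
#' genomes simulated jointly -- can be derived from one simulation
#' without rerunning the coalescent.
#'
#' @inheritParams sim_histogram
#' @return List: `sites` (tibble: `pos` plus one count column per
#'   branch), `pops`, `n` (haploid sizes), `n_sites`.
#' @export
sim_sites <- function(m, n_sites, scale = unit_scale(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- model_to_cargs(m)
  r <- cpp_simulate(a$n, a$age, a$lambda, a$joins, as.integer(n_sites),
                    scale$theta, 1L, 0L, integer())
  sites <- tibble::as_tibble(as.data.frame(r$desc)) |>
    stats::setNames(m$branches$name)
  sites <- dplyr::bind_cols(tibble::tibble(pos = r$pos), sites)
  list(sites = sites, pops = m$branches$name,
       n = stats::setNames(a$n, m$branches$name), n_sites = n_sites)
}

#' Project a site table onto a subset of populations as a histogram
#'
#' @param ss A site table from [sim_sites()].
#' @param pops Population subset (order defines the histogram order).
#' @param max_m Maximum tracked total derived count. Default 4.
#' @return A `rare_histogram` over `pops`.
#' @export
sites_to_histogram <- function(ss, pops, max_m = 4) {
  stopifnot(all(pops %in% ss$pops))
  cm <- as.matrix(ss$sites[, pops, drop = FALSE])
  tot <- rowSums(cm)
  tracked <- tot >= 1 & tot <= max_m
  counts <- tibble::as_tibble(as.data.frame(cm[tracked, , drop = FALSE])) |>
    stats::setNames(pops) |>
    dplyr::mutate(.s = 1) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(pops))) |>
    dplyr::summarise(sites = sum(.data$.s), .groups = "drop")
  rare_histogram(pops, ss$n[pops], counts, max_m,
                 monomorphic = ss$n_sites - sum(tot >= 1),
                 overflow = sum(tot > max_m))
}
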
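# Rare-allele sharing ancestry analysis: carrier calling from read
# counts against a rare-variant reference panel, sharing tables
# stratified by panel allele count, Dutch/Spanish-style ratio curves
# with error propagation, the NED/(NED+IBS) projection, and ancestry
# fractions between two anchor group means.

panel_pops <- function(panel) {
  setdiff(colnames(panel), c("chrom", "pos", "ref", "alt", "total"))
}

#' Call rare-allele carriers from per-site read counts
#'
#' A sample carries the rare (panel) allele at a site if at least
#' `min_support` reads support it; carriers are always treated as
#' heterozygous downstream. Sites in the read table but not in the
#' panel are ignored and tallied.
#'
#' @param reads Tibble with columns `chrom`, `pos`, `rare_reads`,
#'   `total_reads`, and optionally `sample` (several samples at once).
#' @param panel Panel tibble: `chrom`, `pos`, `ref`, `alt`, one allele
#'   count column per reference population, `total` (1..9).
#' @param min_support Minimum reads supporting the rare allele.
#'   Default 2.
#' @return Tibble of carrier calls (`sample`, `chrom`, `pos`), with
#'   attribute `"ignored"` counting off-panel records.
#' @export
call_carriers <- function(reads, panel, min_support = 2) {
  reads <- tibble::as_tibble(reads)
  if (!"sample" %in% names(reads)) reads$sample <- "query"
  if (any(reads$rare_reads < 0 | reads$total_reads < 0))
    stop("read counts must be non-negative")
  key <- paste(panel$chrom, panel$pos)
  in_panel <- paste(reads$chrom, reads$pos) %in% key
  calls <- reads[in_panel & reads$rare_reads >= min_support,
                 c("sample", "chrom", "pos")]
  attr(calls, "ignored") <- sum(!in_panel)
  calls
}

#' Accumulate allele sharing between samples and reference populations
#'
#' For each called carrier site, the site's per-population panel allele
#' counts are added into the (population, total panel count) stratum:
#' a heterozygous carrier shares one allele with each panel copy.
#'
#' @param calls Carrier calls from [call_carriers()].
#' @param panel The panel tibble.
#' @return Sharing table: tibble (`sample`, `population`, `stratum`,
#'   `shared`), complete over strata 1..max(total).
#' @export
build_sharing <- function(calls, panel) {
  pops <- panel_pops(panel)
  long <- panel |>
    tidyr::pivot_longer(dplyr::all_of(pops), names_to = "population",
                        values_to = "count")
  joined <- dplyr::inner_join(tibble::as_tibble(calls), long,
                              by = c("chrom", "pos"),
                              relationship = "many-to-many")
  out <- joined |>
    dplyr::group_by(.data$sample, .data$population, stratum = .data$total) |>
    dplyr::summarise(shared = sum(.data$count), .groups = "drop")
  # complete missing strata with zeros
  full <- tidyr::expand_grid(sample = unique(calls$sample),
                             population = pops,
                             stratum = seq_len(max(panel$total)))
  dplyr::left_join(full, out, by = c("sample", "population", "stratum")) |>
    dplyr::mutate(shared = dplyr::coalesce(.data$shared, 0))
}

#' Sharing ratio between two reference populations, per stratum
#'
#' Ratio of sharing counts (numerator over denominator population) for
#' each allele-count stratum, with standard errors propagated from
#' square-root count statistics: `se = r * sqrt(1/a + 1/b)`. Strata with
#' a zero denominator are omitted and flagged.
#'
#' @param t A sharing table from [build_sharing()].
#' @param num,den Population labels.
#' @return Tibble (`sample`, `stratum`, `num`, `den`, `ratio`, `se`);
#'   attribute `"omitted"` lists zero-denominator strata.
#' @export
ratio_curve <- function(t, num, den) {
  w <- t |>
    dplyr::filter(.data$population %in% c(num, den)) |>
    tidyr::pivot_wider(names_from = "population", values_from = "shared")
  w$num <- w[[num]]; w$den <- w[[den]]
  omitted <- w[w$den == 0, c("sample", "stratum")]
  w <- w[w$den > 0, , drop = FALSE]
  tibble::tibble(sample = w$sample, stratum = w$stratum,
                 num = w$num, den = w$den,
                 ratio = w$num / w$den,
                 se = (w$num / w$den) *
                   sqrt(ifelse(w$num > 0, 1 / w$num, 0) + 1 / w$den)) |>
    structure(omitted = omitted)
}

#' Relative-sharing projection f = NED / (NED + IBS)
#'
#' Sums sharing counts over low allele-count strata (1..`max_stratum`)
#' and projects each sample onto the fraction attributable to the
#' numerator population, with a binomial-style standard error
#' `sqrt(f (1-f) / (NED + IBS))`.
#'
#' @param t A sharing table.
#' @param num,den Population labels (e.g. Dutch-like and Spanish-like).
#' @param max_stratum Highest stratum included. Default 5.
#' @return Tibble (`sample`, `num_shared`, `den_shared`, `f`, `se`).
#' @export
sharing_projection <- function(t, num, den, max_stratum = 5) {
  s <- t |>
    dplyr::filter(.data$stratum <= max_stratum,
                  .data$population %in% c(num, den)) |>
    dplyr::group_by(.data$sample, .data$population) |>
    dplyr::summarise(shared = sum(.data$shared), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "population", values_from = "shared")
  a <- s[[num]]; b <- s[[den]]
  if (any(a + b <= 0)) stop("zero total sharing for some sample")
  f <- a / (a + b)
  tibble::tibble(sample = s$sample, num_shared = a, den_shared = b,
                 f = f, se = sqrt(f * (1 - f) / (a + b)))
}

#' Projection with per-site error propagation
#'
#' Like [sharing_projection()] but computed from the carrier calls so
#' the standard error can respect the per-site clustering of shared
#' allele counts: each carrier site contributes its whole panel count
#' to one stratum at once, so the allele-count binomial formula
#' understates the sampling error by roughly the square root of the
#' mean per-site count. Here `se` is the delta-method error of the
#' ratio-of-sums estimator over independent sites:
#' `se^2 = sum_i (V u_i - U v_i)^2 / (U + V)^4` with per-site numerator
#' and denominator counts `u_i`, `v_i` and totals `U`, `V`.
#'
#' @inheritParams sharing_projection
#' @param calls Carrier calls from [call_carriers()].
#' @param panel The panel tibble.
#' @return Tibble (`sample`, `num_shared`, `den_shared`, `n_sites`,
#'   `f`, `se`).
#' @export
projection_from_calls <- function(calls, panel, num, den, max_stratum = 5) {
  joined <- dplyr::inner_join(
    tibble::as_tibble(calls),
    panel[panel$total <= max_stratum,
          c("chrom", "pos", num, den)],
    by = c("chrom", "pos"))
  joined |>
    dplyr::group_by(.data$sample) |>
    dplyr::group_modify(function(d, key) {
      u <- d[[num]]; v <- d[[den]]
      U <- sum(u); V <- sum(v)
      if (U + V <= 0) stop("zero total sharing for sample ", key$sample)
      tibble::tibble(num_shared = U, den_shared = V, n_sites = nrow(d),
                     f = U / (U + V),
                     se = sqrt(sum((V * u - U * v)^2)) / (U + V)^2)
    }) |>
    dplyr::ungroup()
}

#' Ancestry fraction relative to two anchor means
#'
#' Places a projection value on the axis defined by two anchor group
#' means: 0% at the `iron` (indigenous) anchor, 100% at the `saxon`
#' (immigrant) anchor; values are not clipped. Standard errors are
#' propagated to first order assuming independent uncertainties.
#'
#' @param f Projection value(s).
#' @param iron,saxon Anchor means (must differ).
#' @param se_f,se_iron,se_saxon Optional standard errors.
#' @return Tibble (`fraction`, `se`), percentages.
#' @export
ancestry_fraction <- function(f, iron, saxon, se_f = 0, se_iron = 0,
                              se_saxon = 0) {
  if (isTRUE(all.equal(iron, saxon)))
    stop("anchor means are equal: ancestry axis undefined")
  d <- saxon - iron
  frac <- 100 * (f - iron) / d
  se <- 100 * sqrt((se_f / d)^2 +
                   (se_iron * (f - saxon) / d^2)^2 +
                   (se_saxon * (iron - f) / d^2)^2)
  tibble::tibble(fraction = frac, se = se)
}

#' Group summary of ancestry fractions with explicit exclusions
#'
#' Arithmetic mean and min-max spread over non-excluded samples;
#' exclusion lists are configuration inputs (e.g. known admixed or
#' outlier individuals), never auto-detected.
#'
#' @param fractions Tibble with columns `sample`, `fraction`.
#' @param exclude Character vector of sample ids to exclude.
#' @return One-row tibble (`mean`, `spread_lo`, `spread_hi`, `n_used`,
#'   `excluded` list-column); attribute `"samples"` carries the
#'   per-sample table with an `excluded` flag.
#' @export
group_summary <- function(fractions, exclude = character()) {
  fractions <- tibble::as_tibble(fractions)
  fractions$excluded <- fractions$sample %in% exclude
  used <- fractions[!fractions$excluded, , drop = FALSE]
  if (!nrow(used)) stop("no samples left after exclusion")
  out <- tibble::tibble(mean = mean(used$fraction),
                        spread_lo = min(used$fraction),
                        spread_hi = max(used$fraction),
                        n_used = nrow(used),
                        excluded = list(exclude))
  attr(out, "samples") <- fractions
  out
}

#' Resample a pseudo-haploid individual from panel frequencies
#'
#' Draws, independently at every panel site, carrier status with
#' probability equal to the population's rare-allele frequency
#' (sampling with replacement); used to place reference populations
#' themselves on sharing curves when only frequency data exist.
#'
#' @param panel The panel tibble.
#' @param pop Population column to resample from.
#' @param n_haploids Haploid panel size of `pop` (frequency denominator).
#' @param seed Optional integer seed.
#' @param sample_id Sample label. Default `paste0(pop, "_pseudo")`.
#' @return Carrier calls tibble as from [call_carriers()].
#' @export
resample_haploid <- function(panel, pop, n_haploids, seed = NULL,
                             sample_id = paste0(pop, "_pseudo")) {
  if (!is.null(seed)) set.seed(seed)
  freq <- panel[[pop]] / n_haploids
  if (any(freq < 0 | freq > 1)) stop("frequencies outside [0, 1]")
  hit <- stats::runif(nrow(panel)) < freq
  tibble::tibble(sample = sample_id, chrom = panel$chrom[hit],
                 pos = panel$pos[hit])
}

#' Plot a sharing ratio curve with error bars
#'
#' @param curve Output of [ratio_curve()].
#' @return A ggplot.
#' @export
plot_ratio_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$stratum, y = .data$ratio,
                                      colour = .data$sample)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ratio - .data$se,
                                          ymax = .data$ratio + .data$se),
                             position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "panel allele count", y = "sharing ratio") +
    ggplot2::theme_minimal()
}

#' Plot ancestry fractions as a projection strip
#'
#' @param fractions Tibble with `sample`, `fraction` and optionally
#'   `group`, `se`.
#' @return A ggplot.
#' @export
plot_ancestry_strip <- function(fractions) {
  aesth <- if ("group" %in% names(fractions))
    ggplot2::aes(x = .data$fraction, y = 0, colour = .data$group)
  else ggplot2::aes(x = .data$fraction, y = 0)
  ggplot2::ggplot(fractions, aesth) +
    ggplot2::geom_jitter(height = 0.2, width = 0) +
    ggplot2::geom_vline(xintercept = c(0, 100), linetype = 2) +
    ggplot2::labs(x = "ancestry fraction (%)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
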
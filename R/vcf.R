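#' Build a site-pattern histogram from VCF input
#'
#' Counts biallelic SNPs inside a mappability mask into joint
#' derived-allele count patterns across populations. Sites in the mask
#' but absent from the VCF are monomorphic; `total_sites` is the mask
#' length minus sites skipped for data reasons (missing genotypes,
#' missing ancestral tag, non-SNP records), which keeps the class
#' denominators exact. Coordinates: BED is 0-based half-open, VCF
#' positions 1-based; the conversion is handled by the readers.
#'
#' @param vcf Path to a VCF file (optionally bgzipped).
#' @param pops A data frame with columns `sample`, `population`, or a
#'   path to such a TSV. Every sample must be present in the VCF.
#' @param mask Path to a BED file of callable intervals (sorted,
#'   non-overlapping), or a `GRanges`.
#' @param max_m Maximum tracked total derived count. Default 4.
#' @param polarize `"reference"` (REF is ancestral, the default) or
#'   `"ancestral-tag"` (use the `AA` INFO tag; sites lacking it are
#'   skipped and tallied).
#' @return A `rare_histogram`; attribute `"skipped"` reports skip
#'   tallies by reason.
#' @export
vcf_to_histogram <- function(vcf, pops, mask, max_m = 4,
                             polarize = c("reference", "ancestral-tag")) {
  polarize <- match.arg(polarize)
  if (is.character(pops))
    pops <- utils::read.table(pops, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  pops <- tibble::as_tibble(pops)[, c("sample", "population")]

  if (is.character(mask)) mask <- rtracklayer::import(mask, format = "BED")
  if (!GenomicRanges::isDisjoint(mask))
    stop("mask intervals overlap")
  st <- GenomicRanges::start(mask)
  ch <- as.character(GenomicRanges::seqnames(mask))
  if (any(unlist(tapply(st, ch, function(x) diff(x) < 0))))
    stop("unsorted mask")
  total_sites <- sum(GenomicRanges::width(mask))

  vv <- VariantAnnotation::readVcf(vcf, genome = "unknown")
  missing_samples <- setdiff(pops$sample, colnames(vv))
  if (length(missing_samples))
    stop("samples in pops missing from VCF: ",
         paste(missing_samples, collapse = ", "))

  rr <- SummarizedExperiment::rowRanges(vv)
  in_mask <- GenomicRanges::countOverlaps(rr, mask) > 0
  skipped <- c(outside_mask = sum(!in_mask), non_snp = 0,
               missing_genotype = 0, missing_ancestral = 0)

  snv <- VariantAnnotation::isSNV(vv, singleAltOnly = TRUE)
  skipped[["non_snp"]] <- sum(in_mask & !snv)
  use <- in_mask & snv
  total_sites <- total_sites - skipped[["non_snp"]]

  vv <- vv[use, ]
  gt <- VariantAnnotation::geno(vv)$GT[, pops$sample, drop = FALSE]
  nvar <- nrow(gt)

  # haploid sample sizes from genotype arity (diploid "a|b" or haploid "a")
  ploidy <- if (nvar > 0)
    vapply(seq_along(pops$sample), function(s) {
      g <- gt[, s]
      g <- g[!g %in% c(".", "./.", ".|.")]
      if (!length(g)) 2L else lengths(regmatches(g[1], gregexpr("[0-9.]+", g[1])))
    }, integer(1))
  else rep(2L, length(pops$sample))
  pop_order <- unique(pops$population)
  n <- vapply(pop_order, function(p) sum(ploidy[pops$population == p]),
              integer(1))

  if (nvar > 0) {
    dosage <- matrix(0L, nvar, length(pops$sample))
    miss <- logical(nvar)
    for (s in seq_along(pops$sample)) {
      g <- gt[, s]
      bad <- grepl("\\.", g)
      miss <- miss | bad
      dosage[, s] <- vapply(strsplit(g, "[/|]"), function(a)
        sum(a == "1"), integer(1))
    }
    skipped[["missing_genotype"]] <- sum(miss)
    keep <- !miss

    flip <- rep(FALSE, nvar)
    if (polarize == "ancestral-tag") {
      aa <- VariantAnnotation::info(vv)$AA
      aa <- if (is.null(aa)) rep(NA_character_, nvar) else
        toupper(as.character(aa))
      refs <- as.character(VariantAnnotation::ref(vv))
      alts <- as.character(unlist(VariantAnnotation::alt(vv)))
      is_ref <- !is.na(aa) & aa == refs
      is_alt <- !is.na(aa) & aa == alts
      no_tag <- !(is_ref | is_alt)
      skipped[["missing_ancestral"]] <- sum(no_tag & keep)
      keep <- keep & !no_tag
      flip <- is_alt
    }
    total_sites <- total_sites - sum(!keep)

    dosage <- dosage[keep, , drop = FALSE]
    flip <- flip[keep]
    if (any(flip)) {
      pl <- matrix(ploidy, nrow = sum(keep), ncol = length(ploidy),
                   byrow = TRUE)
      dosage[flip, ] <- pl[flip, ] - dosage[flip, , drop = FALSE]
    }
    mcount <- vapply(pop_order, function(p)
      rowSums(dosage[, pops$population == p, drop = FALSE]), numeric(nrow(dosage)))
    mcount <- matrix(as.integer(mcount), ncol = length(pop_order))
    tot <- rowSums(mcount)
    tracked <- tot >= 1 & tot <= max_m
    overflow <- sum(tot > max_m)
    counts <- tibble::as_tibble(as.data.frame(mcount[tracked, , drop = FALSE])) |>
      stats::setNames(pop_order) |>
      dplyr::mutate(.sites = 1) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(pop_order))) |>
      dplyr::summarise(sites = sum(.data$.sites), .groups = "drop")
  } else {
    counts <- NULL
    overflow <- 0
  }
  tracked_sites <- if (is.null(counts)) 0 else sum(counts$sites)
  h <- rare_histogram(pop_order, n, counts, max_m, overflow = overflow,
                      monomorphic = total_sites - overflow - tracked_sites,
                      total_sites = total_sites)
  attr(h, "skipped") <- skipped
  h
}
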
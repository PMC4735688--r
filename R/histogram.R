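#' Site-pattern histograms
#'
#' A pattern histogram counts, over a set of callable genomic sites, how
#' many sites show each joint configuration of derived-allele counts
#' across populations (a "site pattern"), up to a tracked maximum total
#' derived count `max_m`. Sites with no derived allele go to the
#' `monomorphic` class and sites with total derived count above `max_m`
#' to the `overflow` class, so that
#' `monomorphic + overflow + sum(counts) == total_sites` always holds.
#'
#' @param pops Character vector of population labels (order is fixed and
#'   recorded).
#' @param n Integer haploid sample sizes, one per population.
#' @param counts A data frame with one column per population plus a
#'   `sites` column of site counts.
#' @param max_m Maximum tracked total derived count. Default 4.
#' @param monomorphic,overflow,total_sites Class counts; if
#'   `total_sites` is `NULL` it is set to the class sum.
#' @return An object of class `rare_histogram`.
#' @export
rare_histogram <- function(pops, n, counts = NULL, max_m = 4,
                           monomorphic = 0, overflow = 0, total_sites = NULL) {
  stopifnot(length(pops) == length(n), all(n >= 1))
  n <- stats::setNames(as.integer(n), pops)
  if (is.null(counts)) {
    counts <- tibble::as_tibble(c(stats::setNames(rep(list(integer()), length(pops)), pops),
                                  list(sites = numeric())))
  } else {
    counts <- tibble::as_tibble(counts)[, c(pops, "sites")]
  }
  pm <- as.matrix(counts[, pops, drop = FALSE])
  if (nrow(pm)) {
    if (any(pm < 0) || any(t(pm) > n))
      stop("pattern counts must satisfy 0 <= m_k <= n_k")
    tot <- rowSums(pm)
    if (any(tot < 1) || any(tot > max_m))
      stop("tracked patterns must have 1 <= sum(m) <= max_m")
    if (anyDuplicated(pm))
      stop("duplicate patterns")
  }
  if (is.null(total_sites))
    total_sites <- monomorphic + overflow + sum(counts$sites)
  h <- structure(
    list(pops = pops, n = n, max_m = as.integer(max_m),
         counts = counts[order_patterns(pm), , drop = FALSE],
         monomorphic = monomorphic, overflow = overflow,
         total_sites = total_sites, restricted = FALSE),
    class = "rare_histogram")
  chk <- h$monomorphic + h$overflow + sum(h$counts$sites) - h$total_sites
  if (abs(chk) > 1e-6)
    stop("class counts do not sum to total_sites (off by ", chk, ")")
  h
}

# lexicographic ordering of the pattern matrix rows
order_patterns <- function(pm) {
  if (nrow(pm) == 0) return(integer())
  do.call(order, lapply(seq_len(ncol(pm)), function(k) pm[, k]))
}

pattern_matrix <- function(h) as.matrix(h$counts[, h$pops, drop = FALSE])

#' @export
print.rare_histogram <- function(x, ...) {
  cat(sprintf(
    "<rare_histogram> %d populations (%s), n = %s, max_m = %d%s\n",
    length(x$pops), paste(x$pops, collapse = ", "),
    paste(x$n, collapse = ","), x$max_m,
    if (isTRUE(x$restricted)) ", restricted to shared patterns" else ""))
  cat(sprintf("  total_sites %.0f = monomorphic %.0f + overflow %.0f + %d tracked patterns (%.0f sites)\n",
              x$total_sites, x$monomorphic, x$overflow, nrow(x$counts),
              sum(x$counts$sites)))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @export
as_tibble.rare_histogram <- function(x, ...) x$counts

#' Write / read the histogram text format
#'
#' Header lines `N=`, `MAX_M=`, `TOTAL_SITES=` (and `POPS=`, an optional
#' extension carrying population labels), class lines `MONOMORPHIC`,
#' `OVERFLOW`, then one `m1,...,mK count` line per tracked pattern in
#' lexicographic order.
#'
#' @param h A `rare_histogram`.
#' @param path Optional output path; if omitted lines are returned.
#' @return `write_histogram`: invisibly, the lines. `read_histogram`: a
#'   `rare_histogram`.
#' @export
write_histogram <- function(h, path = NULL) {
  pm <- pattern_matrix(h)
  lines <- c(
    paste0("POPS=", paste(h$pops, collapse = ",")),
    paste0("N=", paste(h$n, collapse = ",")),
    paste0("MAX_M=", h$max_m),
    sprintf("TOTAL_SITES=%.0f", h$total_sites),
    sprintf("MONOMORPHIC %.0f", h$monomorphic),
    sprintf("OVERFLOW %.0f", h$overflow))
  if (nrow(pm))
    lines <- c(lines, sprintf("%s %.0f",
                              apply(pm, 1, paste, collapse = ","),
                              h$counts$sites))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @rdname write_histogram
#' @param text Optional literal text (overrides `path`).
#' @export
read_histogram <- function(path, text = NULL) {
  lines <- if (!is.null(text)) unlist(strsplit(text, "\n")) else readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hdr <- function(key) {
    i <- which(startsWith(lines, paste0(key, "=")))
    if (length(i) != 1) stop("histogram format: need exactly one ", key, "= header")
    sub(paste0("^", key, "="), "", lines[i])
  }
  n <- as.integer(strsplit(hdr("N"), ",")[[1]])
  max_m <- as.integer(hdr("MAX_M"))
  total <- as.numeric(hdr("TOTAL_SITES"))
  pops <- if (any(startsWith(lines, "POPS=")))
    strsplit(hdr("POPS"), ",")[[1]] else paste0("pop", seq_along(n))
  cls <- function(key) {
    i <- which(startsWith(lines, paste0(key, " ")))
    if (length(i) > 1) stop("duplicate ", key, " line")
    if (length(i) == 0) return(0)
    as.numeric(sub(paste0("^", key, " +"), "", lines[i]))
  }
  known <- grepl("^(POPS|N|MAX_M|TOTAL_SITES)=", lines) |
    grepl("^(MONOMORPHIC|OVERFLOW) ", lines) |
    grepl("^[0-9]+(,[0-9]+)* +[0-9]+$", lines)
  if (any(!known))
    stop("malformed histogram line: ", lines[which(!known)[1]])
  body <- lines[grepl("^[0-9]+(,[0-9]+)* ", lines)]
  if (length(body)) {
    parts <- strsplit(body, "[ ]+")
    pm <- lapply(parts, function(p) as.integer(strsplit(p[1], ",")[[1]]))
    arity <- lengths(pm)
    if (any(arity != length(n)))
      stop(sprintf("pattern arity %d does not match header N with %d populations",
                   arity[which(arity != length(n))[1]], length(n)))
    pm <- do.call(rbind, pm)
    counts <- tibble::as_tibble(as.data.frame(pm)) |>
      stats::setNames(pops)
    counts$sites <- as.numeric(vapply(parts, `[`, "", 2))
  } else counts <- NULL
  rare_histogram(pops, n, counts, max_m,
                 monomorphic = cls("MONOMORPHIC"), overflow = cls("OVERFLOW"),
                 total_sites = total)
}

#' Merge per-chunk histograms
#'
#' @param ... `rare_histogram` objects (or a single list of them) with
#'   identical population configuration and `max_m`.
#' @return The classwise sum.
#' @export
merge_histograms <- function(...) {
  hs <- list(...)
  if (length(hs) == 1 && !inherits(hs[[1]], "rare_histogram")) hs <- hs[[1]]
  stopifnot(length(hs) >= 1)
  h1 <- hs[[1]]
  for (h in hs[-1]) {
    if (!identical(h$pops, h1$pops) || !identical(h$n, h1$n) ||
        h$max_m != h1$max_m)
      stop("histograms have mismatched population configuration")
  }
  counts <- dplyr::bind_rows(lapply(hs, function(h) h$counts)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(h1$pops))) |>
    dplyr::summarise(sites = sum(.data$sites), .groups = "drop")
  rare_histogram(h1$pops, h1$n, counts, h1$max_m,
                 monomorphic = sum(vapply(hs, `[[`, 0, "monomorphic")),
                 overflow = sum(vapply(hs, `[[`, 0, "overflow")))
}

#' Restrict a histogram to patterns shared with a query population
#'
#' Keeps only tracked patterns where the query population carries at
#' least one derived allele *and* at least one other population does too.
#' Query-private variants (high false-positive rates in low-coverage
#' samples) and patterns not involving the query are dropped;
#' monomorphic and overflow classes are zeroed and `total_sites` is the
#' retained count.
#'
#' @param h A `rare_histogram`.
#' @param query A population label in `h`.
#' @return A restricted `rare_histogram` (flagged `restricted`).
#' @export
restrict_to_shared <- function(h, query) {
  if (!query %in% h$pops) stop("unknown population: ", query)
  pm <- pattern_matrix(h)
  keep <- if (nrow(pm)) pm[, query] >= 1 & rowSums(pm[, setdiff(h$pops, query),
                                                      drop = FALSE]) >= 1
          else logical()
  out <- rare_histogram(h$pops, h$n, h$counts[keep, , drop = FALSE], h$max_m,
                        monomorphic = 0, overflow = 0)
  out$restricted <- TRUE
  out
}

#' Recode a query population's counts as heterozygous carrier calls
#'
#' Low-coverage (e.g. ancient) queries are genotyped as carrier /
#' non-carrier and always assumed heterozygous, so a query diploid is
#' encoded as 2 haploids carrying exactly 1 derived copy at carrier
#' sites. This collapses the query column of a simulated histogram to
#' `min(m, 1)` and re-aggregates.
#'
#' @param h A `rare_histogram` whose `query` column has sample size 2.
#' @param query The query population label.
#' @return A `rare_histogram`.
#' @export
encode_query_het <- function(h, query) {
  if (!query %in% h$pops) stop("unknown population: ", query)
  counts <- h$counts
  counts[[query]] <- pmin(counts[[query]], 1L)
  counts <- counts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(h$pops))) |>
    dplyr::summarise(sites = sum(.data$sites), .groups = "drop")
  rare_histogram(h$pops, h$n, counts, h$max_m,
                 monomorphic = h$monomorphic, overflow = h$overflow,
                 total_sites = h$total_sites)
}
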
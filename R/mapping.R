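#' Scan merge points for a single query genome on a fitted tree
#'
#' Places one query genome (ancient or modern) onto a population tree by
#' evaluating, for every branch and a grid of times along it, the
#' likelihood that the query's ancestral branch merges there. The query
#' is encoded as 2 haploids with derived count 1 at carrier sites
#' (carrier calls are assumed heterozygous); the histogram is restricted
#' to patterns shared between the query and at least one reference
#' population (query-private variants are excluded). An ancient query's
#' branch is frozen -- inert from the present back to `query_age` -- so
#' merge times below the age are excluded and an age of 0 reproduces the
#' unfrozen computation exactly.
#'
#' @param m A fitted `demography` of the reference tree (no query
#'   branch).
#' @param h A `rare_histogram` including the query population's column
#'   (sample size 2, counts 0/1; see [encode_query_het()]).
#' @param query The query population label in `h`.
#' @param query_age Scaled age of the query sample. Default 0.
#' @param points_per_segment Scan points per branch segment. Default 20.
#' @param root_extent The root branch is scanned up to
#'   `root_extent * last join time`. Default 2.
#' @param scale A [unit_scale()].
#' @param grid A [time_grid()].
#' @param conditional Renormalize the restricted likelihood over the
#'   retained classes. Default TRUE: after the monomorphic and overflow
#'   complements are discarded by the restriction, the unconditional sum
#'   rewards merge points that inflate the total retained probability
#'   mass rather than its shape, which empirically drags every query
#'   toward low tip merges; the conditional composite compares the
#'   sharing profile only. `FALSE` gives the unconditional sum.
#' @return An object of class `merge_scan`: a tibble of scan entries
#'   (branch, time, time_years, loglik, rel_lik) sorted by decreasing
#'   log-likelihood, plus query metadata.
#' @export
merge_scan <- function(m, h, query, query_age = 0, points_per_segment = 20,
                       root_extent = 2, scale = unit_scale(),
                       grid = time_grid(), conditional = TRUE) {
  if (!query %in% h$pops) stop("unknown query population: ", query)
  hr <- if (isTRUE(h$restricted)) h else
    restrict_to_shared(encode_query_het(h, query), query)
  if (nrow(hr$counts) == 0) stop("empty restricted histogram: no shared patterns")
  if (nrow(m$joins) && query_age >= max(m$joins$time) * root_extent)
    stop("query age exceeds the scanned root extent")

  segs <- branch_segments(m, root_extent)
  entries <- list()
  for (i in seq_len(nrow(segs))) {
    lo <- max(segs$start[i], query_age)
    # a merge exactly at the query age is invalid (the sample must
    # predate its branch's first join); start strictly above
    if (query_age > 0 && lo <= query_age) lo <- query_age * (1 + 1e-6)
    hi <- segs$end[i]
    if (hi <= lo) next
    ts <- geom_points(lo, hi, points_per_segment)
    for (t in ts) {
      mq <- graft_query(m, query, hr$n[[query]], segs$branch[i], t, query_age)
      ll <- histogram_loglik(mq, hr, scale, grid, conditional = conditional)
      entries[[length(entries) + 1]] <- tibble::tibble(
        branch = segs$branch[i], time = t, loglik = ll)
    }
  }
  out <- dplyr::bind_rows(entries)
  out$time_years <- scaled_to_years(out$time, scale)
  mx <- max(out$loglik)
  out$rel_lik <- exp(out$loglik - mx)
  out <- out[order(-out$loglik, -out$time), c("branch", "time", "time_years",
                                              "loglik", "rel_lik")]
  structure(list(entries = out, query = query, query_age = query_age,
                 max_loglik = mx, conditional = conditional),
            class = "merge_scan")
}

# branch segments (between the joins a branch absorbs); root gets a
# finite extent for scanning
branch_segments <- function(m, root_extent = 2) {
  b <- m$branches; j <- m$joins
  t_last <- if (nrow(j)) max(j$time) else 0.01
  segs <- list()
  for (k in seq_len(nrow(b))) {
    nm <- b$name[k]
    term <- j$time[j$from == nm]
    ends <- sort(unique(c(j$time[j$into == nm],
                          if (length(term)) term else t_last * root_extent)))
    start <- b$sample_age[k]
    for (e in ends) {
      if (e > start) {
        segs[[length(segs) + 1]] <- tibble::tibble(branch = nm, start = start,
                                                   end = e)
        start <- e
      }
    }
  }
  dplyr::bind_rows(segs)
}

# geometrically spaced points in (lo, hi), denser near lo; the upper
# end is nudged inward so a merge never ties with the branch's own
# terminal join (ties sort the terminal join first and would leave the
# branch already absorbed)
geom_points <- function(lo, hi, n) {
  eps <- max(lo, hi / 200)
  exp(seq(log(eps), log(hi * (1 - 1e-9)), length.out = n))
}

# model plus a query branch of 2 haploids joining `branch` at time t
graft_query <- function(m, query, n_query, branch, t, age) {
  # query branch size = size of the segment it merges into
  lam <- segment_lambda(m, branch, t)
  demography(
    dplyr::bind_rows(m$branches,
                     tibble::tibble(name = query, lambda = lam,
                                    sample_size = n_query, sample_age = age)),
    dplyr::bind_rows(m$joins,
                     tibble::tibble(time = t, into = branch, from = query,
                                    lambda_after = NA_real_)))
}

# lambda of `branch` at time t (piecewise along absorbed joins)
segment_lambda <- function(m, branch, t) {
  lam <- m$branches$lambda[m$branches$name == branch]
  j <- m$joins
  if (nrow(j)) {
    jj <- j[j$into == branch & j$time <= t & !is.na(j$lambda_after), ,
            drop = FALSE]
    if (nrow(jj)) lam <- jj$lambda_after[which.max(jj$time)]
  }
  lam
}

#' @export
print.merge_scan <- function(x, ...) {
  cat(sprintf(
    "<merge_scan> query '%s' (age %g), %d merge points, max logLik %.3f\n",
    x$query, x$query_age, nrow(x$entries), x$max_loglik))
  print(utils::head(x$entries, 5))
  invisible(x)
}

#' @export
as_tibble.merge_scan <- function(x, ...) x$entries

#' Best merge point of a scan
#'
#' @param s A `merge_scan`.
#' @return One-row tibble (branch, time, loglik, tie flag); ties are
#'   broken toward the older time.
#' @export
best_merge <- function(s) {
  e <- s$entries
  if (!nrow(e)) stop("empty scan")
  top <- e[e$loglik == max(e$loglik), , drop = FALSE]
  best <- top[which.max(top$time), , drop = FALSE]
  tibble::tibble(branch = best$branch, time = best$time,
                 loglik = best$loglik, tie = nrow(top) > 1)
}

#' Export a relative-likelihood surface
#'
#' @param s A `merge_scan`.
#' @return Tibble with `exp(logLik - max logLik)` per merge point
#'   (1 exactly at the maximum).
#' @export
surface_export <- function(s) {
  e <- s$entries
  tibble::tibble(branch = e$branch, time = e$time,
                 time_years = e$time_years,
                 rel_lik = exp(e$loglik - max(e$loglik)))
}

#' @export
autoplot.merge_scan <- function(object, ...) {
  e <- object$entries
  ggplot2::ggplot(e, ggplot2::aes(x = .data$time, y = .data$rel_lik,
                                  colour = .data$branch)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "merge time (scaled)", y = "relative likelihood",
                  colour = "branch",
                  title = sprintf("Merge scan for query '%s'", object$query)) +
    ggplot2::theme_minimal()
}
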
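#' Numerical controls for the likelihood engine
#'
#' The engine integrates the per-branch lineage-count chains with
#' rate-controlled classic Runge-Kutta between demographic events and
#' closes the final single-branch epoch in closed form, so accuracy is
#' governed by `substep` (maximum total transition rate times the step
#' size) and `delta` (a hard cap on the step size); the geometric knot
#' parameters are retained for interface stability but the integration
#' no longer needs interior knots.
#'
#' @param delta Maximum step size (scaled time). Default 1e-4.
#' @param growth Geometric growth factor (unused by the exact engine).
#' @param substep Rate-based sub-step control. Default 0.25.
#' @param tail_tol Tolerance on stray probability mass diagnostics.
#' @return An object of class `time_grid`.
#' @export
time_grid <- function(delta = 1e-4, growth = 1.02, substep = 0.25,
                      tail_tol = 1e-10) {
  stopifnot(delta > 0, growth > 1, substep > 0, tail_tol > 0)
  structure(list(delta = delta, growth = growth, substep = substep,
                 tail_tol = tail_tol), class = "time_grid")
}

# ---- pattern enumeration ---------------------------------------------------

# all K-vectors with 1 <= sum <= m_tot
enumerate_configs <- function(K, m_tot) {
  cf <- as.matrix(expand.grid(rep(list(0:m_tot), K)))
  dimnames(cf) <- NULL
  cf <- cf[rowSums(cf) >= 1 & rowSums(cf) <= m_tot, , drop = FALSE]
  storage.mode(cf) <- "integer"
  cf
}

config_keys <- function(cf, base) as.vector(cf %*% base^(seq_len(ncol(cf)) - 1))

# all tracked patterns for a sample configuration
tracked_patterns <- function(n, max_m) {
  cf <- enumerate_configs(length(n), max_m)
  cf <- cf[!apply(t(cf) > n, 2, any), , drop = FALSE]
  cf[order_patterns(cf), , drop = FALSE]
}

# ---- the propagation -------------------------------------------------------

# schedule of demographic events: sample entries (ages) and joins
model_events <- function(m) {
  b <- m$branches; j <- m$joins
  ev <- tibble::tibble(time = numeric(), type = character(), arg = integer())
  anc <- which(b$sample_age > 0 & b$sample_size > 0)
  if (length(anc))
    ev <- dplyr::bind_rows(ev, tibble::tibble(time = b$sample_age[anc],
                                              type = "entry", arg = anc))
  if (nrow(j))
    ev <- dplyr::bind_rows(ev, tibble::tibble(time = j$time, type = "join",
                                              arg = seq_len(nrow(j))))
  ev[order(ev$time, ev$type != "entry"), , drop = FALSE]
}

# delta distribution at (a, b) on an (amax, bmax) lattice
delta_dist <- function(amax, bmax, a, b) {
  d <- matrix(0, (amax + 1) * (bmax + 1), length(a))
  d[cbind(a * (bmax + 1) + b + 1, seq_along(a))] <- 1
  d
}

# Trim unoccupied high-b rows from a branch system. Mass only ever
# flows downward in b, so support shrinks monotonically; dropping rows
# whose total mass across variants is below tol keeps the stiffness
# bound (and the lattice) proportional to the occupied support.
trim_branch <- function(s, tol = 1e-10) {
  W <- s$bmax + 1
  nst <- (s$amax + 1) * W
  # mass per b level, summed over a and variants
  bidx <- rep.int(0:s$bmax, s$amax + 1)
  lvl <- vapply(0:s$bmax, function(b)
    sum(s$dist[bidx == b, , drop = FALSE]), 0)
  cum_top <- rev(cumsum(rev(lvl))) # mass at levels >= b
  new_bmax <- max(which(cum_top > tol)) - 1L
  if (new_bmax >= s$bmax) return(s)
  sel <- bidx <= new_bmax
  s$dist <- s$dist[sel, , drop = FALSE]
  s$bmax <- as.integer(new_bmax)
  s
}

# Exact propagation of all requested patterns through the model.
# patterns: integer matrix, one row per pattern, columns = model branches
# (order of m$branches). Returns list(acc, live) per pattern, where acc
# is the expected time during which one derived lineage subtends exactly
# a specific carrier set with the pattern's counts.
propagate_patterns <- function(m, patterns, grid = time_grid()) {
  v <- validate_demography(m)
  if (length(v)) stop("invalid model: ", paste(v, collapse = "; "))
  b <- m$branches
  K <- nrow(b)
  n <- as.integer(b$sample_size)
  patterns <- matrix(as.integer(patterns), ncol = K)
  npat <- nrow(patterns)
  if (any(t(patterns) > n)) stop("pattern larger than sample size")
  msum <- rowSums(patterns)
  if (any(msum < 1)) stop("monomorphic pattern: sum(m) must be >= 1")
  if (any(msum == sum(n)))
    stop("pattern with every sampled lineage derived has no rare-allele probability")
  m_tot <- max(msum)

  # per-branch systems: distinct initial derived counts are the variants
  sys <- vector("list", K)
  patvar <- matrix(0L, npat, K)
  for (k in seq_len(K)) {
    vals <- sort(unique(patterns[, k]))
    patvar[, k] <- match(patterns[, k], vals) - 1L
    sys[[k]] <- list(
      amax = max(1L, max(vals)), bmax = n[k],
      lambda = b$lambda[k], active = b$sample_age[k] <= 0,
      dist = delta_dist(max(1L, max(vals)), n[k], vals, n[k] - vals))
  }

  acc <- numeric(npat)
  ev <- model_events(m)
  t_cur <- 0
  # integrate in chunks of ~10 top-state e-foldings so that decayed
  # high-b levels can be trimmed away (they drive the stiffness bound)
  sys_rmax <- function() {
    max(1, vapply(sys, function(s) {
      if (!s$active) return(0)
      (s$amax * (s$amax - 1) / 2 + s$bmax * (s$bmax - 1) / 2 +
         s$amax * s$bmax) / s$lambda
    }, 0))
  }
  integrate_to <- function(t_target) {
    while (t_cur < t_target) {
      sys <<- lapply(sys, trim_branch)
      t_next <- min(t_target, t_cur + 6 / sys_rmax())
      st <- cpp_branch_epoch(sys, patvar, acc, t_cur, t_next,
                             grid$substep, grid$delta * 1e4)
      for (k in seq_len(K)) sys[[k]]$dist <<- st$dist[[k]]
      acc <<- st$acc
      t_cur <<- t_next
    }
  }
  for (i in seq_len(nrow(ev))) {
    if (ev$time[i] > t_cur) integrate_to(ev$time[i])
    if (ev$type[i] == "entry") {
      sys[[ev$arg[i]]]$active <- TRUE
    } else {
      jj <- m$joins[ev$arg[i], ]
      ki <- match(jj$into, b$name); kf <- match(jj$from, b$name)
      A <- sys[[ki]]; B <- sys[[kf]]
      pairkey <- patvar[, ki] * (max(patvar[, kf]) + 1L) + patvar[, kf]
      uk <- sort(unique(pairkey))
      pairs <- cbind(uk %/% (max(patvar[, kf]) + 1L), uk %% (max(patvar[, kf]) + 1L))
      amax_out <- min(A$amax + B$amax, m_tot)
      dist <- cpp_convolve_join(A$dist, A$amax, A$bmax, B$dist, B$amax,
                                B$bmax, pairs, amax_out)
      lam <- if (!is.na(jj$lambda_after)) jj$lambda_after else A$lambda
      sys[[ki]] <- list(amax = amax_out, bmax = A$bmax + B$bmax, lambda = lam,
                        active = TRUE, dist = dist)
      patvar[, ki] <- match(pairkey, uk) - 1L
      # collapse the absorbed branch to an inert empty system
      sys[[kf]] <- list(amax = 1L, bmax = 0L, lambda = 1, active = TRUE,
                        dist = delta_dist(1L, 0L, rep(0L, 1), rep(0L, 1)))
      patvar[, kf] <- 0L
    }
  }

  # closed-form tail for the remaining single branch
  kroot <- match(root_branch(m), b$name)
  S <- trim_branch(sys[[kroot]])
  hm <- cpp_h_table(S$amax, S$bmax, S$lambda)
  W <- S$bmax + 1
  amat <- matrix(rep(0:S$amax, each = W), ncol = 1)
  hv <- as.vector(t(hm)) # state order a*(bmax+1)+b
  live <- colSums(S$dist)
  inf_states <- !is.finite(hv)
  if (any(inf_states)) {
    stray <- colSums(S$dist[inf_states, , drop = FALSE])
    if (any(stray > 1e-9))
      stop("probability mass on states with no non-derived lineage: ",
           "pattern cannot be treated as a rare allele")
    hv[inf_states] <- 0
  }
  tail_acc <- as.vector(crossprod(S$dist, hv))
  list(acc = acc + tail_acc[patvar[, kroot] + 1L],
       live = live[patvar[, kroot] + 1L], t_end = t_cur)
}

#' Per-site probability of a rare-allele site pattern
#'
#' The probability that a single site shows the given joint
#' derived-allele counts equals `theta * E[L_x]`, where
#' `theta = 2 n_ref mu` and `E[L_x]` is the expected total length of
#' genealogy branches subtending exactly a carrier set with those
#' counts. Derived lineages must coalesce among themselves before any
#' of them meets a non-derived lineage; the engine propagates the
#' per-branch joint (derived, non-derived) lineage-count distributions
#' backwards in time (exactly -- the process factorizes across branches
#' and joins are convolutions), accumulates the expected time during
#' which exactly one derived lineage remains, and closes the final
#' epoch in closed form. The within-population exchangeability factor
#' `prod_k choose(n_k, m_k)` converts the specific-carrier-set quantity
#' to the count-pattern probability.
#'
#' @param m A `demography`.
#' @param pattern Integer vector of derived-allele counts, one per model
#'   branch (in `m$branches` order), or a matrix of patterns (rows).
#' @param scale A [unit_scale()].
#' @param grid A [time_grid()].
#' @return A tibble with the pattern columns, the expected subtending
#'   length `acc` (scaled time, exchangeability factor included) and the
#'   per-site probability `prob`.
#' @examples
#' m <- demography(tibble::tibble(name = "A", lambda = 1, sample_size = 2))
#' pattern_probability(m, 1)$prob # theta * 2
#' @export
pattern_probability <- function(m, pattern, scale = unit_scale(),
                                grid = time_grid()) {
  pm <- if (is.matrix(pattern)) pattern else matrix(pattern, nrow = 1)
  pr <- propagate_patterns(m, pm, grid)
  n <- m$branches$sample_size
  comb <- apply(pm, 1, function(mm) prod(choose(n, mm)))
  out <- tibble::as_tibble(as.data.frame(pm)) |>
    stats::setNames(m$branches$name)
  out$acc <- pr$acc * comb
  out$prob <- scale$theta * out$acc
  out
}

# ---- total genealogy length ------------------------------------------------

# death-chain RK4: distribution q over 0..n lineages, pair rate 1/lambda;
# also accumulates the integral of E[count]. Returns list(q, int_EN).
death_chain_step <- function(q, lambda, dt, substep, cap_step) {
  n <- length(q) - 1
  if (n < 1 || dt <= 0) return(list(q = q, int_EN = 0))
  rates <- choose(0:n, 2) / lambda
  f <- function(x) c(x[-1] * rates[-1], 0) - rates * x
  Rmax <- rates[n + 1]
  nsub <- max(1, ceiling(max(dt * Rmax / substep, dt / cap_step)))
  h <- dt / nsub
  cnt <- 0:n
  int_EN <- 0
  for (s in seq_len(nsub)) {
    k1 <- f(q); k2 <- f(q + h / 2 * k1); k3 <- f(q + h / 2 * k2)
    k4 <- f(q + h * k3)
    # Simpson rule on E[N(t)] over the sub-step
    e0 <- sum(cnt * q)
    emid <- sum(cnt * (q + h / 2 * k1))
    q <- q + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    e1 <- sum(cnt * q)
    int_EN <- int_EN + h / 6 * (e0 + 4 * emid + e1)
  }
  list(q = q, int_EN = int_EN)
}

#' Expected total genealogy length
#'
#' Expected total branch length (scaled time units) of the genealogy of
#' all sampled lineages, used for the monomorphic-class probability
#' `p0 = 1 - theta * total_tree_length`. Computed exactly: per-branch
#' lineage-count death chains are integrated through every pre-root
#' epoch (accumulating `E[N(t)]`), convolved at joins, and the root
#' epoch is closed with the harmonic tail
#' `E[L | b lineages] = 2 lambda H_{b-1}`.
#'
#' @param m A `demography`.
#' @param n Optional haploid sample sizes per branch (defaults to the
#'   model's sample sizes).
#' @param grid A [time_grid()].
#' @return Expected total length in scaled time units.
#' @examples
#' m1 <- demography(tibble::tibble(name = "A", lambda = 1, sample_size = 2))
#' total_tree_length(m1) # 2
#' @export
total_tree_length <- function(m, n = NULL, grid = time_grid()) {
  v <- validate_demography(m)
  if (length(v)) stop("invalid model: ", paste(v, collapse = "; "))
  b <- m$branches
  if (is.null(n)) n <- b$sample_size
  n <- as.integer(n)
  # per-branch count distributions (NULL = not yet entered)
  q <- lapply(seq_len(nrow(b)), function(k) {
    if (b$sample_age[k] > 0 || n[k] == 0) NULL
    else c(rep(0, n[k]), 1) # delta at n[k] on 0..n[k]
  })
  lambda <- b$lambda
  ev <- model_events(m)
  t_cur <- 0; L <- 0
  for (i in seq_len(nrow(ev))) {
    dt <- ev$time[i] - t_cur
    if (dt > 0) {
      for (k in seq_len(nrow(b))) {
        if (is.null(q[[k]])) next
        st <- death_chain_step(q[[k]], lambda[k], dt, grid$substep,
                               grid$delta * 1e4)
        q[[k]] <- st$q
        L <- L + st$int_EN
      }
      t_cur <- ev$time[i]
    }
    if (ev$type[i] == "entry") {
      k <- ev$arg[i]
      q[[k]] <- c(rep(0, n[k]), 1)
    } else {
      jj <- m$joins[ev$arg[i], ]
      ki <- match(jj$into, b$name); kf <- match(jj$from, b$name)
      qa <- q[[ki]]; qb <- q[[kf]]
      q[[ki]] <- if (is.null(qa)) qb else if (is.null(qb)) qa else {
        r <- numeric(length(qa) + length(qb) - 1)
        for (ii in seq_along(qa))
          r[ii + seq_along(qb) - 1] <- r[ii + seq_along(qb) - 1] + qa[ii] * qb
        r
      }
      q[kf] <- list(NULL)
      if (!is.na(jj$lambda_after)) lambda[ki] <- jj$lambda_after
    }
  }
  kroot <- match(root_branch(m), b$name)
  qr <- q[[kroot]]
  if (is.null(qr)) return(L)
  harm <- c(0, 0, cumsum(1 / seq_len(max(length(qr) - 2, 0))))
  L + 2 * lambda[kroot] * sum(qr * harm[seq_along(qr)])
}

#' Composite log-likelihood of a pattern histogram
#'
#' Multinomial composite log-likelihood over site classes: each tracked
#' pattern with its engine probability, the monomorphic class with
#' `p0 = 1 - theta * total_tree_length`, and the overflow class by
#' complement (floored at 1e-12). For a histogram restricted to shared
#' patterns (see [restrict_to_shared()]) only the retained pattern
#' classes contribute; `conditional = TRUE` additionally renormalizes
#' their probabilities to sum to one over the retained set.
#'
#' @param m A `demography` whose branches with samples match `h$pops`
#'   (by name) and sample sizes.
#' @param h A `rare_histogram`.
#' @param scale A [unit_scale()].
#' @param grid A [time_grid()].
#' @param conditional Renormalize over retained classes (restricted
#'   histograms only). Default FALSE.
#' @return The composite log-likelihood (scalar).
#' @export
histogram_loglik <- function(m, h, scale = unit_scale(), grid = time_grid(),
                             conditional = FALSE) {
  map <- match(h$pops, m$branches$name)
  if (any(is.na(map)))
    stop("histogram populations missing from model: ",
         paste(h$pops[is.na(map)], collapse = ", "))
  if (!all(m$branches$sample_size[map] == h$n))
    stop("model sample sizes do not match histogram")
  K <- nrow(m$branches)

  if (isTRUE(h$restricted)) {
    obs <- pattern_matrix(h)
    if (nrow(obs) == 0) return(0)
    pats <- matrix(0L, nrow(obs), K)
    pats[, map] <- obs
    pp <- pattern_probability(m, pats, scale, grid)
    p <- pmax(pp$prob, 1e-300)
    if (conditional) p <- p / sum(p)
    return(sum(h$counts$sites * log(p)))
  }

  # full histogram: all tracked patterns + monomorphic + overflow
  tr <- tracked_patterns(h$n, h$max_m)
  pats <- matrix(0L, nrow(tr), K)
  pats[, map] <- tr
  pp <- pattern_probability(m, pats, scale, grid)
  p_x <- pp$prob
  p0 <- 1 - scale$theta * total_tree_length(m, grid = grid)
  p_over <- max(1 - p0 - sum(p_x), 1e-12)
  if (p0 <= 0) stop("monomorphic probability <= 0: model grossly inconsistent")

  obs <- pattern_matrix(h)
  idx <- match(config_keys(obs, h$max_m + 1L),
               config_keys(tr, h$max_m + 1L))
  if (anyNA(idx)) stop("histogram contains untracked patterns")
  cnt <- numeric(nrow(tr))
  cnt[idx] <- h$counts$sites
  if (any(p_x <= 0 & cnt > 0))
    stop("non-positive probability for an observed pattern")
  sum(cnt[cnt > 0] * log(p_x[cnt > 0])) +
    h$monomorphic * log(p0) +
    (if (h$overflow > 0) h$overflow * log(p_over) else 0)
}
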
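# Maximum-likelihood fitting and MCMC posterior sampling of demographic
# model parameters against a site-pattern histogram.

# objective on the transformed scale; returns -Inf outside bounds
make_objective <- function(pm, h, scale, grid, conditional = FALSE) {
  force(pm); force(h); force(scale); force(grid)
  evals <- new.env(); evals$n <- 0L
  fn <- function(y) {
    evals$n <- evals$n + 1L
    x <- pmap_from_transformed(pm, y)
    m <- pmap_apply(pm, x)
    if (is.null(m)) return(-Inf)
    ll <- tryCatch(histogram_loglik(m, h, scale, grid,
                                    conditional = conditional),
                   error = function(e) -Inf)
    if (!is.finite(ll)) -Inf else ll
  }
  list(fn = fn, evals = evals)
}

#' Maximize the composite likelihood of a histogram
#'
#' Derivative-free Nelder-Mead simplex maximization on transformed
#' parameters (log sizes, identity on positive parent-relative join-time
#' increments), restarted from a perturbed best point until the
#' improvement drops below `tol` log-units. Deterministic given `seed`.
#'
#' @param m A `demography` template (starting values).
#' @param h A `rare_histogram`.
#' @param free Character vector of free-parameter slots (see
#'   [param_map()]); `NULL` or empty returns the template's likelihood.
#' @param scale A [unit_scale()].
#' @param grid A [time_grid()].
#' @param seed Integer seed for restart perturbations. Default 1.
#' @param tol Restart improvement threshold (log-likelihood units).
#' @param max_restarts Maximum restarts. Default 8.
#' @param maxit Nelder-Mead iterations per start. Default 500.
#' @param conditional Passed to [histogram_loglik()].
#' @return An object of class `raretree_fit`: fitted model, named
#'   parameter estimates, maximized log-likelihood, convergence flag,
#'   evaluation count.
#' @export
fit_demography <- function(m, h, free, scale = unit_scale(),
                           grid = time_grid(), seed = 1, tol = 1e-4,
                           max_restarts = 8, maxit = 500,
                           conditional = FALSE) {
  if (is.null(free) || !length(free)) {
    ll <- histogram_loglik(m, h, scale, grid, conditional = conditional)
    return(structure(list(model = m, pmap = NULL,
                          par = stats::setNames(numeric(), character()),
                          loglik = ll, convergence = TRUE, evals = 1L),
                     class = "raretree_fit"))
  }
  pm <- param_map(m, free)
  obj <- make_objective(pm, h, scale, grid, conditional)
  set.seed(seed)
  y <- pmap_to_transformed(pm, pmap_init(pm))
  best <- list(par = y, value = obj$fn(y))
  if (!is.finite(best$value))
    stop("template model has non-finite likelihood")
  convergence <- FALSE
  perturb <- function(par) {
    for (try in 1:20) {
      cand <- par + stats::rnorm(length(par), 0, 0.05)
      if (is.finite(obj$fn(cand))) return(cand)
    }
    par
  }
  # one-dimensional problems use Brent on the transformed bounds
  optimise_once <- function(start) {
    if (length(start) == 1) {
      lo <- pmap_to_transformed(pm, pm$lower)
      hi <- pmap_to_transformed(pm, pm$upper)
      stats::optim(start, obj$fn, method = "Brent", lower = lo, upper = hi,
                   control = list(fnscale = -1, maxit = maxit))
    } else {
      stats::optim(start, obj$fn, method = "Nelder-Mead",
                   control = list(fnscale = -1, maxit = maxit,
                                  reltol = 1e-10))
    }
  }
  for (r in seq_len(max_restarts)) {
    start <- if (r == 1) best$par else perturb(best$par)
    o <- optimise_once(start)
    if (o$value > best$value + tol) {
      best <- o
    } else {
      if (o$value > best$value) best <- o
      convergence <- TRUE
      break
    }
  }
  x <- pmap_from_transformed(pm, best$par)
  structure(list(model = pmap_apply(pm, x), pmap = pm,
                 par = pmap_slot_values(pm, x), increments = x,
                 loglik = best$value, convergence = convergence,
                 evals = obj$evals$n),
            class = "raretree_fit")
}

#' @export
print.raretree_fit <- function(x, ...) {
  cat(sprintf("<raretree_fit> logLik = %.3f, %s after %d evaluations\n",
              x$loglik, if (x$convergence) "converged" else "NOT converged",
              x$evals))
  if (length(x$par)) print(tidy(x))
  invisible(x)
}

#' @export
tidy.raretree_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' @export
glance.raretree_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, nobs = NA_integer_,
                 convergence = x$convergence, evals = x$evals)
}

# Random-walk Metropolis on a generic log-density: joint Gaussian
# proposals with per-component scales (one density evaluation per step),
# a global step factor adapted toward the multivariate optimum
# acceptance rate during the first `burn_frac` of the chain, frozen
# afterwards. Exposed internally so the kernel can be tested against
# analytic stationary distributions.
rw_metropolis <- function(logpost, start, steps, seed = 1, burn_frac = 0.2,
                          comp_scale = NULL, prop_chol = NULL,
                          init_scale = 0.1, target_accept = 0.234) {
  if (steps < 1) stop("chain length must be >= 1")
  set.seed(seed)
  d <- length(start)
  sc <- if (is.null(comp_scale)) rep(init_scale, d) else comp_scale
  g <- 1 # global factor
  cur <- start
  cur_lp <- logpost(cur)
  if (!is.finite(cur_lp)) stop("starting point has non-finite log-density")
  burn <- floor(steps * burn_frac)
  chain <- matrix(NA_real_, steps, d)
  lp <- numeric(steps)
  acc_win <- 0; try_win <- 0; n_acc <- 0
  for (s in seq_len(steps)) {
    prop <- if (is.null(prop_chol)) cur + stats::rnorm(d, 0, g * sc)
            else cur + g * as.vector(prop_chol %*% stats::rnorm(d))
    prop_lp <- logpost(prop)
    try_win <- try_win + 1
    if (is.finite(prop_lp) && log(stats::runif(1)) < prop_lp - cur_lp) {
      cur <- prop; cur_lp <- prop_lp
      acc_win <- acc_win + 1
      n_acc <- n_acc + 1
    }
    if (s <= burn && s %% 25 == 0) {
      g <- g * exp(1.5 * (acc_win / max(try_win, 1) - target_accept))
      acc_win <- 0; try_win <- 0
    }
    chain[s, ] <- cur
    lp[s] <- cur_lp
  }
  list(chain = chain, logpost = lp, burn = burn,
       accept_rate = n_acc / steps, scales = g * sc)
}

#' Posterior covariance estimate from the observed information
#'
#' Numerical Hessian of the composite log-likelihood at a fit's optimum
#' on the transformed parameter scale, inverted (with an eigenvalue
#' floor for near-flat directions) to give a Gaussian approximation of
#' the posterior covariance. Intended as the proposal covariance for
#' [mcmc_demography()], where matching the correlation structure makes
#' short chains mix far better than diagonal proposals.
#'
#' @param fit A `raretree_fit` with free parameters.
#' @param h The fitted `rare_histogram`.
#' @param scale,grid,conditional As in [fit_demography()].
#' @param eps Finite-difference step on the transformed scale.
#' @return A covariance matrix (free parameters, transformed scale).
#' @export
fit_covariance <- function(fit, h, scale = unit_scale(), grid = time_grid(),
                           conditional = FALSE, eps = 0.04) {
  pm <- fit$pmap
  if (is.null(pm)) stop("fit has no free parameters")
  obj <- make_objective(pm, h, scale, grid, conditional)
  y <- pmap_to_transformed(pm, fit$increments)
  d <- length(y)
  H <- matrix(0, d, d)
  f0 <- obj$fn(y)
  fd <- function(dy) obj$fn(y + dy)
  for (i in seq_len(d)) {
    ei <- rep(0, d); ei[i] <- eps
    H[i, i] <- (fd(ei) - 2 * f0 + fd(-ei)) / eps^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- rep(0, d); ej[j] <- eps
      H[i, j] <- H[j, i] <-
        (fd(ei + ej) - fd(ei - ej) - fd(-ei + ej) + fd(-ei - ej)) /
        (4 * eps^2)
    }
  }
  info <- -H
  e <- eigen(info, symmetric = TRUE)
  vals <- pmax(e$values, max(e$values) * 1e-6)
  cov <- e$vectors %*% diag(1 / vals, d) %*% t(e$vectors)
  dimnames(cov) <- list(pm$names, pm$names)
  cov
}

# per-component proposal scales from a finite-difference curvature probe
# at the starting point (falls back to a small default on flat axes)
curvature_scales <- function(fn, y, f0 = fn(y), eps = 0.05) {
  d <- length(y)
  vapply(seq_len(d), function(j) {
    yp <- y; yp[j] <- y[j] + eps
    ym <- y; ym[j] <- y[j] - eps
    h2 <- (fn(yp) - 2 * f0 + fn(ym)) / eps^2
    if (is.finite(h2) && h2 < 0) min(1 / sqrt(-h2), 1) else 0.1
  }, numeric(1)) * 2.4 / sqrt(d)
}

#' Posterior sampling of demographic parameters by MCMC
#'
#' Random-walk Metropolis on the transformed parameters (flat priors on
#' the transformed scale within bounds) with joint Gaussian proposals:
#' per-component scales from a finite-difference curvature probe, or a
#' full proposal covariance (see [fit_covariance()]) which mixes much
#' better when parameters are correlated. A global step factor is
#' adapted toward an acceptance rate of 0.234 during the first 20% of
#' the chain (burn-in, discarded from summaries) and frozen afterwards.
#' Reproducible given `seed`.
#'
#' @param fit A `raretree_fit` (or a `demography` used as template; then
#'   `free` and `h` must be supplied consistently).
#' @param h The `rare_histogram` that was fitted.
#' @param steps Total chain length (including burn-in).
#' @param seed Integer seed. Default 1.
#' @param free Free slots when `fit` is a bare model.
#' @param proposal_cov Optional proposal covariance on the transformed
#'   scale (e.g. from [fit_covariance()]); default is a diagonal
#'   curvature probe.
#' @param scale,grid,conditional As in [fit_demography()].
#' @return An object of class `raretree_mcmc`: the chain (natural-scale
#'   slot values per draw), log-likelihoods, acceptance rate, burn-in
#'   length, and per-parameter summaries (median, central 80% interval).
#' @export
mcmc_demography <- function(fit, h, steps = 500, seed = 1, free = NULL,
                            proposal_cov = NULL, scale = unit_scale(),
                            grid = time_grid(), conditional = FALSE) {
  if (inherits(fit, "demography")) {
    if (is.null(free)) stop("free parameter slots required with a bare model")
    pm <- param_map(fit, free)
    start_x <- pmap_init(pm)
  } else {
    pm <- fit$pmap
    if (is.null(pm)) stop("fit has no free parameters")
    start_x <- fit$increments
  }
  obj <- make_objective(pm, h, scale, grid, conditional)
  y0 <- pmap_to_transformed(pm, start_x)
  if (is.null(proposal_cov)) {
    sc <- curvature_scales(obj$fn, y0)
    r <- rw_metropolis(obj$fn, y0, steps, seed = seed, comp_scale = sc)
  } else {
    ch <- t(chol(proposal_cov)) * 2.4 / sqrt(length(y0))
    r <- rw_metropolis(obj$fn, y0, steps, seed = seed, prop_chol = ch)
  }
  # natural-scale slot values (actual join times, sizes) per draw
  nat <- matrix(NA_real_, nrow(r$chain), length(pm$names),
                dimnames = list(NULL, pm$names))
  for (i in seq_len(nrow(r$chain)))
    nat[i, ] <- pmap_slot_values(pm, pmap_from_transformed(pm, r$chain[i, ]))
  kept <- nat[(r$burn + 1):nrow(nat), , drop = FALSE]
  summ <- tibble::tibble(
    term = pm$names,
    median = apply(kept, 2, stats::median),
    lo80 = apply(kept, 2, stats::quantile, 0.1),
    hi80 = apply(kept, 2, stats::quantile, 0.9))
  structure(list(chain = tibble::as_tibble(as.data.frame(nat)),
                 loglik = r$logpost, burn = r$burn,
                 accept_rate = r$accept_rate, summary = summ,
                 seed = seed, steps = steps),
            class = "raretree_mcmc")
}

#' @export
print.raretree_mcmc <- function(x, ...) {
  cat(sprintf(
    "<raretree_mcmc> %d steps (%d burn-in), acceptance rate %.2f\n",
    x$steps, x$burn, x$accept_rate))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.raretree_mcmc <- function(x, ...) x$summary

#' @export
glance.raretree_mcmc <- function(x, ...) {
  tibble::tibble(steps = x$steps, burn = x$burn,
                 accept_rate = x$accept_rate,
                 logLik_best = max(x$loglik))
}

#' Graft a new population onto a fitted tree, trying candidate branches
#'
#' Implements the step-by-step topology-building protocol: the new
#' population is attached to each candidate branch in turn with a free
#' attachment time and free branch size, the likelihood is maximized,
#' and candidates are returned ranked by log-likelihood.
#'
#' @param fit A `raretree_fit` (or `demography`) for the current tree.
#' @param h A `rare_histogram` including the new population's column.
#' @param new_pop The new population's label in `h`.
#' @param candidates Branch labels to try attaching to (default: all
#'   current branches).
#' @param new_age Sample age of the new population (scaled). Default 0.
#' @param scale,grid,seed As in [fit_demography()].
#' @param ... Passed to [fit_demography()].
#' @return A list of `raretree_fit`, sorted by decreasing log-likelihood,
#'   with attribute `"ranking"` (tibble: candidate, logLik).
#' @export
add_population <- function(fit, h, new_pop, candidates = NULL, new_age = 0,
                           scale = unit_scale(), grid = time_grid(),
                           seed = 1, ...) {
  base <- if (inherits(fit, "raretree_fit")) fit$model else fit
  if (is.null(candidates)) candidates <- base$branches$name
  if (!new_pop %in% h$pops) stop("new population missing from histogram")
  n_new <- h$n[[new_pop]]
  fits <- list()
  for (cand in candidates) {
    # attach halfway up the candidate's remaining segment as a start
    term <- base$joins$time[base$joins$from == cand]
    t_hi <- if (length(term)) term else
      (if (nrow(base$joins)) 2 * max(base$joins$time) else 0.01)
    t_lo <- max(new_age, 0)
    f <- NULL
    # try several starting attachment times; a start colliding with an
    # existing event gives a zero increment and is skipped
    for (frac in c(0.618, 0.3, 0.8, 0.45, 0.9)) {
      t0 <- t_lo + frac * (t_hi - t_lo)
      mm <- demography(
        dplyr::bind_rows(base$branches,
                         tibble::tibble(name = new_pop, lambda = 1,
                                        sample_size = n_new,
                                        sample_age = new_age)),
        dplyr::bind_rows(base$joins,
                         tibble::tibble(time = t0, into = cand,
                                        from = new_pop,
                                        lambda_after = NA_real_)))
      jidx <- which(mm$joins$into == cand & mm$joins$from == new_pop)
      f <- tryCatch(
        fit_demography(mm, h, free = c(paste0("lambda:", new_pop),
                                       paste0("time:", jidx)),
                       scale = scale, grid = grid, seed = seed, ...),
        error = function(e) NULL)
      if (!is.null(f)) break
    }
    if (!is.null(f)) {
      f$candidate <- cand
      fits[[cand]] <- f
    }
  }
  if (!length(fits)) stop("no candidate attachment converged")
  ord <- order(vapply(fits, `[[`, 0, "loglik"), decreasing = TRUE)
  fits <- fits[ord]
  attr(fits, "ranking") <- tibble::tibble(
    candidate = unname(vapply(fits, `[[`, "", "candidate")),
    logLik = unname(vapply(fits, `[[`, 0, "loglik")))
  fits
}
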
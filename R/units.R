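#' Unit scaling between coalescent and real units
#'
#' Internally all times are scaled coalescent times in units of
#' `2 * n_ref` generations and all branch sizes are ratios
#' `lambda = N_branch / n_ref`. The scaled per-site mutation rate is
#' `theta = 2 * n_ref * mu` (mutations per lineage per scaled time unit).
#' Conversion to real units uses the per-generation per-site mutation
#' rate and the generation time:
#' years = scaled_time * 2 * n_ref * gen_years, diploids = lambda * n_ref.
#'
#' @param n_ref Reference diploid effective size used as the internal
#'   scaling constant. Default 20000.
#' @param mu Per-generation per-site mutation rate. Default 1.25e-8.
#' @param gen_years Years per generation. Default 29.
#' @return An object of class `unit_scale`.
#' @examples
#' u <- unit_scale()
#' u$theta # 2 * 20000 * 1.25e-8 = 5e-4
#' @export
unit_scale <- function(n_ref = 20000, mu = 1.25e-8, gen_years = 29) {
  stopifnot(n_ref > 0, mu > 0, gen_years > 0)
  structure(
    list(n_ref = n_ref, mu = mu, gen_years = gen_years,
         theta = 2 * n_ref * mu),
    class = "unit_scale"
  )
}

#' @export
print.unit_scale <- function(x, ...) {
  cat(sprintf(
    "<unit_scale> n_ref = %g diploids, mu = %g /gen/site, generation = %g y, theta = %g\n",
    x$n_ref, x$mu, x$gen_years, x$theta))
  invisible(x)
}

scaled_to_years <- function(t_scaled, scale) {
  t_scaled * 2 * scale$n_ref * scale$gen_years
}

years_to_scaled <- function(years, scale) {
  years / (2 * scale$n_ref * scale$gen_years)
}
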
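# shared toy models and fixtures, built in code

one_pop <- function(n = 2, lambda = 1) {
  demography(tibble::tibble(name = "A", lambda = lambda, sample_size = n))
}

# the 2-population reference design: n = (4, 4), join at 0.002,
# lambda = (1, 0.5), ancestral 2
two_pop <- function() {
  demography(
    tibble::tibble(name = c("A", "B"), lambda = c(1, 0.5),
                   sample_size = c(4, 4)),
    tibble::tibble(time = 0.002, into = "A", from = "B", lambda_after = 2))
}

three_pop <- function(n = c(4, 4, 2)) {
  demography(
    tibble::tibble(name = c("A", "B", "C"), lambda = c(1, 0.5, 2),
                   sample_size = n),
    tibble::tibble(time = c(0.002, 0.005), into = c("A", "A"),
                   from = c("B", "C"), lambda_after = c(2, 1)))
}

# a six-branch ladder tree with ordered joins (shape of a European-style
# caterpillar phylogeny)
six_pop <- function() {
  demography(
    tibble::tibble(name = paste0("P", 1:6), lambda = c(2, 1, 0.6, 3, 1.5, 1),
                   sample_size = rep(4L, 6)),
    tibble::tibble(time = c(0.003, 0.0035, 0.004, 0.0045, 0.006),
                   into = c("P5", "P4", "P3", "P2", "P1"),
                   from = c("P6", "P5", "P4", "P3", "P2"),
                   lambda_after = c(1.2, 1.4, 1.1, 1.0, 1.0)))
}

toy_histogram <- function() {
  rare_histogram(
    pops = c("A", "B"), n = c(4, 4),
    counts = tibble::tibble(A = c(1L, 1L, 0L), B = c(0L, 2L, 1L),
                            sites = c(57, 11, 40)),
    max_m = 4, monomorphic = 880, overflow = 12)
}
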
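# shared fixtures and small statistical helpers for the test suite

# default parameter set used throughout: N = 1000, VS = 2N (delta = 1),
# equal selection shares
test_params <- function(U = NA_real_) {
  suppressWarnings(model_params(N = 1000, U = U))
}

# mean +/- 1.96 * SEM from contiguous batch means of a (possibly
# autocorrelated) stationary series; stat is applied per batch
batch_ci <- function(x, nbatch = 10, stat = mean) {
  n <- length(x)
  idx <- cut(seq_len(n), nbatch, labels = FALSE)
  bs <- vapply(split(x, idx), stat, numeric(1))
  m <- mean(bs)
  half <- 1.96 * stats::sd(bs) / sqrt(nbatch)
  c(mean = m, lo = m - half, hi = m + half)
}

ci_covers <- function(ci, value) ci[["lo"]] <= value && value <= ci[["hi"]]

# a small hand-built state: two alleles with known effects
toy_state <- function() {
  population_state(af = c(1, 0.5), am = c(1, -0.5), x = c(0.25, 0.5),
                   Ff = 0.2, Fm = -0.1, generation = 5L)
}
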
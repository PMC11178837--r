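# shared fixtures and independent oracles for the test suite

# simulate a clean recording at the analysis rate and cut it into epochs
make_epochs <- function(truth, n_epochs = 24, epoch_len = 5, fs = 200,
                        seed = 1, normalize = TRUE) {
  rec <- simulate_var_recording(truth, nuisance_spec(),
                                duration = n_epochs * epoch_len, fs = fs,
                                seed = seed)
  if (normalize) rec <- normalize_recordings(rec)
  segment_epochs(rec, epoch_len)
}

# single-bin periodogram power of x at frequency f (f assumed on the
# DFT grid)
periodogram_power <- function(x, fs, f) {
  n <- length(x)
  k <- round(f * n / fs)
  Mod(fft(x)[k + 1])^2 / n
}

# expected periodogram power of a unit-amplitude sinusoid aligned with
# a DFT bin: |X|^2/n = (a n / 2)^2 / n = a^2 n / 4
sinusoid_peak_power <- function(amp, n) amp^2 * n / 4

# exhaustive-enumeration oracle for the discrimination ratio of one set
# of per-trial counts (matches the strict-inequality definition but is
# computed from first principles, no package code)
enum_ratio <- function(splus, sminus) {
  f1 <- sum(vapply(splus, function(s) all(s > sminus), TRUE)) / length(splus)
  f2 <- sum(vapply(sminus, function(s) all(s < splus), TRUE)) / length(sminus)
  f1 * f2
}

# expected discrimination ratio when correct counts are iid Poisson
# (lam_plus) and incorrect counts iid Poisson (lam_minus), n_plus and
# n_minus trials: E[f1 f2] by exchangeability equals
# P(s+_1 > max S-  and  s-_1 < min S+), enumerated over a truncated
# count grid
enum_expected_ratio <- function(lam_plus, lam_minus, n_plus, n_minus,
                                kmax = 40) {
  pp <- dpois(0:kmax, lam_plus)
  pm <- dpois(0:kmax, lam_minus)
  Fm <- ppois(0:kmax, lam_minus)   # cdf of incorrect counts
  Fp <- ppois(0:kmax, lam_plus)    # cdf of correct counts
  tot <- 0
  for (a in 1:kmax) for (b in 0:(a - 1)) {
    p_rest_minus <- if (a >= 1) Fm[a]^(n_minus - 1) else 0  # all others < a
    p_rest_plus <- (1 - Fp[b + 1])^(n_plus - 1)             # all others > b
    tot <- tot + pp[a + 1] * pm[b + 1] * p_rest_minus * p_rest_plus
  }
  tot
}

# brute-force Benjamini-Hochberg step-up, straight from the definition
bh_stepup <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= (seq_len(m) / m) * alpha)
  flags <- logical(m)
  if (length(k)) flags[o[seq_len(max(k))]] <- TRUE
  flags
}

# exact two-sided rank-sum p-value by enumerating every group labelling
# (small samples, no ties assumed handled by half-credit U)
enum_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a); m <- length(b)
  combs <- utils::combn(n + m, m)
  u_obs <- sum(outer(b, a, function(x, y) (x > y) + 0.5 * (x == y)))
  us <- apply(combs, 2, function(idx) {
    bb <- pooled[idx]; aa <- pooled[-idx]
    sum(outer(bb, aa, function(x, y) (x > y) + 0.5 * (x == y)))
  })
  mu <- n * m / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# tiny bivariate truth with a one-way coupling, used across tests
coupled_bivariate_truth <- function(coef = 0.5) {
  A <- matrix(c(0.5, 0, coef, 0.4), 2, 2, byrow = TRUE)
  var_ground_truth(list(A))
}
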
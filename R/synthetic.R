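#' VAR ground truth for synthetic recordings
#'
#' Specifies the generative model behind synthetic LFP: a stationary
#' vector autoregression with a known directed coefficient graph and
#' innovation covariance.  Downstream stages (VAR fitting, spectral
#' Granger causality, group inference) are validated by recovering this
#' known structure.
#'
#' @param coeffs list of p square coefficient matrices (channels x
#'   channels); element k is the lag-k matrix, entry `[i, j]` the
#'   influence of channel j at lag k on channel i.
#' @param noise_cov innovation covariance; must be symmetric positive
#'   definite.  Defaults to the identity.
#' @param region_labels channel/site names.
#'
#' @return An object of class `var_truth` with fields `n_channels`,
#'   `order`, `coeffs`, `noise_cov`, `region_labels`.
#' @export
var_ground_truth <- function(coeffs, noise_cov = NULL,
                             region_labels = NULL) {
  if (is.matrix(coeffs)) coeffs <- list(coeffs)
  n <- nrow(coeffs[[1]])
  for (A in coeffs)
    if (!is.matrix(A) || nrow(A) != n || ncol(A) != n)
      stop("every coefficient matrix must be ", n, " x ", n)
  if (is.null(noise_cov)) noise_cov <- diag(n)
  noise_cov <- as.matrix(noise_cov)
  if (nrow(noise_cov) != n || ncol(noise_cov) != n ||
      max(abs(noise_cov - t(noise_cov))) > 1e-10)
    stop("noise_cov must be a symmetric ", n, " x ", n, " matrix")
  ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("noise_cov must be positive definite")
  if (is.null(region_labels)) region_labels <- paste0("ch", seq_len(n))
  if (length(region_labels) != n) stop("need one region label per channel")
  coeffs <- lapply(coeffs, function(A) {
    dimnames(A) <- list(region_labels, region_labels); A
  })
  dimnames(noise_cov) <- list(region_labels, region_labels)
  truth <- structure(
    list(n_channels = n, order = length(coeffs), coeffs = coeffs,
         noise_cov = noise_cov, region_labels = as.character(region_labels)),
    class = "var_truth")
  rho <- companion_spectral_radius(truth)
  if (rho >= 1)
    stop(sprintf("non-stationary VAR: companion spectral radius %.4f >= 1", rho))
  truth
}

#' @export
print.var_truth <- function(x, ...) {
  cat(sprintf("<var_truth> %d channels, order %d, spectral radius %.3f\n",
              x$n_channels, x$order, companion_spectral_radius(x)))
  invisible(x)
}

companion_matrix <- function(coeffs) {
  n <- nrow(coeffs[[1]]); p <- length(coeffs)
  A <- matrix(0, n * p, n * p)
  A[seq_len(n), ] <- do.call(cbind, coeffs)
  if (p > 1)
    A[(n + 1):(n * p), seq_len(n * (p - 1))] <- diag(n * (p - 1))
  A
}

#' Spectral radius of the VAR companion matrix
#'
#' Values below 1 certify stationarity of the process.
#'
#' @param x a `var_truth` or `var_model`, or a list of coefficient
#'   matrices.
#' @return The largest eigenvalue modulus of the companion matrix.
#' @export
companion_spectral_radius <- function(x) {
  coeffs <- if (is.list(x) && !is.null(x$coeffs)) x$coeffs else x
  max(Mod(eigen(companion_matrix(coeffs), only.values = TRUE)$values))
}

#' Default six-site ground truth
#'
#' A stationary VAR(2) over the six recorded regions (PRL, IL, NAcC,
#' NAcS, dCA1, vCA1).  Each site carries AR(2) dynamics with
#' coefficients (1.7, -0.72), i.e. real poles at 0.9 and 0.8: strongly
#' autocorrelated, low-frequency-dominated signals whose persistence
#' survives down-sampling, so fitted models clear the R-squared
#' adequacy gate the way resting-state LFP does.  Five
#' directed lag-1 couplings form the true causal graph, with the
#' accumbens core as the dominant source (mirroring the kind of
#' core-centred connectivity the analysis is designed to resolve):
#' NAcC->NAcS (0.25), NAcC->IL (0.20), PRL->dCA1 (0.20), dCA1->NAcS
#' (0.15), vCA1->dCA1 (0.20).
#'
#' @param edge_scale named numeric vector of multipliers applied to
#'   individual true edges, named `"source->target"`; used to create
#'   alternative (e.g. coupling-halved) genotypes.
#' @return A `var_truth`.
#' @export
default_ground_truth <- function(edge_scale = NULL) {
  regions <- c("PRL", "IL", "NAcC", "NAcS", "dCA1", "vCA1")
  n <- length(regions)
  A1 <- diag(1.7, n); A2 <- diag(-0.72, n)
  edges <- list(c("NAcC", "NAcS", 0.25), c("NAcC", "IL", 0.20),
                c("PRL", "dCA1", 0.20), c("dCA1", "NAcS", 0.15),
                c("vCA1", "dCA1", 0.20))
  dimnames(A1) <- dimnames(A2) <- list(regions, regions)
  for (e in edges) {
    w <- as.numeric(e[3])
    key <- paste0(e[1], "->", e[2])
    if (!is.null(edge_scale) && key %in% names(edge_scale))
      w <- w * edge_scale[[key]]
    A1[e[2], e[1]] <- w
  }
  var_ground_truth(list(A1, A2), region_labels = regions)
}

#' True directed edges of the default ground truth
#' @return data.frame with columns `source`, `target`.
#' @export
default_true_edges <- function() {
  data.frame(source = c("NAcC", "NAcC", "PRL", "dCA1", "vCA1"),
             target = c("NAcS", "IL", "dCA1", "NAcS", "dCA1"),
             stringsAsFactors = FALSE)
}

#' Nuisance components added to synthetic LFP
#'
#' Line-frequency contamination and transient high-amplitude movement
#' artifacts, the two nuisance features the preprocessing stage must
#' remove.  Artifacts are boxcar offsets of `artifact_amp` signal
#' standard deviations lasting `artifact_dur` seconds, placed by a
#' Poisson process with rate `artifact_rate` per minute.
#'
#' @param line_freq line frequency in Hz (default 50).
#' @param line_amp sinusoid amplitude per channel, in signal SD units.
#' @param artifact_rate events per minute.
#' @param artifact_amp boxcar height in multiples of the channel SD.
#' @param artifact_dur boxcar duration in seconds.
#' @return An object of class `nuisance_spec`.
#' @export
nuisance_spec <- function(line_freq = 50, line_amp = 0, artifact_rate = 0,
                          artifact_amp = 10, artifact_dur = 0.5) {
  vals <- c(line_freq, line_amp, artifact_rate, artifact_amp, artifact_dur)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all nuisance parameters must be finite and non-negative")
  structure(list(line_freq = line_freq, line_amp = line_amp,
                 artifact_rate = artifact_rate, artifact_amp = artifact_amp,
                 artifact_dur = artifact_dur),
            class = "nuisance_spec")
}

simulate_var_signals <- function(truth, n_samples, burn) {
  cf <- do.call(cbind, truth$coeffs)
  L <- t(chol(truth$noise_cov))
  var_sim_cpp(cf, L, as.integer(n_samples), as.integer(burn))
}

#' Simulate an LFP-like recording from a VAR ground truth
#'
#' Draws a stationary VAR realisation (a burn-in of `10 * order` samples,
#' at least 0.5 s, is discarded), then adds the nuisance components:
#' a line-frequency sinusoid and Poisson-placed boxcar artifacts.
#' Deterministic for a fixed seed.
#'
#' @param truth a [var_ground_truth()].
#' @param nuisance a [nuisance_spec()]; default adds nothing.
#' @param duration recording length in seconds.
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @param animal_id,genotype recording metadata.
#' @return An [lfp_recording()].
#' @export
simulate_var_recording <- function(truth, nuisance = nuisance_spec(),
                                   duration = 600, fs = 1017, seed = 1,
                                   animal_id = "animal1", genotype = "WT") {
  stopifnot(inherits(truth, "var_truth"), inherits(nuisance, "nuisance_spec"))
  rho <- companion_spectral_radius(truth)
  if (rho >= 1)
    stop(sprintf("non-stationary truth (companion spectral radius %.4f)", rho))
  if (nuisance$line_amp > 0 && fs <= 2 * nuisance$line_freq)
    stop("fs must exceed twice the line frequency")
  n_samples <- floor(duration * fs)
  if (n_samples < 100 * truth$order)
    stop("recording too short: need at least 100 * order samples")
  burn <- max(10 * truth$order, ceiling(0.5 * fs))
  set.seed(seed)
  y <- simulate_var_signals(truth, n_samples, burn)

  if (nuisance$line_amp > 0) {
    tt <- (seq_len(n_samples) - 1) / fs
    sds <- apply(y, 1, sd)
    line <- sin(2 * pi * nuisance$line_freq * tt)
    y <- y + (nuisance$line_amp * sds) %o% line
  }
  if (nuisance$artifact_rate > 0) {
    n_events <- rpois(1, nuisance$artifact_rate * duration / 60)
    if (n_events > 0) {
      onsets <- floor(runif(n_events, 0, n_samples - 1)) + 1
      len <- max(1L, round(nuisance$artifact_dur * fs))
      sds <- apply(y, 1, sd)
      for (o in onsets) {
        idx <- o:min(o + len - 1L, n_samples)
        y[, idx] <- y[, idx] + nuisance$artifact_amp * sds
      }
      attr(y, "artifact_onsets") <- onsets
    }
  }
  rec <- lfp_recording(y, fs = fs, region_labels = truth$region_labels,
                       animal_id = animal_id, genotype = genotype)
  rec$seed <- seed
  rec
}

# Accumulated Gram matrix of [y_t, lags 1..P] across contiguous segments.
# segments: list of channels x samples matrices.  Returns list(G, mean
# vector, nobs); all regressions for any channel subset and any order
# <= P can be read off sub-blocks of G.
lag_gram <- function(segments, P) {
  if (is.matrix(segments)) segments <- list(segments)
  n <- nrow(segments[[1]])
  m <- n * (P + 1)
  G <- matrix(0, m, m); s <- numeric(m); nobs <- 0
  for (seg in segments) {
    out <- lag_gram_cpp(seg, as.integer(P))
    G <- G + out$G; s <- s + out$s; nobs <- nobs + out$nobs
  }
  list(G = G, s = s, nobs = nobs, n = n, P = P)
}

# Residual variance of regressing channel `target` on lags 1..p of the
# channel subset `predictors`, from an accumulated lag Gram matrix.
gram_residual_variance <- function(gram, target, predictors, p) {
  stopifnot(p <= gram$P)
  n <- gram$n
  yi <- target                                  # column of y_t block
  xi <- as.vector(outer(predictors, n * seq_len(p), `+`))  # lag blocks
  Syy <- gram$G[yi, yi] / gram$nobs
  Sxy <- gram$G[xi, yi] / gram$nobs
  Sxx <- gram$G[xi, xi, drop = FALSE] / gram$nobs
  beta <- solve(Sxx, Sxy)
  drop(Syy - crossprod(Sxy, beta))
}

#' Population pairwise-conditional Granger causality by long simulation
#'
#' The parameter-recovery oracle for the state-space spectral pipeline:
#' simulates a long realisation of the ground truth (default 1e6
#' samples) and computes time-domain conditional Granger causality from
#' `source` to `target` given all remaining channels as the log ratio of
#' reduced- to full-model residual variances from least-squares
#' regressions.  Both regressions use `order_regress` lags (default
#' `max(20, 4 * order)`) so the reduced model, which is generically
#' VARMA, is well approximated by a finite autoregression.
#'
#' This function is deliberately independent of the state-space
#' computation in [spectral_gc()]: it knows nothing about Riccati
#' equations and serves as its cross-check.
#'
#' @param truth a [var_ground_truth()].
#' @param source,target channel indices or region names.
#' @param n_samples realisation length.
#' @param order_regress lag order used for both regressions.
#' @param seed simulation seed.
#' @return Granger causality in nats (non-negative up to Monte-Carlo
#'   error).
#' @export
true_timedomain_gc <- function(truth, source, target, n_samples = 1e6,
                               order_regress = NULL, seed = 1) {
  stopifnot(inherits(truth, "var_truth"))
  src <- resolve_channel(truth$region_labels, source)
  tgt <- resolve_channel(truth$region_labels, target)
  if (src == tgt) stop("source and target must differ")
  if (is.null(order_regress)) order_regress <- max(20L, 4L * truth$order)
  set.seed(seed)
  y <- simulate_var_signals(truth, n_samples, burn = 100 * truth$order)
  gram <- lag_gram(y, order_regress)
  gc_from_gram(gram, src, tgt, order_regress)
}

# shared between the oracle and tests that reuse one long realisation
gc_from_gram <- function(gram, src, tgt, p) {
  n <- gram$n
  v_full <- gram_residual_variance(gram, tgt, seq_len(n), p)
  v_red <- gram_residual_variance(gram, tgt, setdiff(seq_len(n), src), p)
  log(v_red / v_full)
}

resolve_channel <- function(labels, ch) {
  if (is.character(ch)) {
    i <- match(ch, labels)
    if (is.na(i)) stop("unknown channel: ", ch)
    return(i)
  }
  i <- as.integer(ch)
  if (i < 1 || i > length(labels)) stop("channel index out of range: ", ch)
  i
}

#' Draw a random stable VAR ground truth
#'
#' Utility for property-style fuzz tests: draws sparse random coefficient
#' matrices and rescales the companion matrix until the spectral radius
#' is at most `max_radius`.
#'
#' @param n_channels,order model dimensions.
#' @param density probability that an off-diagonal coefficient is
#'   nonzero.
#' @param max_radius target bound on the companion spectral radius.
#' @param seed integer seed.
#' @return A `var_truth`.
#' @export
random_stable_truth <- function(n_channels = 6, order = 2, density = 0.15,
                                max_radius = 0.8, seed = 1) {
  set.seed(seed)
  coeffs <- lapply(seq_len(order), function(k) {
    A <- matrix(rnorm(n_channels^2, sd = 0.3), n_channels)
    mask <- matrix(runif(n_channels^2) < density, n_channels)
    diag(mask) <- TRUE
    A * mask / k
  })
  rho <- max(Mod(eigen(companion_matrix(coeffs), only.values = TRUE)$values))
  if (rho > max_radius) {
    sc <- max_radius / rho
    coeffs <- lapply(seq_along(coeffs), function(k) coeffs[[k]] * sc^k)
  }
  var_ground_truth(coeffs)
}
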
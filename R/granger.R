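#' Canonical frequency bands
#'
#' The six analysis bands: delta 2-4, theta 6-10, beta 15-25, low gamma
#' 35-45, mid gamma 55-75 and high gamma 70-90 Hz.  The mid- and
#' high-gamma bands overlap by construction and are integrated
#' independently.
#'
#' @return data.frame with columns `band`, `lo`, `hi`.
#' @export
canonical_bands <- function() {
  data.frame(band = c("delta", "theta", "beta", "gamma_low", "gamma_mid",
                      "gamma_high"),
             lo = c(2, 6, 15, 35, 55, 70),
             hi = c(4, 10, 25, 45, 75, 90),
             stringsAsFactors = FALSE)
}

check_bands <- function(bands, fmax = 100) {
  need <- c("band", "lo", "hi")
  if (!all(need %in% names(bands))) stop("bands need columns band, lo, hi")
  if (any(bands$lo <= 0) || any(bands$lo >= bands$hi) || any(bands$hi > fmax))
    stop("invalid band limits: need 0 < lo < hi <= ", fmax)
  invisible(bands)
}

# innovations state-space form of a VAR: z_t = [y_{t-1},...,y_{t-p}],
# z_{t+1} = A z_t + K e_t,  y_t = C z_t + e_t
var_to_ss <- function(coeffs, sigma) {
  n <- nrow(sigma)
  A <- companion_matrix(coeffs)
  C <- do.call(cbind, coeffs)
  K <- rbind(diag(n), matrix(0, n * (length(coeffs) - 1), n))
  list(A = A, C = C, K = K, V = sigma)
}

# VAR transfer function Psi(lambda) = (I - sum_k A_k e^{-i k lambda})^{-1}
var_transfer <- function(coeffs, lambda) {
  n <- nrow(coeffs[[1]])
  M <- diag(n) + 0i
  for (k in seq_along(coeffs))
    M <- M - coeffs[[k]] * exp(-1i * k * lambda)
  solve(M)
}

# Spectral factor of the reduced model obtained by dropping the source
# channel: returns a function applying the reduced model's inverse
# transfer function B_r(lambda) to a complex vector, via an
# eigendecomposition of (A - K_r C_r) when well conditioned.
reduced_system <- function(ss, r, method = "sda") {
  m <- nrow(ss$A); n <- nrow(ss$V)
  Cr <- ss$C[r, , drop = FALSE]
  Q <- ss$K %*% ss$V %*% t(ss$K)
  sol <- solve_dare(ss$A, Cr, Q, ss$V[r, r, drop = FALSE],
                    S = ss$K %*% ss$V[, r, drop = FALSE], method = method)
  Abar <- ss$A - sol$K %*% Cr
  eg <- tryCatch(eigen(Abar), error = function(e) NULL)
  use_eig <- FALSE
  if (!is.null(eg) && all(is.finite(Mod(eg$values)))) {
    kappa <- tryCatch(rcond(eg$vectors), error = function(e) 0)
    if (is.finite(kappa) && kappa > 1e-9) {
      W1 <- Cr %*% eg$vectors
      W2 <- solve(eg$vectors, sol$K)
      use_eig <- TRUE
    }
  }
  apply_B <- if (use_eig) {
    function(lambda, v) {
      # B_r v = v - C_r (e^{i lambda} I - Abar)^{-1} K_r v
      v - W1 %*% ((W2 %*% v) / (exp(1i * lambda) - eg$values))
    }
  } else {
    function(lambda, v) {
      v - Cr %*% solve(diag(m) * exp(1i * lambda) - Abar, sol$K %*% v)
    }
  }
  list(Vr = sol$V, apply_B = apply_B)
}

#' Spectral pairwise-conditional Granger causality
#'
#' For every ordered channel pair (source j, target i), the Granger
#' causality from j to i conditional on all remaining channels, resolved
#' over frequency.  The fitted VAR is recast in innovations state-space
#' form; for each source the "reduced" model that omits the source
#' channel is obtained exactly by solving a discrete algebraic Riccati
#' equation (no reduced VAR is fitted), and the conditional spectral
#' value at frequency lambda is
#' `log V_R\[ii\] - log(V_R\[ii\] - |G_ij(lambda)|^2 sigma_j|rest)`,
#' where `V_R` is the reduced model's innovation covariance, `G` the
#' transfer function from the full innovations to the reduced
#' innovations, and `sigma_j|rest` the partial variance of the source
#' innovation.  Values are non-negative; anything below `1e-12` is
#' clipped to zero to absorb round-off.
#'
#' @param model a stable `var_model` (or a `var_truth`, giving
#'   population values).
#' @param freq frequency grid in Hz, inside `(0, fs/2]`; default 0.25 Hz
#'   spacing over (0, 100].
#' @param fs sampling rate; taken from the model when present.
#' @return An object of class `spectral_gc`: list with `gc`, an array
#'   `[target, source, frequency]` (diagonal `NA`), `freq`, `fs`,
#'   `region_labels`.
#' @export
spectral_gc <- function(model, freq = NULL, fs = NULL) {
  if (inherits(model, "var_truth"))
    model <- list(coeffs = model$coeffs, noise_cov = model$noise_cov,
                  region_labels = model$region_labels, fs = fs,
                  stable = TRUE,
                  spectral_radius = companion_spectral_radius(model))
  if (is.null(fs)) fs <- model$fs
  if (is.null(fs)) stop("sampling rate unknown; supply fs")
  if (is.null(freq)) freq <- seq(0.25, min(100, fs / 2), by = 0.25)
  if (any(freq <= 0) || any(freq > fs / 2 + 1e-9))
    stop("frequency grid must lie in (0, fs/2]")
  if (!isTRUE(model$stable))
    stop(sprintf("unstable VAR (spectral radius %.4f): spectral GC undefined",
                 model$spectral_radius))
  lambdas <- 2 * pi * freq / fs
  g <- spectral_gc_core(model$coeffs, model$noise_cov, lambdas)
  dimnames(g) <- list(model$region_labels, model$region_labels, NULL)
  structure(list(gc = g, freq = freq, fs = fs,
                 region_labels = model$region_labels),
            class = "spectral_gc")
}

# gc array [target, source, lambda] on an angular-frequency grid
spectral_gc_core <- function(coeffs, sigma, lambdas, floor_at = 1e-12) {
  n <- nrow(sigma)
  ss <- var_to_ss(coeffs, sigma)
  red <- vector("list", n)
  vpar <- numeric(n)
  for (j in seq_len(n)) {
    r <- setdiff(seq_len(n), j)
    red[[j]] <- tryCatch(reduced_system(ss, r), error = function(e)
      stop("spectral GC failed for source channel ", j, ": ",
           conditionMessage(e), call. = FALSE))
    vpar[j] <- sigma[j, j] -
      drop(sigma[j, r] %*% solve(sigma[r, r, drop = FALSE], sigma[r, j]))
  }
  g <- array(NA_real_, dim = c(n, n, length(lambdas)))
  for (k in seq_along(lambdas)) {
    Psi <- var_transfer(coeffs, lambdas[k])
    for (j in seq_len(n)) {
      r <- setdiff(seq_len(n), j)
      gcol <- red[[j]]$apply_B(lambdas[k], Psi[r, j, drop = FALSE])
      vr <- diag(red[[j]]$Vr)
      num <- Mod(gcol)^2 * vpar[j]
      val <- log(vr) - log(pmax(vr - num, .Machine$double.xmin))
      val[val < floor_at] <- 0
      g[r, j, k] <- val
    }
  }
  g
}

#' @export
print.spectral_gc <- function(x, ...) {
  cat(sprintf("<spectral_gc> %d channels, %d frequencies (%.2f-%.2f Hz @ %g Hz)\n",
              dim(x$gc)[1], length(x$freq), min(x$freq), max(x$freq), x$fs))
  invisible(x)
}

#' Time-domain conditional Granger causality, state-space route
#'
#' The time-domain pairwise-conditional value
#' `log(V_R[ii] / V[ii])` from the reduced-model Riccati solution.  Its
#' average over the frequency circle is (to numerical tolerance) the
#' mean of the spectral decomposition returned by [spectral_gc()].
#'
#' @param model a `var_model` or `var_truth`.
#' @param source,target channel indices or names.
#' @return GC in nats.
#' @export
timedomain_gc_ss <- function(model, source, target) {
  coeffs <- model$coeffs
  sigma <- model$noise_cov
  labels <- model$region_labels
  src <- resolve_channel(labels, source)
  tgt <- resolve_channel(labels, target)
  ss <- var_to_ss(coeffs, sigma)
  r <- setdiff(seq_len(nrow(sigma)), src)
  red <- reduced_system(ss, r)
  pos <- match(tgt, r)
  log(red$Vr[pos, pos] / sigma[tgt, tgt])
}

#' Mean of spectral GC over the full frequency circle
#'
#' Trapezoidal average of the conditional spectral GC over angular
#' frequencies `[0, pi]` (the spectrum is symmetric, so this equals the
#' full-circle mean).  Used to check the Geweke integral identity
#' against the time-domain value.
#'
#' @param model a `var_model` or `var_truth`.
#' @param source,target channel indices or names.
#' @param n_freq number of grid intervals.
#' @return Mean spectral GC in nats.
#' @export
spectral_gc_circle_mean <- function(model, source, target, n_freq = 1024) {
  coeffs <- model$coeffs
  sigma <- model$noise_cov
  labels <- model$region_labels
  src <- resolve_channel(labels, source)
  tgt <- resolve_channel(labels, target)
  lambdas <- seq(0, pi, length.out = n_freq + 1)
  g <- spectral_gc_core(coeffs, sigma, lambdas)
  f <- g[tgt, src, ]
  (sum(f) - (f[1] + f[n_freq + 1]) / 2) / n_freq  # trapezoid mean

}

#' Band-limited Granger causality
#'
#' Trapezoidal integral of the spectral GC over `[lo, hi]` in Hz (units
#' nats x Hz); band endpoints off the grid are linearly interpolated.
#' `reduce = "mean"` divides by the band width, returning the band-mean
#' instead of the integral.
#'
#' @param sgc a [spectral_gc()].
#' @param lo,hi band limits in Hz; must be covered by the grid.
#' @param reduce `"integral"` (default) or `"mean"`.
#' @return Matrix `[target, source]` of band values (diagonal `NA`).
#' @export
band_integral <- function(sgc, lo, hi, reduce = c("integral", "mean")) {
  stopifnot(inherits(sgc, "spectral_gc"))
  reduce <- match.arg(reduce)
  fr <- sgc$freq
  if (lo < min(fr) - 1e-9 || hi > max(fr) + 1e-9 || lo >= hi)
    stop(sprintf("band [%g, %g] outside the frequency grid [%g, %g]",
                 lo, hi, min(fr), max(fr)))
  inside <- which(fr > lo + 1e-12 & fr < hi - 1e-12)
  if (length(inside) >= 2 && max(diff(fr[inside])) > 0.5 + 1e-9)
    stop("grid resolution coarser than 0.5 Hz inside the band")
  grid <- sort(unique(c(lo, fr[inside], hi)))
  n <- dim(sgc$gc)[1]
  out <- matrix(NA_real_, n, n,
                dimnames = list(sgc$region_labels, sgc$region_labels))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    y <- approx(fr, sgc$gc[i, j, ], xout = grid, rule = 2)$y
    v <- sum(diff(grid) * (head(y, -1) + y[-1]) / 2)
    out[i, j] <- if (reduce == "mean") v / (hi - lo) else v
  }
  out
}

#' Band-limited GC table for one animal
#'
#' Applies [band_integral()] over a band table and returns a tidy
#' data.frame.
#'
#' @param sgc a [spectral_gc()].
#' @param bands band table (see [canonical_bands()]).
#' @param reduce passed to [band_integral()].
#' @param animal_id,genotype metadata columns attached to the output.
#' @return data.frame with columns `animal`, `genotype`,
#'   `source_region`, `target_region`, `band`, `gc_value`.
#' @export
band_gc <- function(sgc, bands = canonical_bands(),
                    reduce = c("integral", "mean"),
                    animal_id = "animal1", genotype = "WT") {
  stopifnot(inherits(sgc, "spectral_gc"))
  reduce <- match.arg(reduce)
  check_bands(bands, fmax = sgc$fs / 2)
  labels <- sgc$region_labels
  n <- length(labels)
  rows <- lapply(seq_len(nrow(bands)), function(b) {
    M <- band_integral(sgc, bands$lo[b], bands$hi[b], reduce = reduce)
    idx <- which(!is.na(M), arr.ind = TRUE)
    data.frame(animal = animal_id, genotype = genotype,
               source_region = labels[idx[, "col"]],
               target_region = labels[idx[, "row"]],
               band = bands$band[b], gc_value = M[idx],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Band-limited GC for a cohort of epoch sets
#'
#' Per animal: AIC order selection, VAR fit, adequacy gating, spectral
#' conditional GC on the frequency grid, and band integration.  Animals
#' failing the adequacy gates (multivariate R-squared, residual
#' whiteness, model consistency) are excluded with their reason recorded
#' in the returned `qc` table -- never silently dropped.  With
#' `qc_action = "warn"` failing animals are kept but flagged; with
#' `"none"` the gates are not evaluated against thresholds.
#'
#' @param epoch_sets list of `epoch_set`s, one per animal.
#' @param max_order AIC search range; alternatively fix the order with
#'   `order`.
#' @param order optional fixed VAR order (skips AIC).
#' @param freq frequency grid in Hz (default 0.25 Hz over (0, 100]).
#' @param bands band table.
#' @param reduce band reduction, `"integral"` or `"mean"`.
#' @param qc list of gate thresholds
#'   (`r2_min = 0.3`, `consistency_min = 80`, `require_whiteness = TRUE`).
#' @param qc_action `"enforce"`, `"warn"` or `"none"`.
#' @return A list of class `band_gc_cohort`: `band_gc` (tidy table over
#'   included animals), `qc` (per-animal diagnostics and inclusion
#'   flag), `models` (fitted `var_model`s).
#' @export
gc_cohort <- function(epoch_sets, max_order = 30, order = NULL,
                      freq = NULL, bands = canonical_bands(),
                      reduce = c("integral", "mean"),
                      qc = list(), qc_action = c("enforce", "warn", "none")) {
  reduce <- match.arg(reduce)
  qc_action <- match.arg(qc_action)
  qc <- modifyList(list(r2_min = 0.3, consistency_min = 80,
                        require_whiteness = TRUE), qc)
  tabs <- list(); qcs <- list(); models <- list()
  for (eps in epoch_sets) {
    if (length(eps$region_labels) < 2)
      stop("need at least 2 channels per animal (", eps$animal_id, ")")
    p <- if (is.null(order)) select_var_order(eps, max_order)$order else order
    model <- fit_var(eps, p)
    reasons <- character()
    if (qc_action != "none") {
      di <- model$diagnostics
      if (di$r_squared <= qc$r2_min)
        reasons <- c(reasons, sprintf("R2 %.1f%% <= %.0f%%",
                                      100 * di$r_squared, 100 * qc$r2_min))
      if (qc$require_whiteness && !di$whiteness_ok)
        reasons <- c(reasons, "residual whiteness rejected (Durbin-Watson)")
      if (!is.na(di$consistency) && di$consistency < qc$consistency_min)
        reasons <- c(reasons, sprintf("consistency %.1f%% < %.0f%%",
                                      di$consistency, qc$consistency_min))
      if (!model$stable) reasons <- c(reasons, "unstable fitted VAR")
    }
    include <- length(reasons) == 0 || qc_action != "enforce"
    qcs[[length(qcs) + 1L]] <- data.frame(
      animal = eps$animal_id, genotype = eps$genotype, order = p,
      r_squared = model$diagnostics$r_squared,
      consistency = model$diagnostics$consistency,
      whiteness_ok = model$diagnostics$whiteness_ok,
      stable = model$stable, included = include,
      reason = if (length(reasons)) paste(reasons, collapse = "; ") else "",
      stringsAsFactors = FALSE)
    if (length(reasons) && qc_action == "warn")
      warning(eps$animal_id, ": ", paste(reasons, collapse = "; "))
    models[[eps$animal_id]] <- model
    if (!include) next
    sgc <- spectral_gc(model, freq = freq)
    tabs[[length(tabs) + 1L]] <- band_gc(sgc, bands = bands, reduce = reduce,
                                         animal_id = eps$animal_id,
                                         genotype = eps$genotype)
  }
  structure(list(band_gc = do.call(rbind, tabs),
                 qc = do.call(rbind, qcs), models = models),
            class = "band_gc_cohort")
}

#' @export
print.band_gc_cohort <- function(x, ...) {
  cat(sprintf("<band_gc_cohort> %d animals (%d included), %d band x pair values\n",
              nrow(x$qc), sum(x$qc$included),
              if (is.null(x$band_gc)) 0L else nrow(x$band_gc)))
  invisible(x)
}
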
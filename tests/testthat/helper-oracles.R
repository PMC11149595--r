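# Independent oracles used across tests: kept deliberately naive and
# separate from the implementation paths they check.

# absorbed dose of d0*exp(-lambda*t) by adaptive quadrature on [0, 20/lambda]
# plus the analytic tail
quad_ad <- function(d0, lambda) {
  head <- stats::integrate(function(t) d0 * exp(-lambda * t),
                           lower = 0, upper = 20 / lambda,
                           rel.tol = 1e-10)$value
  head + d0 / lambda * exp(-20)
}

# pool-adjacent-violators on (already volume-ordered) values
pav <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  val <- y; wt <- w; idx <- as.list(seq_len(n))
  i <- 1L
  while (i < length(val)) {
    if (val[i] > val[i + 1L]) {
      val[i] <- (val[i] * wt[i] + val[i + 1L] * wt[i + 1L]) /
        (wt[i] + wt[i + 1L])
      wt[i] <- wt[i] + wt[i + 1L]
      idx[[i]] <- c(idx[[i]], idx[[i + 1L]])
      val <- val[-(i + 1L)]; wt <- wt[-(i + 1L)]; idx[[i + 1L]] <- NULL
      i <- max(1L, i - 1L)
    } else i <- i + 1L
  }
  out <- numeric(n)
  for (k in seq_along(val)) out[idx[[k]]] <- val[k]
  out
}

# Spearman rho as Pearson correlation of the ranks, written out in full
spearman_brute <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# grid-search minimizer of the log-scale least-squares objective used by
# the monoexponential fit
grid_monoexp <- function(t_h, doserate, lambda_grid) {
  sse <- vapply(lambda_grid, function(l) {
    logd0 <- mean(log(doserate) + l * t_h)
    sum((log(doserate) - (logd0 - l * t_h))^2)
  }, 0)
  l <- lambda_grid[which.min(sse)]
  list(lambda = l, d0 = exp(mean(log(doserate) + l * t_h)))
}

# small noise-free config shared by several tests
noise_free_config <- function(n_patients = 6L, seed = 0L, pve = NULL, ...) {
  cohort_config(
    n_patients = n_patients, seed = seed, pve = pve,
    counting = list(cf = 10, duration_s = 2700, noise_free = TRUE),
    response_noise_sd = 0, tox_noise_scale = 0, ...)
}
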
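# shared fixtures: small 1D/2D deconvolution problems built in code

unit_grid_1d <- function(M = 64L) sampling_grid(spike_domain(0, 1), M)

psf_1d <- function(sigma = 0.07) gaussian_psf(sigma)

# noiseless acquisition y = Phi(mu) + b for given spikes
noiseless_data <- function(positions, amplitudes, psf, grid, b = 0.01) {
  m <- dirac_measure(positions, amplitudes)
  forward_image(m, psf, grid) + b
}

small_kl_problem <- function(positions = 0.5, amplitudes = 1, M = 64L,
                             sigma = 0.07, b = 0.01) {
  grid <- unit_grid_1d(M)
  psf <- psf_1d(sigma)
  y <- noiseless_data(positions, amplitudes, psf, grid, b)
  list(spec = fidelity_spec("kl", y = y, b = b), psf = psf, grid = grid,
       gt = dirac_measure(positions, amplitudes))
}

small_l2_problem <- function(positions = 0.5, amplitudes = 1, M = 64L,
                             sigma = 0.07, b = 0.01) {
  grid <- unit_grid_1d(M)
  psf <- psf_1d(sigma)
  y <- noiseless_data(positions, amplitudes, psf, grid, b)
  list(spec = fidelity_spec("l2", y = y, b = b), psf = psf, grid = grid,
       gt = dirac_measure(positions, amplitudes))
}

# --- independent analytic oracles for the duality checks ----------------

# scalar KL function g_t(s) of the conjugate pair
g_t <- function(s, t, lambda) (s - t + t * log(t) - t * log(s)) / lambda

# conjugate of the integral KL functional G = D_KL(. , y) / lambda, with
# the same quadrature convention as the fidelity module
G_star_oracle <- function(s_star, y, lambda, grid) {
  if (any(s_star >= 1 / lambda)) return(Inf)
  grid$pixel_measure * sum(-(y / lambda) * log(1 - lambda * s_star))
}

# conjugate of the TV norm + non-negativity indicator: 0 on {psi <= 1}
F_star_oracle <- function(psi_values) {
  if (all(psi_values <= 1 + 1e-12)) 0 else Inf
}

# --- brute-force amplitude solvers (oracles for the estimation step) ----

# non-negative LASSO with L2 fidelity by KKT active-set enumeration:
# minimise 0.5*h*||B a - r||^2 + lambda * sum(a), a >= 0
nnlasso_enumerate <- function(B, r, lambda, h) {
  n <- ncol(B)
  G <- h * crossprod(B)           # Gram in the weighted inner product
  beta <- h * drop(crossprod(B, r))
  best <- NULL
  best_obj <- Inf
  obj <- function(a) 0.5 * h * sum((drop(B %*% a) - r)^2) + lambda * sum(a)
  for (mask in 0:(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    a <- numeric(n)
    if (length(S) > 0L) {
      sol <- try(solve(G[S, S, drop = FALSE], beta[S] - lambda), silent = TRUE)
      if (inherits(sol, "try-error")) next
      if (any(sol < 0)) next
      a[S] <- sol
    }
    # dual feasibility on the inactive set
    grad <- drop(G %*% a) - beta + lambda
    if (any(grad[a == 0] < -1e-9)) next
    o <- obj(a)
    if (o < best_obj) { best_obj <- o; best <- a }
  }
  list(amplitudes = best, objective = best_obj)
}

# signed LASSO (alpha = 0) by sign-pattern enumeration
lasso_enumerate <- function(B, r, lambda, h) {
  n <- ncol(B)
  G <- h * crossprod(B)
  beta <- h * drop(crossprod(B, r))
  obj <- function(a) 0.5 * h * sum((drop(B %*% a) - r)^2) + lambda * sum(abs(a))
  best <- numeric(n)
  best_obj <- obj(best)
  signs <- expand.grid(rep(list(c(-1, 0, 1)), n))
  for (i in seq_len(nrow(signs))) {
    s <- as.numeric(signs[i, ])
    S <- which(s != 0)
    a <- numeric(n)
    if (length(S) > 0L) {
      sol <- try(solve(G[S, S, drop = FALSE], beta[S] - lambda * s[S]),
                 silent = TRUE)
      if (inherits(sol, "try-error")) next
      if (any(sign(sol) != s[S])) next
      a[S] <- sol
    }
    grad <- drop(G %*% a) - beta
    if (any(abs(grad[a == 0]) > lambda + 1e-9)) next
    o <- obj(a)
    if (o < best_obj) { best_obj <- o; best <- a }
  }
  list(amplitudes = best, objective = best_obj)
}
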
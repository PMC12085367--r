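#' Sliding Frank-Wolfe configuration
#'
#' @param max_iters maximum number of outer iterations (one spike inserted
#'   per iteration).
#' @param cert_tol stopping slack: the solver stops when the certificate
#'   value at the best candidate position is `<= 1 + cert_tol`.
#' @param lattice_refine refinement factor of the certificate search
#'   lattice relative to the acquisition grid.
#' @param amp_solver_iters,amp_solver_tol budget and relative-change
#'   tolerance of the proximal-gradient amplitude solver.
#' @param sliding_enabled run the joint position-amplitude refinement.
#' @param sliding_period run the sliding step only every `sliding_period`-th
#'   iteration (`1` = always; larger values limit sliding, trading accuracy
#'   for speed on large problems).
#' @param sliding_max_evals function-evaluation budget of the local joint
#'   optimiser.
#' @param prune_atol amplitudes with magnitude `<= prune_atol` are dropped
#'   after each iteration.
#' @param merge_radius spikes closer than this are merged after each
#'   iteration (`0` disables merging).
#' @return a list of class `sfw_config`.
#' @export
sfw_config <- function(max_iters = 20L, cert_tol = 1e-4, lattice_refine = 4L,
                       amp_solver_iters = 500L, amp_solver_tol = 1e-10,
                       sliding_enabled = TRUE, sliding_period = 1L,
                       sliding_max_evals = 200L,
                       prune_atol = 1e-8, merge_radius = 1e-3) {
  stopifnot(max_iters >= 1L, cert_tol > 0, lattice_refine >= 1L,
            amp_solver_iters >= 1L, amp_solver_tol > 0,
            sliding_period >= 1L, sliding_max_evals >= 1L,
            prune_atol >= 0, merge_radius >= 0)
  structure(as.list(environment()), class = "sfw_config")
}

#' Regularised objective of the variational model
#'
#' \eqn{T_{f,\lambda}(\mu) = f_{y,b}(\Phi\mu) + \lambda|\mu|(\Omega)
#' + \alpha\,\iota_{M^+}(\mu)}: data term plus TV norm plus, for the
#' constrained model, `+Inf` whenever any amplitude is negative.
#'
#' @param m a [dirac_measure()].
#' @param lambda regularisation parameter.
#' @param spec,psf,grid model components.
#' @return the objective value (possibly `+Inf`).
#' @export
sfw_objective <- function(m, lambda, spec, psf, grid) {
  if (spec$alpha == 1L && any(m$amplitudes < 0)) return(Inf)
  fidelity_value(forward_image(m, psf, grid), spec, grid) + lambda * tv_norm(m)
}

#' Locate the certificate maximum
#'
#' Insertion rule of the conditional-gradient iteration: scan the refined
#' lattice, then polish by bounded continuous ascent. For the unconstrained
#' model the maximum of \eqn{|\eta|} is sought.
#'
#' @param cert a [dual_certificate()] field.
#' @param grid acquisition [sampling_grid()].
#' @param config an [sfw_config()].
#' @return list with `x` (d-vector) and `value` (certificate magnitude
#'   there, `>=` the lattice maximum by construction).
#' @export
certificate_argmax <- function(cert, grid, config = sfw_config()) {
  s <- certificate_sup(cert, grid, refine = config$lattice_refine,
                       polish = TRUE)
  list(x = s$x, value = s$value)
}

# value and gradient of the smooth part a -> f(B a) for fixed spike basis B
smooth_amp_fn <- function(B, spec, grid) {
  shape_img <- function(v) if (length(dim(spec$y)) > 1L) array(v, dim(spec$y)) else v
  list(
    value = function(a) fidelity_value(shape_img(drop(B %*% a)), spec, grid),
    grad = function(a) {
      g <- fidelity_gradient(shape_img(drop(B %*% a)), spec, grid)
      grid$pixel_measure * drop(crossprod(B, as.vector(g)))
    })
}

#' Amplitude re-estimation at fixed positions
#'
#' Solves \eqn{\min_a f_{y,b}(\Phi_x a) + \lambda\|a\|_1} (with `a >= 0`
#' under the constrained model) by proximal gradient descent with
#' backtracking on the smooth part: soft-thresholding for the unconstrained
#' model, the shifted non-negative threshold `max(z - s*lambda, 0)` for the
#' constrained one. The KL term is smooth on the feasible set since
#' \eqn{\Phi_x a + b \ge b > 0} for `a >= 0`.
#'
#' @param positions `N x d` matrix of spike positions (N >= 1).
#' @param lambda regularisation parameter.
#' @param spec,psf,grid model components.
#' @param config an [sfw_config()].
#' @param init optional warm-start amplitudes (defaults to zeros).
#' @return list with `amplitudes`, `objective` (value of the solved
#'   problem) and `converged`.
#' @export
amplitude_step <- function(positions, lambda, spec, psf, grid,
                           config = sfw_config(), init = NULL) {
  positions <- as_positions(positions, dim = grid$domain$dim)
  n <- nrow(positions)
  stopifnot(n >= 1L)
  B <- spike_basis(positions, psf, grid)
  fn <- smooth_amp_fn(B, spec, grid)
  a <- if (is.null(init)) numeric(n) else as.numeric(init)
  if (spec$alpha == 1L) a <- pmax(a, 0)
  penal <- function(a) lambda * sum(abs(a))
  prox <- function(z, s) {
    if (spec$alpha == 1L) pmax(z - s * lambda, 0)
    else sign(z) * pmax(abs(z) - s * lambda, 0)
  }
  f_a <- fn$value(a)
  if (!is.finite(f_a)) { a <- numeric(n); f_a <- fn$value(a) }
  # accelerated proximal gradient with backtracking and monotone restarts
  step <- 1 / max(grid$pixel_measure * sum(B * B), .Machine$double.eps)
  z <- a                      # extrapolated point
  tk <- 1
  converged <- FALSE
  for (it in seq_len(config$amp_solver_iters)) {
    f_z <- fn$value(z)
    if (!is.finite(f_z)) { z <- a; tk <- 1; f_z <- f_a }
    g <- fn$grad(z)
    repeat {
      a_new <- prox(z - step * g, step)
      f_new <- fn$value(a_new)
      dz <- a_new - z
      q <- f_z + sum(g * dz) + sum(dz * dz) / (2 * step)
      if (is.finite(f_new) && f_new <= q + 1e-12 * abs(q)) break
      step <- step / 2
      if (step < 1e-300) break
    }
    if (f_new + penal(a_new) > f_a + penal(a)) {
      # extrapolation overshot: restart the momentum from the last iterate
      if (sqrt(sum((z - a)^2)) < .Machine$double.eps) { converged <- TRUE; break }
      z <- a
      tk <- 1
      next
    }
    # prox-gradient residual at the accepted iterate
    moved <- sqrt(sum((a_new - a)^2))
    rel <- (f_a + penal(a) - f_new - penal(a_new)) /
      max(1, abs(f_a + penal(a)))
    t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- a_new + ((tk - 1) / t_next) * (a_new - a)
    tk <- t_next
    a <- a_new
    f_a <- f_new
    if (moved < config$amp_solver_tol && rel < config$amp_solver_tol) {
      converged <- TRUE
      break
    }
    step <- step * 1.2     # let the step recover after backtracking
  }
  list(amplitudes = a, objective = f_a + penal(a), converged = converged)
}

# objective and analytic gradient for the sliding step, parameterised by
# theta = c(u, vec(positions)) with amplitudes a = sgn * u, u >= 0
sliding_problem <- function(sgn, n, d, lambda, spec, psf, grid) {
  shape_img <- function(v) if (length(dim(spec$y)) > 1L) array(v, dim(spec$y)) else v
  unpack <- function(theta) {
    u <- theta[seq_len(n)]
    pos <- matrix(theta[-seq_len(n)], n, d)
    list(u = u, pos = pos, a = sgn * u)
  }
  fn <- function(theta) {
    z <- unpack(theta)
    B <- spike_basis(z$pos, psf, grid)
    v <- fidelity_value(shape_img(drop(B %*% z$a)), spec, grid) +
      lambda * sum(z$u)
    if (!is.finite(v)) v <- .Machine$double.xmax / 1e6
    v
  }
  gr <- function(theta) {
    z <- unpack(theta)
    B <- spike_basis(z$pos, psf, grid)
    w <- shape_img(drop(B %*% z$a))
    g_img <- as.vector(fidelity_gradient(w, spec, grid))
    gu <- sgn * (grid$pixel_measure * drop(crossprod(B, g_img))) + lambda
    gx <- matrix(0, n, d)
    for (k in seq_len(d)) {
      Dk <- spike_basis(z$pos, psf, grid, deriv_axis = k)
      gx[, k] <- z$a * (grid$pixel_measure * drop(crossprod(Dk, g_img)))
    }
    c(gu, as.vector(gx))
  }
  list(fn = fn, gr = gr, unpack = unpack)
}

#' Joint refinement of positions and amplitudes (sliding step)
#'
#' Local minimisation of the objective over all amplitudes and positions
#' simultaneously, starting from the current measure, with box constraints
#' keeping positions in \eqn{\Omega} and amplitudes non-negative under the
#' constrained model (for the unconstrained model each amplitude's sign is
#' frozen at its entry value). The result is accepted only if it improves
#' the objective; on any optimiser failure the entry measure is returned
#' unchanged.
#'
#' @param m entry [dirac_measure()].
#' @param lambda,spec,psf,grid model components.
#' @param config an [sfw_config()].
#' @return the refined `dirac_measure` (objective never increased).
#' @export
sliding_step <- function(m, lambda, spec, psf, grid, config = sfw_config()) {
  if (m$n == 0L) return(m)
  d <- grid$domain$dim
  n <- m$n
  sgn <- sign(m$amplitudes)
  sgn[sgn == 0] <- 1
  prob <- sliding_problem(sgn, n, d, lambda, spec, psf, grid)
  theta0 <- c(abs(m$amplitudes), as.vector(m$positions))
  lower <- c(rep(0, n), rep(grid$domain$lower, each = n))
  upper <- c(rep(Inf, n), rep(grid$domain$upper, each = n))
  f0 <- prob$fn(theta0)
  opt <- try(stats::optim(theta0, prob$fn, prob$gr, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = config$sliding_max_evals)),
             silent = TRUE)
  if (inherits(opt, "try-error") || !is.finite(opt$value) || opt$value > f0)
    return(m)
  z <- prob$unpack(opt$par)
  dirac_measure(z$pos, z$a)
}

#' Sliding Frank-Wolfe solver
#'
#' Minimises the variational objective at fixed \eqn{\lambda} by greedy
#' spike insertion: each outer iteration evaluates the dual certificate,
#' stops if its maximum is `<= 1 + cert_tol` (the optimality condition up
#' to slack), otherwise inserts a spike at the certificate argmax,
#' re-estimates all amplitudes under the \eqn{\ell^1} penalty
#' ([amplitude_step()]), refines jointly ([sliding_step()]), then prunes
#' and merges.
#'
#' @param spec,psf,grid model components.
#' @param lambda regularisation parameter `> 0`.
#' @param m0 initial measure (default: the zero measure).
#' @param config an [sfw_config()].
#' @return list of class `sfw_result` with `measure`, `objective_trace`
#'   (including the initial objective; non-increasing), `cert_sup_trace`
#'   (certificate value at the candidate of each iteration), `converged`
#'   and `n_iters`.
#' @export
sfw_solve <- function(spec, psf, grid, lambda, m0 = NULL,
                      config = sfw_config()) {
  stopifnot(lambda > 0)
  m <- m0 %||% zero_measure(grid$domain$dim)
  obj <- sfw_objective(m, lambda, spec, psf, grid)
  objective_trace <- obj
  cert_sup_trace <- numeric(0)
  converged <- FALSE
  n_iters <- 0L
  for (k in seq_len(config$max_iters)) {
    cert <- dual_certificate(m, lambda, spec, psf, grid)
    cand <- certificate_argmax(cert, grid, config)
    cert_sup_trace <- c(cert_sup_trace, cand$value)
    if (cand$value <= 1 + config$cert_tol) {
      converged <- TRUE
      break
    }
    n_iters <- k
    positions <- rbind(m$positions, matrix(cand$x, 1L))
    amp <- amplitude_step(positions, lambda, spec, psf, grid, config,
                          init = c(m$amplitudes, 0))
    m_new <- dirac_measure(positions, amp$amplitudes)
    if (config$sliding_enabled && (k %% config$sliding_period == 0L))
      m_new <- sliding_step(m_new, lambda, spec, psf, grid, config)
    m_new <- merge_close(prune_spikes(m_new, config$prune_atol),
                         config$merge_radius)
    obj_new <- sfw_objective(m_new, lambda, spec, psf, grid)
    if (obj_new <= obj) {          # accept only improvements
      m <- m_new
      obj <- obj_new
    }
    objective_trace <- c(objective_trace, obj)
  }
  structure(list(measure = m, objective_trace = objective_trace,
                 cert_sup_trace = cert_sup_trace, converged = converged,
                 n_iters = n_iters),
            class = "sfw_result")
}

#' @export
print.sfw_result <- function(x, ...) {
  cat(sprintf("<sfw_result> %d iteration(s), %d spike(s), %s, objective %g\n",
              x$n_iters, x$measure$n,
              if (x$converged) "converged" else "budget reached",
              utils::tail(x$objective_trace, 1L)))
  invisible(x)
}
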
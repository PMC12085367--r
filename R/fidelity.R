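#' Data-fidelity specification
#'
#' Bundles the acquisition \eqn{y^\delta}, the background \eqn{b} and the
#' choice of data term:
#' * `"l2"`: \eqn{f_{y,b}(w) = \tfrac12 \|w + b - y\|_{L^2(\Omega)}^2}, the
#'   Beurling-LASSO fidelity for additive Gaussian noise (`alpha = 0`,
#'   unconstrained amplitudes, by default);
#' * `"kl"`: \eqn{f_{y,b}(w) = \tilde D_{KL}(w + b, y)}, the
#'   Kullback-Leibler divergence matched to Poisson counts, used with the
#'   non-negativity constraint (`alpha = 1`) and requiring `b > 0` and
#'   `y >= 0`.
#'
#' @param kind `"l2"` or `"kl"`.
#' @param y acquisition image on the grid (counts / intensity).
#' @param b background: scalar or image; strictly positive for `"kl"`.
#' @param alpha `0` or `1`: whether the non-negativity constraint on the
#'   measure is active. Defaults to `1` for `"kl"`, `0` for `"l2"`.
#' @return An object of class `fidelity_spec`.
#' @export
fidelity_spec <- function(kind = c("kl", "l2"), y, b = 0,
                          alpha = if (kind == "kl") 1L else 0L) {
  kind <- match.arg(kind)
  if (!alpha %in% c(0L, 1L)) stop("alpha must be 0 or 1")
  if (kind == "kl") {
    if (any(b <= 0)) stop("KL fidelity requires a strictly positive background")
    if (any(y < 0)) stop("KL fidelity requires non-negative data")
  }
  structure(list(kind = kind, y = y, b = b, alpha = as.integer(alpha)),
            class = "fidelity_spec")
}

#' @export
print.fidelity_spec <- function(x, ...) {
  cat(sprintf("<fidelity_spec> %s, alpha = %d, background %s\n",
              toupper(x$kind), x$alpha,
              if (length(x$b) == 1L) format(x$b) else "image"))
  invisible(x)
}

#' Squared-L2 data term
#'
#' \eqn{\tfrac12 \|w + b - y\|^2_{L^2(\Omega)}} with the grid quadrature
#' weight; zero exactly when `w + b` reproduces the data.
#'
#' @param w model image \eqn{\Phi\mu} on the grid.
#' @param spec a [fidelity_spec()] (the `kind` is not checked: this is the
#'   L2 formula regardless).
#' @param grid the [sampling_grid()] carrying the quadrature weight.
#' @return a non-negative scalar.
#' @export
l2_fidelity <- function(w, spec, grid) {
  r <- as.vector(w) + as.vector(spec$y) * 0 + spec$b - as.vector(spec$y)
  0.5 * grid$pixel_measure * sum(r * r)
}

#' Kullback-Leibler data term
#'
#' The extended divergence \eqn{\tilde D_{KL}(w + b, y)}: `+Inf` whenever
#' `w + b` is non-positive somewhere, otherwise
#' \deqn{\int_\Omega (w + b) - y + y(\log y - \log(w + b)) \, dx}
#' with the continuous-extension convention \eqn{y \log y = 0} at
#' zero-count pixels (Poisson draws can be exactly 0 even though the model
#' assumes `y > 0` almost everywhere).
#'
#' @inheritParams l2_fidelity
#' @return a scalar `>= 0`, or `+Inf`; zero iff `w + b = y`.
#' @export
kl_fidelity <- function(w, spec, grid) {
  s <- as.vector(w) + spec$b + as.vector(spec$y) * 0
  y <- as.vector(spec$y)
  if (any(s <= 0)) return(Inf)
  term <- s - y
  pos <- y > 0
  term[pos] <- term[pos] + y[pos] * (log(y[pos]) - log(s[pos]))
  grid$pixel_measure * sum(term)
}

#' Evaluate the configured data term
#'
#' Dispatches to [l2_fidelity()] or [kl_fidelity()] according to
#' `spec$kind`.
#'
#' @inheritParams l2_fidelity
#' @return fidelity value (possibly `+Inf` for KL).
#' @export
fidelity_value <- function(w, spec, grid) {
  switch(spec$kind,
         l2 = l2_fidelity(w, spec, grid),
         kl = kl_fidelity(w, spec, grid))
}

#' Gradient of the data term
#'
#' Gradient in the weighted \eqn{L^2(\Omega)} inner product, as an image:
#' `w + b - y` for L2, `1 - y / (w + b)` for KL (defined only where
#' `w + b > 0`). The directional derivative of the fidelity along `v`
#' equals `image_inner(gradient, v, grid)`.
#'
#' @inheritParams l2_fidelity
#' @return an image of the same shape as `w`.
#' @export
fidelity_gradient <- function(w, spec, grid) {
  y <- spec$y
  if (spec$kind == "l2") {
    g <- w + spec$b + y * 0 - y
  } else {
    s <- w + spec$b + y * 0
    if (any(s <= 0))
      stop("KL gradient undefined: model + background non-positive somewhere")
    g <- 1 - y / s
  }
  g
}

#' Dual certificate of the variational problem
#'
#' The certificate \eqn{\eta(\lambda, \mu) = \tilde\eta(\mu)/\lambda} with
#' \eqn{\tilde\eta(\mu) = -\Phi^* \nabla f_{y,b}(\Phi\mu)} for the
#' unconstrained model, and its pointwise positive part for the constrained
#' one (the positive part is applied *after* the adjoint). At a solution,
#' \eqn{\|\eta\|_\infty \le 1} with \eqn{\eta = 1} on the support; values
#' above 1 locate where the next spike should be inserted.
#'
#' @param m current [dirac_measure()].
#' @param lambda regularisation parameter `> 0`.
#' @param spec a [fidelity_spec()].
#' @param psf,grid forward model.
#' @return An object of class `certificate_field` with `$eval(xs)` (batch
#'   evaluation of \eqn{\eta} at continuous points), `$eval_raw(xs)` (the
#'   signed field before the positive part, for smooth local search),
#'   `$lattice(axes)` (separable evaluation on a product lattice),
#'   `$lambda` and `$alpha`.
#' @export
dual_certificate <- function(m, lambda, spec, psf, grid) {
  stopifnot(lambda > 0)
  g <- fidelity_gradient(forward_image(m, psf, grid), spec, grid)
  neg_g <- -g
  alpha <- spec$alpha
  eval_raw <- function(xs) adjoint_field_batch(neg_g, psf, grid, xs) / lambda
  structure(list(
    eval = function(xs) {
      v <- eval_raw(xs)
      if (alpha == 1L) pmax(v, 0) else v
    },
    eval_raw = eval_raw,
    lattice = function(axes) {
      v <- adjoint_field_lattice(neg_g, psf, grid, axes) / lambda
      if (alpha == 1L) pmax(v, 0) else v
    },
    lambda = lambda, alpha = alpha),
    class = "certificate_field")
}

# refined product lattice used for sup-norm scans: refine x the acquisition
# sampling per axis
refined_axes <- function(grid, refine = 4L) {
  d <- grid$domain$dim
  lapply(seq_len(d), function(k) {
    Mk <- grid$shape[k] * as.integer(refine)
    hk <- (grid$domain$upper[k] - grid$domain$lower[k]) / Mk
    grid$domain$lower[k] + (seq_len(Mk) - 0.5) * hk
  })
}

#' Sup-norm and argmax of a certificate field
#'
#' Two-stage estimate of \eqn{\sup_\Omega} of the certificate (of
#' \eqn{|\eta|} for the unconstrained model, of \eqn{\eta} for the
#' constrained one, whose field is non-negative by construction): a dense
#' scan on a product lattice `refine` times finer than the acquisition
#' grid, then bounded continuous local maximisation started from the best
#' lattice point. Ties on the lattice break at the lowest flattened index,
#' so results are deterministic.
#'
#' @param cert a [dual_certificate()] field.
#' @param grid the acquisition [sampling_grid()].
#' @param refine lattice refinement factor (default 4).
#' @param polish logical: run the local continuous ascent after the scan.
#' @return list with `value` (the sup estimate), `x` (its location, a
#'   d-vector) and `lattice_value` (the best value on the lattice alone).
#' @export
certificate_sup <- function(cert, grid, refine = 4L, polish = TRUE) {
  axes <- refined_axes(grid, refine)
  vals <- cert$lattice(axes)
  mag <- if (cert$alpha == 1L) vals else abs(vals)
  i_best <- which.max(as.vector(mag))   # first max: lowest flattened index
  idx <- arrayInd(i_best, .dim = lengths(axes))
  x0 <- vapply(seq_along(axes), function(k) axes[[k]][idx[k]], numeric(1))
  lattice_value <- as.vector(mag)[i_best]
  value <- lattice_value
  x <- x0
  if (polish && lattice_value > 0) {
    # ascend the smooth signed field with the sign fixed at the start point
    sgn <- if (cert$alpha == 1L) 1 else sign(cert$eval_raw(matrix(x0, 1L)))
    if (sgn == 0) sgn <- 1
    f <- function(z) -sgn * cert$eval_raw(matrix(z, 1L))
    opt <- try(stats::optim(x0, f, method = "L-BFGS-B",
                            lower = grid$domain$lower,
                            upper = grid$domain$upper),
               silent = TRUE)
    if (!inherits(opt, "try-error") && is.finite(opt$value) &&
        -opt$value >= lattice_value) {
      value <- -opt$value
      x <- opt$par
    }
  }
  list(value = value, x = x, lattice_value = lattice_value)
}

#' Closed-form dual variable of the constrained Poisson model
#'
#' For the KL model the solution of the dual problem has the closed form
#' \deqn{p_\lambda = \frac{y - \Phi\mu - b}{\lambda(\Phi\mu + b)},}
#' which satisfies \eqn{p_\lambda > -1/\lambda} wherever `y > 0`. Used for
#' optimality diagnostics, never for computation.
#'
#' @inheritParams dual_certificate
#' @return an image on the grid.
#' @export
dual_variable <- function(m, lambda, spec, psf, grid) {
  if (spec$kind != "kl") stop("dual_variable is defined for the KL model")
  stopifnot(lambda > 0)
  s <- forward_image(m, psf, grid) + spec$b + spec$y * 0
  if (any(s <= 0)) stop("model + background must be positive everywhere")
  (spec$y - s) / (lambda * s)
}

#' Convex conjugate of the scalar Kullback-Leibler function
#'
#' For \eqn{g_t(s) = (s - t + t\log t - t\log s)/\lambda} on `s > 0`, the
#' conjugate is
#' \deqn{g_t^*(s^*) = -\frac{t}{\lambda}\log(1 - \lambda s^*)}
#' for \eqn{s^* < 1/\lambda} and \eqn{+\infty} otherwise, with maximiser
#' \eqn{\hat s = t/(1 - \lambda s^*)}. Exposed as an analytic oracle for
#' duality checks.
#'
#' @param s_star conjugate argument.
#' @param t positive reference value (a data pixel).
#' @param lambda positive scale.
#' @return the conjugate value, possibly `+Inf`.
#' @export
kl_conjugate_1d <- function(s_star, t, lambda) {
  stopifnot(t > 0, lambda > 0)
  ifelse(s_star >= 1 / lambda, Inf, -(t / lambda) * log(1 - lambda * s_star))
}
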
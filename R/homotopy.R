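#' Homotopy continuation configuration
#'
#' Controls the outer loop that drives \eqn{\lambda} down a multiplicative
#' path until the data residual falls below a noise-calibrated target.
#'
#' @param gamma relaxation factor in `(0, 1)` of the initial
#'   \eqn{\lambda_1 = \gamma\,\|\tilde\eta(\mu_0)\|_\infty}; values close
#'   to 1 start just below the threshold at which the initialisation is
#'   already optimal.
#' @param c positive update margin: after each unsuccessful outer step the
#'   next \eqn{\lambda} is chosen so the certificate of the current iterate
#'   has sup-norm exactly `1 + c`, guaranteeing the warm start is not
#'   optimal and at least one insertion happens.
#' @param max_outer cap on the number of outer iterations.
#' @param sigma_target stopping threshold on the residual
#'   \eqn{\sigma_t = f_{y,b}(\Phi\hat\mu_t)}; see [sigma_target_oracle()]
#'   and [sigma_target_masked()] for calibrations.
#' @param inner an [sfw_config()] for the inner solver (typically with a
#'   budget of 1-2 iterations: the measure keeps improving across outer
#'   steps anyway).
#' @return a list of class `homotopy_config`.
#' @export
homotopy_config <- function(gamma = 0.9, c = 15, max_outer = 12L,
                            sigma_target, inner = sfw_config(max_iters = 1L)) {
  stopifnot(gamma > 0, gamma < 1, c > 0, max_outer >= 1L,
            sigma_target >= 0)
  structure(list(gamma = gamma, c = c, max_outer = as.integer(max_outer),
                 sigma_target = sigma_target, inner = inner),
            class = "homotopy_config")
}

#' Initial regularisation parameter
#'
#' \eqn{\lambda_1 = \gamma\,\|\eta(1, \mu_0)\|_\infty}, so that by
#' homogeneity \eqn{\|\eta(\lambda_1, \mu_0)\|_\infty = 1/\gamma > 1} and
#' the first inner solve is guaranteed to insert a spike. For the KL model
#' started at the zero measure with scalar background this equals
#' \eqn{\gamma\,\|(\Phi^*((y - b)/b))_+\|_\infty}; for L2 with `b = 0` it
#' is \eqn{\gamma\,\|\Phi^* y\|_\infty}.
#'
#' @param m0 initial measure.
#' @param gamma relaxation in `(0, 1)`.
#' @param spec,psf,grid model components.
#' @param refine certificate lattice refinement.
#' @return \eqn{\lambda_1 > 0}; errors if the certificate vanishes (the
#'   data are already explained by `m0` and no homotopy is needed).
#' @export
lambda_init <- function(m0, gamma, spec, psf, grid, refine = 4L) {
  stopifnot(gamma > 0, gamma < 1)
  cert1 <- dual_certificate(m0, 1, spec, psf, grid)
  sup1 <- certificate_sup(cert1, grid, refine = refine)$value
  if (sup1 <= 0)
    stop("certificate of the initial measure vanishes; nothing to reconstruct")
  gamma * sup1
}

#' Multiplicative lambda update
#'
#' \eqn{\lambda_{t+1} = \lambda_t \,
#' \|\eta(\lambda_t,\hat\mu_t)\|_\infty / (1 + c)}, so that, by the
#' \eqn{1/\lambda} homogeneity of the certificate,
#' \eqn{\|\eta(\lambda_{t+1},\hat\mu_t)\|_\infty = 1 + c > 1} exactly, and
#' \eqn{\lambda} decreases whenever the current certificate sup-norm is
#' below `1 + c`.
#'
#' @param lambda_t current parameter.
#' @param cert_sup certificate sup-norm at `(lambda_t, mu_t)`, re-evaluated
#'   at the returned solution.
#' @param c positive margin.
#' @return \eqn{\lambda_{t+1} > 0}.
#' @export
lambda_update <- function(lambda_t, cert_sup, c) {
  stopifnot(lambda_t > 0, cert_sup >= 0, c > 0)
  lambda_t * cert_sup / (1 + c)
}

#' Data residual of a measure
#'
#' \eqn{\sigma = f_{y,b}(\Phi\mu)}: the configured fidelity evaluated at
#' the measure (background handled inside the fidelity).
#'
#' @param m a [dirac_measure()].
#' @param spec,psf,grid model components.
#' @return a non-negative scalar (or `+Inf` for an infeasible KL argument).
#' @export
residual <- function(m, spec, psf, grid) {
  fidelity_value(forward_image(m, psf, grid), spec, grid)
}

#' Oracle residual target from the ground truth
#'
#' `inflation * f_{y,b}(Phi mu_gt)`: available in simulations only, where
#' the exact residual at the truth can be computed. The benchmark presets
#' inflate by 1.5 (1D protocol) or 1.1 (3D L2 protocol).
#'
#' @param m_gt ground-truth measure.
#' @param spec,psf,grid model components.
#' @param inflation multiplicative safety factor.
#' @return \eqn{\sigma_{target} > 0} (0 for noiseless data).
#' @export
sigma_target_oracle <- function(m_gt, spec, psf, grid, inflation = 1.5) {
  inflation * residual(m_gt, spec, psf, grid)
}

#' Residual target estimated from a background region
#'
#' Data-driven calibration needing no ground truth: assuming the measure
#' vanishes on a background region \eqn{\Omega_{bg}} (e.g. an outer ring of
#' the field of view), the fidelity of the *zero* measure restricted to
#' that region, rescaled by \eqn{|\Omega| / |\Omega_{bg}|}, estimates the
#' residual level of pure noise over the whole domain:
#' \deqn{\sigma_{target} = f_{y,b}(0)\big|_{\Omega_{bg}}
#'   \frac{|\Omega|}{|\Omega_{bg}|}.}
#' Accurate for the KL/Poisson model; for the L2 model with
#' signal-dependent noise it can be off (the noise level differs between
#' background and foreground), in which case the oracle target is
#' preferable when available.
#'
#' @param y acquisition image.
#' @param mask logical array on the grid, `TRUE` on the background region
#'   (see [background_mask()]); must be non-empty.
#' @param b background value (scalar or image).
#' @param kind `"kl"` or `"l2"`.
#' @param grid the [sampling_grid()].
#' @return the estimated target.
#' @export
sigma_target_masked <- function(y, mask, b, kind = c("kl", "l2"), grid) {
  kind <- match.arg(kind)
  mask <- as.vector(mask)
  if (!any(mask)) stop("background mask is empty")
  yv <- as.vector(y)[mask]
  bv <- if (length(b) == 1L) rep(b, sum(mask)) else as.vector(b)[mask]
  if (kind == "kl") {
    if (any(bv <= 0)) stop("KL requires b > 0")
    term <- bv - yv
    pos <- yv > 0
    term[pos] <- term[pos] + yv[pos] * (log(yv[pos]) - log(bv[pos]))
    val <- grid$pixel_measure * sum(term)
  } else {
    val <- 0.5 * grid$pixel_measure * sum((bv - yv)^2)
  }
  val * length(mask) / sum(mask)    # |Omega| / |Omega_bg|
}

#' Poisson discrepancy-principle target
#'
#' First-order approximation of the expected KL residual at the truth,
#' \eqn{|\Omega|/2}, in the same quadrature units as [kl_fidelity()].
#' Provided for comparison: with small per-pixel counts or a large domain
#' it is typically a poor estimate compared to the masked one.
#'
#' @param grid a [sampling_grid()].
#' @return \eqn{|\Omega| / 2}.
#' @export
poisson_discrepancy_target <- function(grid) {
  domain_volume(grid$domain) / 2
}

#' Estimate a constant background from a masked region
#'
#' Quadrature mean of the acquisition over the background region,
#' \eqn{b = |\Omega_{bg}|^{-1} \int_{\Omega_{bg}} y}.
#'
#' @param y acquisition image.
#' @param mask logical background mask (non-empty).
#' @return the scalar estimate.
#' @export
estimate_background <- function(y, mask) {
  mask <- as.vector(mask)
  if (!any(mask)) stop("background mask is empty")
  mean(as.vector(y)[mask])
}

#' Homotopy continuation over lambda
#'
#' The automatic regularisation-path algorithm: initialise
#' \eqn{\lambda_1} by [lambda_init()]; at each outer step solve the inner
#' problem by [sfw_solve()] warm-started at the previous iterate, record
#' the residual \eqn{\sigma_t}, stop once \eqn{\sigma_t \le}
#' `sigma_target` (or the outer budget is exhausted), otherwise decrease
#' \eqn{\lambda} by [lambda_update()] with the certificate sup-norm
#' re-evaluated at the current solution. With exact inner solves the
#' residual sequence is strictly decreasing and the TV norm strictly
#' increasing along the path; with truncated inner budgets a
#' non-decreasing residual is reported as a warning and the run continues.
#'
#' @param spec,psf,grid model components.
#' @param config a [homotopy_config()].
#' @param m0 initial measure (default: zero measure).
#' @return list of class `homotopy_result` with `measure` (final iterate),
#'   `trace` (data frame: `t`, `lambda`, `sigma`, `n_spikes`, `cert_sup`,
#'   `tv`), `converged` (`TRUE` iff the residual target was met) and
#'   `sigma_target`.
#' @export
homotopy_solve <- function(spec, psf, grid, config, m0 = NULL) {
  m <- m0 %||% zero_measure(grid$domain$dim)
  refine <- config$inner$lattice_refine
  sigma0 <- residual(m, spec, psf, grid)
  if (sigma0 <= config$sigma_target) {
    # the initial measure already explains the data to target accuracy
    return(structure(list(measure = m,
                          trace = data.frame(t = integer(0),
                                             lambda = numeric(0),
                                             sigma = numeric(0),
                                             n_spikes = integer(0),
                                             cert_sup = numeric(0),
                                             tv = numeric(0)),
                          converged = TRUE,
                          sigma_target = config$sigma_target),
                     class = "homotopy_result"))
  }
  lambda <- lambda_init(m, config$gamma, spec, psf, grid, refine = refine)
  rows <- list()
  converged <- FALSE
  sigma_prev <- Inf
  for (t in seq_len(config$max_outer)) {
    res <- sfw_solve(spec, psf, grid, lambda, m0 = m, config = config$inner)
    m <- res$measure
    sigma <- residual(m, spec, psf, grid)
    cert <- dual_certificate(m, lambda, spec, psf, grid)
    cert_sup <- certificate_sup(cert, grid, refine = refine)$value
    rows[[t]] <- data.frame(t = t, lambda = lambda, sigma = sigma,
                            n_spikes = m$n, cert_sup = cert_sup,
                            tv = tv_norm(m))
    if (sigma >= sigma_prev)
      warning(sprintf(
        "residual did not decrease at outer iteration %d (inexact inner solve)", t),
        call. = FALSE)
    sigma_prev <- sigma
    if (sigma <= config$sigma_target) {
      converged <- TRUE
      break
    }
    if (t < config$max_outer) {
      lambda_next <- lambda_update(lambda, cert_sup, config$c)
      if (lambda_next >= lambda)
        warning("lambda did not decrease (certificate sup >= 1 + c)",
                call. = FALSE)
      lambda <- lambda_next
    }
  }
  structure(list(measure = m, trace = do.call(rbind, rows),
                 converged = converged, sigma_target = config$sigma_target),
            class = "homotopy_result")
}

#' @export
print.homotopy_result <- function(x, ...) {
  n <- nrow(x$trace)
  cat(sprintf(
    "<homotopy_result> %d outer iteration(s), %d spike(s), sigma %s (target %g), %s\n",
    n, x$measure$n,
    if (n > 0L) format(x$trace$sigma[n]) else "(initial)", x$sigma_target,
    if (x$converged) "target met" else "budget reached"))
  invisible(x)
}

#' Write a homotopy trace to CSV
#'
#' @param result a `homotopy_result`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_trace <- function(result, file) {
  utils::write.csv(result$trace, file, row.names = FALSE)
  invisible(file)
}
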
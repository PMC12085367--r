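#' Simulation scenario presets
#'
#' Phantom and acquisition settings for the package's benchmark protocols:
#' * `"sim1d"`: \eqn{\Omega = [0, 1]}, 128 samples, 6 spikes with
#'   amplitudes uniform on `[0.6, 1.4]`, Gaussian PSF `sigma = 0.07`,
#'   constant background `b = 0.01`;
#' * `"sim2d"`: \eqn{\Omega = [0, 1]^2}, 128 x 128 pixels, 15 spikes with
#'   amplitudes uniform on `[0.5, 1.5]`, isotropic `sigma = 0.07`,
#'   `b = 0.05`;
#' * `"sim3d"`: \eqn{\Omega = [-1300, 1300]^2 \times [-1000, 1000]} (nm),
#'   40 x 40 x 8 voxels (65 nm lateral / 250 nm axial), 7 spikes with
#'   amplitudes uniform on `[0.6, 1.4]`, anisotropic
#'   `sigma = (200, 200, 400)` nm, `b = 0.5`;
#' * `"custom"`: every field supplied explicitly.
#'
#' Acquisitions are pixelwise Poisson draws with mean
#' `photon_scale * (Phi mu + b)`, returned divided by `photon_scale`, so
#' the acquisition stays in model intensity units whatever the count
#' scale. `photon_scale` is the single knob linking unit amplitudes to
#' photon counts; `1` draws counts directly at the intensity scale of the
#' unit-mass PSF (the low-count regime), while the 1D benchmark preset
#' uses the calibrated value 128 (brightest pixel around 10^3 counts; see
#' the methods vignette for the calibration procedure).
#'
#' @param name preset name.
#' @param domain,shape,n_spikes,amplitude_range,psf,b,photon_scale
#'   overrides of the preset fields (all required for `"custom"`).
#' @return list of class `scenario_preset` with the fields above plus
#'   `grid` (the [sampling_grid()]).
#' @export
scenario_preset <- function(name = c("sim1d", "sim2d", "sim3d", "custom"),
                            domain = NULL, shape = NULL, n_spikes = NULL,
                            amplitude_range = NULL, psf = NULL, b = NULL,
                            photon_scale = NULL) {
  name <- match.arg(name)
  def <- switch(name,
    sim1d = list(domain = spike_domain(0, 1), shape = 128L, n_spikes = 6L,
                 amplitude_range = c(0.6, 1.4), psf = gaussian_psf(0.07),
                 b = 0.01, photon_scale = 128),
    sim2d = list(domain = spike_domain(c(0, 0), c(1, 1)),
                 shape = c(128L, 128L), n_spikes = 15L,
                 amplitude_range = c(0.5, 1.5),
                 psf = gaussian_psf(c(0.07, 0.07)), b = 0.05,
                 photon_scale = 1),
    sim3d = list(domain = spike_domain(c(-1300, -1300, -1000),
                                       c(1300, 1300, 1000)),
                 shape = c(40L, 40L, 8L), n_spikes = 7L,
                 amplitude_range = c(0.6, 1.4),
                 psf = gaussian_psf(c(200, 200, 400)), b = 0.5,
                 photon_scale = 1),
    custom = list(domain = NULL, shape = NULL, n_spikes = NULL,
                  amplitude_range = NULL, psf = NULL, b = NULL,
                  photon_scale = 1))
  p <- list(name = name,
            domain = domain %||% def$domain,
            shape = shape %||% def$shape,
            n_spikes = n_spikes %||% def$n_spikes,
            amplitude_range = amplitude_range %||% def$amplitude_range,
            psf = psf %||% def$psf,
            b = b %||% def$b,
            photon_scale = photon_scale %||% def$photon_scale)
  if (any(vapply(p, is.null, logical(1))))
    stop("incomplete preset: supply all fields for 'custom'")
  stopifnot(p$photon_scale > 0, p$amplitude_range[1] <= p$amplitude_range[2])
  p$grid <- sampling_grid(p$domain, p$shape)
  structure(p, class = "scenario_preset")
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat(sprintf("<scenario_preset> %s: %d spikes on %s grid, b = %g, photon_scale = %g\n",
              x$name, x$n_spikes, paste(x$shape, collapse = " x "), x$b,
              x$photon_scale))
  invisible(x)
}

#' Draw a random ground-truth measure
#'
#' Positions i.i.d. uniform on \eqn{\Omega} (no minimum separation is
#' enforced: near-coincident spikes are a genuine feature of the protocol
#' and limit the achievable detection rate), amplitudes i.i.d. uniform on
#' the preset's amplitude range.
#'
#' @param preset a [scenario_preset()].
#' @param seed optional integer; when given, the RNG is seeded locally so
#'   the draw is reproducible without disturbing the caller's RNG stream.
#' @return a [dirac_measure()].
#' @export
generate_ground_truth <- function(preset, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  d <- preset$domain$dim
  n <- preset$n_spikes
  pos <- vapply(seq_len(d), function(k)
    stats::runif(n, preset$domain$lower[k], preset$domain$upper[k]),
    numeric(n))
  pos <- matrix(pos, n, d)
  amp <- stats::runif(n, preset$amplitude_range[1], preset$amplitude_range[2])
  dirac_measure(pos, amp, domain = preset$domain)
}

#' Simulate a Poisson acquisition
#'
#' Per-pixel independent Poisson draws with mean
#' `photon_scale * (Phi mu + b)`, divided back by `photon_scale` so the
#' returned image is in model intensity units; its expectation equals
#' \eqn{\Phi\mu + b}. A strictly positive background makes every mean
#' positive, so zero counts become rare as `photon_scale` grows.
#'
#' @param m_gt ground-truth [dirac_measure()].
#' @param preset a [scenario_preset()].
#' @param seed optional integer seed (local, as in
#'   [generate_ground_truth()]).
#' @return acquisition image on the preset grid.
#' @export
simulate_acquisition <- function(m_gt, preset, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  mu <- forward_image(m_gt, preset$psf, preset$grid) + preset$b
  if (any(mu < 0)) stop("negative Poisson mean: check amplitudes/background")
  counts <- stats::rpois(length(mu), preset$photon_scale * as.vector(mu))
  y <- counts / preset$photon_scale
  if (preset$domain$dim == 1L) y else array(y, dim = preset$shape)
}

#' Simulate a Gaussian-noise acquisition
#'
#' Baseline additive model \eqn{y = \Phi\mu + b + \omega} with i.i.d.
#' zero-mean Gaussian noise.
#'
#' @param m_gt ground-truth measure.
#' @param preset a [scenario_preset()].
#' @param noise_sd standard deviation of the noise (`>= 0`).
#' @param seed optional integer seed (local).
#' @return acquisition image (may be negative; intended for the L2 model).
#' @export
gaussian_noise_acquisition <- function(m_gt, preset, noise_sd, seed = NULL) {
  stopifnot(noise_sd >= 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  mu <- forward_image(m_gt, preset$psf, preset$grid) + preset$b
  y <- as.vector(mu) + stats::rnorm(length(mu), sd = noise_sd)
  if (preset$domain$dim == 1L) y else array(y, dim = preset$shape)
}

#' Outer-ring background mask
#'
#' Indicator of the outer ring (1D: end segments; 2D: square ring; 3D:
#' shell) of the grid with fractional width `margin_fraction` per axis:
#' cell `i` on axis `k` belongs to the mask iff
#' `i < floor(margin_fraction * M_k)` or
#' `i >= M_k - floor(margin_fraction * M_k)` (0-based). Used by the masked
#' residual-target and background estimators, assuming spikes keep away
#' from the border.
#'
#' @param grid a [sampling_grid()].
#' @param margin_fraction fraction in `(0, 0.5)`.
#' @return logical array of the grid shape.
#' @export
background_mask <- function(grid, margin_fraction = 0.1) {
  stopifnot(margin_fraction > 0, margin_fraction < 0.5)
  d <- grid$domain$dim
  border <- lapply(seq_len(d), function(k) {
    Mk <- grid$shape[k]
    nk <- floor(margin_fraction * Mk)
    idx <- seq_len(Mk)
    idx <= nk | idx > Mk - nk
  })
  if (d == 1L) return(border[[1L]])
  mask <- array(FALSE, dim = grid$shape)
  idx_grid <- as.matrix(expand.grid(lapply(grid$shape, seq_len)))
  on_border <- rep(FALSE, nrow(idx_grid))
  for (k in seq_len(d)) on_border <- on_border | border[[k]][idx_grid[, k]]
  array(on_border, dim = grid$shape)
}
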
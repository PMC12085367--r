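#' Gaussian point spread function
#'
#' Separable Gaussian measurement kernel with per-axis standard deviations
#' (physical units). The kernel centred at \eqn{x} evaluates at \eqn{s} as
#' \deqn{\varphi_x(s) = \prod_k (2\pi\sigma_k^2)^{-1/2}
#'   \exp(-(s_k - x_k)^2 / 2\sigma_k^2),}
#' i.e. it integrates to one over \eqn{R^d}. The isotropic case takes a
#' single width; 3D microscopy stacks typically use an axial width larger
#' than the lateral ones.
#'
#' @param sigma numeric vector of per-axis standard deviations, all `> 0`.
#' @return An object of class `gaussian_psf`.
#' @examples
#' gaussian_psf(0.07)               # 1D
#' gaussian_psf(c(200, 200, 400))   # anisotropic 3D, nm
#' @export
gaussian_psf <- function(sigma) {
  sigma <- as.numeric(sigma)
  if (any(sigma <= 0) || any(!is.finite(sigma))) stop("sigma must be > 0")
  if (length(sigma) < 1L || length(sigma) > 3L)
    stop("sigma must have length 1, 2 or 3")
  structure(list(sigma = sigma, dim = length(sigma)), class = "gaussian_psf")
}

#' @export
print.gaussian_psf <- function(x, ...) {
  cat(sprintf("<gaussian_psf> sigma = (%s)\n", paste(x$sigma, collapse = ", ")))
  invisible(x)
}

#' Regular sampling grid on a domain
#'
#' Cell-centred discretisation of \eqn{\Omega}: axis `k` with `shape[k]`
#' cells has centres `lower + (i + 0.5) * h_k`, `i = 0, ..., M_k - 1`, with
#' spacing `h_k = (upper_k - lower_k) / M_k`. The quadrature weight
#' (`pixel_measure` \eqn{= \prod_k h_k}) multiplies every discretised
#' \eqn{L^2(\Omega)} integral, so fidelities, adjoints and inner products
#' are stable under grid refinement; the total weight equals
#' \eqn{|\Omega|} exactly.
#'
#' @param domain a [spike_domain()].
#' @param shape integer vector of per-axis sample counts `M_k >= 1`.
#' @return An object of class `sampling_grid` with fields `domain`, `shape`,
#'   `h` (per-axis spacing), `pixel_measure` and `axes` (list of per-axis
#'   centre coordinates).
#' @export
sampling_grid <- function(domain, shape) {
  shape <- as.integer(shape)
  if (length(shape) != domain$dim) stop("shape length must match domain dim")
  if (any(shape < 1L)) stop("all grid sizes must be >= 1")
  h <- (domain$upper - domain$lower) / shape
  axes <- lapply(seq_len(domain$dim), function(k)
    domain$lower[k] + (seq_len(shape[k]) - 0.5) * h[k])
  structure(list(domain = domain, shape = shape, h = h,
                 pixel_measure = prod(h), axes = axes),
            class = "sampling_grid")
}

#' @export
print.sampling_grid <- function(x, ...) {
  cat(sprintf("<sampling_grid> %s cells, pixel measure %g\n",
              paste(x$shape, collapse = " x "), x$pixel_measure))
  invisible(x)
}

#' Evaluate the PSF kernel
#'
#' @param psf a [gaussian_psf()].
#' @param s,x points in \eqn{R^d} (numeric vectors).
#' @return \eqn{\varphi_x(s) > 0}; maximal at `s = x`.
#' @export
psf_eval <- function(psf, s, x) {
  s <- as.numeric(s); x <- as.numeric(x)
  if (length(s) != psf$dim || length(x) != psf$dim)
    stop("point dimension does not match PSF")
  prod(stats::dnorm(s - x, sd = psf$sigma))
}

# per-axis kernel matrix: K[i, j] = dnorm(centres[i] - xs[j], sd = sigma)
axis_kernel <- function(centres, xs, sigma, deriv = FALSE) {
  D <- outer(centres, xs, "-")
  K <- stats::dnorm(D, sd = sigma)
  if (deriv) K * D / sigma^2 else K   # d/dx of dnorm(c - x)
}

# M_total x N matrix whose column j is the vectorised image of a unit spike
# at positions[j, ]; deriv_axis > 0 differentiates that axis w.r.t. the
# spike position.
spike_basis <- function(positions, psf, grid, deriv_axis = 0L) {
  positions <- as_positions(positions, dim = grid$domain$dim)
  d <- grid$domain$dim
  if (nrow(positions) > 0L && ncol(positions) != d)
    stop("position dimension does not match grid")
  n <- nrow(positions)
  M <- prod(grid$shape)
  if (n == 0L) return(matrix(numeric(0), M, 0L))
  Ks <- lapply(seq_len(d), function(k)
    axis_kernel(grid$axes[[k]], positions[, k], psf$sigma[k],
                deriv = (k == deriv_axis)))
  if (d == 1L) return(Ks[[1L]])
  B <- matrix(0, M, n)
  for (j in seq_len(n)) {
    v <- Ks[[1L]][, j]
    for (k in 2L:d) v <- as.vector(outer(v, Ks[[k]][, j]))
    B[, j] <- v
  }
  B
}

check_dims <- function(psf, grid) {
  if (psf$dim != grid$domain$dim)
    stop("PSF dimension does not match grid dimension")
}

#' Forward operator on a Dirac measure
#'
#' Samples \eqn{\Phi\mu_{a,x} = \sum_i a_i \varphi_{x_i}} at every grid
#' centre. Evaluation is direct (spikes x pixels) so positions are truly
#' continuous; no FFT or interpolation is involved.
#'
#' @param m a [dirac_measure()].
#' @param psf a [gaussian_psf()].
#' @param grid a [sampling_grid()].
#' @return an array of dimension `grid$shape` (a plain vector in 1D), in
#'   intensity units; all zeros for the zero measure, non-negative whenever
#'   all amplitudes are.
#' @export
forward_image <- function(m, psf, grid) {
  check_dims(psf, grid)
  if (m$n > 0L && ncol(m$positions) != grid$domain$dim)
    stop("measure dimension does not match grid")
  v <- if (m$n == 0L) numeric(prod(grid$shape))
       else drop(spike_basis(m$positions, psf, grid) %*% m$amplitudes)
  if (grid$domain$dim == 1L) v else array(v, dim = grid$shape)
}

#' Adjoint field at continuous points
#'
#' Quadrature approximation of
#' \eqn{\Phi^* p(x) = \langle p, \varphi_x \rangle_{L^2(\Omega)}}:
#' `pixel_measure * sum_t p(t) phi_x(t)` over grid centres `t`. This is the
#' building block of the dual certificate, which must be evaluated at
#' arbitrary off-grid positions.
#'
#' @param p image (array on `grid`).
#' @param psf a [gaussian_psf()].
#' @param grid a [sampling_grid()].
#' @param x a single point (numeric vector of length `d`).
#' @return a scalar, linear in `p`.
#' @export
adjoint_field <- function(p, psf, grid, x) {
  adjoint_field_batch(p, psf, grid, matrix(as.numeric(x), 1L))[1L]
}

#' @rdname adjoint_field
#' @param xs an `n x d` matrix of evaluation points (or numeric vector in
#'   1D); may have zero rows.
#' @return `adjoint_field_batch()`: a numeric vector of length `nrow(xs)`.
#' @export
adjoint_field_batch <- function(p, psf, grid, xs) {
  check_dims(psf, grid)
  xs <- as_positions(xs, dim = grid$domain$dim)
  if (nrow(xs) == 0L) return(numeric(0))
  B <- spike_basis(xs, psf, grid)
  drop(crossprod(B, as.vector(p))) * grid$pixel_measure
}

# Adjoint field on a product lattice given as a list of per-axis coordinate
# vectors; returns an array of dim lengths(axes). Exploits separability of
# the Gaussian kernel (sequential tensor contractions), which keeps dense
# certificate scans cheap in 2D/3D.
adjoint_field_lattice <- function(p, psf, grid, axes) {
  check_dims(psf, grid)
  d <- grid$domain$dim
  stopifnot(length(axes) == d)
  Ks <- lapply(seq_len(d), function(k)
    axis_kernel(grid$axes[[k]], axes[[k]], psf$sigma[k]))
  if (d == 1L) {
    out <- drop(crossprod(Ks[[1L]], as.vector(p)))
  } else {
    # contract axis by axis: (M1,...,Mk,...) x (Mk,Lk) -> (..., Lk)
    cur <- array(as.vector(p), dim = grid$shape)
    for (k in seq_len(d)) {
      dm <- dim(cur)
      m1 <- dm[1L]
      rest <- prod(dm[-1L])
      cur <- crossprod(matrix(cur, m1, rest), Ks[[k]])  # (rest, Lk)
      cur <- array(cur, dim = c(dm[-1L], ncol(Ks[[k]])))
    }
    out <- cur
  }
  out * grid$pixel_measure
}

#' Discrete L2(Omega) inner product of two images
#'
#' @param a,b images on `grid`.
#' @param grid a [sampling_grid()].
#' @return `pixel_measure * sum(a * b)`.
#' @export
image_inner <- function(a, b, grid) {
  grid$pixel_measure * sum(as.vector(a) * as.vector(b))
}

#' Read / write images as plain-text arrays
#'
#' The package's platform-neutral array format is a text file whose first
#' line is `# dims: M1 M2 ...` followed by the array values in column-major
#' order, one per line. `read_image()` also accepts TIFF files (single
#' images or z-stacks, axis order z, y, x mapped to an `(x, y, z)` array)
#' when the `tiff` package is available.
#'
#' @param x image array.
#' @param file path; `.txt`/`.dat` for the text format, `.tif`/`.tiff` for
#'   TIFF input.
#' @return `read_image()`: a numeric array. `write_image()`: `file`,
#'   invisibly.
#' @export
write_image <- function(x, file) {
  dims <- if (is.null(dim(x))) length(x) else dim(x)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste("# dims:", paste(dims, collapse = " ")), con)
  writeLines(format(as.vector(x), digits = 17, trim = TRUE, scientific = TRUE), con)
  invisible(file)
}

#' @rdname write_image
#' @export
read_image <- function(file) {
  if (grepl("\\.tiff?$", file, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    img <- tiff::readTIFF(file, all = TRUE, as.is = TRUE)
    if (is.list(img) && length(img) == 1L) img <- img[[1L]]
    if (is.list(img)) {                  # z-stack: list of (y, x) slices
      slices <- lapply(img, function(s) t(as.matrix(s)))  # -> (x, y)
      img <- array(unlist(slices), dim = c(dim(slices[[1L]]), length(slices)))
    } else if (length(dim(img)) == 2L) {
      img <- t(as.matrix(img))
    }
    return(img)
  }
  first <- readLines(file, n = 1L)
  if (!grepl("^# dims:", first)) stop("not an offgridspikes image file: ", file)
  dims <- as.integer(strsplit(sub("^# dims:\\s*", "", first), "\\s+")[[1L]])
  vals <- utils::read.table(file, skip = 1L)[[1L]]
  if (length(vals) != prod(dims)) stop("corrupt image file: ", file)
  if (length(dims) == 1L) as.numeric(vals) else array(as.numeric(vals), dim = dims)
}
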
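#' Rectangular spatial domain
#'
#' The domain \eqn{\Omega \subset R^d} on which spikes live: an axis-aligned
#' box in physical coordinates, \eqn{d \in \{1,2,3\}}. All positions handled
#' by the package are expressed in these physical units; conversion to and
#' from pixel indices is the job of [sampling_grid()].
#'
#' @param lower,upper numeric vectors of equal length `d` with
#'   `lower[k] < upper[k]` for every axis.
#' @return An object of class `spike_domain` with fields `lower`, `upper`,
#'   `dim`.
#' @examples
#' spike_domain(0, 1)
#' spike_domain(c(-1300, -1300, -1000), c(1300, 1300, 1000))
#' @export
spike_domain <- function(lower, upper) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != length(upper))
    stop("'lower' and 'upper' must have the same length")
  d <- length(lower)
  if (d < 1L || d > 3L) stop("domain dimension must be 1, 2 or 3")
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("domain bounds must be finite")
  if (any(lower >= upper)) stop("'lower' must be strictly below 'upper'")
  structure(list(lower = lower, upper = upper, dim = d),
            class = "spike_domain")
}

#' Volume of a domain
#'
#' @param domain a [spike_domain()].
#' @return \eqn{|\Omega| = \prod_k (upper_k - lower_k)}.
#' @export
domain_volume <- function(domain) {
  prod(domain$upper - domain$lower)
}

#' @export
print.spike_domain <- function(x, ...) {
  cat(sprintf("<spike_domain> d = %d, [%s] x ... x [%s]\n", x$dim,
              paste(c(x$lower[1], x$upper[1]), collapse = ", "),
              paste(c(x$lower[x$dim], x$upper[x$dim]), collapse = ", ")))
  invisible(x)
}

# coerce positions to an N x d matrix
as_positions <- function(positions, dim = NULL) {
  if (is.null(positions)) positions <- matrix(numeric(0), 0L, max(1L, dim %||% 1L))
  if (!is.matrix(positions)) {
    if (is.null(dim) || dim == 1L) {
      positions <- matrix(as.numeric(positions), ncol = 1L)
    } else {
      positions <- matrix(as.numeric(positions), ncol = dim, byrow = TRUE)
    }
  }
  storage.mode(positions) <- "double"
  positions
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Discrete (Dirac) measure
#'
#' A finite weighted sum of Dirac masses
#' \eqn{\mu_{a,x} = \sum_{i=1}^N a_i \delta_{x_i}} with continuous positions
#' \eqn{x_i \in \Omega} and amplitudes \eqn{a_i}. `N = 0` represents the zero
#' measure. The non-negativity of amplitudes is *not* enforced here: the
#' constrained model handles it through its indicator (see [sfw_objective()]).
#'
#' @param positions an `N x d` matrix (or a numeric vector for `d = 1`) of
#'   physical positions.
#' @param amplitudes numeric vector of length `N`.
#' @param domain optional [spike_domain()]; when given, positions are checked
#'   to lie within its bounds (inclusive).
#' @return An object of class `dirac_measure` with fields `positions`
#'   (matrix), `amplitudes`, `n`.
#' @examples
#' m <- dirac_measure(c(0.2, 0.8), c(1, 2))
#' tv_norm(m)
#' @export
dirac_measure <- function(positions, amplitudes = numeric(0), domain = NULL) {
  positions <- as_positions(positions, dim = domain$dim)
  amplitudes <- as.numeric(amplitudes)
  if (nrow(positions) != length(amplitudes))
    stop("number of positions and amplitudes differ")
  if (!is.null(domain)) {
    if (ncol(positions) != domain$dim && nrow(positions) > 0L)
      stop("position dimension does not match domain")
    if (nrow(positions) > 0L) {
      lo <- matrix(domain$lower, nrow(positions), domain$dim, byrow = TRUE)
      hi <- matrix(domain$upper, nrow(positions), domain$dim, byrow = TRUE)
      if (any(positions < lo) || any(positions > hi))
        stop("positions must lie inside the domain")
    }
  }
  structure(list(positions = positions, amplitudes = amplitudes,
                 n = length(amplitudes)),
            class = "dirac_measure")
}

#' Zero measure in a given dimension
#' @param dim spatial dimension.
#' @return the `dirac_measure` with `N = 0`.
#' @export
zero_measure <- function(dim = 1L) {
  dirac_measure(matrix(numeric(0), 0L, dim), numeric(0))
}

#' @export
print.dirac_measure <- function(x, ...) {
  cat(sprintf("<dirac_measure> N = %d spike(s), |mu|(Omega) = %g\n",
              x$n, tv_norm(x)))
  if (x$n > 0L) {
    df <- data.frame(x$positions, amplitude = x$amplitudes)
    names(df)[seq_len(ncol(x$positions))] <-
      paste0("x", seq_len(ncol(x$positions)) - 1L)
    print(utils::head(df, 10L), ...)
    if (x$n > 10L) cat(sprintf("  ... and %d more\n", x$n - 10L))
  }
  invisible(x)
}

#' Total variation norm of a discrete measure
#'
#' For a weighted sum of Diracs the TV norm coincides with the \eqn{\ell^1}
#' norm of the amplitude vector, \eqn{|\mu_{a,x}|(\Omega) = \|a\|_1}. It is
#' the sparsity-promoting regulariser of the variational model.
#'
#' @param m a [dirac_measure()].
#' @return \eqn{\sum_i |a_i|}; `0` for the zero measure.
#' @export
tv_norm <- function(m) {
  sum(abs(m$amplitudes))
}

#' Remove negligible spikes
#'
#' Drops every spike whose amplitude magnitude is at most `atol`; the
#' amplitude re-estimation step of the solver can drive amplitudes exactly
#' to zero. Survivor order is preserved.
#'
#' @param m a [dirac_measure()].
#' @param atol non-negative tolerance on `|a_i|`.
#' @return the pruned `dirac_measure`.
#' @export
prune_spikes <- function(m, atol = 0) {
  stopifnot(atol >= 0)
  keep <- abs(m$amplitudes) > atol
  dirac_measure(m$positions[keep, , drop = FALSE], m$amplitudes[keep])
}

#' Merge nearly coincident spikes
#'
#' Greedy agglomeration in index order: each spike absorbs all later spikes
#' within Euclidean distance `radius`, replacing the group by a single spike
#' at the amplitude-weighted mean position with the summed amplitude. The
#' total mass \eqn{\sum_i a_i} is conserved exactly. The joint
#' position-amplitude refinement can collapse two spikes onto one location;
#' this cleans that up deterministically.
#'
#' @param m a [dirac_measure()].
#' @param radius non-negative merge radius (physical units).
#' @return the merged `dirac_measure`.
#' @export
merge_close <- function(m, radius = 0) {
  stopifnot(radius >= 0)
  if (m$n <= 1L) return(m)
  pos <- m$positions
  amp <- m$amplitudes
  used <- rep(FALSE, m$n)
  out_pos <- list()
  out_amp <- numeric(0)
  for (i in seq_len(m$n)) {
    if (used[i]) next
    grp <- i
    for (j in seq_len(m$n)) {
      if (j == i || used[j]) next
      dij <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (dij <= radius) grp <- c(grp, j)
    }
    used[grp] <- TRUE
    a <- sum(amp[grp])
    # amplitude-weighted mean; plain mean if the group mass cancels
    w <- if (abs(a) > 0) amp[grp] / a else rep(1 / length(grp), length(grp))
    x <- drop(crossprod(w, pos[grp, , drop = FALSE]))
    out_pos[[length(out_pos) + 1L]] <- x
    out_amp <- c(out_amp, a)
  }
  dirac_measure(do.call(rbind, out_pos), out_amp)
}

#' Read / write spike lists
#'
#' Spike lists are serialised as CSV with header `x0[,x1[,x2]],amplitude`,
#' one row per spike, positions in physical units.
#'
#' @param m a [dirac_measure()].
#' @param file path of the CSV file.
#' @return `write_spikes()` returns `file` invisibly; `read_spikes()` returns
#'   a `dirac_measure`.
#' @export
write_spikes <- function(m, file) {
  d <- if (m$n > 0L) ncol(m$positions) else ncol(m$positions)
  df <- as.data.frame(m$positions)
  names(df) <- paste0("x", seq_len(max(1L, d)) - 1L)[seq_len(ncol(m$positions))]
  df$amplitude <- m$amplitudes
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(file) {
  df <- utils::read.csv(file)
  if (!"amplitude" %in% names(df)) stop("no 'amplitude' column in ", file)
  pos_cols <- setdiff(names(df), "amplitude")
  dirac_measure(as.matrix(df[pos_cols]), df$amplitude)
}
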
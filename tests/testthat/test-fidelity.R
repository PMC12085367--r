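test_that("L2 fidelity is the weighted half squared residual", {
  grid <- unit_grid_1d(32L)
  y <- stats::runif(32, 1, 2)
  spec <- fidelity_spec("l2", y = y, b = 0.1)
  expect_equal(l2_fidelity(y - 0.1, spec, grid), 0)
  spec0 <- fidelity_spec("l2", y = rep(0.1, 32), b = 0.1)
  expect_equal(l2_fidelity(numeric(32), spec0, grid), 0)
  # single-pixel grid with unit pixel measure: residual 2 -> 1/2 * 4
  g1 <- sampling_grid(spike_domain(0, 1), 1L)
  s1 <- fidelity_spec("l2", y = 1, b = 0)
  expect_equal(l2_fidelity(3, s1, g1), 2)
})

test_that("KL fidelity implements the extended divergence", {
  g1 <- sampling_grid(spike_domain(0, 1), 1L)
  s1 <- fidelity_spec("kl", y = 1, b = 1)
  expect_equal(kl_fidelity(0, s1, g1), 0)              # w + b = y
  expect_equal(kl_fidelity(1, s1, g1), 1 - log(2))     # scalar formula
  expect_identical(kl_fidelity(-2, s1, g1), Inf)       # infeasible argument

  grid <- unit_grid_1d(16L)
  y <- c(numeric(4), stats::rpois(12, 3))              # zero-count pixels
  spec <- fidelity_spec("kl", y = y, b = 0.5)
  v <- kl_fidelity(y - 0.5 + 1e-9 * (y == 0), spec, grid)
  expect_true(is.finite(v))                            # y log y = 0 at y = 0
  # non-negativity with equality only at the data
  set.seed(2)
  for (i in 1:5) {
    w <- stats::runif(16, 0.1, 3)
    expect_gte(kl_fidelity(w, spec, grid), 0)
  }
  yy <- stats::runif(16, 0.5, 2)
  sp <- fidelity_spec("kl", y = yy, b = 0.2)
  expect_equal(kl_fidelity(yy - 0.2, sp, grid), 0, tolerance = 1e-12)
})

test_that("fidelity gradients match finite differences", {
  grid <- unit_grid_1d(12L)
  set.seed(21)
  y <- stats::runif(12, 0.5, 2)
  for (kind in c("l2", "kl")) {
    spec <- fidelity_spec(kind, y = y, b = 0.3)
    w <- stats::runif(12, 0.2, 1.5)
    g <- fidelity_gradient(w, spec, grid)
    v <- stats::rnorm(12)
    eps <- 1e-6
    fd <- (fidelity_value(w + eps * v, spec, grid) -
             fidelity_value(w - eps * v, spec, grid)) / (2 * eps)
    expect_equal(fd, image_inner(g, v, grid), tolerance = 1e-6)
  }
  # KL gradient special values
  spec <- fidelity_spec("kl", y = c(0, rep(1, 11)), b = 0.5)
  g <- fidelity_gradient(rep(0.5, 12), spec, grid)
  expect_equal(g[1], 1)                                 # zero-count pixel
  expect_error(fidelity_gradient(rep(-1, 12), spec, grid), "non-positive")
})

test_that("dual certificate has the stated structure and homogeneity", {
  prob <- small_kl_problem(positions = c(0.3, 0.7), amplitudes = c(1, 0.8))
  m0 <- zero_measure(1L)
  lam <- 2.5
  cert <- dual_certificate(m0, lam, prob$spec, prob$psf, prob$grid)
  xs <- matrix(seq(0.05, 0.95, by = 0.05), ncol = 1L)

  # at mu = 0 with scalar b: eta = (Phi*((y - b)/b))_+ / lambda
  direct <- adjoint_field_batch((prob$spec$y - prob$spec$b) / prob$spec$b,
                                prob$psf, prob$grid, xs) / lam
  expect_equal(cert$eval(xs), pmax(direct, 0), tolerance = 1e-12)
  expect_true(all(cert$eval(xs) >= 0))                  # alpha = 1 field

  # 1/lambda homogeneity: eta(2 lambda) = eta(lambda) / 2
  cert2 <- dual_certificate(m0, 2 * lam, prob$spec, prob$psf, prob$grid)
  expect_equal(cert2$eval(xs), cert$eval(xs) / 2, tolerance = 1e-12)

  # L2 with alpha = 0, b = 0, mu = 0: eta = Phi* y / lambda (signed)
  grid <- prob$grid
  y <- forward_image(prob$gt, prob$psf, grid)
  specl2 <- fidelity_spec("l2", y = y, b = 0)
  certl2 <- dual_certificate(m0, lam, specl2, prob$psf, grid)
  expect_equal(certl2$eval(xs),
               adjoint_field_batch(y, prob$psf, grid, xs) / lam,
               tolerance = 1e-12)
})

test_that("certificate sup scan beats its lattice and is deterministic", {
  prob <- small_kl_problem(positions = 0.55, amplitudes = 1)
  cert <- dual_certificate(zero_measure(1L), 1, prob$spec, prob$psf,
                           prob$grid)
  s <- certificate_sup(cert, prob$grid, refine = 4L)
  expect_gte(s$value, s$lattice_value)
  expect_lt(abs(s$x - 0.55), 0.01)
  s2 <- certificate_sup(cert, prob$grid, refine = 4L)
  expect_identical(s, s2)
})

test_that("dual variable obeys its closed form and lower bound", {
  prob <- small_kl_problem(positions = c(0.4, 0.6), amplitudes = c(1, 1))
  lam <- 0.7
  # exact fit: p_lambda = 0
  p0 <- dual_variable(prob$gt, lam, prob$spec, prob$psf, prob$grid)
  expect_equal(max(abs(p0)), 0, tolerance = 1e-12)
  # positive data: p_lambda > -1/lambda
  m <- dirac_measure(0.5, 0.3)
  p <- dual_variable(m, lam, prob$spec, prob$psf, prob$grid)
  expect_gt(min(p), -1 / lam)
  # algebraic identity with the fidelity gradient: -lambda p = grad/(w+b)
  w <- forward_image(m, prob$psf, prob$grid)
  g <- fidelity_gradient(w, prob$spec, prob$grid)
  expect_equal(-lam * p * (w + prob$spec$b), g * (w + prob$spec$b),
               tolerance = 1e-12)
})

test_that("scalar KL conjugate matches its closed form and a numeric sup", {
  expect_identical(kl_conjugate_1d(2, t = 1, lambda = 1), Inf)
  expect_identical(kl_conjugate_1d(1, t = 3, lambda = 1), Inf)
  expect_equal(kl_conjugate_1d(0, t = 2, lambda = 3), 0)
  expect_equal(kl_conjugate_1d(0.5, t = 1, lambda = 1), -log(0.5),
               tolerance = 1e-12)
  # cross-check by numerically maximising s * s_star - g_t(s) over s > 0
  set.seed(31)
  for (i in 1:10) {
    t <- stats::runif(1, 0.5, 3)
    lam <- stats::runif(1, 0.5, 2)
    s_star <- stats::runif(1, -2, 1 / lam - 0.05)
    num <- stats::optimize(function(s) s * s_star - g_t(s, t, lam),
                           interval = c(1e-8, 1e4), maximum = TRUE,
                           tol = 1e-12)
    expect_equal(kl_conjugate_1d(s_star, t, lam), num$objective,
                 tolerance = 1e-6)
    # the maximiser is s_hat = t / (1 - lambda s_star)
    expect_equal(num$maximum, t / (1 - lam * s_star), tolerance = 1e-4)
  }
})

test_that("Fenchel-Young holds for the scalar and integral conjugates", {
  set.seed(41)
  for (i in 1:20) {
    t <- stats::runif(1, 0.2, 4)
    lam <- stats::runif(1, 0.2, 3)
    s <- stats::runif(1, 0.05, 5)
    s_star <- stats::runif(1, -3, 1 / lam - 1e-3)
    lhs <- g_t(s, t, lam) + kl_conjugate_1d(s_star, t, lam)
    expect_gte(lhs, s * s_star - 1e-10)
    s_hat <- t / (1 - lam * s_star)
    expect_equal(g_t(s_hat, t, lam) + kl_conjugate_1d(s_star, t, lam),
                 s_hat * s_star, tolerance = 1e-9)
  }

  # integral form: G(s) + G*(s*) >= <s, s*> with the grid quadrature
  grid <- unit_grid_1d(16L)
  set.seed(42)
  y <- stats::runif(16, 0.5, 2)
  lam <- 1.3
  G <- function(s) {
    spec <- fidelity_spec("kl", y = y, b = 1e-12)
    kl_fidelity(s - 1e-12, spec, grid) / lam
  }
  for (i in 1:5) {
    s <- stats::runif(16, 0.2, 3)
    s_star <- stats::runif(16, -1, 1 / lam - 0.05)
    lhs <- G(s) + G_star_oracle(s_star, y, lam, grid)
    expect_gte(lhs, image_inner(s, s_star, grid) - 1e-8)
    s_hat <- y / (1 - lam * s_star)
    expect_equal(G(s_hat) + G_star_oracle(s_star, y, lam, grid),
                 image_inner(s_hat, s_star, grid), tolerance = 1e-8)
  }

  # penalty conjugate: 0 on {psi <= 1}, +Inf otherwise
  expect_identical(F_star_oracle(c(0.2, 0.9, 1.0)), 0)
  expect_identical(F_star_oracle(c(0.2, 1.2)), Inf)
})

test_that("fidelity specs validate their domains", {
  expect_error(fidelity_spec("kl", y = c(1, 2), b = 0), "positive")
  expect_error(fidelity_spec("kl", y = c(-1, 2), b = 0.1), "non-negative")
  expect_silent(fidelity_spec("l2", y = c(-1, 2), b = 0))
})
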
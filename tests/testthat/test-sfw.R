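test_that("objective combines fidelity, TV penalty and the constraint", {
  prob <- small_kl_problem(positions = 0.4, amplitudes = 1)
  m0 <- zero_measure(1L)
  # zero measure: objective is the divergence between background and data
  expect_equal(sfw_objective(m0, 2, prob$spec, prob$psf, prob$grid),
               kl_fidelity(numeric(64), prob$spec, prob$grid))
  # indicator of the non-negativity constraint
  mneg <- dirac_measure(c(0.3, 0.6), c(1, -0.1))
  expect_identical(sfw_objective(mneg, 1, prob$spec, prob$psf, prob$grid), Inf)
  # lambda = 0 reduces to the bare fidelity
  m <- dirac_measure(0.5, 0.7)
  expect_equal(sfw_objective(m, 0, prob$spec, prob$psf, prob$grid),
               residual(m, prob$spec, prob$psf, prob$grid))
})

test_that("certificate argmax finds a missing spike location", {
  prob <- small_kl_problem(positions = 0.437, amplitudes = 1)
  cert <- dual_certificate(zero_measure(1L), 0.05, prob$spec, prob$psf,
                           prob$grid)
  cand <- certificate_argmax(cert, prob$grid, sfw_config())
  expect_lt(abs(cand$x - 0.437), 1 / (64 * 4))     # within a fine cell
  # the polished value can only improve on the lattice scan
  s <- certificate_sup(cert, prob$grid, refine = 4L, polish = FALSE)
  expect_gte(cand$value, s$value)
})

test_that("amplitude step solves the penalised least-squares problem", {
  grid <- unit_grid_1d(64L)
  psf <- psf_1d()
  # noiseless L2, b = 0, true position, lambda ~ 0: closed form
  y <- forward_image(dirac_measure(0.5, 1.3), psf, grid)
  spec <- fidelity_spec("l2", y = y, b = 0, alpha = 0L)
  res <- amplitude_step(matrix(0.5), 1e-10, spec, psf, grid)
  phi <- forward_image(dirac_measure(0.5, 1), psf, grid)
  a_closed <- image_inner(y, phi, grid) / image_inner(phi, phi, grid)
  expect_equal(res$amplitudes, a_closed, tolerance = 1e-6)
  expect_equal(res$amplitudes, 1.3, tolerance = 1e-6)

  # lambda at least the certificate sup at zero: all-zero is optimal
  cert0 <- dual_certificate(zero_measure(1L), 1, spec, psf, grid)
  sup0 <- certificate_sup(cert0, grid)$value
  res0 <- amplitude_step(matrix(c(0.4, 0.6), 2L), sup0 * 1.01, spec, psf,
                         grid, init = c(0.5, 0.5))
  expect_equal(res0$amplitudes, c(0, 0), tolerance = 1e-8)

  # KL with the constraint active: no negative amplitudes
  prob <- small_kl_problem(positions = c(0.35, 0.65), amplitudes = c(1, 0.4))
  resk <- amplitude_step(rbind(0.35, 0.5, 0.65), 0.05, prob$spec, prob$psf,
                         prob$grid)
  expect_true(all(resk$amplitudes >= 0))
})

test_that("amplitude step matches brute-force solvers on small supports", {
  grid <- unit_grid_1d(48L)
  psf <- psf_1d()
  set.seed(51)
  for (rep_i in 1:4) {
    pos <- matrix(sort(stats::runif(3, 0.15, 0.85)), 3L)
    a_true <- stats::runif(3, 0.3, 1.2)
    y <- forward_image(dirac_measure(pos, a_true), psf, grid) +
      0.05 * stats::rnorm(48)
    lam <- stats::runif(1, 0.05, 0.5)
    B <- offgridspikes:::spike_basis(pos, psf, grid)
    cfg <- sfw_config(amp_solver_iters = 5000L, amp_solver_tol = 1e-14)

    # non-negative model vs KKT active-set enumeration
    spec1 <- fidelity_spec("l2", y = y, b = 0, alpha = 1L)
    mine1 <- amplitude_step(pos, lam, spec1, psf, grid, cfg)
    oracle1 <- nnlasso_enumerate(B, y, lam, grid$pixel_measure)
    expect_equal(mine1$amplitudes, oracle1$amplitudes, tolerance = 1e-6)

    # unconstrained model vs sign-pattern enumeration
    spec0 <- fidelity_spec("l2", y = y, b = 0, alpha = 0L)
    mine0 <- amplitude_step(pos, lam, spec0, psf, grid, cfg)
    oracle0 <- lasso_enumerate(B, y, lam, grid$pixel_measure)
    expect_equal(mine0$amplitudes, oracle0$amplitudes, tolerance = 1e-6)
  }

  # KL model vs an independent smooth constrained optimiser (the penalty
  # is linear on a >= 0, so the problem is smooth there)
  set.seed(52)
  for (rep_i in 1:3) {
    pos <- matrix(sort(stats::runif(2, 0.2, 0.8)), 2L)
    yk <- forward_image(dirac_measure(pos, c(0.8, 1.1)), psf, grid) + 0.01
    yk <- stats::rpois(48, 64 * yk) / 64
    speck <- fidelity_spec("kl", y = yk, b = 0.01)
    lam <- 0.05
    cfg <- sfw_config(amp_solver_iters = 20000L, amp_solver_tol = 1e-15)
    mine <- amplitude_step(pos, lam, speck, psf, grid, cfg)
    B <- offgridspikes:::spike_basis(pos, psf, grid)
    fobj <- function(a) kl_fidelity(drop(B %*% a), speck, grid) + lam * sum(a)
    ora <- stats::optim(c(0.5, 0.5), fobj, method = "L-BFGS-B",
                        lower = c(0, 0),
                        control = list(factr = 10, maxit = 500))
    expect_equal(mine$amplitudes, ora$par, tolerance = 1e-5)
    expect_lte(mine$objective, ora$value + 1e-9)
  }
})

test_that("sliding refines positions without increasing the objective", {
  prob <- small_kl_problem(positions = 0.5, amplitudes = 1)
  lam <- 1e-3
  # an offset start: the slide must strictly reduce the position error
  half_px <- 0.5 / 64
  m_off <- dirac_measure(0.5 + half_px, 1)
  slid <- sliding_step(m_off, lam, prob$spec, prob$psf, prob$grid)
  expect_lt(abs(slid$positions[1, 1] - 0.5), half_px)
  o0 <- sfw_objective(m_off, lam, prob$spec, prob$psf, prob$grid)
  o1 <- sfw_objective(slid, lam, prob$spec, prob$psf, prob$grid)
  expect_lte(o1, o0)

  # a (near) local minimum is a fixed point
  amp <- amplitude_step(matrix(0.5), lam, prob$spec, prob$psf, prob$grid,
                        config = sfw_config(amp_solver_iters = 5000L))
  m_star <- dirac_measure(0.5, amp$amplitudes)
  slid2 <- sliding_step(m_star, lam, prob$spec, prob$psf, prob$grid)
  expect_equal(slid2$positions[1, 1], 0.5, tolerance = 1e-4)
  expect_equal(slid2$amplitudes, m_star$amplitudes, tolerance = 1e-3)
})

test_that("the solver recovers noiseless spikes and certifies optimality", {
  cfg <- sfw_config(max_iters = 8L)
  for (kind in c("kl", "l2")) {
    prob <- if (kind == "kl") small_kl_problem(0.5, 1)
            else small_l2_problem(0.5, 1)
    lam <- 1e-3
    res <- sfw_solve(prob$spec, prob$psf, prob$grid, lam, config = cfg)
    expect_true(res$converged)
    expect_equal(res$measure$n, 1L)
    expect_lt(abs(res$measure$positions[1, 1] - 0.5), 1e-3)
    expect_lt(abs(res$measure$amplitudes[1] - 1), 1e-2)
    # optimality: certificate <= 1 + tol everywhere, ~ 1 on the support
    cert <- dual_certificate(res$measure, lam, prob$spec, prob$psf,
                             prob$grid)
    expect_lte(certificate_sup(cert, prob$grid)$value, 1 + 1e-3)
    at_spikes <- cert$eval(res$measure$positions)
    expect_true(all(abs(at_spikes - 1) < 1e-2))
  }

  # well-separated two-spike problem
  prob2 <- small_kl_problem(c(0.3, 0.75), c(1, 0.8))
  res2 <- sfw_solve(prob2$spec, prob2$psf, prob2$grid, 1e-3, config = cfg)
  ev <- evaluate_spikes(prob2$gt, res2$measure, 0.05)
  expect_equal(ev$tp, 2L)
  expect_lt(ev$rmse_x, 1e-3)
  expect_lt(ev$rmse_a, 1e-2)
  # any residual unmatched mass is numerically negligible
  mt <- match_spikes(prob2$gt, res2$measure, 0.05)
  spurious <- setdiff(seq_len(res2$measure$n), mt$pairs$rec)
  expect_lt(sum(abs(res2$measure$amplitudes[spurious])), 1e-3)
})

test_that("solver contracts: no-iteration case and monotone objective", {
  prob <- small_kl_problem(c(0.4, 0.7), c(1, 1))
  m0 <- zero_measure(1L)
  cert1 <- dual_certificate(m0, 1, prob$spec, prob$psf, prob$grid)
  sup1 <- certificate_sup(cert1, prob$grid)$value
  # lambda above the certificate scale: initialisation already optimal
  res <- sfw_solve(prob$spec, prob$psf, prob$grid, sup1 * 1.01, m0 = m0)
  expect_true(res$converged)
  expect_equal(res$n_iters, 0L)
  expect_equal(res$measure$n, 0L)

  # noisy problem: accepted objective values never increase
  set.seed(61)
  y <- stats::rpois(64, 128 * (prob$spec$y)) / 128
  spec <- fidelity_spec("kl", y = y, b = 0.01)
  res2 <- sfw_solve(spec, prob$psf, prob$grid, 0.02,
                    config = sfw_config(max_iters = 6L))
  expect_true(all(diff(res2$objective_trace) <= 1e-12))

  # tightening the stopping slack cannot worsen the final objective
  res_loose <- sfw_solve(spec, prob$psf, prob$grid, 0.02,
                         config = sfw_config(max_iters = 10L, cert_tol = 0.3))
  res_tight <- sfw_solve(spec, prob$psf, prob$grid, 0.02,
                         config = sfw_config(max_iters = 10L, cert_tol = 1e-4))
  expect_lte(utils::tail(res_tight$objective_trace, 1L),
             utils::tail(res_loose$objective_trace, 1L) + 1e-10)
})
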
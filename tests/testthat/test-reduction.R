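test_that("binomial central sums reduce to the familiar central moments", {
  m <- c(0.4, 0.2, 0.11, 0.066)   # m1..m4 of some admissible distribution
  expect_equal(central_sum(0, 0, m[1], m), 1)
  expect_equal(central_sum(1, 0, m[1], m), 0)
  expect_equal(central_sum(2, 0, m[1], m), m[2] - m[1]^2)
  expect_equal(central_sum(3, 0, m[1], m),
               m[3] - 3 * m[1] * m[2] + 2 * m[1]^3)
  expect_error(central_sum(3, 2, m[1], m), "close_moments")
})

test_that("closures extend a moment sequence correctly", {
  spec_t <- closure_spec(2, 2, "truncation")
  expect_equal(close_moments(c(0.3, 0.2), 4, spec_t), c(0.3, 0.2, 0, 0))
  # Gaussian closure must reproduce true normal moments; quadrature oracle
  for (ms in list(c(0, 1), c(0.3, 0.2))) {
    mean <- ms[1]; sd <- sqrt(ms[2])
    m12 <- c(mean, normal_raw_moment(2, mean, sd))
    got <- close_moments(m12, 6, closure_spec(2, 4, "gaussian"))
    want <- vapply(1:6, normal_raw_moment, numeric(1), mean = mean, sd = sd)
    expect_equal(got, want, tolerance = 1e-9)
  }
  # the literal recursion (prefactor k) overshoots: m4 = 4 for the standard
  # normal instead of the true 3 -- kept only for comparison studies
  lit <- close_moments(c(0, 1), 4, closure_spec(2, 2, "gaussian_literal"))
  expect_equal(lit[3:4], c(0, 4))
  expect_error(close_moments(c(0, 1), 3,
                             structure(list(method = "bogus"),
                                       class = "closure_spec")),
               "unknown closure")
})

test_that("Taylor coefficients are exact for the worked models", {
  qm <- quadratic_model(1.1, 0.6, 0.35, 0.02, beta = 0, domain = c(-2, 2))
  x0 <- 0.8
  expect_equal(taylor_coefficients(qm, "f", x0, 3),
               c(1.1 - 0.6 * (x0 - 0.35)^2, -1.2 * (x0 - 0.35), -0.6, 0))
  expect_equal(taylor_coefficients(qm, "V", x0, 2), c(0.02, 0, 0))
  hm <- hill_benchmark()
  # f' = f_max k_x / (k_x + x)^2, halved at x = k_x twice over
  expect_equal(taylor_coefficients(hm, "f", 0.4, 1), c(1, 2 / 1.6),
               tolerance = 1e-12)
  expect_error(taylor_coefficients(hm, "f", 7, 2), "outside")
})

test_that("a truncated Taylor series of a polynomial is expansion-point independent", {
  qm <- quadratic_model(0.9, 1.4, 0.25, 0, beta = 0, domain = c(-3, 3))
  xs <- c(-1.5, 0.2, 1.1)
  set.seed(42)
  for (x in xs) {
    fx <- qm$f(0, x, 1)
    for (x0 in stats::runif(20, -3, 3)) {
      cf <- taylor_coefficients(qm, "f", x0, 2)
      expect_equal(sum(cf * (x - x0)^(0:2)), fx, tolerance = 1e-10)
    }
  }
})

test_that("the generic assembly collapses onto the classical quadratic system", {
  a <- 1.3; b <- 0.7; X <- 0.4; V0 <- 0.05; beta <- 1e-3; kappa <- 2
  mod <- quadratic_model(a, b, X, V0, beta = beta, kappa = kappa,
                         domain = c(-5, 5))
  spec <- closure_spec(2, 2, "gaussian")
  set.seed(7)
  for (i in 1:300) {
    P <- stats::runif(1, 0.05, 3)
    m1 <- stats::runif(1, -1, 1)
    s2 <- stats::runif(1, 1e-3, 0.5)
    st <- moment_state(P, c(m1, s2 + m1^2))
    got <- moment_rhs(st, mod, spec, t = 0, warn = FALSE)
    want <- classical_quadratic_rhs(P, m1, s2, a, b, X, V0, beta, kappa)
    expect_equal(got, unname(want), tolerance = 1e-12)
  }
  # the literal closure does NOT collapse onto it (the m3 term differs)
  got_lit <- moment_rhs(moment_state(1, c(0.3, 0.3^2 + 0.1)), mod,
                        closure_spec(2, 2, "gaussian_literal"),
                        t = 0, warn = FALSE)
  want <- classical_quadratic_rhs(1, 0.3, 0.1, a, b, X, V0, beta, kappa)
  expect_gt(abs(got_lit[2] - want[2]), 1e-4)
})

test_that("degenerate states have the expected right-hand sides", {
  flat <- quadratic_model(0, 0, 0.5, 0, beta = 0, kappa = 0.7,
                          domain = c(0, 1))
  st <- moment_state(0.4, c(0.5, 0.26))
  rhs <- moment_rhs(st, flat, closure_spec(2, 2, "gaussian"), warn = FALSE)
  expect_equal(rhs, c(-0.4^2 / 0.7, 0, 0))
  # monomorphic population: the selection term vanishes, drift remains
  qm <- quadratic_model(1, 2, 0.8, 0.07, beta = 0, kappa = Inf,
                        domain = c(0, 1))
  mono <- moment_state(1, c(0.3, 0.09))
  expect_equal(moment_rhs(mono, qm, closure_spec(2, 2, "gaussian"),
                          warn = FALSE)[2], 0.07)
  expect_error(moment_rhs(structure(list(P = -1, m = c(0.3, 0.1), t = 0),
                                    class = "moment_state"),
                          qm, closure_spec(2, 2, "gaussian")), "positive")
  expect_warning(moment_rhs(moment_state(1, c(1.4, 2.2)), qm,
                            closure_spec(2, 2, "gaussian")),
                 "series-truncation")
})

test_that("moment ODEs reproduce closed-form variance dynamics", {
  beta <- 2e-3
  mod <- quadratic_model(0.5, 0, 0.5, 0, beta = beta, kappa = Inf,
                         domain = c(-20, 20))
  s0 <- moment_state(1, c(0.4, 0.4^2 + 0.01))
  tr <- integrate_moments(s0, mod, closure_spec(2, 2, "gaussian"),
                          t_span = c(0, 10), n_out = 51)
  s2 <- tr$m[, 2] - tr$m[, 1]^2
  expect_equal(s2, 0.01 + 2 * beta * tr$times, tolerance = 1e-8)
  # with selection, the variance settles at sqrt(beta / b_sel); finite
  # carrying capacity keeps the population bounded over the long horizon
  b <- 0.8
  mod2 <- quadratic_model(0.5, b, 0.5, 0, beta = beta, kappa = 1,
                          domain = c(-20, 20))
  tr2 <- integrate_moments(moment_state(1, c(0.5, 0.5^2 + 0.04)), mod2,
                           closure_spec(2, 2, "gaussian"),
                           t_span = c(0, 2000), n_out = 21)
  s2_end <- unname(tr2$m[21, 2] - tr2$m[21, 1]^2)
  expect_equal(s2_end, sqrt(beta / b), tolerance = 1e-6)
})

test_that("integrated population size respects the growth-rate bound", {
  # f <= a everywhere, so P can never exceed max(P0, kappa * a)
  a <- 0.9; kappa <- 1.5
  mod <- quadratic_model(a, 0.5, 0.5, 0, beta = 1e-3, kappa = kappa,
                         domain = c(-10, 10))
  tr <- integrate_moments(moment_state(0.1, c(0.2, 0.2^2 + 0.02)), mod,
                          closure_spec(2, 2, "gaussian"),
                          t_span = c(0, 50), n_out = 101)
  expect_lt(max(tr$P), max(0.1, kappa * a) * (1 + 1e-6))
})

test_that("initial moments come out of densities correctly", {
  # uniform density
  st <- initial_moments_from_density(function(x) rep(2, length(x)), 2,
                                     domain = c(0, 1))
  expect_equal(st$P, 2, tolerance = 1e-9)
  expect_equal(st$m, c(1 / 2, 1 / 3), tolerance = 1e-9)
  # the benchmark's bell-shaped start: mean recovered exactly (the
  # boundaries sit 10 sd away, truncation is immaterial)
  stf <- initial_moments_from_density(hill_benchmark_p0(), 2,
                                      domain = c(0, 1.2))
  expect_equal(stf$m[1], 0.2, tolerance = 1e-6)
  # sharp limit: m_k -> xbar^k
  std <- initial_moments_from_density(
    truncated_normal_density(0.6, 0.01, 0, 1, 1), 3, domain = c(0, 1))
  expect_equal(std$m, c(0.6, 0.36, 0.216), tolerance = 2e-3)
  expect_error(initial_moments_from_density(function(x) 0 * x, 2,
                                            domain = c(0, 1)), "mass")
})

test_that("moment rescaling is exact and invertible", {
  # pure scaling, l = 0
  expect_equal(rescale_moments(c(0.24, 0.09), "to_unit", 0, 1.2),
               c(0.2, 0.0625))
  m <- c(0.24, 0.09, 0.05)
  expect_equal(rescale_moments(rescale_moments(m, "to_unit", 0, 1.2),
                               "from_unit", 0, 1.2), m, tolerance = 1e-12)
  # affine case checked against direct quadrature of the mapped density
  l <- 0.1; L <- 1.1
  p0 <- truncated_normal_density(0.5, 0.12, l, L, 1)
  m_orig <- initial_moments_from_density(p0, 3, domain = c(l, L))$m
  q0 <- function(y) p0(l + (L - l) * y) * (L - l)   # density of (x-l)/(L-l)
  m_unit_direct <- initial_moments_from_density(q0, 3, domain = c(0, 1))$m
  expect_equal(rescale_moments(m_orig, "to_unit", l, L), m_unit_direct,
               tolerance = 1e-9)
  expect_error(rescale_moments(m, "to_unit", 1, 1), "exceed")
})

test_that("reduced and full dynamics agree for the Hill/tanh benchmark", {
  mod <- hill_benchmark()
  sol <- solve_pde(mod, hill_benchmark_p0(), t_end = 35,
                   grid = pde_grid(c(0, 1.2), 300), n_out = 71)
  mt <- extract_moments(sol, 2)
  st0 <- initial_moments_from_density(hill_benchmark_p0(), 2,
                                      domain = c(0, 1.2))
  tr <- integrate_moments(rescale_moments(st0, "to_unit", 0, 1.2),
                          rescale_model_to_unit(mod),
                          closure_spec(2, 2, "gaussian"),
                          t_span = sol$times)
  cmp <- compare_moments(mt, rescale_moments(tr, "from_unit", 0, 1.2))
  expect_lt(cmp$sup_rel_err[cmp$quantity == "m1"], 0.05)
})

test_that("a degenerate time horizon returns the initial state", {
  mod <- quadratic_model(1, 1, 0.5, 0, beta = 0, domain = c(0, 1))
  s0 <- moment_state(1, c(0.5, 0.26))
  tr <- integrate_moments(s0, mod, closure_spec(2, 2, "gaussian"),
                          t_span = c(0, 0))
  expect_equal(length(tr$times), 1L)
  expect_equal(unname(tr$m[1, ]), s0$m)
})
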
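test_that("constructors validate their inputs", {
  f0 <- function(t, x, P) 0 * x
  expect_error(phenotype_model(f0, f0, beta = -1, domain = c(0, 1)), "beta")
  expect_error(phenotype_model(f0, f0, beta = 0, kappa = 0, domain = c(0, 1)),
               "kappa")
  expect_error(phenotype_model(f0, f0, beta = 0, domain = c(1, 0)), "domain")
  expect_error(phenotype_model(function(t, x, P) 1 / x, f0, beta = 0,
                               domain = c(0, 1)), "finite")
  expect_error(quadratic_model(a = 1, b_sel = -2, X = 0, V0 = 0, beta = 0),
               "b_sel")
  expect_error(hill_tanh_model(2, 0.4, 0.5, omega = 3, beta = 0), "omega")
  expect_error(gfunction_params(0.5, 0.1, 0.01, k_half = 0, b_res = 1,
                                kappa = 1, alpha = 0), "k_half")
  expect_error(gfunction_params(-0.5, 0.1, 0.01, 1, 1, 1, 0), "r_max")
})

test_that("quadratic model has exact polynomial Taylor structure", {
  mod <- quadratic_model(a = 1, b_sel = 2, X = 0.5, V0 = 0.3, beta = 0,
                         domain = c(-1, 2))
  # expansion at the fitness peak: slope vanishes, curvature is -b_sel
  expect_equal(taylor_coefficients(mod, "f", 0.5, 4), c(1, 0, -2, 0, 0))
  # away from the peak
  expect_equal(taylor_coefficients(mod, "f", 0, 3), c(0.5, 2, -2, 0))
  # constant drift: c0 only
  expect_equal(taylor_coefficients(mod, "V", 0.7, 3), c(0.3, 0, 0, 0))
  # degenerate flat model
  flat <- quadratic_model(0, 0, 0.5, 0, beta = 0, domain = c(0, 1))
  xs <- seq(0, 1, length.out = 11)
  expect_equal(flat$f(0, xs, 1), rep(0, 11))
  expect_equal(flat$V(0, xs, 1), rep(0, 11))
})

test_that("analytic derivative providers agree with high-order finite differences", {
  probe_model <- function(mod, t = 0, P = 0.05, orders = 1:3, n_probe = 50,
                          pad = 0.05) {
    d <- mod$domain
    h <- 0.01 * (d[2] - d[1])
    xs <- seq(d[1] + pad * (d[2] - d[1]), d[2] - pad * (d[2] - d[1]),
              length.out = n_probe)
    for (which in c("f", "V")) {
      g <- function(x) if (which == "f") mod$f(t, x, P) else mod$V(t, x, P)
      prov <- if (which == "f") mod$df_dx else mod$dV_dx
      for (n in orders) {
        got <- vapply(xs, function(x) prov(t, x, P, n)[1], numeric(1))
        want <- vapply(xs, function(x) richardson_deriv(g, x, n, h),
                       numeric(1))
        lab <- sprintf("%s model, %s, order %d", mod$name, which, n)
        if (max(abs(want)) < 1e-6) {
          # derivative is identically (numerically) zero
          expect_lt(max(abs(got)), 1e-6, label = lab)
        } else {
          expect_lt(max(abs(got - want)) / max(abs(want)), 1e-5,
                    label = paste(lab, "rel err"))
        }
      }
    }
  }
  probe_model(quadratic_model(1.3, 0.7, 0.4, 0.05, beta = 1e-3,
                              domain = c(-1, 2)))
  probe_model(hill_benchmark(omega = 1))
  probe_model(hill_benchmark(omega = 2))
  gp <- gfunction_params(0.45, 0.8, 0.01, 1, 10, 1e4, 1e-4)
  probe_model(gfunction_model(gp, c_of_t = function(t) 1, beta = 0,
                              domain = c(0, 3)), P = 6000)
  # third derivatives of the quadratic growth vanish identically
  qm <- quadratic_model(1, 2, 0.5, 0, beta = 0, domain = c(0, 1))
  expect_equal(qm$df_dx(0, 0.3, 1, 3L), 0)
  expect_equal(qm$df_dx(0, 0.9, 1, 5L), 0)
})

test_that("Hill growth and tanh drift hit their landmark values", {
  mod <- hill_benchmark()
  # half-saturation at x = k_x, and the benchmark parameter set gives 1 there
  expect_equal(mod$f(0, 0.4, 1), 1)
  expect_equal(hill_tanh_model(3, 0.25, 1, 1, beta = 0)$f(0, 0.25, 1), 1.5)
  # drift vanishes where either tanh factor vanishes
  expect_equal(mod$V(0, 1, 1), 0)
  expect_equal(mod$V(0, 0, 1), 0)
  # closed-form first derivative of the Hill term at the Michaelis constant
  cf <- taylor_coefficients(mod, "f", 0.4, 1)
  expect_equal(cf, c(2 / 2, 2 / (4 * 0.4)), tolerance = 1e-12)
})

test_that("G-function model satisfies its structural identities", {
  gp <- gfunction_params(r_max = 0.6, g = 0.3, d = 0.07, k_half = 1.5,
                         b_res = 12, kappa = 5e3, alpha = 1e-4)
  off <- gfunction_model(gp, c_of_t = function(t) 0, beta = 0,
                         domain = c(0, 4))
  xs <- seq(0, 4, length.out = 17)
  # without treatment and at carrying capacity, fitness is pure death ...
  expect_equal(off$f(0, xs, gp$kappa), rep(-gp$d, 17))
  # ... and flat in the trait, so the drift vanishes too
  expect_equal(off$dV_dx(0, xs, gp$kappa, 0L) * 0 +
                 off$V(0, xs, gp$kappa), rep(0, 17))
  # no treatment, vanishing population: intrinsic growth minus death
  expect_equal(off$f(0, 0, 1e-12), gp$r_max - gp$d, tolerance = 1e-12)

  # gradient of fitness: symbolic differentiation as independent oracle
  on <- gfunction_model(gp, c_of_t = function(t) 1, beta = 0,
                        domain = c(0, 4))
  P <- 2000
  Gexpr <- quote(r_max * exp(-g * x) * (1 - P / kappa) - d -
                   1 / (k_half + b_res * x))
  dG <- stats::D(Gexpr, "x")
  env <- list(r_max = gp$r_max, g = gp$g, d = gp$d, k_half = gp$k_half,
              b_res = gp$b_res, kappa = gp$kappa, P = P)
  want <- vapply(xs, function(x) eval(dG, c(env, list(x = x))), numeric(1))
  got <- on$df_dx(0, xs, P, 1L)
  expect_equal(got, want, tolerance = 1e-12)
  # and it matches the closed form r'(x)(1 - P/kappa) + c b/(k + b x)^2
  expect_equal(got,
               -gp$g * gp$r_max * exp(-gp$g * xs) * (1 - P / gp$kappa) +
                 gp$b_res / (gp$k_half + gp$b_res * xs)^2,
               tolerance = 1e-12)
})

test_that("parameter files round-trip through the JSON reader", {
  f <- system.file("extdata", "gfunction_params_synthetic.json",
                   package = "phenomoments")
  gp <- read_gfunction_params(f)
  expect_s3_class(gp, "gfunction_params")
  expect_equal(gp$kappa, 1e4)
  expect_equal(gp$b_res, 60)
})
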
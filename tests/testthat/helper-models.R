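# Shared builders and independent numerical oracles.

# The Hill-growth/tanh-drift benchmark problem (growth saturating in x,
# drift pushing mass toward x = 1, logistic competition).
hill_benchmark <- function(omega = 1, domain = c(0, 1.2)) {
  hill_tanh_model(f_max = 2, k_x = 0.4, V_max = 0.5, omega = omega,
                  beta = 1e-4, kappa = 0.1, domain = domain)
}

hill_benchmark_p0 <- function(domain = c(0, 1.2)) {
  truncated_normal_density(0.2, 0.02, domain[1], domain[2], 1)
}

# Drift/growth-free diffusion model (conservation and variance checks).
diffusion_only_model <- function(beta, domain = c(0, 1)) {
  phenotype_model(function(t, x, P) 0 * x, function(t, x, P) 0 * x,
                  beta = beta, kappa = Inf, domain = domain,
                  competition_enabled = FALSE, name = "diffusion_only")
}

# Twice-Richardson-extrapolated central difference: O(h^6) oracle for
# d^n g / dx^n, independent of the package's derivative providers.
richardson_deriv <- function(g, x, n, h) {
  fd <- function(hh) {
    i <- 0:n
    sum((-1)^i * choose(n, i) * g(x + (n / 2 - i) * hh)) / hh^n
  }
  r1 <- (4 * fd(h / 2) - fd(h)) / 3
  r2 <- (4 * fd(h / 4) - fd(h / 2)) / 3
  (16 * r2 - r1) / 15
}

# Raw moments of a (possibly truncated) normal by adaptive quadrature:
# oracle for the Gaussian closure recursion.
normal_raw_moment <- function(k, mean, sd, lower = -Inf, upper = Inf) {
  stats::integrate(function(x) x^k * stats::dnorm(x, mean, sd),
                   lower, upper, rel.tol = 1e-12)$value /
    stats::integrate(function(x) stats::dnorm(x, mean, sd),
                     lower, upper, rel.tol = 1e-12)$value
}

# Classical population-size / mean-trait / variance system for quadratic
# selection with constant drift, written directly (not via the reduction):
# independent oracle for the exact-equivalence property.
classical_quadratic_rhs <- function(P, m1, s2, a, b, X, V0, beta, kappa) {
  dP <- (a - b * (m1 - X)^2 - b * s2) * P - P^2 / kappa
  dm1 <- -2 * b * (m1 - X) * s2 + V0
  ds2 <- 2 * beta - 2 * b * s2^2
  c(dP = dP, dm1 = dm1, dm2 = ds2 + 2 * m1 * dm1)  # m2 = s2 + m1^2
}

# Synthetic G-function parameter set under which all three therapy variants
# progress quickly (strong resistance benefit): used for ordering and
# switching tests.
fast_failure_gparams <- function() {
  gfunction_params(r_max = 0.45, g = 0.1, d = 0.01, k_half = 1,
                   b_res = 500, kappa = 1e4, alpha = 1e-5)
}
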
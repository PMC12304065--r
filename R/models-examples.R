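## Constructors for the three worked example models: quadratic selection with
## constant drift, Hill growth with tanh drift, and the G-function
## adaptive-dynamics model.

# Accept a constant or a function of time.
as_tfun <- function(z, what) {
  if (is.function(z)) return(z)
  if (is.numeric(z) && length(z) == 1L && is.finite(z)) {
    force(z); return(function(t) z)
  }
  stop("'", what, "' must be a single number or a function of t")
}

#' Quadratic-selection model with constant drift
#'
#' Growth rate \eqn{f(t,x) = a(t) - b_{sel}(t) (x - X(t))^2} and drift
#' \eqn{V(t,x) = V_0(t)}: the polynomial special case in which the moment
#' reduction (with two tracked moments and Gaussian closure) is exactly the
#' classical population-size / mean-trait / variance ODE system.  `X` is the
#' fittest trait, `a` the background fitness at that trait, and `b_sel` the
#' selection gradient.
#'
#' All four parameters may be constants or functions of time.  Derivatives in
#' `x` are analytic: all orders above 2 of `f` (above 0 of `V`) vanish.
#'
#' @param a background fitness at the fittest trait (1/time).
#' @param b_sel selection gradient \eqn{\ge 0} (1/(time x phenotype^2)).
#' @param X fittest trait (phenotype).
#' @param V0 constant drift velocity (phenotype/time).
#' @param beta,kappa,domain see [phenotype_model()].
#' @return a [phenotype_model()].
#' @export
quadratic_model <- function(a, b_sel, X, V0, beta, kappa = Inf,
                            domain = c(0, 1)) {
  if (is.numeric(b_sel) && any(b_sel < 0))
    stop("'b_sel' must be non-negative")
  af <- as_tfun(a, "a"); bf <- as_tfun(b_sel, "b_sel")
  Xf <- as_tfun(X, "X"); Vf <- as_tfun(V0, "V0")

  f <- function(t, x, P) af(t) - bf(t) * (x - Xf(t))^2
  V <- function(t, x, P) rep_len(Vf(t), length(x))
  df <- function(t, x, P, order) {
    switch(as.character(order),
           "0" = f(t, x, P),
           "1" = -2 * bf(t) * (x - Xf(t)),
           "2" = rep_len(-2 * bf(t), length(x)),
           rep_len(0, length(x)))
  }
  dV <- function(t, x, P, order) {
    if (order == 0L) V(t, x, P) else rep_len(0, length(x))
  }
  phenotype_model(f, V, beta = beta, kappa = kappa, domain = domain,
                  df_dx = df, dV_dx = dV, name = "quadratic")
}

# n-th x-derivative expressions of an expression, via repeated stats::D.
d_exprs <- function(expr, n_max) {
  out <- vector("list", n_max + 1L)
  out[[1L]] <- expr
  for (n in seq_len(n_max)) out[[n + 1L]] <- stats::D(out[[n]], "x")
  out
}

#' Hill-growth / tanh-drift model
#'
#' Growth rate \eqn{f(t,x) = f_{max}\, x / (k_x + x)} (Michaelis-Menten
#' saturation in the expression level \eqn{x}) and drift
#' \eqn{V(t,x) = V_{max} \tanh(x^\omega) \tanh(1 - x)}, a smooth but
#' non-polynomial pair for which the Taylor truncation order genuinely
#' matters.  Derivatives of `f` are closed-form; derivatives of `V` are exact
#' symbolic derivatives (tanh rewritten through exp and differentiated
#' repeatedly), evaluated at run time.
#'
#' @param f_max maximum intrinsic growth rate \eqn{\ge 0} (1/time).
#' @param k_x Michaelis coefficient \eqn{> 0} (phenotype).
#' @param V_max maximal drift speed \eqn{\ge 0} (phenotype/time).
#' @param omega drift exponent, 1 or 2.
#' @param beta,kappa,domain see [phenotype_model()].
#' @param max_order highest x-derivative of `V` prepared symbolically.
#' @return a [phenotype_model()].
#' @export
hill_tanh_model <- function(f_max, k_x, V_max, omega = 1, beta,
                            kappa = Inf, domain = c(0, 1.2),
                            max_order = 8L) {
  stopifnot(is.numeric(f_max), length(f_max) == 1L, f_max >= 0,
            is.numeric(k_x), length(k_x) == 1L, k_x > 0,
            is.numeric(V_max), length(V_max) == 1L, V_max >= 0)
  if (!(omega %in% c(1, 2))) stop("'omega' must be 1 or 2")

  f <- function(t, x, P) f_max * x / (k_x + x)
  # f = f_max (1 - k_x/(k_x+x)):  d^n f = f_max k_x (-1)^(n+1) n! (k_x+x)^-(n+1)
  df <- function(t, x, P, order) {
    if (order == 0L) return(f(t, x, P))
    f_max * k_x * (-1)^(order + 1) * factorial(order) /
      (k_x + x)^(order + 1)
  }

  # tanh(z) = 1 - 2/(exp(2 z) + 1), so stats::D can differentiate it.
  vexpr <- if (omega == 1) {
    quote(V_max * (1 - 2 / (exp(2 * x) + 1)) *
            (1 - 2 / (exp(2 * (1 - x)) + 1)))
  } else {
    quote(V_max * (1 - 2 / (exp(2 * x^2) + 1)) *
            (1 - 2 / (exp(2 * (1 - x)) + 1)))
  }
  vds <- d_exprs(vexpr, max_order)
  venv <- list(V_max = V_max)
  V <- function(t, x, P) eval(vds[[1L]], c(venv, list(x = x)))
  dV <- function(t, x, P, order) {
    if (order > max_order)
      stop("hill_tanh_model: symbolic V derivatives prepared up to order ",
           max_order)
    v <- eval(vds[[order + 1L]], c(venv, list(x = x)))
    rep_len(v, length(x))
  }

  phenotype_model(f, V, beta = beta, kappa = kappa, domain = domain,
                  df_dx = df, dV_dx = dV, name = "hill_tanh")
}

#' Parameters of the G-function adaptive-dynamics model
#'
#' Validates and bundles the parameters of the fitness-generating function
#' \deqn{G(x, P) = r_{max} e^{-g x} (1 - P/\kappa) - d - c(t)/(k_{half} + b_{res} x),}
#' where \eqn{x} is the resistance trait, \eqn{c(t) \in \{0,1\}} the
#' treatment signal, and the drift velocity is gradient ascent on fitness,
#' \eqn{V = \alpha \partial_x G}.
#'
#' @param r_max maximal growth rate (1/time).
#' @param g cost of resistance (1/phenotype).
#' @param d intrinsic death rate (1/time).
#' @param k_half treatment half-effect constant (dimensionless), \eqn{> 0}.
#' @param b_res resistance benefit (1/phenotype).
#' @param kappa carrying capacity (cells).
#' @param alpha speed of phenotypic adaptation (phenotype^2/time).
#' @return a list of class `gfunction_params`.
#' @export
gfunction_params <- function(r_max, g, d, k_half, b_res, kappa, alpha) {
  p <- list(r_max = r_max, g = g, d = d, k_half = k_half,
            b_res = b_res, kappa = kappa, alpha = alpha)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("'", nm, "' must be a single non-negative number")
  }
  if (k_half <= 0) stop("'k_half' must be positive")
  if (kappa <= 0) stop("'kappa' must be positive")
  structure(p, class = "gfunction_params")
}

#' Read G-function parameters from a JSON file
#'
#' @param file path to a JSON object with the fields of
#'   [gfunction_params()].  The package ships
#'   `inst/extdata/gfunction_params_synthetic.json`, a synthetic stand-in
#'   parameter set (see the vignette) for the adaptive-therapy example.
#' @return a `gfunction_params` object.
#' @export
read_gfunction_params <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  keep <- intersect(names(j),
                    c("r_max", "g", "d", "k_half", "b_res", "kappa", "alpha"))
  do.call(gfunction_params, j[keep])
}

# G and its exact x-derivatives.  For n >= 1:
#   d^n/dx^n [r_max e^{-gx}] = (-g)^n r_max e^{-gx}
#   d^n/dx^n [-c/(k + b x)]  = c (-1)^(n+1) n! b^n / (k + b x)^(n+1)
gfun_deriv <- function(p, x, P, cval, order) {
  lg <- 1 - P / p$kappa
  r_part <- (-p$g)^order * p$r_max * exp(-p$g * x) * lg
  if (order == 0L) {
    r_part - p$d - cval / (p$k_half + p$b_res * x)
  } else {
    r_part + cval * (-1)^(order + 1) * factorial(order) * p$b_res^order /
      (p$k_half + p$b_res * x)^(order + 1)
  }
}

#' G-function adaptive-dynamics model
#'
#' Builds a [phenotype_model()] with \eqn{f(t,x,P) = G(x,P)} and
#' \eqn{V(t,x,P) = \alpha\, \partial_x G(x,P)}.  The logistic term lives
#' inside \eqn{G}, so the separate quadratic competition term is disabled.
#' All x-derivatives of \eqn{G} are closed-form.
#'
#' @param params a [gfunction_params()] object.
#' @param c_of_t treatment signal: function of time returning 0 (off) or
#'   1 (on).
#' @param beta diffusion coefficient (phenotype^2/time).
#' @param domain phenotypic interval; the resistance trait is unbounded in
#'   the adaptive-dynamics formulation, so the default is a generous box.
#' @return a [phenotype_model()].
#' @export
gfunction_model <- function(params, c_of_t = function(t) 1, beta = 0,
                            domain = c(0, 10)) {
  stopifnot(inherits(params, "gfunction_params"), is.function(c_of_t))
  p <- params
  f <- function(t, x, P) gfun_deriv(p, x, P, c_of_t(t), 0L)
  V <- function(t, x, P) p$alpha * gfun_deriv(p, x, P, c_of_t(t), 1L)
  df <- function(t, x, P, order) gfun_deriv(p, x, P, c_of_t(t), order)
  dV <- function(t, x, P, order)
    p$alpha * gfun_deriv(p, x, P, c_of_t(t), order + 1L)
  m <- phenotype_model(f, V, beta = beta, kappa = p$kappa, domain = domain,
                       df_dx = df, dV_dx = dV,
                       competition_enabled = FALSE, name = "gfunction")
  m$gparams <- p
  m$c_of_t <- c_of_t
  m
}
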
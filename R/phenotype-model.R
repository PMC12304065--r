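#' Define a phenotype-structured population model
#'
#' A `phenotype_model` bundles everything the PDE solver and the moment
#' reduction need to know about a phenotype-structured population: the
#' intrinsic growth rate \eqn{f(t,x,P)}, the phenotypic drift velocity
#' \eqn{V(t,x,P)}, the diffusion coefficient \eqn{\beta}, the carrying
#' capacity coefficient \eqn{\kappa} of the quadratic competition term
#' \eqn{-P^2/\kappa}, and the phenotypic domain \eqn{[l, L]}.
#'
#' Both `f` and `V` receive the current population size `P` as a third
#' argument.  Models in which the logistic term lives inside the growth rate
#' itself (the G-function formulation of adaptive dynamics) use that argument
#' and disable the separate competition term; classical nonlocal
#' Lotka-Volterra models ignore `P` inside `f` and keep
#' `competition_enabled = TRUE`.
#'
#' Derivative providers return \eqn{\partial_x^n f} (or \eqn{V}) at a point;
#' the moment reduction evaluates them at the current mean trait every
#' right-hand-side call.  When no analytic provider is supplied, central
#' finite differences with an order-dependent step are used.
#'
#' @param f function of `(t, x, P)`, vectorised in `x`: intrinsic growth rate
#'   (1/time).
#' @param V function of `(t, x, P)`, vectorised in `x`: drift velocity
#'   (phenotype/time).
#' @param beta diffusion coefficient \eqn{\beta \ge 0} (phenotype^2/time).
#' @param kappa carrying capacity coefficient \eqn{\kappa > 0} (cells x time);
#'   `Inf` disables the competition term.
#' @param domain numeric length-2, the phenotypic interval \eqn{[l, L]},
#'   `l < L`.
#' @param df_dx,dV_dx optional derivative providers: functions of
#'   `(t, x, P, order)` returning \eqn{\partial_x^n} of `f` (resp. `V`) for
#'   `order >= 0`.  `NULL` selects the finite-difference fallback.
#' @param competition_enabled logical; whether the separate \eqn{-P^2/\kappa}
#'   death term is active.  Defaults to `is.finite(kappa)`.
#' @param name optional model label used in printing and metadata.
#' @param probe_check logical; evaluate `f` and `V` on a probe grid and fail
#'   on non-finite values (the boundedness assumption of the model class).
#'
#' @return an object of class `phenotype_model`.
#' @seealso [quadratic_model()], [hill_tanh_model()], [gfunction_model()]
#' @export
phenotype_model <- function(f, V, beta, kappa = Inf, domain,
                            df_dx = NULL, dV_dx = NULL,
                            competition_enabled = is.finite(kappa),
                            name = "custom", probe_check = TRUE) {
  stopifnot(is.function(f), is.function(V))
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0)
    stop("'beta' must be a single non-negative number")
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) || kappa <= 0)
    stop("'kappa' must be positive (possibly Inf)")
  if (!is.numeric(domain) || length(domain) != 2L || !all(is.finite(domain)) ||
      domain[1] >= domain[2])
    stop("'domain' must be a finite interval c(l, L) with l < L")

  width <- domain[2] - domain[1]
  if (is.null(df_dx)) df_dx <- fd_provider(f, width)
  if (is.null(dV_dx)) dV_dx <- fd_provider(V, width)

  model <- structure(
    list(f = f, V = V, df_dx = df_dx, dV_dx = dV_dx,
         beta = beta, kappa = kappa,
         competition_enabled = isTRUE(competition_enabled),
         domain = domain, name = name),
    class = "phenotype_model")

  if (probe_check) {
    xs <- seq(domain[1], domain[2], length.out = 21L)
    fv <- f(0, xs, 1)
    vv <- V(0, xs, 1)
    if (!all(is.finite(fv)) || !all(is.finite(vv)))
      stop("f and V must evaluate to finite values on [l, L]")
  }
  model
}

# Central finite-difference derivative provider.  Step scaled by order:
# h_n = eps^(1/(n+2)) * (L - l), the usual truncation/roundoff balance for an
# O(h^2) central stencil of the n-th derivative.
fd_provider <- function(g, width) {
  force(g); force(width)
  function(t, x, P, order) {
    if (order == 0L) return(g(t, x, P))
    h <- .Machine$double.eps^(1 / (order + 2)) * width
    i <- 0:order
    offs <- (order / 2 - i) * h
    acc <- 0
    for (j in seq_along(i))
      acc <- acc + (-1)^i[j] * choose(order, i[j]) * g(t, x + offs[j], P)
    acc / h^order
  }
}

#' @export
print.phenotype_model <- function(x, ...) {
  cat("Phenotype-structured model:", x$name, "\n")
  cat(sprintf("  domain  [l, L] = [%g, %g]\n", x$domain[1], x$domain[2]))
  cat(sprintf("  beta  = %g   kappa = %g   competition term %s\n",
              x$beta, x$kappa,
              if (x$competition_enabled) "enabled" else "disabled"))
  invisible(x)
}
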
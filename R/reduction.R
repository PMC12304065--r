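## The core model-reduction machinery: assemble the closed ODE system for
## (P, m1, ..., mN) from any phenotype_model, for arbitrary numbers of
## tracked moments N and Taylor truncation order M, under Gaussian or
## truncation closure, and integrate it.

#' Closure specification for the moment reduction
#'
#' @param N number of tracked moments (\eqn{\ge 1}).
#' @param M Taylor truncation order for the growth and drift terms
#'   (\eqn{\ge 0}): derivatives of \eqn{f} and \eqn{V} up to order `M`,
#'   taken at the current mean trait, enter the equations.
#' @param method closure supplying the moments of order `N+1, ..., N+M` that
#'   the truncated sums still reference:
#'   \describe{
#'     \item{`"gaussian"`}{normal-moment recursion
#'       \eqn{m_k = m_1 m_{k-1} + (k-1)(m_2 - m_1^2) m_{k-2}} (default; this
#'       is the recursion satisfied by the raw moments of a normal
#'       distribution, and the variant that makes the reduction of the
#'       quadratic model collapse exactly onto the classical
#'       size/mean/variance system).}
#'     \item{`"gaussian_literal"`}{the same recursion with prefactor `k`
#'       instead of `k-1`, retained verbatim from the source formulation for
#'       comparison; it does not reproduce true normal moments (it gives
#'       \eqn{m_4 = 4} for the standard normal instead of 3).}
#'     \item{`"truncation"`}{\eqn{m_k = 0} above order `N`.}
#'   }
#' @return a list of class `closure_spec`.
#' @export
closure_spec <- function(N = 2L, M = 2L,
                         method = c("gaussian", "gaussian_literal",
                                    "truncation")) {
  method <- match.arg(method)
  N <- as.integer(N); M <- as.integer(M)
  if (is.na(N) || N < 1L) stop("'N' must be an integer >= 1")
  if (is.na(M) || M < 0L) stop("'M' must be an integer >= 0")
  structure(list(N = N, M = M, method = method), class = "closure_spec")
}

#' State of the reduced system
#'
#' @param P population size (> 0).
#' @param m numeric vector of raw moments `m1, ..., mN` of the normalized
#'   phenotypic density.  The zeroth moment is identically 1 and never
#'   stored.
#' @param t time attached to the state.
#' @return list of class `moment_state`.
#' @export
moment_state <- function(P, m, t = 0) {
  if (!is.numeric(P) || length(P) != 1L || !is.finite(P) || P <= 0)
    stop("'P' must be a single positive number")
  if (!is.numeric(m) || length(m) < 1L || any(!is.finite(m)))
    stop("'m' must be a finite numeric vector m1..mN")
  if (length(m) >= 2L && m[2] - m[1]^2 < -1e-10)
    warning("negative variance: m2 < m1^2 beyond tolerance; state is not a valid moment sequence")
  structure(list(P = P, m = as.numeric(m), t = t), class = "moment_state")
}

#' Taylor coefficients of the growth or drift term about a point
#'
#' Returns \eqn{c_n = \partial_x^n g(t, x)|_{x_0} / n!} for
#' `n = 0, ..., M`, where `g` is the model's growth rate `f` or drift `V`.
#' The reduction evaluates these about the current mean trait at every
#' right-hand-side call.
#'
#' @param model a [phenotype_model()].
#' @param which `"f"` or `"V"`.
#' @param x0 expansion point, inside the model domain.
#' @param M highest order.
#' @param t,P time and population size passed to the derivative providers.
#' @return numeric vector `c0, ..., cM`.
#' @export
taylor_coefficients <- function(model, which = c("f", "V"), x0, M, t = 0,
                                P = 1) {
  which <- match.arg(which)
  if (x0 < model$domain[1] - 1e-12 || x0 > model$domain[2] + 1e-12)
    stop("expansion point x0 = ", x0, " outside the model domain")
  prov <- if (which == "f") model$df_dx else model$dV_dx
  vapply(0:M, function(n) {
    v <- tryCatch(prov(t, x0, P, n),
                  error = function(e) stop(
                    "derivative provider for '", which, "' failed at order ",
                    n, ", x0 = ", x0, ": ", conditionMessage(e)))
    v[1] / factorial(n)
  }, numeric(1))
}

#' Binomial central-moment sum
#'
#' The building block of the reduced equations:
#' \deqn{S(n, k) = \sum_{i=0}^{n} (-1)^i \binom{n}{i} m_1^i\, m_{n+k-i},}
#' the weighted moment that replaces the integral of
#' \eqn{x^k (x - m_1)^n \hat p}.  `S(n, 0)` is the n-th central moment
#' expressed in raw moments.
#'
#' @param n,k non-negative integers.
#' @param m1 the first moment.
#' @param moments numeric vector of raw moments `m1, m2, ...` long enough to
#'   contain index `n + k` (apply the closure first if it is not);
#'   \eqn{m_0 = 1} is implicit.
#' @return scalar.
#' @export
central_sum <- function(n, k, m1, moments) {
  if (n + k > length(moments) && n + k > 0L)
    stop("central_sum needs m", n + k,
         "; supply closed moments first (see close_moments)")
  i <- 0:n
  idx <- n + k - i
  mvals <- ifelse(idx == 0L, 1, moments[pmax(idx, 1L)])
  sum((-1)^i * choose(n, i) * m1^i * mvals)
}

#' Close a moment sequence above the tracked order
#'
#' Extends raw moments `m1..mN` up to order `K` using the closure rule of
#' `spec` (see [closure_spec()]).  The Gaussian recursions are applied
#' successively, so already-closed moments feed the next order.
#'
#' @param m numeric vector `m1..mN`.
#' @param K highest order required (\eqn{\ge N}).
#' @param spec a [closure_spec()] (only `method` is used).
#' @return numeric vector `m1..mK`.
#' @export
close_moments <- function(m, K, spec) {
  N <- length(m)
  if (K <= N) return(m[seq_len(K)])
  full <- c(m, numeric(K - N))
  mom <- function(j) if (j == 0L) 1 else full[j]
  for (k in (N + 1L):K) {
    full[k] <- switch(spec$method,
      truncation = 0,
      gaussian = m[1] * mom(k - 1L) +
        (k - 1) * (mom(2L) - m[1]^2) * mom(k - 2L),
      gaussian_literal = m[1] * mom(k - 1L) +
        k * (mom(2L) - m[1]^2) * mom(k - 2L),
      stop("unknown closure method: ", spec$method))
  }
  full
}

#' Right-hand side of the reduced moment system
#'
#' Assembles \eqn{d/dt\,(P, m_1, \dots, m_N)} generically from the
#' truncated-Taylor moment equations: with
#' \eqn{f_n, V_n} the Taylor coefficients of growth and drift about
#' \eqn{m_1} and \eqn{S(n,k)} the binomial sums of [central_sum()],
#' \deqn{P' = P \sum_{n=0}^{M} f_n S(n,0) - P^2/\kappa,}
#' \deqn{m_1' = \sum_{n=0}^{M} (V_n - m_1 f_n) S(n,0) + \sum_{n=0}^{M} f_n S(n,1),}
#' \deqn{m_k' = -m_k \sum f_n S(n,0) + \beta k(k-1) m_{k-2}
#'   + k \sum V_n S(n,k-1) + \sum f_n S(n,k), \quad 2 \le k \le N.}
#' The competition term \eqn{-P^2/\kappa} is included only when the model
#' enables it.  Moments of order `N+1..N+M` are supplied by the closure on
#' the current state.  The mean-trait equation is assembled as its own
#' branch; it has a different drift/growth structure from the \eqn{k \ge 2}
#' equations and is not a special case of them.
#'
#' @param state a [moment_state()] with `length(state$m) == spec$N`.
#' @param model a [phenotype_model()].
#' @param spec a [closure_spec()].
#' @param t time.
#' @param warn logical; warn when \eqn{m_1} leaves the open unit interval on
#'   a unit domain (the series-truncation argument relies on
#'   \eqn{0 < m_1 < 1}).
#' @return numeric vector `c(dP, dm1, ..., dmN)`.
#' @export
moment_rhs <- function(state, model, spec, t = state$t, warn = TRUE) {
  P <- state$P
  if (!is.finite(P) || P <= 0) stop("population size must be positive")
  N <- spec$N; M <- spec$M
  m <- state$m
  if (length(m) != N) stop("state has ", length(m), " moments but spec$N = ", N)
  m1 <- m[1]
  if (warn && isTRUE(all.equal(model$domain, c(0, 1))) &&
      (m1 <= 0 || m1 >= 1))
    warning("m1 = ", signif(m1, 6),
            " outside (0, 1): the series-truncation argument no longer applies")

  x0 <- min(max(m1, model$domain[1]), model$domain[2])
  fn <- taylor_coefficients(model, "f", x0, M, t = t, P = P)
  Vn <- taylor_coefficients(model, "V", x0, M, t = t, P = P)

  full <- close_moments(m, N + M, spec)
  S <- function(n, k) central_sum(n, k, m1, full)
  S0 <- vapply(0:M, S, numeric(1), k = 0L)
  S1 <- vapply(0:M, S, numeric(1), k = 1L)

  growth <- sum(fn * S0)
  dP <- P * growth - if (model$competition_enabled) P^2 / model$kappa else 0
  dm <- numeric(N)
  dm[1] <- sum((Vn - m1 * fn) * S0) + sum(fn * S1)
  if (N >= 2L) {
    for (k in 2:N) {
      mk2 <- if (k == 2L) 1 else full[k - 2L]
      Sk  <- vapply(0:M, S, numeric(1), k = k)
      Sk1 <- vapply(0:M, S, numeric(1), k = k - 1L)
      dm[k] <- -m[k] * growth + model$beta * k * (k - 1) * mk2 +
        k * sum(Vn * Sk1) + sum(fn * Sk)
    }
  }
  c(dP, dm)
}

new_moment_trajectory <- function(times, P, m, m0 = NULL, meta = list(),
                                  flags = NULL) {
  m <- as.matrix(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("m", seq_len(ncol(m)))
  structure(list(times = times, P = P, m = m, m0 = m0, meta = meta,
                 flags = flags),
            class = "moment_trajectory")
}

#' Integrate the reduced moment system
#'
#' Integrates the ODEs assembled by [moment_rhs()] with an adaptive
#' Runge-Kutta method (via \pkg{deSolve}).  The zeroth moment is never
#' integrated: \eqn{m_0 \equiv 1} is structural.  The pipeline is fully
#' deterministic.
#'
#' After integration the trajectory is checked: times at which \eqn{m_1}
#' leaves the open unit interval (unit-domain models only) or the variance
#' \eqn{m_2 - m_1^2} drops below \code{-1e-10} are flagged; a single summary
#' warning is emitted and the flags are kept on the returned object, so
#' closure-failure modes can be studied rather than erroring out.
#'
#' @param initial a [moment_state()] with `spec$N` moments.
#' @param model a [phenotype_model()].
#' @param spec a [closure_spec()].
#' @param t_span either a length-2 interval or a vector of output times.
#' @param n_out number of output times when `t_span` is an interval.
#' @param rtol,atol integration tolerances.
#' @param method \pkg{deSolve} method.
#' @return a `moment_trajectory`: `times`, `P`, moment matrix `m`,
#'   validity `flags` and `meta`data recording the closure and tolerances.
#' @export
integrate_moments <- function(initial, model, spec, t_span, n_out = 201L,
                              rtol = 1e-8, atol = 1e-10, method = "ode45") {
  stopifnot(inherits(initial, "moment_state"),
            inherits(model, "phenotype_model"),
            inherits(spec, "closure_spec"))
  if (length(initial$m) != spec$N)
    stop("initial state must carry exactly spec$N = ", spec$N, " moments")
  times <- if (length(t_span) == 2L)
    seq(t_span[1], t_span[2], length.out = n_out) else sort(t_span)
  if (diff(range(times)) == 0)           # degenerate horizon: initial state only
    return(new_moment_trajectory(times = times[1], P = initial$P,
                                 m = matrix(initial$m, nrow = 1),
                                 meta = list(source = "reduction",
                                             model = model$name,
                                             N = spec$N, M = spec$M,
                                             closure = spec$method,
                                             domain = model$domain)))

  y0 <- c(P = initial$P, stats::setNames(initial$m,
                                         paste0("m", seq_len(spec$N))))
  rhs <- function(t, y, parms) {
    if (!all(is.finite(y)))
      stop(sprintf("moment ODE breakdown at t = %.6g (non-finite state; closure = %s)",
                   t, spec$method))
    # floor P for internal trial stages; the solution itself stays positive
    # because dP/dt -> 0 as P -> 0+
    st <- structure(list(P = max(y[[1]], .Machine$double.xmin),
                         m = y[-1], t = t),
                    class = "moment_state")
    list(moment_rhs(st, model, spec, t = t, warn = FALSE))
  }
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop("ODE integration failed near t = ", max(out[, 1]),
         "; last state P = ", out[nrow(out), 2])
  out <- as.matrix(out)

  P <- out[, 2]
  m <- out[, -(1:2), drop = FALSE]
  flags <- list()
  if (isTRUE(all.equal(model$domain, c(0, 1)))) {
    bad <- m[, 1] <= 0 | m[, 1] >= 1
    flags$m1_in_unit <- !bad
    if (any(bad))
      warning(sprintf(
        "m1 leaves the open unit interval from t = %.4g; trajectory flagged (truncation argument violated)",
        out[which(bad)[1], 1]))
  }
  if (spec$N >= 2L) {
    negv <- (m[, 2] - m[, 1]^2) < -1e-10
    flags$variance_ok <- !negv
    if (any(negv))
      warning(sprintf(
        "variance m2 - m1^2 becomes negative from t = %.4g; trajectory flagged invalid",
        out[which(negv)[1], 1]))
  }
  new_moment_trajectory(times = out[, 1], P = P, m = m,
                        meta = list(source = "reduction",
                                    model = model$name,
                                    N = spec$N, M = spec$M,
                                    closure = spec$method,
                                    rtol = rtol, atol = atol,
                                    method = method,
                                    domain = model$domain),
                        flags = flags)
}

#' Initial moments from an initial density
#'
#' Computes \eqn{P(0) = \int p^0} and
#' \eqn{m_k(0) = \int x^k p^0 / \int p^0} over the domain, by adaptive
#' quadrature for a density given as a function, or trapezoid quadrature for
#' a density tabulated on a grid.
#'
#' @param p0 density: function of `x`, or numeric vector on `grid$x`.
#' @param k_max highest moment order.
#' @param domain interval `c(l, L)` (required for a function `p0`).
#' @param grid a [pde_grid()] (required for a tabulated `p0`).
#' @return a [moment_state()] at `t = 0` with attribute `"m_all"` holding
#'   `m1..m_k_max`.
#' @export
initial_moments_from_density <- function(p0, k_max, domain = NULL,
                                         grid = NULL) {
  if (is.function(p0)) {
    if (is.null(domain)) stop("'domain' is required for a density function")
    ik <- function(k) stats::integrate(function(x) x^k * p0(x),
                                       domain[1], domain[2],
                                       rel.tol = 1e-10,
                                       subdivisions = 400L)$value
    mass <- ik(0L)
    if (mass <= 0) stop("initial density has zero mass")
    m <- vapply(seq_len(k_max), function(k) ik(k) / mass, numeric(1))
  } else {
    if (is.null(grid)) stop("'grid' is required for a tabulated density")
    w <- grid$w; x <- grid$x
    mass <- sum(w * p0)
    if (mass <= 0) stop("initial density has zero mass")
    m <- vapply(seq_len(k_max),
                function(k) sum(w * x^k * p0) / mass, numeric(1))
  }
  st <- moment_state(P = mass, m = m, t = 0)
  attr(st, "m_all") <- m
  st
}

# Raw moments of an affinely transformed variable: if y = (x - l)/s then
# E[y^k] = s^-k sum_j C(k,j) (-l)^(k-j) E[x^j], and conversely
# E[x^k] = sum_j C(k,j) l^(k-j) s^j E[y^j].
affine_moments <- function(m, shift, scale) {
  K <- length(m)
  mom <- function(j) if (j == 0L) 1 else m[j]
  vapply(seq_len(K), function(k) {
    j <- 0:k
    sum(choose(k, j) * shift^(k - j) * scale^j *
          vapply(j, mom, numeric(1)))
  }, numeric(1))
}

#' Rescale moments between the model domain and the unit interval
#'
#' The series-truncation argument behind the reduced system needs
#' \eqn{0 < m_1 < 1}, so models on \eqn{[l, L]} are mapped to \eqn{[0, 1]}
#' before integration and the resulting moments mapped back
#' (for \eqn{l = 0} this is the pure scaling \eqn{m_k \to m_k / L^k} and
#' back \eqn{m_k \to m_k L^k}; for general \eqn{l} the affine map
#' \eqn{x \to (x - l)/(L - l)} with the binomial moment transformation).
#'
#' @param obj a numeric vector of raw moments `m1..mK`, a [moment_state()],
#'   or a `moment_trajectory`.
#' @param direction `"to_unit"` or `"from_unit"`.
#' @param l,L original domain bounds, `l < L`.
#' @return object of the same type with transformed moments.
#' @export
rescale_moments <- function(obj, direction = c("to_unit", "from_unit"),
                            l, L) {
  direction <- match.arg(direction)
  if (L <= l) stop("'L' must exceed 'l'")
  s <- L - l
  tr <- function(m) {
    if (direction == "to_unit") affine_moments(m, shift = -l / s,
                                               scale = 1 / s)
    else affine_moments(m, shift = l, scale = s)
  }
  if (inherits(obj, "moment_trajectory")) {
    obj$m <- t(apply(obj$m, 1L, tr))
    colnames(obj$m) <- paste0("m", seq_len(ncol(obj$m)))
    obj$meta$rescaled <- direction
    obj
  } else if (inherits(obj, "moment_state")) {
    moment_state(obj$P, tr(obj$m), obj$t)
  } else {
    tr(as.numeric(obj))
  }
}

#' Rescale a model to the unit phenotypic domain
#'
#' Returns the model expressed in the transformed trait
#' \eqn{y = (x - l)/(L - l)}: growth unchanged pointwise, drift divided by
#' the domain width, diffusion divided by its square, derivative providers
#' scaled by the appropriate powers of the width.
#'
#' @param model a [phenotype_model()].
#' @return a [phenotype_model()] on `c(0, 1)`.
#' @export
rescale_model_to_unit <- function(model) {
  l <- model$domain[1]; s <- model$domain[2] - l
  f0 <- model$f; V0 <- model$V; df0 <- model$df_dx; dV0 <- model$dV_dx
  phenotype_model(
    f = function(t, y, P) f0(t, l + s * y, P),
    V = function(t, y, P) V0(t, l + s * y, P) / s,
    df_dx = function(t, y, P, order) s^order * df0(t, l + s * y, P, order),
    dV_dx = function(t, y, P, order)
      s^(order - 1) * dV0(t, l + s * y, P, order),
    beta = model$beta / s^2, kappa = model$kappa, domain = c(0, 1),
    competition_enabled = model$competition_enabled,
    name = paste0(model$name, "_unit"))
}
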
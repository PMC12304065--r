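## Reference finite-difference solver for the full phenotype-structured PDE
##   dp/dt = beta p_xx - (V p)_x + (f - P/kappa) p   on [l, L],
## no-flux boundaries (beta p_x + V p = 0 at l and L), explicit forward-Euler
## time stepping, first-order upwind advection and second-order central
## diffusion, written in conservative (flux-difference) form so that the
## discrete total mass is conserved exactly when f == 0 and competition is
## disabled.

#' Uniform phenotype grid
#'
#' @param domain interval `c(l, L)`.
#' @param nx number of grid cells; the grid has `nx + 1` nodes with
#'   `x[1] = l`, `x[nx+1] = L`.
#' @return list with `x` (nodes), `dx`, `w` (trapezoid quadrature weights)
#'   and `domain`.
#' @export
pde_grid <- function(domain, nx = 600L) {
  stopifnot(length(domain) == 2L, domain[1] < domain[2], nx >= 4L)
  x <- seq(domain[1], domain[2], length.out = nx + 1L)
  dx <- (domain[2] - domain[1]) / nx
  w <- c(dx / 2, rep(dx, nx - 1L), dx / 2)
  list(x = x, dx = dx, w = w, domain = domain)
}

# Stable explicit step.  Upwind advection acts as extra diffusion |V| dx / 2,
# so diffusion and advection limits combine harmonically; a strongly negative
# net growth rate (early-time competition) further shrinks the positivity
# bound.  This is always at least as strict as the separate bounds
# dx^2/(2 beta) and dx/max|V|.
cfl_dt <- function(model, grid, t_probe = 0, P_probe = 1) {
  vmax <- max(abs(model$V(t_probe, grid$x, P_probe)))
  growth <- model$f(t_probe, grid$x, P_probe) -
    if (model$competition_enabled) P_probe / model$kappa else 0
  gneg <- max(0, -min(growth))
  denom <- 2 * model$beta / grid$dx^2 + vmax / grid$dx + gneg
  0.9 / max(denom, 1e-300)
}

#' Solve the phenotype-structured PDE
#'
#' Explicit scheme on a uniform grid: node-centred finite volumes with
#' trapezoid weights, upwind advective flux and central diffusive flux at the
#' cell faces, zero flux through both boundaries, forward-Euler in time.
#' The nonlocal population size \eqn{P(t)} is recomputed by trapezoid
#' quadrature every step.
#'
#' @param model a [phenotype_model()].
#' @param p0 initial density: numeric vector on the grid nodes, or a function
#'   of `x`.  Must be non-negative with positive mass.
#' @param t_end final time.
#' @param dt time step; `NULL` (default) uses the stability bound
#'   `0.9 / (2 beta / dx^2 + max|V| / dx + max(0, -min growth))`, the
#'   positivity-preserving step for the combined scheme (at least as strict
#'   as the separate diffusion and advection limits).
#' @param grid a [pde_grid()]; default 600 cells over the model domain.
#' @param n_out number of equally spaced output times (including 0 and
#'   `t_end`) at which the density is stored.
#' @param output_times explicit output times overriding `n_out`.
#' @param on_cfl what to do when the requested `dt` exceeds the stability
#'   bound: `"adjust"` reduces it with a message, `"error"` aborts, naming
#'   the maximal admissible step.
#' @return object of class `pde_solution`: list with `times`, `x`, density
#'   matrix `p` (times in rows), population sizes `P`, the grid and solver
#'   metadata.
#' @export
solve_pde <- function(model, p0, t_end, dt = NULL, grid = NULL,
                      n_out = 141L, output_times = NULL,
                      on_cfl = c("adjust", "error")) {
  stopifnot(inherits(model, "phenotype_model"), t_end >= 0)
  on_cfl <- match.arg(on_cfl)
  if (is.null(grid)) grid <- pde_grid(model$domain)
  x <- grid$x; dx <- grid$dx; w <- grid$w
  J <- length(x) - 1L

  p <- if (is.function(p0)) p0(x) else as.numeric(p0)
  if (length(p) != length(x)) stop("p0 must have one value per grid node")
  if (any(!is.finite(p)) || any(p < 0)) stop("p0 must be finite and >= 0")
  if (sum(w * p) <= 0) stop("p0 must have positive mass")

  dt_max <- cfl_dt(model, grid, 0, sum(w * p))
  if (is.null(dt)) {
    dt <- dt_max
  } else if (dt > dt_max) {
    if (on_cfl == "error")
      stop(sprintf("dt = %g violates the stability bound; maximal admissible dt = %g",
                   dt, dt_max))
    message(sprintf("solve_pde: dt = %g exceeds the stability bound, reduced to %g",
                    dt, dt_max))
    dt <- dt_max
  }

  if (is.null(output_times))
    output_times <- seq(0, t_end, length.out = max(2L, n_out))
  output_times <- sort(unique(c(0, output_times, t_end)))
  K <- length(output_times)

  Pmat <- matrix(NA_real_, nrow = K, ncol = length(x))
  Pv <- numeric(K)
  Pmat[1L, ] <- p
  Pv[1L] <- sum(w * p)

  xf <- (x[-1L] + x[-length(x)]) / 2  # interior face midpoints
  comp <- model$competition_enabled
  t_now <- 0
  for (k in seq_len(K - 1L)) {
    t_target <- output_times[k + 1L]
    while (t_now < t_target - 1e-14 * max(1, t_target)) {
      step <- min(dt, t_target - t_now)
      P_now <- sum(w * p)
      Vf <- model$V(t_now, xf, P_now)
      Vf <- rep_len(Vf, J)
      upw <- ifelse(Vf > 0, p[-length(p)], p[-1L])
      flux <- Vf * upw - model$beta * diff(p) / dx
      flux_ext <- c(0, flux, 0)           # no-flux boundaries
      growth <- model$f(t_now, x, P_now) - if (comp) P_now / model$kappa else 0
      p <- p + step * (-diff(flux_ext) / w + growth * p)
      t_now <- t_now + step
    }
    t_now <- t_target
    Pmat[k + 1L, ] <- p
    Pv[k + 1L] <- sum(w * p)
  }

  structure(list(times = output_times, x = x, p = Pmat, P = Pv,
                 grid = grid, dt = dt, model_name = model$name,
                 settings = list(dx = dx, dt = dt, n_steps_per_unit = 1 / dt)),
            class = "pde_solution")
}

#' Extract moments of the normalized phenotypic density
#'
#' Normalizes the solved density by the population size,
#' \eqn{\hat p = p / P}, and computes the raw moments
#' \eqn{m_k(t) = \int x^k \hat p\, dx} for `k = 0, ..., k_max` by trapezoid
#' quadrature at every stored time.  Small negative scheme noise (magnitude
#' below `1e-12` of the density maximum) is clipped to zero first.
#'
#' @param sol a [solve_pde()] result.
#' @param k_max highest moment order.
#' @return a `moment_trajectory` (see [integrate_moments()]) with columns
#'   `m0, ..., m<k_max>`; `m0` is retained as a diagnostic of the structural
#'   identity \eqn{m_0 \equiv 1}.
#' @export
extract_moments <- function(sol, k_max = 3L) {
  stopifnot(inherits(sol, "pde_solution"), k_max >= 0L)
  if (any(sol$P <= 0))
    stop("population size must stay positive to normalize the density")
  w <- sol$grid$w; x <- sol$x
  pmat <- sol$p
  pmat[pmat < 0] <- 0
  mom <- matrix(NA_real_, nrow = length(sol$times), ncol = k_max + 1L)
  xk <- outer(x, 0:k_max, `^`)            # nodes x orders
  for (i in seq_along(sol$times)) {
    ph <- pmat[i, ] / sol$P[i]
    mom[i, ] <- as.numeric(crossprod(xk, w * ph))
  }
  colnames(mom) <- paste0("m", 0:k_max)
  new_moment_trajectory(times = sol$times, P = sol$P,
                        m = mom[, -1L, drop = FALSE], m0 = mom[, 1L],
                        meta = list(source = "pde", model = sol$model_name,
                                    dx = sol$grid$dx, dt = sol$dt,
                                    domain = sol$grid$domain))
}

#' Normalized density at the domain boundaries
#'
#' The moment equations drop the boundary terms of the flux integrals on the
#' grounds that the density at the edges of the admissible phenotype range is
#' biologically negligible.  This diagnostic reports \eqn{\hat p(t, l)} and
#' \eqn{\hat p(t, L)} at the stored time nearest `t`, and warns when either
#' exceeds `warn_threshold` times the current density maximum, i.e. when the
#' neglect assumption is in doubt (typically: the domain is too small for the
#' drift).
#'
#' @param sol a [solve_pde()] result.
#' @param t time at which to evaluate (nearest stored time is used).
#' @param warn_threshold relative threshold for the warning; `NA` disables.
#' @return named numeric: `lower`, `upper`.
#' @export
boundary_mass <- function(sol, t, warn_threshold = 1e-3) {
  stopifnot(inherits(sol, "pde_solution"))
  if (t < min(sol$times) - 1e-12 || t > max(sol$times) + 1e-12)
    stop("t outside the solved time range")
  i <- which.min(abs(sol$times - t))
  ph <- sol$p[i, ] / sol$P[i]
  out <- c(lower = ph[1L], upper = ph[length(ph)])
  if (!is.na(warn_threshold)) {
    rel <- max(out) / max(ph)
    if (is.finite(rel) && rel > warn_threshold)
      warning(sprintf(
        "normalized boundary density is %.3g of the density maximum at t = %g; boundary-term neglect is questionable (consider a wider domain)",
        rel, sol$times[i]))
  }
  out
}

#' @export
print.pde_solution <- function(x, ...) {
  cat("Phenotype-structured PDE solution (", x$model_name, ")\n", sep = "")
  cat(sprintf("  %d output times on [%g, %g]; grid dx = %g (%d nodes); dt = %g\n",
              length(x$times), min(x$times), max(x$times),
              x$grid$dx, length(x$x), x$dt))
  cat(sprintf("  P(0) = %.6g  ->  P(t_end) = %.6g\n",
              x$P[1], x$P[length(x$P)]))
  invisible(x)
}

#' @export
plot.pde_solution <- function(x, times = NULL, ...) {
  idx <- if (is.null(times)) {
    unique(round(seq(1, length(x$times), length.out = 6)))
  } else {
    vapply(times, function(t) which.min(abs(x$times - t)), 1L)
  }
  cols <- grDevices::hcl.colors(length(idx), "viridis")
  graphics::matplot(x$x, t(x$p[idx, , drop = FALSE]), type = "l", lty = 1,
                    col = cols, xlab = "phenotype x", ylab = "density p(t, x)",
                    ...)
  graphics::legend("topright", legend = sprintf("t = %.3g", x$times[idx]),
                   col = cols, lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
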
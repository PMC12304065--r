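## Adaptive-therapy experiment: bang-bang treatment controller with
## hysteresis, simulated either with the classical homogeneous
## adaptive-dynamics system (population size + mean trait) or with the
## heterogeneous N = M = 2 moment reductions of the same G-function model.

#' Adaptive-therapy protocol
#'
#' Treatment is applied from the start, interrupted when the tumour falls to
#' `lower_frac` of its initial size, and re-applied when it regrows to
#' `upper_frac` of the initial size.  Progression is declared the first time
#' the tumour reaches `ttp_frac` of the carrying capacity.
#'
#' @param P_init initial tumour size (cells).
#' @param lower_frac treatment-off threshold as a fraction of `P_init`.
#' @param upper_frac treatment-on threshold as a fraction of `P_init`.
#' @param ttp_frac progression threshold as a fraction of the carrying
#'   capacity.
#' @param initial_on logical; treatment state at `t = 0`.
#' @return list of class `therapy_protocol`.
#' @export
therapy_protocol <- function(P_init, lower_frac = 0.5, upper_frac = 1,
                             ttp_frac = 0.7, initial_on = TRUE) {
  stopifnot(is.numeric(P_init), P_init > 0)
  if (!(lower_frac > 0 && lower_frac < upper_frac && upper_frac <= 1))
    stop("need 0 < lower_frac < upper_frac <= 1")
  if (!(ttp_frac > 0 && ttp_frac <= 1))
    stop("need 0 < ttp_frac <= 1")
  structure(list(P_init = P_init, lower_frac = lower_frac,
                 upper_frac = upper_frac, ttp_frac = ttp_frac,
                 initial_on = isTRUE(initial_on)),
            class = "therapy_protocol")
}

#' One step of the hysteresis treatment controller
#'
#' @param P_now current tumour size (> 0).
#' @param c_prev current treatment state, 0 or 1.
#' @param protocol a [therapy_protocol()].
#' @return next treatment state, 0 or 1.
#' @export
controller_step <- function(P_now, c_prev, protocol) {
  stopifnot(P_now > 0, c_prev %in% c(0, 1))
  if (c_prev == 1 && P_now <= protocol$lower_frac * protocol$P_init) return(0)
  if (c_prev == 0 && P_now >= protocol$upper_frac * protocol$P_init) return(1)
  c_prev
}

#' Simulate adaptive therapy under the G-function model
#'
#' Runs the bang-bang adaptive-therapy protocol for one of three model
#' variants:
#' \describe{
#'   \item{`"n1m1"`}{the homogeneous (monomorphic) adaptive-dynamics system
#'     \eqn{P' = P\,G(m_1, P)}, \eqn{m_1' = \alpha\, \partial_x G(m_1, P)}
#'     (the diffusion coefficient plays no role).}
#'   \item{`"n2m2_gaussian"`, `"n2m2_truncation"`}{the generic moment
#'     reduction of the same model with `N = M = 2` and Gaussian or
#'     truncation closure, started from a monomorphic state
#'     (\eqn{m_2(0) = m_1(0)^2}).}
#' }
#' Threshold crossings (treatment on/off and progression) are located by the
#' integrator's root finder and the integration restarted at each switch, so
#' switching is event-accurate.
#'
#' @param variant one of `"n1m1"`, `"n2m2_gaussian"`, `"n2m2_truncation"`.
#' @param params a [gfunction_params()] object.
#' @param protocol a [therapy_protocol()].
#' @param t_end simulation horizon (time units of the parameters, typically
#'   days); progression may be censored at `t_end`.
#' @param m1_init initial mean resistance trait.
#' @param beta diffusion coefficient for the heterogeneous variants
#'   (ignored by `"n1m1"`).
#' @param domain phenotypic interval used by the derivative machinery of the
#'   heterogeneous variants.
#' @param n_out approximate number of stored output times.
#' @param rtol,atol integration tolerances.
#' @return object of class `therapy_sim`: list with `trajectory` (a
#'   `moment_trajectory`), `t_ttp` (`NA` when censored), `censored`,
#'   `switches` (times at which treatment toggled), `dose_record`
#'   (data frame of treatment intervals), `cycles` (completed on-periods),
#'   `cumulative_dose_at_ttp`, `variant` and `params`.
#' @export
simulate_adaptive_therapy <- function(variant = c("n1m1", "n2m2_gaussian",
                                                  "n2m2_truncation"),
                                      params, protocol, t_end,
                                      m1_init = 0, beta = 0,
                                      domain = c(0, 10),
                                      n_out = 2000L,
                                      rtol = 1e-8, atol = 1e-8) {
  variant <- match.arg(variant)
  stopifnot(inherits(params, "gfunction_params"),
            inherits(protocol, "therapy_protocol"), t_end > 0)
  p <- params
  lower <- protocol$lower_frac * protocol$P_init
  upper <- protocol$upper_frac * protocol$P_init
  ttp_level <- protocol$ttp_frac * p$kappa

  c_env <- new.env(parent = emptyenv())
  c_env$c <- as.numeric(protocol$initial_on)
  c_sig <- function(t) c_env$c

  if (variant == "n1m1") {
    rhs <- function(t, y, parms) {
      G <- gfun_deriv(p, y[2], y[1], c_env$c, 0L)
      dG <- gfun_deriv(p, y[2], y[1], c_env$c, 1L)
      list(c(y[1] * G, p$alpha * dG))
    }
    y0 <- c(P = protocol$P_init, m1 = m1_init)
  } else {
    model <- gfunction_model(p, c_of_t = c_sig, beta = beta, domain = domain)
    spec <- closure_spec(N = 2L, M = 2L,
                         method = if (variant == "n2m2_gaussian")
                           "gaussian" else "truncation")
    rhs <- function(t, y, parms) {
      st <- structure(list(P = y[[1]], m = y[-1], t = t),
                      class = "moment_state")
      list(moment_rhs(st, model, spec, t = t, warn = FALSE))
    }
    y0 <- c(P = protocol$P_init, m1 = m1_init, m2 = m1_init^2)
  }

  if (protocol$P_init >= ttp_level) {
    traj <- new_moment_trajectory(times = 0, P = protocol$P_init,
                                  m = matrix(y0[-1], nrow = 1),
                                  meta = list(variant = variant))
    return(structure(list(trajectory = traj, t_ttp = 0, censored = FALSE,
                          switches = numeric(0),
                          dose_record = data.frame(t_start = numeric(0),
                                                   t_end = numeric(0),
                                                   c = numeric(0)),
                          cycles = 0L, cumulative_dose_at_ttp = 0,
                          variant = variant, params = p,
                          protocol = protocol),
                     class = "therapy_sim"))
  }

  rootfun <- function(t, y, parms) {
    sw <- if (c_env$c == 1) y[1] - lower else y[1] - upper
    c(sw, y[1] - ttp_level)
  }

  out_dt <- t_end / n_out
  rows <- NULL
  switches <- numeric(0)
  dose <- list()
  t_now <- 0
  t_ttp <- NA_real_
  seg <- 0L
  while (t_now < t_end - 1e-12 && seg < 20000L) {
    seg <- seg + 1L
    times <- unique(c(seq(t_now, t_end, by = out_dt), t_end))
    if (length(times) < 2L) times <- c(t_now, t_end)
    out <- deSolve::lsodar(y = y0, times = times, func = rhs, parms = NULL,
                           rootfunc = rootfun, rtol = rtol, atol = atol)
    istate <- attr(out, "istate")
    if (istate[1] < 0)
      stop(sprintf(
        "integrator failure in segment %d (t ~ %.4g, treatment %s, %d switches so far)",
        seg, max(out[, 1]), if (c_env$c == 1) "on" else "off",
        length(switches)))
    rows <- rbind(rows, if (is.null(rows)) out else out[-1L, , drop = FALSE])
    t_reached <- out[nrow(out), 1]
    y0 <- out[nrow(out), -1L]
    dose[[length(dose) + 1L]] <- c(t_now, t_reached, c_env$c)
    iroot <- attr(out, "iroot")
    t_now <- t_reached
    if (!is.null(iroot) && length(iroot) >= 2L && iroot[2] == 1L) {
      t_ttp <- t_reached                         # progression reached
      break
    }
    if (!is.null(iroot) && iroot[1] == 1L) {     # treatment toggles
      switches <- c(switches, t_reached)
      c_env$c <- 1 - c_env$c
    } else if (t_reached >= t_end - 1e-12) {
      break
    }
  }

  dose_record <- do.call(rbind, lapply(dose, function(r)
    data.frame(t_start = r[1], t_end = r[2], c = r[3])))
  traj <- new_moment_trajectory(
    times = rows[, 1], P = rows[, 2],
    m = rows[, -(1:2), drop = FALSE],
    meta = list(source = "therapy", variant = variant,
                alpha = p$alpha, beta = beta,
                rtol = rtol, atol = atol))
  on_periods <- dose_record[dose_record$c == 1, , drop = FALSE]
  dose_at_ttp <- if (!is.na(t_ttp)) cumulative_dose(dose_record, t_ttp)
    else cumulative_dose(dose_record, t_now)
  structure(list(trajectory = traj, t_ttp = t_ttp,
                 censored = is.na(t_ttp), switches = switches,
                 dose_record = dose_record, cycles = nrow(on_periods),
                 cumulative_dose_at_ttp = dose_at_ttp,
                 variant = variant, params = p, protocol = protocol),
            class = "therapy_sim")
}

#' Cumulative administered dose
#'
#' Integrates the on/off treatment signal: the cumulative dose
#' \eqn{\int_0^t c(s)\,ds} grows with slope 1 while treatment is on and is
#' flat while it is off.
#'
#' @param dose_record data frame with columns `t_start`, `t_end`, `c`
#'   (as returned by [simulate_adaptive_therapy()]).
#' @param t evaluation time(s).
#' @return numeric vector of cumulative doses.
#' @export
cumulative_dose <- function(dose_record, t) {
  stopifnot(all(c("t_start", "t_end", "c") %in% names(dose_record)))
  vapply(t, function(tt) {
    ov <- pmin(dose_record$t_end, tt) - dose_record$t_start
    sum(dose_record$c * pmax(ov, 0))
  }, numeric(1))
}

#' @export
print.therapy_sim <- function(x, ...) {
  cat("Adaptive-therapy simulation (", x$variant, ")\n", sep = "")
  cat(sprintf("  P(0) = %g, kappa = %g, alpha = %g\n",
              x$protocol$P_init, x$params$kappa, x$params$alpha))
  if (x$censored) {
    cat(sprintf("  no progression by t = %g (censored); %d treatment cycles\n",
                max(x$trajectory$times), x$cycles))
  } else {
    cat(sprintf("  time to progression = %.4g; %d treatment cycles; cumulative dose at progression = %.4g\n",
                x$t_ttp, x$cycles, x$cumulative_dose_at_ttp))
  }
  invisible(x)
}

#' @export
plot.therapy_sim <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  tr <- x$trajectory
  graphics::plot(tr$times, tr$P, type = "l", xlab = "time",
                 ylab = "tumour size P(t)", ...)
  graphics::abline(h = x$protocol$ttp_frac * x$params$kappa, lty = 3)
  graphics::plot(tr$times, tr$m[, 1], type = "l", xlab = "time",
                 ylab = "mean resistance m1(t)", ...)
  invisible(x)
}
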
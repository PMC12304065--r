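## Experiment orchestration: a single validated configuration document
## drives the PDE solve, the moment reduction, their comparison, and the
## therapy simulation, and every output is written with a metadata sidecar
## that records all resolved settings, so a run is reproducible from its
## outputs alone.

config_schema <- list(
  model     = c("type", "params"),
  domain    = NULL,
  beta      = NULL,
  kappa     = NULL,
  initial   = c("x_bar0", "sigma0", "P0"),
  pde       = c("nx", "dt", "t_end", "n_out"),
  reduction = c("N", "M", "closure", "rtol", "atol", "t_end", "n_out"),
  therapy   = c("variant", "t_end", "P_init", "m1_init", "lower_frac",
                "upper_frac", "ttp_frac", "n_out"),
  run       = NULL,
  output_dir = NULL)

#' Validate an experiment configuration
#'
#' Accepts a list, or a path to a YAML or JSON document, with sections
#' `model` (type and parameters), `domain`, `beta`, `kappa`, `initial`
#' (truncated-normal `x_bar0`, `sigma0`, `P0`), `pde`, `reduction`,
#' `therapy`, `run` (which pipelines to execute) and `output_dir`.  Unknown
#' keys anywhere are rejected; everything is validated before any
#' computation starts.
#'
#' @param x list or file path.
#' @return the validated configuration, class `experiment_config`.
#' @export
experiment_config <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- if (grepl("\\.json$", x)) jsonlite::read_json(x, simplifyVector = TRUE)
         else yaml::read_yaml(x)
  }
  if (!is.list(x)) stop("configuration must be a list or a YAML/JSON file")
  unknown <- setdiff(names(x), names(config_schema))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  for (sec in names(config_schema)) {
    allowed <- config_schema[[sec]]
    if (!is.null(allowed) && !is.null(x[[sec]]) && sec != "model") {
      bad <- setdiff(names(x[[sec]]), allowed)
      if (length(bad))
        stop("unknown keys in '", sec, "': ", paste(bad, collapse = ", "))
    }
  }
  if (is.null(x$model) || is.null(x$model$type))
    stop("configuration must name a model type")
  if (!x$model$type %in% c("quadratic", "hill_tanh", "gfunction"))
    stop("unknown model type: ", x$model$type)
  if (is.null(x$run)) x$run <- "reduction"
  bad_run <- setdiff(x$run, c("pde", "reduction", "therapy"))
  if (length(bad_run)) stop("unknown pipelines: ", paste(bad_run, collapse = ", "))
  if (is.null(x$domain)) x$domain <- c(0, 1)
  if (is.null(x$beta)) x$beta <- 0
  if (is.null(x$kappa)) x$kappa <- Inf
  structure(x, class = c("experiment_config", "list"))
}

build_model_from_config <- function(cfg) {
  pr <- cfg$model$params
  switch(cfg$model$type,
    quadratic = do.call(quadratic_model,
      c(pr[c("a", "b_sel", "X", "V0")],
        list(beta = cfg$beta, kappa = cfg$kappa, domain = cfg$domain))),
    hill_tanh = do.call(hill_tanh_model,
      c(pr[intersect(names(pr), c("f_max", "k_x", "V_max", "omega"))],
        list(beta = cfg$beta, kappa = cfg$kappa, domain = cfg$domain))),
    gfunction = {
      gp <- do.call(gfunction_params,
                    pr[intersect(names(pr),
                                 c("r_max", "g", "d", "k_half", "b_res",
                                   "kappa", "alpha"))])
      gfunction_model(gp, beta = cfg$beta, domain = cfg$domain)
    })
}

#' Run a configured experiment
#'
#' Executes the pipelines named in `config$run`: `"pde"` (reference
#' finite-difference solve and moment extraction), `"reduction"` (the closed
#' moment ODE system, integrated on the unit domain and rescaled back), and
#' `"therapy"` (the adaptive-therapy protocol).  When both `"pde"` and
#' `"reduction"` run, a comparison report with the relative sup-norm and
#' final-time error of every tracked moment is produced, computed after
#' rescaling the reduced moments back to the original domain.
#'
#' When `config$output_dir` is set, trajectory CSVs, the comparison table
#' and a `metadata.json` with every resolved setting are written there.
#'
#' @param config an [experiment_config()] (or list / file path coercible to
#'   one).
#' @param quiet suppress per-stage log messages.
#' @return invisibly, a list with the computed objects (`pde`, `pde_moments`,
#'   `reduction`, `therapy`, `comparison`, `metadata`).
#' @export
run_experiment <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "experiment_config")) config
         else experiment_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- list()
  warnings_seen <- character(0)
  note_warning <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(withCallingHandlers(expr, warning = note_warning),
                    error = function(e)
                      stop("stage '", name, "' failed: ",
                           conditionMessage(e), call. = FALSE))
    say("stage %-10s done in %.2f s", name,
        proc.time()[["elapsed"]] - t0)
    res
  }

  model <- stage("model", build_model_from_config(cfg))
  N <- cfg$reduction$N %||% 2L

  p0 <- NULL
  if (!is.null(cfg$initial))
    p0 <- truncated_normal_density(cfg$initial$x_bar0, cfg$initial$sigma0,
                                   cfg$domain[1], cfg$domain[2],
                                   cfg$initial$P0 %||% 1)

  if ("pde" %in% cfg$run) {
    pc <- cfg$pde %||% list()
    grid <- pde_grid(cfg$domain, nx = pc$nx %||% 600L)
    out$pde <- stage("pde",
      solve_pde(model, p0, t_end = pc$t_end %||% 1, dt = pc$dt,
                grid = grid, n_out = pc$n_out %||% 141L))
    out$pde_moments <- extract_moments(out$pde, k_max = max(N, 3L))
  }

  if ("reduction" %in% cfg$run) {
    rc <- cfg$reduction %||% list()
    spec <- closure_spec(N = N, M = rc$M %||% 2L,
                         method = rc$closure %||% "gaussian")
    st0 <- initial_moments_from_density(p0, k_max = N, domain = cfg$domain)
    t_end <- rc$t_end %||% cfg$pde$t_end %||% 1
    times <- if (!is.null(out$pde)) out$pde$times
             else seq(0, t_end, length.out = rc$n_out %||% 201L)
    unit <- !isTRUE(all.equal(cfg$domain, c(0, 1)))
    red <- stage("reduction", {
      mdl <- if (unit) rescale_model_to_unit(model) else model
      s0 <- if (unit)
        rescale_moments(st0, "to_unit", cfg$domain[1], cfg$domain[2])
        else st0
      tr <- integrate_moments(s0, mdl, spec, t_span = times,
                              rtol = rc$rtol %||% 1e-8,
                              atol = rc$atol %||% 1e-10)
      if (unit) rescale_moments(tr, "from_unit", cfg$domain[1], cfg$domain[2])
      else tr
    })
    out$reduction <- red
  }

  if (!is.null(out$pde_moments) && !is.null(out$reduction)) {
    out$comparison <- stage("compare",
      compare_moments(out$pde_moments, out$reduction))
  }

  if ("therapy" %in% cfg$run) {
    tc <- cfg$therapy
    proto <- therapy_protocol(P_init = tc$P_init,
                              lower_frac = tc$lower_frac %||% 0.5,
                              upper_frac = tc$upper_frac %||% 1,
                              ttp_frac = tc$ttp_frac %||% 0.7)
    out$therapy <- stage("therapy",
      simulate_adaptive_therapy(tc$variant %||% "n1m1", model$gparams,
                                proto, t_end = tc$t_end,
                                m1_init = tc$m1_init %||% 0,
                                beta = cfg$beta, domain = cfg$domain,
                                n_out = tc$n_out %||% 2000L))
  }

  meta <- list(config = unclass(cfg),
               package_version = as.character(
                 utils::packageVersion("phenomoments")),
               warnings = warnings_seen)
  out$metadata <- meta
  if (length(warnings_seen))
    say("warnings surfaced during the run:\n  %s",
        paste(unique(warnings_seen), collapse = "\n  "))

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(cfg$output_dir, f)
    if (!is.null(out$pde)) {
      dens <- data.frame(
        t = rep(out$pde$times, each = length(out$pde$x)),
        x = rep(out$pde$x, times = length(out$pde$times)),
        p = as.vector(t(out$pde$p)))
      utils::write.csv(dens, fp("pde_density.csv"), row.names = FALSE)
      write_moment_trajectory(out$pde_moments, fp("pde_moments.csv"))
    }
    if (!is.null(out$reduction))
      write_moment_trajectory(out$reduction, fp("reduced_moments.csv"))
    if (!is.null(out$comparison))
      utils::write.csv(out$comparison, fp("comparison.csv"),
                       row.names = FALSE)
    if (!is.null(out$therapy)) {
      write_moment_trajectory(out$therapy$trajectory,
                              fp("therapy_trajectory.csv"))
      utils::write.csv(out$therapy$dose_record, fp("therapy_dose.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(t_ttp = out$therapy$t_ttp, censored = out$therapy$censored,
             cycles = out$therapy$cycles,
             cumulative_dose_at_ttp = out$therapy$cumulative_dose_at_ttp),
        fp("therapy_summary.json"), auto_unbox = TRUE, digits = NA,
        na = "null")
    }
    jsonlite::write_json(meta, fp("metadata.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  invisible(out)
}

#' Compare PDE-extracted and reduced moment trajectories
#'
#' Interpolates the reduced trajectory onto the PDE output times and reports,
#' for the population size and every common moment, the relative sup-norm
#' error and the final-time relative error.
#'
#' @param pde_moments trajectory from [extract_moments()].
#' @param reduced trajectory from [integrate_moments()] (already rescaled to
#'   the same domain).
#' @return data frame with columns `quantity`, `sup_rel_err`,
#'   `final_rel_err`.
#' @export
compare_moments <- function(pde_moments, reduced) {
  times <- pde_moments$times
  get_red <- if (length(reduced$times) < 2L) {
    function(v) rep(v[1], length(times))
  } else {
    function(v) stats::approx(reduced$times, v, xout = times, rule = 2)$y
  }
  qty <- c("P", intersect(colnames(pde_moments$m), colnames(reduced$m)))
  rows <- lapply(qty, function(q) {
    a <- if (q == "P") pde_moments$P else pde_moments$m[, q]
    b <- if (q == "P") get_red(reduced$P) else get_red(reduced$m[, q])
    sc <- max(abs(a))
    data.frame(quantity = q,
               sup_rel_err = max(abs(a - b)) / sc,
               final_rel_err = abs(a[length(a)] - b[length(b)]) /
                 abs(a[length(a)]))
  })
  do.call(rbind, rows)
}
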
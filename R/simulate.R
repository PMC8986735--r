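# Integration of treatment courses and treatment-response metrics.

STATE_UNITS <- c(N_P = "count", N_V = "count", N_I = "count", N_M = "count",
                 N_C = "count", C_M = "nM", C_Ab_P = "nM", C_Ab_V = "nM",
                 C_Ab_I = "nM", C_Ab_M = "nM", C_D_P = "nM", C_D_V = "nM",
                 C_D_I = "nM", C_D_C = "nM", C_E = "-", C_P = "-",
                 B = "cm3")

# Bolus events for the integrator: IV doses jump the corresponding plasma
# state. Bolus concentrations always use the agent's volume of distribution;
# NP doses are converted from mg/kg of miRNA payload to particle counts at
# the current NP size. Mouse IP antibody doses are a forcing term in the
# right-hand side, not events.
build_events <- function(ps, regimen) {
  if (nrow(regimen) == 0) return(NULL)
  ctx <- ps$context; th <- ps$therapy
  ev <- list()
  for (i in seq_len(nrow(regimen))) {
    r <- regimen[i, ]
    if (r$agent == "miRNA_NP") {
      ev[[length(ev) + 1]] <- data.frame(
        var = 1, time = r$time,
        value = np_count_for_dose(r$amount * ctx$body_weight, th$phi_NP))
    } else if (r$agent == "doxorubicin") {
      ev[[length(ev) + 1]] <- data.frame(
        var = 11, time = r$time,
        value = nmol_to_nM(mg_to_nmol(r$amount * ctx$body_weight, MW_DOX),
                           th$V_D_dox))
    } else if (r$agent == "antibody" && r$route == "IV_bolus") {
      ev[[length(ev) + 1]] <- data.frame(
        var = 7, time = r$time,
        value = nmol_to_nM(mg_to_nmol(r$amount * ctx$body_weight, MW_AB),
                           th$V_D_Ab))
    } else if (r$agent == "antibody" && r$route == "IP") {
      # the peritoneal absorption forcing switches on at the dose time;
      # a zero-magnitude event forces a solver restart at the discontinuity
      ev[[length(ev) + 1]] <- data.frame(var = 7, time = r$time, value = 0)
    }
  }
  if (length(ev) == 0) return(NULL)
  ev <- do.call(rbind, ev)
  ev$method <- "add"
  ev[order(ev$time), ]
}

default_atol <- function() {
  c(rep(1e-2, 5),        # NP counts (injections are 1e10-1e15 particles)
    rep(1e-6, 11),       # concentrations (nM) and protein levels: antibody
                         # states span ~20 orders of magnitude per dose
                         # cycle and sub-1e-6 nM levels are far below any
                         # EC50 in the model
    1e-14)               # tumor volume (single-cell inception is 1e-9 cm^3)
}

#' Simulate a treatment course
#'
#' Integrates the 17-state system with the stiff-capable lsoda solver.
#' Bolus administrations are applied as integrator events (the solver is
#' stopped and restarted at each discontinuity); every dose time is a grid
#' point of the returned trajectory.
#'
#' @param ps A [parameter_set()].
#' @param regimen A `regimen` data frame; [no_treatment()] for control.
#' @param t_end End of simulation (weeks); must cover the last dose.
#' @param t_start Start time (weeks), with `y0` the state there.
#' @param y0 Initial state; defaults to the model's stated initial
#'   conditions at tumor inception.
#' @param dt_out Output resolution (weeks).
#' @param rtol,atol Solver tolerances; `atol` may be a 17-vector.
#' @param method deSolve integration method. The default "bdf" (backward
#'   differentiation formulas) is robust to the severe stiffness that
#'   develops when a responding tumor collapses and the per-volume
#'   transport terms grow as 1/B; "lsoda" switches methods automatically
#'   and can stall on such trajectories. If the requested method fails
#'   mid-course the solve is retried once with the L-stable implicit
#'   Runge-Kutta method "radau" before an error is raised.
#' @param compiled Use the compiled right-hand side (default); the pure-R
#'   reference is available for cross-checking.
#' @return A `trajectory` object: list with `times`, `states` (matrix with
#'   one column per state), `regimen`, `context`.
#' @export
simulate_course <- function(ps, regimen = no_treatment(), t_end = 104,
                            t_start = 0, y0 = NULL, dt_out = 0.5,
                            rtol = 1e-6, atol = default_atol(),
                            method = "bdf", compiled = TRUE) {
  if (nrow(regimen) > 0) {
    if (t_end < max(regimen$time))
      stop("t_end must be at or after the last dose")
    if (any(regimen$time < t_start))
      stop("doses before t_start are not supported; branch earlier")
  }
  if (is.null(y0)) y0 <- initial_state(ps)
  y0 <- stats::setNames(as.numeric(y0), STATE_NAMES)
  times <- sort(unique(c(seq(t_start, t_end, by = dt_out), t_end,
                         regimen$time)))
  events <- build_events(ps, regimen)
  parms <- pack_parms(ps, regimen)
  # lsoda emits diagnostic warnings for steps it retried but completed;
  # real failures surface through istate and are raised as errors below
  benign <- paste0("(convergence test failures)|(error test failures)|",
                   "(steps taken before)|(Returning early)|",
                   "(step size becomes too small)|(returning these|--- )")
  muffle <- function(expr) withCallingHandlers(expr, warning = function(w) {
    if (grepl(benign, conditionMessage(w))) invokeRestart("muffleWarning")
  })
  solve_with <- function(meth) {
    if (compiled) {
      muffle(deSolve::ode(y = y0, times = times, func = "derivs_mir22",
                          parms = parms, dllname = "mir22sim",
                          initfunc = "init_mir22", method = meth,
                          rtol = rtol, atol = atol, maxsteps = 100000,
                          events = if (is.null(events)) NULL else
                            list(data = events)))
    } else {
      muffle(deSolve::ode(y = y0, times = times,
                          func = function(t, y, parms) rhs_r(t, y, parms),
                          parms = parms, method = meth,
                          rtol = rtol, atol = atol, maxsteps = 100000,
                          events = if (is.null(events)) NULL else
                            list(data = events)))
    }
  }
  failed <- function(o) attr(o, "istate")[1] < 0 || nrow(o) < length(times)
  out <- solve_with(method)
  if (failed(out) && method != "radau") out <- solve_with("radau")
  if (failed(out))
    stop("ODE solver failed at t = ", out[nrow(out), 1],
         " (last valid time)")
  states <- unname(out[, -1, drop = FALSE])
  colnames(states) <- STATE_NAMES
  # negative excursions below the absolute tolerance are solver noise on
  # states decaying through zero; clamp them so trajectories honor the
  # model's non-negativity
  tol <- rep_len(atol, 17)
  for (j in seq_len(17)) {
    noise <- states[, j] < 0 & states[, j] > -tol[j]
    states[noise, j] <- 0
  }
  if (any(!is.finite(states)))
    stop("non-finite state in solution: ",
         STATE_NAMES[which(!is.finite(states), arr.ind = TRUE)[1, 2]])
  structure(list(times = out[, 1], states = states, regimen = regimen,
                 context = ps$context),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", x$context$species, "course,",
      length(x$times), "time points over",
      sprintf("%.4g", max(x$times) - min(x$times)), "weeks,",
      nrow(x$regimen), "dose events\n")
  cat("  final tumor volume:",
      sprintf("%.4g", x$states[nrow(x$states), "B"]), "cm^3\n")
  invisible(x)
}

#' Interpolate trajectory states at a time
#' @param traj A `trajectory`.
#' @param t Time (weeks) within the simulated range.
#' @return Named state vector.
#' @export
state_at <- function(traj, t) {
  if (t < min(traj$times) || t > max(traj$times))
    stop("t outside the simulated range")
  hit <- which(abs(traj$times - t) < 1e-9)
  if (length(hit)) return(traj$states[hit[1], ])
  apply(traj$states, 2, function(col)
    stats::approx(traj$times, col, xout = t)$y)
}

#' Tidy long-format view of a trajectory
#' @param x A `trajectory`.
#' @param ... Unused.
#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(
    time_wk = rep(x$times, times = ncol(x$states)),
    state = rep(colnames(x$states), each = length(x$times)),
    value = as.vector(x$states),
    units = rep(unname(STATE_UNITS[colnames(x$states)]),
                each = length(x$times)),
    stringsAsFactors = FALSE)
}

#' Export a trajectory to CSV or JSON
#' @param traj A `trajectory`.
#' @param path Output path; format chosen by extension (.csv or .json).
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Percent tumor growth inhibition
#'
#' %TGI = (1 - B_treated / B_control) * 100 evaluated at `t_eval`
#' (default 104 weeks post tumor inception).
#'
#' @param traj_treated,traj_control Trajectories covering `t_eval`.
#' @param t_eval Evaluation time (weeks).
#' @return Percent TGI (<= 100).
#' @export
percent_tgi <- function(traj_treated, traj_control, t_eval = 104) {
  Bt <- state_at(traj_treated, t_eval)[["B"]]
  Bc <- state_at(traj_control, t_eval)[["B"]]
  if (Bc <= 0) stop("control tumor volume is zero at the evaluation time")
  (1 - Bt / Bc) * 100
}

RESPONSE_LEVELS <- c("progressive", "stable", "intermediate", "partial",
                     "major")

#' RECIST-analog response classification
#'
#' Classes: progressive disease (TGI <= 0), stable disease (0 < TGI <= 10),
#' intermediate response (10 < TGI <= 30), partial response
#' (30 < TGI <= 50), major response (TGI > 50).
#'
#' @param tgi Percent TGI (finite), vectorized.
#' @return Factor with the five response levels.
#' @export
classify_response <- function(tgi) {
  if (any(!is.finite(tgi))) stop("tgi must be finite")
  cut(tgi, breaks = c(-Inf, 0, 10, 30, 50, Inf), labels = RESPONSE_LEVELS,
      right = TRUE)
}

#' Simulate matched treated and control arms and compute %TGI
#'
#' The control arm shares the pre-treatment history with the treated arm
#' (the model is deterministic, so the course is simulated once up to the
#' first dose and then branched).
#'
#' @param ps A [parameter_set()].
#' @param regimen Treatment regimen.
#' @param t_eval Evaluation time (weeks).
#' @param keep_trajectories Return the two branch trajectories.
#' @param ... Passed to [simulate_course()].
#' @return List with `tgi`, `response`, `B_treated`, `B_control` (and the
#'   trajectories if requested).
#' @export
simulate_tgi <- function(ps, regimen, t_eval = 104,
                         keep_trajectories = FALSE, ...) {
  dosed <- nrow(regimen) > 0 && min(regimen$time) < t_eval
  t0 <- if (dosed) min(c(regimen$time, t_eval)) else t_eval
  y0 <- initial_state(ps)
  if (t0 > 0) {
    base <- simulate_course(ps, no_treatment(), t_end = t0, ...)
    y0 <- base$states[nrow(base$states), ]
  }
  control <- if (t0 < t_eval) {
    simulate_course(ps, no_treatment(), t_end = t_eval, t_start = t0,
                    y0 = y0, ...)
  } else base
  treated <- if (dosed) {
    simulate_course(ps, regimen, t_end = t_eval, t_start = t0, y0 = y0, ...)
  } else control
  tgi <- percent_tgi(treated, control, t_eval)
  out <- list(tgi = tgi, response = as.character(classify_response(tgi)),
              B_treated = state_at(treated, t_eval)[["B"]],
              B_control = state_at(control, t_eval)[["B"]])
  if (keep_trajectories) {
    out$treated <- treated
    out$control <- control
  }
  out
}
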
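# Simultaneous nonlinear least-squares calibration against multi-arm
# longitudinal data, with goodness-of-fit reporting.

#' Define a calibration problem
#'
#' Bundles the observed datasets (the four-arm tumor-volume design plus the
#' optional eEF2K series, in the [generate_invivo_like()] schema) with the
#' free parameters to estimate. Free parameters are shared across arms;
#' the arm-specific growth constants (sigma, B_star) keep their per-arm
#' baseline values. Residuals are normalized per series by the maximum
#' observed mean so tumor-volume and protein series are commensurable.
#'
#' @param data An `invivo_dataset` (columns arm, measure, time_wk, mean,
#'   sd, n).
#' @param free Named list; each element is `c(start, lower, upper)` for one
#'   free parameter (biological or therapy).
#' @return Object of class `calibration_problem`.
#' @export
calibration_problem <- function(data, free) {
  if (nrow(data) == 0) stop("need at least one dataset")
  if (length(free) == 0) stop("need at least one free parameter")
  for (nm in names(free)) {
    v <- free[[nm]]
    if (length(v) != 3 || any(!is.finite(v)) || any(v <= 0))
      stop("free parameter '", nm, "' needs finite positive ",
           "c(start, lower, upper)")
    if (v[1] < v[2] || v[1] > v[3]) stop("start outside bounds for ", nm)
    arm_truth_params(data$arm[1], stats::setNames(list(v[1]), nm)) # name check
  }
  structure(list(data = data, free = free), class = "calibration_problem")
}

# Model predictions aligned with the rows of `data` for one candidate
# parameter vector (natural scale, named).
predict_calibration <- function(values, data, ...) {
  pred <- rep(NA_real_, nrow(data))
  for (arm in unique(data$arm)) {
    idx <- data$arm == arm
    ps <- arm_truth_params(arm, as.list(values))
    horizon <- max(data$time_wk[idx])
    traj <- simulate_course(ps, arm_regimen(arm, horizon),
                            t_end = horizon, ...)
    for (msr in unique(data$measure[idx])) {
      j <- idx & data$measure == msr
      state <- if (msr == "tumor_volume_cm3") "B" else "C_E"
      pred[j] <- vapply(data$time_wk[j],
                        function(t) state_at(traj, t)[[state]], numeric(1))
    }
  }
  pred
}

#' Fit free model parameters by nonlinear least squares
#'
#' Minimizes the summed squared normalized residuals jointly across all
#' arms with bounded Levenberg-Marquardt (log10-parameterized), using
#' multiple starts (the supplied start plus Latin-hypercube starts within
#' the bounds) to mitigate local minima. Non-convergence is reported with
#' the best-found vector, never silently.
#'
#' @param problem A [calibration_problem()].
#' @param seed Integer seed for the multi-start draws.
#' @param n_starts Total number of starts (>= 1).
#' @param ... Passed to the integrator.
#' @return Object of class `calibration_fit`: `estimates`, `deviance`,
#'   `residuals`, `converged`, `message`, `starts` (per-start summary),
#'   `data` with a `predicted` column.
#' @export
fit_parameters <- function(problem, seed = 1, n_starts = 10, ...) {
  data <- problem$data
  free <- problem$free
  nms <- names(free)
  lower <- log10(vapply(free, `[`, numeric(1), 2))
  upper <- log10(vapply(free, `[`, numeric(1), 3))
  start0 <- log10(vapply(free, `[`, numeric(1), 1))

  # per-series normalization weights
  key <- paste(data$arm, data$measure)
  wmax <- stats::ave(data$mean, key, FUN = function(v) max(abs(v)))
  wmax[wmax == 0] <- 1

  resid_fn <- function(par_log) {
    values <- stats::setNames(10^par_log, nms)
    pred <- tryCatch(predict_calibration(values, data, ...),
                     error = function(e) NULL)
    if (is.null(pred)) return(rep(1e6, nrow(data)))
    (pred - data$mean) / wmax
  }

  starts <- matrix(start0, nrow = 1)
  if (n_starts > 1) {
    extra <- lhs_sample(nms, n_starts - 1, seed, lower = 0, upper = 1)
    extra <- sweep(sweep(extra, 2, upper - lower, `*`), 2, lower, `+`)
    starts <- rbind(starts, extra)
  }

  best <- NULL
  per_start <- list()
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-10,
                           # finite-difference steps must exceed ODE solver
                           # noise (rtol 1e-6); sqrt(epsfcn) ~ 1e-3 gives
                           # ~0.1% parameter steps on the log10 scale
                           epsfcn = 1e-6)),
      error = function(e) NULL)
    if (is.null(fit)) next
    per_start[[length(per_start) + 1]] <- data.frame(
      start = s, deviance = fit$deviance, info = fit$info)
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  converged <- best$info %in% 1:4
  estimates <- stats::setNames(10^best$par, nms)
  data$predicted <- predict_calibration(estimates, data, ...)
  structure(list(estimates = estimates, deviance = best$deviance,
                 residuals = best$fvec, converged = converged,
                 message = best$message,
                 starts = do.call(rbind, per_start), data = data),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit>", if (x$converged) "converged" else
    "NOT converged", "| deviance", format(x$deviance, digits = 4), "\n")
  print(signif(x$estimates, 5))
  invisible(x)
}

#' Pearson goodness of fit
#'
#' Product-moment correlation between predicted and observed series with a
#' two-sided p-value.
#'
#' @param predicted,observed Numeric vectors of equal length >= 3.
#' @return List with `r` and `p_value`.
#' @export
goodness_of_fit <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 3)
    stop("predicted and observed must have equal length >= 3")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0)
    stop("zero-variance input")
  ct <- stats::cor.test(predicted, observed)
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Per-arm goodness of fit of a calibration
#' @param fit A `calibration_fit`.
#' @return Data frame with arm, measure, r, p_value.
#' @export
fit_quality <- function(fit) {
  d <- fit$data
  out <- list()
  for (arm in unique(d$arm)) for (msr in unique(d$measure[d$arm == arm])) {
    j <- d$arm == arm & d$measure == msr
    g <- goodness_of_fit(d$predicted[j], d$mean[j])
    out[[length(out) + 1]] <- data.frame(arm = arm, measure = msr,
                                         r = g$r, p_value = g$p_value)
  }
  do.call(rbind, out)
}
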
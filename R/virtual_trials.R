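# Virtual-patient populations, dose-response curves and parameter
# sensitivity analysis of percent tumor growth inhibition.

#' Patient-specific (perturbable) parameters
#'
#' The 16 patient-specific parameters sampled when building virtual
#' populations: the eEF2K/PD-L1/tumor signaling constants, tumor growth and
#' immune-death rates, the perfusion and vascular surface-area scales, and
#' the miRNA-22 production parameters.
#' @return Character vector of parameter names.
#' @export
dagger_parameters <- function() {
  c("A_B_E", "A_M_E", "K_B_E", "g_E0", "A_E_P", "K_E_P", "g_P0",
    "A_E_B", "K_E_B", "sigma", "delta_B_I", "eps_P", "Q", "S",
    "g_M0", "eps_B")
}

#' Default global-sensitivity parameter set
#'
#' The patient-specific set plus the five therapy parameters governing
#' miRNA-22 stability and potency and NP size, degradability and release.
#' @return Character vector of 21 parameter names.
#' @export
gsa_parameters <- function() {
  c(dagger_parameters(), "delta_M", "phi_NP", "delta_NP", "EC50_M", "k_rel")
}

#' Apply multiplicative factors to named model parameters
#'
#' Factors multiply the baseline value. "Q" and "S" scale the whole
#' perfusion and surface-area laws (for humans, the constants 1512 and
#' 135); "phi_NP" scales the NP diameter, which propagates to clearance,
#' permeability, diffusivity and per-particle payload when the model is
#' packed. A parameter named "dummy" is accepted and ignored (null-effect
#' control for sensitivity analyses).
#'
#' @param ps A [parameter_set()].
#' @param factors Named numeric vector of multiplicative factors.
#' @return Modified `parameter_set`.
#' @export
apply_param_factors <- function(ps, factors) {
  for (nm in names(factors)) {
    f <- factors[[nm]]
    if (nm == "dummy") next
    if (nm == "Q") {
      ps$context$plasma_flow$a <- ps$context$plasma_flow$a * f
    } else if (nm == "S") {
      ps$context$surface_area$a1 <- ps$context$surface_area$a1 * f
      if (ps$context$surface_area$mode == "exponential")
        ps$context$surface_area$a2 <- ps$context$surface_area$a2 * f
    } else if (nm %in% names(ps$bio)) {
      ps$bio[[nm]] <- ps$bio[[nm]] * f
    } else if (nm %in% names(ps$therapy)) {
      ps$therapy[[nm]] <- ps$therapy[[nm]] * f
    } else {
      stop("unknown parameter: ", nm)
    }
  }
  ps
}

#' Latin hypercube sample of a parameter space
#'
#' Stratified sampling: for each parameter, exactly one draw falls in each
#' of the `n` equal-width strata of its range. Reproducible by seed.
#'
#' @param specs Data frame with columns `name`, `lower`, `upper` (one row
#'   per parameter), or a character vector of names with shared
#'   `lower`/`upper` arguments.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param lower,upper Shared bounds when `specs` is a character vector.
#' @return n x k matrix of sampled values, columns named by parameter.
#' @export
lhs_sample <- function(specs, n, seed, lower = NULL, upper = NULL) {
  if (is.character(specs))
    specs <- data.frame(name = specs, lower = lower, upper = upper)
  if (nrow(specs) == 0) stop("empty parameter specification")
  if (any(specs$upper <= specs$lower)) stop("bounds must satisfy lower < upper")
  if (n < 1) stop("n must be >= 1")
  u <- with_seed(seed, lhs::randomLHS(n, nrow(specs)))
  x <- sweep(u, 2, specs$upper - specs$lower, `*`)
  x <- sweep(x, 2, specs$lower, `+`)
  colnames(x) <- specs$name
  x
}

# Run thunk under a local RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a virtual patient population
#'
#' Each patient is the baseline parameter set with Latin-hypercube-sampled
#' multiplicative overrides of the patient-specific parameters within
#' +/- `frac` of baseline.
#'
#' @param ps Baseline (usually human) [parameter_set()].
#' @param param_names Parameters to perturb; subset of
#'   [dagger_parameters()] by default.
#' @param n Population size.
#' @param frac Half-width of the perturbation as a fraction of baseline.
#' @param seed Integer seed.
#' @return `virtual_population` object.
#' @export
generate_population <- function(ps, param_names = dagger_parameters(),
                                n = 2000, frac = 0.5, seed = 1) {
  known <- c(dagger_parameters(), names(ps$bio), names(ps$therapy), "dummy")
  bad <- setdiff(param_names, known)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  factors <- if (frac == 0) {
    matrix(1, n, length(param_names),
           dimnames = list(NULL, param_names))
  } else {
    lhs_sample(param_names, n, seed, lower = 1 - frac, upper = 1 + frac)
  }
  structure(list(base = ps, factors = factors, frac = frac, seed = seed),
            class = "virtual_population")
}

#' Parameter set of one virtual patient
#' @param pop A `virtual_population`.
#' @param i Patient index.
#' @export
patient_params <- function(pop, i) {
  apply_param_factors(pop$base, pop$factors[i, ])
}

#' @export
print.virtual_population <- function(x, ...) {
  cat("<virtual_population>", nrow(x$factors), "patients,",
      ncol(x$factors), "perturbed parameters (+/-",
      sprintf("%.0f%%", 100 * x$frac), "of baseline), seed", x$seed, "\n")
  invisible(x)
}

#' Run a virtual trial
#'
#' Simulates the treated and matched untreated control course for every
#' patient in the population and classifies each on the RECIST-analog
#' scale. Individual solver failures are recorded, not dropped silently.
#'
#' @param pop A `virtual_population`.
#' @param regimen Treatment regimen applied to every patient.
#' @param t_eval Evaluation time (weeks).
#' @param ... Passed to the integrator.
#' @return `trial_result`: per-patient %TGI, response classes, class
#'   fractions, failure indices.
#' @export
run_virtual_trial <- function(pop, regimen, t_eval = 104, ...) {
  n <- nrow(pop$factors)
  tgi <- rep(NA_real_, n)
  failures <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch(simulate_tgi(patient_params(pop, i), regimen,
                                 t_eval = t_eval, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("patient %d: %s", i,
                                      conditionMessage(res)))
    } else {
      tgi[i] <- res$tgi
    }
  }
  if (all(is.na(tgi))) stop("all patient simulations failed")
  if (length(failures))
    warning(length(failures), " patient simulation(s) failed")
  cls <- classify_response(tgi[!is.na(tgi)])
  fractions <- as.numeric(table(cls) / length(cls))
  names(fractions) <- RESPONSE_LEVELS
  structure(list(tgi = tgi, classes = cls, fractions = fractions,
                 regimen = regimen, seed = pop$seed, failures = failures),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("<trial_result>", length(x$tgi), "patients;",
      nrow(x$regimen), "dose events\n")
  print(round(x$fractions, 3))
  invisible(x)
}

#' Export per-patient trial results
#' @param trial A `trial_result`.
#' @param path CSV (per-patient TGI) or JSON (summary) path.
#' @export
write_trial <- function(trial, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(fractions = as.list(trial$fractions),
                              n = length(trial$tgi),
                              failures = trial$failures),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    ok <- !is.na(trial$tgi)
    utils::write.csv(data.frame(patient = which(ok), tgi = trial$tgi[ok],
                                response = as.character(trial$classes)),
                     path, row.names = FALSE)
  }
  invisible(path)
}

#' Population dose sweep
#'
#' %TGI for every patient at every dose of a miRNA-22-NP dose grid under a
#' shared schedule. The pre-treatment course and the untreated control of
#' each patient are simulated once and reused across doses.
#'
#' @param pop A `virtual_population`.
#' @param doses miRNA-22 doses (mg/kg).
#' @param frequency "QW" or "Q2W".
#' @param start,duration Treatment window (weeks).
#' @param t_eval Evaluation time (weeks).
#' @param ... Passed to the integrator.
#' @return List with `tgi` (patients x doses matrix) and `fractions`
#'   (doses x response classes matrix of population fractions).
#' @export
population_dose_sweep <- function(pop, doses, frequency = c("QW", "Q2W"),
                                  start = 80, duration = 24, t_eval = 104,
                                  ...) {
  frequency <- match.arg(frequency)
  proto <- if (frequency == "QW") "human_QW" else "human_Q2W"
  n <- nrow(pop$factors)
  tgi <- matrix(NA_real_, n, length(doses),
                dimnames = list(NULL, paste0("dose_", doses)))
  regs <- lapply(doses, function(d)
    if (d > 0) build_schedule(proto, dose = d, start = start,
                              duration = duration) else no_treatment())
  for (i in seq_len(n)) {
    pp <- patient_params(pop, i)
    ok <- tryCatch({
      base <- simulate_course(pp, no_treatment(), t_end = start, ...)
      y0 <- base$states[nrow(base$states), ]
      ctrl <- simulate_course(pp, no_treatment(), t_end = t_eval,
                              t_start = start, y0 = y0, ...)
      Bc <- state_at(ctrl, t_eval)[["B"]]
      for (k in seq_along(doses)) {
        tgi[i, k] <- if (doses[k] == 0) 0 else {
          tr <- simulate_course(pp, regs[[k]], t_end = t_eval,
                                t_start = start, y0 = y0, ...)
          (1 - state_at(tr, t_eval)[["B"]] / Bc) * 100
        }
      }
      TRUE
    }, error = function(e) FALSE)
    if (!ok) next
  }
  fr <- t(apply(tgi, 2, function(col) {
    col <- col[is.finite(col)]
    as.numeric(table(classify_response(col)) / length(col))
  }))
  colnames(fr) <- RESPONSE_LEVELS
  rownames(fr) <- paste0("dose_", doses)
  list(tgi = tgi, fractions = fr, doses = doses)
}

#' Dose-response curve for one subject
#'
#' %TGI at `t_eval` for a grid of miRNA-22-NP doses under once-weekly or
#' every-two-weeks dosing. The tumor growth class can be pinned by the
#' ratio of immune-induced death rate to growth rate (delta_B_I / sigma):
#' 0.99, 0.9 and 0.75 correspond to slow, medium and fast growing tumors
#' (implemented by setting delta_B_I = ratio * sigma).
#'
#' @param ps Subject [parameter_set()].
#' @param doses miRNA-22 doses (mg/kg), >= 0; dose 0 is the control and
#'   yields exactly 0.
#' @param frequency "QW" or "Q2W".
#' @param growth_ratio Optional delta_B_I / sigma ratio.
#' @param start,duration Treatment window (weeks).
#' @param t_eval Evaluation time (weeks).
#' @param ... Passed to the integrator.
#' @return Data frame with `dose` and `tgi`.
#' @export
dose_response_curve <- function(ps, doses, frequency = c("QW", "Q2W"),
                                growth_ratio = NULL, start = 80,
                                duration = 24, t_eval = 104, ...) {
  frequency <- match.arg(frequency)
  if (any(doses < 0)) stop("doses must be non-negative")
  if (!is.null(growth_ratio))
    ps$bio$delta_B_I <- growth_ratio * ps$bio$sigma
  proto <- if (frequency == "QW") "human_QW" else "human_Q2W"
  tgi <- vapply(doses, function(d) {
    if (d == 0) return(0)
    simulate_tgi(ps, build_schedule(proto, dose = d, start = start,
                                    duration = duration),
                 t_eval = t_eval, ...)$tgi
  }, numeric(1))
  data.frame(dose = doses, tgi = tgi)
}

#' Local sensitivity of %TGI to one parameter
#'
#' One-at-a-time perturbation over a factor range (default 0.2x to 5x of
#' baseline, 500 levels, baseline included), all other parameters held at
#' baseline.
#'
#' @param ps Baseline [parameter_set()].
#' @param param Parameter name (see [apply_param_factors()]).
#' @param regimen Treatment regimen (default: reference human QW course).
#' @param factor_range Perturbation factor range.
#' @param levels Number of factor levels.
#' @param t_eval Evaluation time (weeks).
#' @param ... Passed to the integrator.
#' @return Data frame with `factor` and `tgi`.
#' @export
local_sensitivity <- function(ps, param,
                              regimen = build_schedule("human_QW"),
                              factor_range = c(0.2, 5), levels = 500,
                              t_eval = 104, ...) {
  f <- sort(unique(c(1, seq(factor_range[1], factor_range[2],
                            length.out = levels))))
  tgi <- vapply(f, function(fac) {
    simulate_tgi(apply_param_factors(ps, stats::setNames(fac, param)),
                 regimen, t_eval = t_eval, ...)$tgi
  }, numeric(1))
  data.frame(factor = f, tgi = tgi)
}

#' Global sensitivity analysis by LHS and multivariate regression
#'
#' All parameters of interest are perturbed simultaneously by Latin
#' hypercube sampling of multiplicative factors in `factor_range`; %TGI is
#' computed for every combination; and per replicate a multivariate linear
#' regression of %TGI on the z-scored factors yields one standardized
#' regression coefficient per parameter, the sensitivity index (SI).
#' Parameters are ranked by mean |SI| and grouped into brackets by one-way
#' ANOVA with Tukey's honest significant difference on the per-replicate
#' |SI| values: a parameter starts a new bracket when it differs
#' significantly (p < 0.05) from the leading parameter of the current one.
#'
#' @param ps Baseline [parameter_set()].
#' @param params Parameter names (default [gsa_parameters()]).
#' @param n Samples per replicate.
#' @param replicates Number of LHS replicates.
#' @param seed Integer master seed; replicate r uses seed + r.
#' @param regimen Treatment regimen.
#' @param factor_range Perturbation factor range.
#' @param t_eval Evaluation time (weeks).
#' @param ... Passed to the integrator.
#' @return `gsa_result`: SI matrix (replicates x parameters), ranking data
#'   frame with brackets, Tukey table.
#' @export
global_sensitivity <- function(ps, params = gsa_parameters(), n = 10000,
                               replicates = 10, seed = 1,
                               regimen = build_schedule("human_QW"),
                               factor_range = c(0.2, 5), t_eval = 104, ...) {
  if (length(params) < 2) stop("need at least two parameters")
  si <- matrix(NA_real_, replicates, length(params),
               dimnames = list(NULL, params))
  for (r in seq_len(replicates)) {
    x <- lhs_sample(params, n, seed + r,
                    lower = factor_range[1], upper = factor_range[2])
    tgi <- apply(x, 1, function(row) {
      res <- tryCatch(simulate_tgi(
        apply_param_factors(ps, stats::setNames(row, params)),
        regimen, t_eval = t_eval, ...), error = function(e) NULL)
      if (is.null(res)) NA_real_ else res$tgi
    })
    keep <- is.finite(tgi)
    xs <- scale(x[keep, , drop = FALSE])
    if (qr(xs)$rank < ncol(xs)) stop("rank-deficient design matrix")
    ys <- as.numeric(scale(tgi[keep]))
    si[r, ] <- stats::coef(stats::lm(ys ~ xs))[-1]
  }
  absdf <- data.frame(si = as.vector(abs(si)),
                      parameter = factor(rep(params, each = replicates)))
  fit <- stats::aov(si ~ parameter, data = absdf)
  tukey <- stats::TukeyHSD(fit)$parameter
  mean_abs <- colMeans(abs(si))
  ord <- names(sort(mean_abs, decreasing = TRUE))
  p_of <- function(a, b) {
    key <- paste(a, b, sep = "-"); alt <- paste(b, a, sep = "-")
    if (key %in% rownames(tukey)) tukey[key, "p adj"]
    else tukey[alt, "p adj"]
  }
  bracket <- integer(length(ord)); bracket[1] <- 1L; lead <- ord[1]
  for (i in seq_along(ord)[-1]) {
    if (p_of(ord[i], lead) < 0.05) {
      bracket[i] <- bracket[i - 1] + 1L
      lead <- ord[i]
    } else bracket[i] <- bracket[i - 1]
  }
  ranking <- data.frame(parameter = ord, mean_si = colMeans(si)[ord],
                        mean_abs_si = mean_abs[ord], bracket = bracket,
                        row.names = NULL)
  structure(list(si = si, ranking = ranking, tukey = tukey, seed = seed),
            class = "gsa_result")
}

#' @export
print.gsa_result <- function(x, ...) {
  cat("<gsa_result>", nrow(x$si), "replicates,", ncol(x$si), "parameters\n")
  print(x$ranking, digits = 3)
  invisible(x)
}
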
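# Chou-Talalay median-effect analysis of drug synergy.
#
# The median-effect equation fa/fu = (D/Dm)^m linearizes to
# log(fa/(1-fa)) = m log(D) - m log(Dm); monotherapy fits supply (Dm, m)
# per agent and the combination index at a combination datum with effect
# fa is CI = sum_i D_i / Dx_i with Dx_i = Dm_i (fa/(1-fa))^(1/m_i)
# (mutually exclusive form; CI < 1 synergy, = 1 additivity, > 1
# antagonism).

FA_CLIP <- 1e-6   # logit-fit usable range: fa in [FA_CLIP, 1 - FA_CLIP]

REFERENCE_DOSES <- c(miRNA_NP = 0.026, doxorubicin = 2.4, antibody = 2)

synergy_regimen <- function(agents, doses, start = 80, duration = 24) {
  parts <- list()
  if ("miRNA_NP" %in% agents)
    parts <- c(parts, list(dose_event(
      "miRNA_NP", seq(start, start + duration - 1, 1), doses[["miRNA_NP"]])))
  if ("doxorubicin" %in% agents)
    parts <- c(parts, list(dose_event(
      "doxorubicin", seq(start, start + duration - 1, 3),
      doses[["doxorubicin"]])))
  if ("antibody" %in% agents)
    parts <- c(parts, list(dose_event(
      "antibody", seq(start, start + duration - 1, 3), doses[["antibody"]])))
  do.call(combine_regimens, parts)
}

#' Simulated dose-effect table for mono- and combination therapies
#'
#' Simulates %TGI for constant-ratio dose grids anchored at the reference
#' clinical doses (miRNA-22 0.026 mg/kg QW, doxorubicin 2.4 mg/kg Q3W,
#' atezolizumab 2 mg/kg Q3W) on the reference subject and converts it to
#' the fractional effect fa = %TGI / 100.
#'
#' @param ps Reference subject [parameter_set()].
#' @param therapies Character vector; each element is a `+`-separated
#'   combination of "miRNA_NP", "doxorubicin", "antibody".
#' @param multipliers Constant-ratio dose multipliers applied to all agents
#'   of a therapy simultaneously.
#' @param ref_doses Named anchor doses (mg/kg).
#' @param t_eval Evaluation time (weeks).
#' @param ... Passed to the integrator.
#' @return Data frame: therapy, multiplier, per-agent doses, tgi, fa.
#' @export
simulate_dose_response_matrix <- function(
    ps,
    therapies = c("miRNA_NP", "doxorubicin", "antibody",
                  "miRNA_NP+doxorubicin", "miRNA_NP+antibody",
                  "miRNA_NP+doxorubicin+antibody"),
    multipliers = c(0.25, 0.5, 1, 2, 4),
    ref_doses = REFERENCE_DOSES, t_eval = 104, ...) {
  if (any(multipliers <= 0)) stop("dose multipliers must be positive")
  rows <- list()
  for (th in therapies) {
    agents <- strsplit(th, "+", fixed = TRUE)[[1]]
    if (!all(agents %in% names(ref_doses)))
      stop("unknown agent in therapy: ", th)
    for (m in multipliers) {
      doses <- ref_doses[agents] * m
      reg <- synergy_regimen(agents, doses)
      tgi <- simulate_tgi(ps, reg, t_eval = t_eval, ...)$tgi
      row <- data.frame(therapy = th, multiplier = m,
                        dose_miRNA_NP = if ("miRNA_NP" %in% agents)
                          doses[["miRNA_NP"]] else 0,
                        dose_doxorubicin = if ("doxorubicin" %in% agents)
                          doses[["doxorubicin"]] else 0,
                        dose_antibody = if ("antibody" %in% agents)
                          doses[["antibody"]] else 0,
                        tgi = tgi, fa = tgi / 100)
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Median-effect fit of a dose-effect series
#'
#' Least-squares line of log(fa/(1-fa)) on log(D); returns the median-effect
#' dose Dm (dose for fa = 0.5), the sigmoidicity m, and the correlation r
#' of the linearized plot. Points with fa outside (FA_CLIP, 1 - FA_CLIP)
#' are excluded to avoid infinite logits.
#'
#' @param doses Doses (positive, same units throughout).
#' @param fa Fractional effects in [0, 1).
#' @return Object of class `median_effect_fit` with Dm, m, r, n_points.
#' @export
median_effect_fit <- function(doses, fa) {
  if (length(doses) != length(fa)) stop("doses and fa lengths differ")
  use <- is.finite(doses) & is.finite(fa) & doses > 0 &
    fa > FA_CLIP & fa < 1 - FA_CLIP
  if (sum(use) < 2)
    stop("need at least 2 dose-effect points with 0 < fa < 1")
  d <- doses[use]; f <- fa[use]
  if (length(unique(d)) < 2) stop("doses must not be all identical")
  x <- log(d); y <- log(f / (1 - f))
  fit <- stats::lm(y ~ x)
  b <- unname(stats::coef(fit)[1])
  m <- unname(stats::coef(fit)[2])
  Dm <- exp(-b / m)   # +Inf when the observed effect is dose-flat (m -> 0)
  structure(list(Dm = Dm, m = m, intercept = b, r = stats::cor(x, y),
                 n_points = length(d)),
            class = "median_effect_fit")
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("<median_effect_fit> Dm = %.4g, m = %.3f, r = %.4f (n = %d)\n",
              x$Dm, x$m, x$r, x$n_points))
  invisible(x)
}

# Dose of one agent alone producing effect fa, from its median-effect fit:
# Dx = Dm (fa/fu)^(1/m), evaluated on the fitted line in log space so the
# dose-flat limit m -> 0 resolves correctly (Dx -> Inf for any effect above
# the agent's plateau, i.e. the agent contributes no dose equivalent).
dose_for_effect <- function(fit, fa) {
  log_dx <- (log(fa / (1 - fa)) - fit$intercept) / fit$m
  exp(log_dx)
}

#' Combination index at combination data points
#'
#' For each combination point with per-agent doses D_i and observed effect
#' fa, CI = sum_i D_i / Dx_i where Dx_i is the dose of agent i alone that
#' would produce fa (mutually exclusive Chou-Talalay form; extends to three
#' agents by summation). Points with fa outside (0, 1) are skipped with a
#' warning. The summary CI is the median of the per-point values.
#'
#' @param mono_fits Named list of `median_effect_fit`, one per agent.
#' @param combo_points Data frame with one `dose_<agent>` column per agent
#'   and an `fa` column.
#' @return Object of class `synergy_result`: per-point CI and summary.
#' @export
combination_index <- function(mono_fits, combo_points) {
  agents <- names(mono_fits)
  dose_cols <- paste0("dose_", agents)
  missing <- setdiff(dose_cols, names(combo_points))
  if (length(missing))
    stop("combo_points lacks column(s): ", paste(missing, collapse = ", "))
  ci <- rep(NA_real_, nrow(combo_points))
  for (k in seq_len(nrow(combo_points))) {
    fa <- combo_points$fa[k]
    if (!is.finite(fa) || fa <= 0 || fa >= 1) {
      warning("skipping combination point with fa outside (0, 1): fa = ", fa)
      next
    }
    ci[k] <- sum(vapply(agents, function(a) {
      D <- combo_points[[paste0("dose_", a)]][k]
      if (D == 0) return(0)
      Dx <- dose_for_effect(mono_fits[[a]], fa)
      if (Dx == 0)
        warning("agent ", a, " alone already exceeds effect fa = ", fa,
                " at vanishing dose; its CI contribution is infinite")
      D / Dx
    }, numeric(1)))
  }
  structure(list(agents = agents, points = cbind(combo_points, ci = ci),
                 ci = ci, summary_ci = stats::median(ci, na.rm = TRUE)),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat("<synergy_result>", paste(x$agents, collapse = " + "),
      sprintf("| summary CI = %.3f\n", x$summary_ci))
  print(round(x$ci, 3))
  invisible(x)
}

#' Full Chou-Talalay synergy analysis from model simulations
#'
#' Simulates the dose-effect matrix, fits the median-effect line for each
#' monotherapy, and computes combination indices for each miRNA-22
#' combination at every combination datum.
#'
#' @param ps Reference subject [parameter_set()].
#' @param multipliers Constant-ratio dose multipliers.
#' @param ... Passed to [simulate_dose_response_matrix()].
#' @return List with the fa table, per-agent fits and per-combination
#'   `synergy_result`s.
#' @export
chou_talalay_analysis <- function(ps, multipliers = c(0.25, 0.5, 1, 2, 4),
                                  ...) {
  fa_tab <- simulate_dose_response_matrix(ps, multipliers = multipliers, ...)
  mono <- list()
  for (a in c("miRNA_NP", "doxorubicin", "antibody")) {
    sub <- fa_tab[fa_tab$therapy == a, ]
    mono[[a]] <- median_effect_fit(sub[[paste0("dose_", a)]], sub$fa)
  }
  combos <- grep("\\+", unique(fa_tab$therapy), value = TRUE)
  results <- list()
  for (cb in combos) {
    agents <- strsplit(cb, "+", fixed = TRUE)[[1]]
    sub <- fa_tab[fa_tab$therapy == cb, ]
    results[[cb]] <- combination_index(mono[agents], sub)
  }
  list(fa_table = fa_tab, mono_fits = mono, combinations = results)
}
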
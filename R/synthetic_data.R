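# In-vivo-like synthetic datasets for calibration.
#
# The generator emulates the design of the mouse studies behind the model:
# MDA-MB-231 xenografts (inoculum 0.001 cm^3) measured weekly, under
# control conditions or treated with 0.15 mg/kg IV miRNA-22-NP once a week,
# 4 mg/kg IV doxorubicin once a week, or 5 mg/kg IP atezolizumab once every
# 5 days; the miRNA arm additionally reports an eEF2K time course. Values
# are produced by the model itself under known "truth" parameters with
# multiplicative lognormal noise per animal, so calibration can be tested
# by parameter recovery.

MOUSE_ARM_REGIMENS <- list(
  control = NULL,
  miRNA = "mouse_miRNA",
  dox = "mouse_dox",
  atezo = "mouse_atezo"
)

arm_regimen <- function(arm, horizon = Inf) {
  proto <- MOUSE_ARM_REGIMENS[[arm]]
  reg <- if (is.null(proto)) no_treatment() else build_schedule(proto)
  # doses after the last measurement cannot influence the dataset
  reg[reg$time <= horizon, , drop = FALSE]
}

#' Default synthetic study design
#'
#' Weekly tumor-volume measurements over weeks 1-6 post inoculation for the
#' four arms, with the eEF2K series attached to the miRNA arm.
#' @export
default_study_design <- function() {
  list(arms = c("control", "miRNA", "dox", "atezo"),
       times = 1:6, eEF2K_arm = "miRNA")
}

#' Generate in-vivo-like longitudinal datasets
#'
#' Per animal, multiplicative lognormal noise with coefficient of variation
#' `noise_cv` (unit mean) is applied to the deterministic model trajectory;
#' per-time arm means and standard deviations are computed across animals.
#'
#' @param truth Named list of parameter overrides applied to every arm's
#'   mouse baseline (the generating "truth", retained for recovery tests).
#'   Values replace entries of the biological or therapy lists.
#' @param design List with `arms`, `times` (weeks) and `eEF2K_arm`; see
#'   [default_study_design()].
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param n_animals Animals per arm.
#' @param seed Integer seed.
#' @param ... Passed to the integrator.
#' @return Object of class `invivo_dataset`: data frame with columns
#'   arm, measure, time_wk, mean, sd, n; attributes `seed` and `truth`.
#' @export
generate_invivo_like <- function(truth = list(),
                                 design = default_study_design(),
                                 noise_cv = 0.1, n_animals = 8, seed = 1,
                                 ...) {
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  if (n_animals < 1) stop("n_animals must be >= 1")
  bad <- setdiff(design$arms, names(MOUSE_ARM_REGIMENS))
  if (length(bad)) stop("unknown arm(s): ", paste(bad, collapse = ", "))
  sdlog <- sqrt(log(1 + noise_cv^2))
  rows <- with_seed(seed, {
    out <- list()
    for (arm in design$arms) {
      ps <- arm_truth_params(arm, truth)
      traj <- simulate_course(ps, arm_regimen(arm, max(design$times)),
                              t_end = max(design$times), ...)
      measures <- "tumor_volume_cm3"
      if (identical(arm, design$eEF2K_arm))
        measures <- c(measures, "eEF2K_level")
      for (msr in measures) {
        state <- if (msr == "tumor_volume_cm3") "B" else "C_E"
        mu <- vapply(design$times,
                     function(t) state_at(traj, t)[[state]], numeric(1))
        noise <- matrix(stats::rlnorm(n_animals * length(mu),
                                      meanlog = -sdlog^2 / 2, sdlog = sdlog),
                        nrow = n_animals)
        animals <- sweep(noise, 2, mu, `*`)
        out[[length(out) + 1]] <- data.frame(
          arm = arm, measure = msr, time_wk = design$times,
          mean = colMeans(animals),
          sd = if (n_animals > 1) apply(animals, 2, stats::sd) else 0,
          n = n_animals)
      }
    }
    out
  })
  structure(do.call(rbind, rows), seed = seed, truth = truth,
            class = c("invivo_dataset", "data.frame"))
}

# Mouse parameter set for one arm with truth overrides applied.
arm_truth_params <- function(arm, truth = list()) {
  ps_arm <- if (arm == "control") "control" else arm
  ps <- mouse_parameters(arm = ps_arm)
  for (nm in names(truth)) {
    if (nm %in% names(ps$bio)) ps$bio[[nm]] <- truth[[nm]]
    else if (nm %in% names(ps$therapy)) ps$therapy[[nm]] <- truth[[nm]]
    else stop("unknown truth parameter: ", nm)
  }
  ps
}

#' Write a synthetic dataset (CSV) and its truth sidecar (JSON)
#' @param dataset An `invivo_dataset`.
#' @param path CSV path; the truth parameters are written next to it as
#'   `<path>.truth.json`.
#' @export
write_invivo_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  jsonlite::write_json(list(seed = attr(dataset, "seed"),
                            truth = attr(dataset, "truth")),
                       paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_invivo_dataset
#' @export
read_invivo_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  truth_path <- paste0(path, ".truth.json")
  if (file.exists(truth_path)) {
    meta <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    attr(df, "seed") <- meta$seed
    attr(df, "truth") <- as.list(meta$truth)
  }
  class(df) <- c("invivo_dataset", "data.frame")
  df
}
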
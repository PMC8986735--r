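# Dose events and named treatment schedules.

AGENTS <- c("miRNA_NP", "doxorubicin", "antibody")
ROUTES <- c("IV_bolus", "IP")

#' Create dose events
#'
#' A regimen is a data frame of administrations with one row per event.
#' Amounts are in mg/kg of the active agent (for miRNA_NP, mg/kg of miRNA-22
#' payload; the corresponding particle number is derived from the NP size).
#'
#' @param agent One of "miRNA_NP", "doxorubicin", "antibody" (recycled).
#' @param time Administration times, weeks post tumor inception.
#' @param amount Dose in mg/kg (recycled).
#' @param route "IV_bolus" or "IP" (recycled).
#' @return A data frame of class `regimen`.
#' @export
dose_event <- function(agent, time, amount, route = "IV_bolus") {
  agent <- match.arg(agent, AGENTS, several.ok = TRUE)
  route <- match.arg(route, ROUTES, several.ok = TRUE)
  if (any(time < 0)) stop("dose times must be non-negative")
  if (any(amount < 0)) stop("dose amounts must be non-negative")
  r <- data.frame(agent = agent, route = route, time = time, amount = amount,
                  stringsAsFactors = FALSE)
  r <- r[order(r$time), , drop = FALSE]
  rownames(r) <- NULL
  class(r) <- c("regimen", "data.frame")
  r
}

#' An empty regimen (untreated control)
#' @export
no_treatment <- function() {
  r <- data.frame(agent = character(0), route = character(0),
                  time = numeric(0), amount = numeric(0),
                  stringsAsFactors = FALSE)
  class(r) <- c("regimen", "data.frame")
  r
}

combine_regimens <- function(...) {
  r <- do.call(rbind, lapply(list(...), as.data.frame))
  r <- r[order(r$time), , drop = FALSE]
  rownames(r) <- NULL
  class(r) <- c("regimen", "data.frame")
  r
}

#' Build a named treatment schedule
#'
#' Mouse protocols reproduce the calibration study designs: miRNA-22-NP
#' 0.15 mg/kg IV at weeks 2-5; doxorubicin 4 mg/kg IV at weeks 1-3;
#' atezolizumab 5 mg/kg IP every 5 days at weeks 1, 1.71, ..., 4.57.
#' Human protocols start at week 80 post tumor inception and span 24 weeks
#' (~6 months): miRNA-22-NP QW (24 weekly doses) or Q2W (12 doses) at a
#' configurable dose (default the allometrically scaled 0.026 mg/kg);
#' doxorubicin 2.4 mg/kg and atezolizumab 2 mg/kg every three weeks
#' (8 doses each). Combination protocols concatenate their components.
#'
#' @param protocol Protocol name, see Details.
#' @param dose Override of the protocol's default agent dose (mg/kg). For
#'   combinations, a named vector (names among miRNA_NP, doxorubicin,
#'   antibody).
#' @param start Treatment start (weeks); human protocols only.
#' @param duration Treatment span (weeks); human protocols only.
#' @return A `regimen` data frame.
#' @export
build_schedule <- function(protocol = c("mouse_miRNA", "mouse_dox",
                                        "mouse_atezo", "human_QW",
                                        "human_Q2W", "human_Q3W_dox",
                                        "human_Q3W_atezo",
                                        "human_QW_dox", "human_QW_atezo",
                                        "human_QW_dox_atezo"),
                           dose = NULL, start = 80, duration = 24) {
  protocol <- match.arg(protocol)
  pick <- function(agent, default) {
    if (is.null(dose)) return(default)
    if (!is.null(names(dose))) {
      if (agent %in% names(dose)) unname(dose[[agent]]) else default
    } else dose
  }
  qw   <- function() seq(start, start + duration - 1, by = 1)
  q2w  <- function() seq(start, start + duration - 1, by = 2)
  q3w  <- function() seq(start, start + duration - 1, by = 3)
  switch(protocol,
    mouse_miRNA = dose_event("miRNA_NP", 2:5, pick("miRNA_NP", 0.15)),
    mouse_dox   = dose_event("doxorubicin", 1:3, pick("doxorubicin", 4)),
    mouse_atezo = dose_event("antibody", c(1, 1.71, 2.43, 3.14, 3.86, 4.57),
                             pick("antibody", 5), route = "IP"),
    human_QW  = dose_event("miRNA_NP", qw(), pick("miRNA_NP", 0.026)),
    human_Q2W = dose_event("miRNA_NP", q2w(), pick("miRNA_NP", 0.026)),
    human_Q3W_dox   = dose_event("doxorubicin", q3w(),
                                 pick("doxorubicin", 2.4)),
    human_Q3W_atezo = dose_event("antibody", q3w(), pick("antibody", 2)),
    human_QW_dox = combine_regimens(
      dose_event("miRNA_NP", qw(), pick("miRNA_NP", 0.026)),
      dose_event("doxorubicin", q3w(), pick("doxorubicin", 2.4))),
    human_QW_atezo = combine_regimens(
      dose_event("miRNA_NP", qw(), pick("miRNA_NP", 0.026)),
      dose_event("antibody", q3w(), pick("antibody", 2))),
    human_QW_dox_atezo = combine_regimens(
      dose_event("miRNA_NP", qw(), pick("miRNA_NP", 0.026)),
      dose_event("doxorubicin", q3w(), pick("doxorubicin", 2.4)),
      dose_event("antibody", q3w(), pick("antibody", 2)))
  )
}

#' Write / read a regimen as a YAML file
#' @param regimen A `regimen` data frame.
#' @param path File path.
#' @export
write_regimen <- function(regimen, path) {
  yaml::write_yaml(lapply(seq_len(nrow(regimen)), function(i)
    as.list(regimen[i, ])), path)
  invisible(path)
}

#' @rdname write_regimen
#' @export
read_regimen <- function(path) {
  rows <- yaml::read_yaml(path)
  if (length(rows) == 0) return(no_treatment())
  do.call(combine_regimens, lapply(rows, function(r)
    dose_event(r$agent, r$time, r$amount, r$route)))
}
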
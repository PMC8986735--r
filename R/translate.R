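# Allometric mouse-to-human translation of parameters and doses.

#' Allometric scaling of a parameter value
#'
#' value * (bw_dst / bw_src)^exponent, with the standard exponents -0.25
#' for first-order rate constants, 0.75 for clearances and doses, and 1.0
#' for volumes of distribution.
#'
#' @param value Parameter value (positive).
#' @param exponent Allometric exponent.
#' @param bw_src,bw_dst Source and target body weights (kg); defaults are
#'   the 0.02 kg mouse and the 70 kg reference human.
#' @return Scaled value.
#' @export
allometric_scale <- function(value, exponent, bw_src = 0.02, bw_dst = 70) {
  if (any(value <= 0) || bw_src <= 0 || bw_dst <= 0)
    stop("value and body weights must be positive")
  value * (bw_dst / bw_src)^exponent
}

#' Human per-kg dose from a total mouse dose
#'
#' Scales a total mouse dose (mg) with the 0.75 dose exponent and divides
#' by the human body weight: the 4 ug/mouse miRNA-22 dose (0.15 mg/kg in a
#' 20 g mouse) maps to 0.026 mg/kg in a 70 kg human.
#'
#' @param total_mouse_dose Total dose in the mouse (mg).
#' @param bw_m,bw_h Mouse and human body weights (kg).
#' @param exponent Dose-scaling exponent (default 0.75).
#' @return Human dose in mg/kg.
#' @export
human_dose_from_mouse <- function(total_mouse_dose, bw_m = 0.02, bw_h = 70,
                                  exponent = 0.75) {
  if (total_mouse_dose <= 0 || bw_m <= 0 || bw_h <= 0)
    stop("dose and body weights must be positive")
  allometric_scale(total_mouse_dose, exponent, bw_m, bw_h) / bw_h
}

# Mouse tumor growth rate was estimated per study arm; the human value
# scales the mean of the three treatment-arm estimates.
mean_mouse_sigma <- function() mean(c(3.1, 3.75, 3.13))

#' Translate a mouse parameter set to the human scale
#'
#' Applies the -0.25 rate-constant exponent to the tumor growth rate
#' (mean of the three mouse arm estimates), the immune- and chemo-induced
#' death rates and (via the clearance sub-model) the NP clearance rate;
#' scales antibody clearance with exponent 0.75 and its distribution volume
#' with exponent 1.0; and substitutes the non-allometric human physiology
#' verbatim (constant perfusion 1512 mL/mL/wk, vascular surface area 135
#' cm2/cm3, plasma volume 3000 mL, carrying capacity 100 cm3, literature
#' doxorubicin clearance/volume, single-cell tumor inception). The antibody
#' route switches to IV bolus.
#'
#' @param mouse_ps A mouse [parameter_set()].
#' @param use_printed Substitute the printed (rounded) human values for the
#'   scaled rate constants (default); `FALSE` keeps full-precision scaling.
#' @return List with the human `parameter_set` (`params`) and a provenance
#'   data frame recording, per changed parameter, whether it was scaled or
#'   substituted.
#' @export
humanize_parameters <- function(mouse_ps, use_printed = TRUE) {
  if (mouse_ps$context$species != "mouse")
    stop("expected a mouse parameter set")
  bw_m <- mouse_ps$context$body_weight
  hu <- human_parameters()
  prov <- list()
  note <- function(name, kind, value) {
    prov[[length(prov) + 1]] <<- data.frame(parameter = name, kind = kind,
                                            value = value)
  }
  scaled <- function(v, expo) allometric_scale(v, expo, bw_m, 70)

  hb <- mouse_ps$bio
  hb$sigma <- if (use_printed) 0.43 else scaled(mean_mouse_sigma(), -0.25)
  note("sigma", "scaled (-0.25, mean of arms)", hb$sigma)
  hb$delta_B_I <- if (use_printed) 0.39 else scaled(hb$delta_B_I, -0.25)
  note("delta_B_I", "scaled (-0.25)", hb$delta_B_I)
  hb$delta_B_C <- if (use_printed) 0.3198 else scaled(hb$delta_B_C, -0.25)
  note("delta_B_C", "scaled (-0.25)", hb$delta_B_C)
  hb$B_star <- hu$bio$B_star;  note("B_star", "substituted", hb$B_star)
  hb$B_0 <- hu$bio$B_0;        note("B_0", "substituted (single cell)", hb$B_0)

  ht <- mouse_ps$therapy
  ht$Cl_Ab <- if (use_printed) 1400 else scaled(ht$Cl_Ab, 0.75)
  note("Cl_Ab", "scaled (0.75)", ht$Cl_Ab)
  ht$V_D_Ab <- if (use_printed) 6900 else scaled(ht$V_D_Ab, 1.0)
  note("V_D_Ab", "scaled (1.0)", ht$V_D_Ab)
  ht$Cl_dox <- hu$therapy$Cl_dox;   note("Cl_dox", "substituted", ht$Cl_dox)
  ht$V_D_dox <- hu$therapy$V_D_dox; note("V_D_dox", "substituted", ht$V_D_dox)

  note("V_P", "substituted", hu$context$V_P)
  note("Q", "substituted (constant)", hu$context$plasma_flow$a)
  note("S", "substituted (constant)", hu$context$surface_area$a1)
  note("k_Cl", "scaled (-0.25, via clearance sub-model)",
       np_clearance_rate(ht$phi_NP * 1e-7, hu$context))

  ps <- structure(list(context = hu$context, bio = hb, therapy = ht,
                       options = mouse_ps$options),
                  class = "parameter_set")
  validate_parameter_set(ps)
  list(params = ps, provenance = do.call(rbind, prov))
}
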
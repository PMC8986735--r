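# Parameter sets, species contexts and dosing constants.
#
# Internal unit conventions (used by every function in the package):
#   time          weeks
#   volume        mL (== cm^3)
#   concentration nM
#   NP amounts    particle counts
#   length        cm for transport formulas, nm for particle/pore diameters

MW_DOX <- 543.52   # doxorubicin, g/mol
MW_AB  <- 1.45e5   # atezolizumab (IgG1), g/mol

# Reference nanoparticle loading: 4 ug miRNA-22 per mouse corresponds to
# ~2.5e10 particles of 70 nm, i.e. 6.25e12 particles per mg at that size.
NP_PER_MG_REF  <- 2.5e10 / 0.004
PHI_NP_REF_NM  <- 70

#' Species context for the tumor-compartment model
#'
#' Bundles the whole-organism quantities that differ between the mouse in
#' which the model is calibrated and the 70-kg human to which it is
#' translated: body weight, plasma volume, peritoneal fluid volume (mouse
#' only), and the empirical tumor plasma-flow and vascular surface-area
#' laws. Mice use tumor-volume-dependent exponential laws; humans use
#' constants (Q = 1512 mL/mL/wk, S = 135 cm2/cm3).
#'
#' @param species "mouse" or "human".
#' @return An object of class `species_context`.
#' @export
species_context <- function(species = c("mouse", "human")) {
  species <- match.arg(species)
  if (species == "mouse") {
    ctx <- list(
      species = "mouse",
      body_weight = 0.02,     # kg
      V_P  = 1,               # plasma volume, mL
      V_pc = 0.1,             # peritoneal fluid volume, mL
      plasma_flow  = list(mode = "exponential", a = 2843, b = 0.65),
      surface_area = list(mode = "exponential",
                          a1 = 0.26, b1 = 4.5, a2 = 138, b2 = 0.04)
    )
  } else {
    ctx <- list(
      species = "human",
      body_weight = 70,       # kg
      V_P  = 3000,            # mL
      V_pc = NA_real_,        # IP route not used in humans
      plasma_flow  = list(mode = "constant", a = 1512),
      surface_area = list(mode = "constant", a1 = 135)
    )
  }
  structure(ctx, class = "species_context")
}

# Arm-specific mouse estimates: the tumor growth rate constant and carrying
# capacity were estimated separately for each in vivo study arm.
MOUSE_SIGMA  <- c(miRNA = 3.1, dox = 3.75, atezo = 3.13, control = 3.1)
MOUSE_BSTAR  <- c(miRNA = 2.21, dox = 2.5, atezo = 2.99, control = 2.21)

#' Biological (tumor/protein) parameters
#'
#' Tumor-intrinsic and signaling parameters of the model: eEF2K and PD-L1
#' production/degradation with their Michaelis-Menten couplings, tumor
#' growth/death rates, tumor composition fractions and transport geometry.
#'
#' @param species "mouse" or "human".
#' @param arm For mouse, which study arm the growth constants refer to
#'   (`sigma` and `B_star` are arm-specific estimates).
#' @return Named list of parameters (rates per week, volumes mL,
#'   lengths as documented per field).
#' @export
biological_params <- function(species = c("mouse", "human"),
                              arm = c("miRNA", "dox", "atezo", "control")) {
  species <- match.arg(species)
  arm <- match.arg(arm)
  p <- list(
    # eEF2K
    A_B_E = 11.9,    # stimulation of eEF2K production by tumor (-)
    A_M_E = 10.52,   # stimulation of eEF2K degradation by miRNA-22 (-)
    K_B_E = 16.03,   # MM constant, tumor -> eEF2K production (cm^3)
    delta_E = 60.48, # eEF2K decay rate (wk^-1)
    g_E0 = 36.3,     # basal eEF2K production (wk^-1)
    C_E0 = 0.58,     # eEF2K initial condition (-)
    # PD-L1
    A_E_P = 3.32,    # stimulation of PD-L1 production by eEF2K (-)
    A_Ab_P = 1.79,   # stimulation of PD-L1 degradation by anti-PD-L1 (-)
    K_E_P = 8.1,     # MM constant, eEF2K -> PD-L1 production (-)
    delta_P = 60.48, # PD-L1 decay rate (wk^-1)
    g_P0 = 10.44,    # basal PD-L1 production (wk^-1)
    C_P0 = 0.21,     # PD-L1 initial condition (-)
    # tumor
    A_E_B = 4.5,     # stimulation of tumor growth by eEF2K (-)
    K_E_B = 8.78,    # MM constant, eEF2K -> tumor growth (-)
    A_E_D = 0.1,     # eEF2K-induced chemoresistance factor (-)
    K_E_D = 10.0,    # MM constant for chemoresistance (-)
    sigma = MOUSE_SIGMA[[arm]],   # tumor growth rate constant (wk^-1)
    B_star = MOUSE_BSTAR[[arm]],  # carrying capacity (cm^3)
    delta_B_I = 3.0, # immune-induced tumor death rate (wk^-1)
    eps_P = 1.9,     # PD-L1 efficiency at blocking immune kill (-)
    delta_B_C = 2.46,# chemo-induced tumor death rate (wk^-1)
    # geometry / transport
    phi_pore = 1700, # tumor vessel wall pore diameter (nm)
    L = 0.01,        # intercapillary length (cm)
    eta_B_B = 7.42,  # tumor blood viscosity (cP)
    eta_B_I = 3.5,   # tumor interstitium viscosity (cP)
    B_0 = 0.001,     # inoculated tumor volume (cm^3)
    f_v = 0.17,      # vascular volume fraction (-)
    f_c = 0.4,       # cancer-cell volume fraction (-)
    f_cy = 0.4,      # cytoplasmic fraction of a cancer cell (-)
    dx = 5e-4        # capillary wall thickness (cm)
  )
  if (species == "human") {
    p$sigma <- 0.43      # allometric (-0.25) scaling of the mean mouse estimate
    p$B_star <- 100
    p$delta_B_I <- 0.39
    p$delta_B_C <- 0.3198
    p$B_0 <- 1e-9        # single-cell inception (config-exposed default)
  }
  p
}

#' Therapy-related parameters
#'
#' Agent-specific constants for the three modeled therapies: miRNA-22-loaded
#' nanoparticles, doxorubicin and atezolizumab, plus the interstitial
#' diffusivities of each agent.
#'
#' The nanoparticle extravasation efficiency `alpha_NP` is a dimensionless
#' scalar multiplying the hindered-pore NP permeability. Together with the
#' effective per-NP payload `M_0` it sets the scale of cytosolic miRNA-22
#' exposure per injected dose; because the payload-delivery product is not
#' identifiable from first principles it was calibrated once so that the
#' reference human course (0.026 mg/kg once weekly for 24 weeks) reproduces
#' the reported ~29 percent tumor growth inhibition, and is exposed here for
#' recalibration. `k_endo` is likewise a calibration-level default.
#'
#' @param species "mouse" or "human".
#' @return Named list of therapy parameters.
#' @export
therapy_params <- function(species = c("mouse", "human")) {
  species <- match.arg(species)
  p <- list(
    # nanoparticle
    phi_NP = 70,       # NP diameter (nm)
    delta_NP = 7.7,    # NP degradation rate (wk^-1)
    M_0 = 0.007,       # effective per-NP miRNA payload (nM mL)
    k_rel = 0.99,      # miRNA release rate from NPs (wk^-1)
    k_endo = 10,       # endocytosis rate (wk^-1), calibration default
    alpha_NP = 1.86e-9, # NP extravasation efficiency (-), calibrated
    # miRNA-22
    EC50_M = 2.34,     # EC50 of miRNA-22 on eEF2K degradation (nM)
    g_M0 = 0.033,      # basal miRNA-22 production (nM wk^-1)
    eps_B = 1,         # tumor inhibition of miRNA-22 production (cm^-3)
    delta_M = 4.851,   # miRNA-22 decay rate (wk^-1)
    # doxorubicin
    Cl_dox = 8.4e3,    # plasma clearance (mL wk^-1)
    V_D_dox = 734,     # volume of distribution (mL)
    delta_D = 2.0,     # cytosolic degradation rate (wk^-1)
    EC50_D = 25,       # EC50 on tumor death (nM)
    # atezolizumab
    phi_Ab = 10,       # antibody diameter (nm)
    delta_Ab = 1.21,   # degradation rate (wk^-1)
    Cl_Ab = 3.07,      # plasma clearance (mL wk^-1)
    V_D_Ab = 1.97,     # volume of distribution (mL)
    EC50_Ab = 0.0446,  # EC50 on PD-L1 degradation (nM)
    k_abs = 100,       # peritoneal absorption rate (wk^-1)
    # interstitial diffusivities (cm^2 wk^-1), printed baselines
    D_NP = 0.0112,
    D_Ab = 0.0784,
    D_dox = 0.4933
  )
  if (species == "human") {
    p$Cl_dox <- 4.25e6
    p$V_D_dox <- 3.65e5
    p$Cl_Ab <- 1400
    p$V_D_Ab <- 6900
  }
  p
}

#' Assemble a full parameter set
#'
#' @param species "mouse" or "human".
#' @param arm Mouse study arm (ignored for human).
#' @param bio,therapy Optional replacement parameter lists.
#' @param options List of model options:
#'   \describe{
#'     \item{plasma_volume_mode}{"vp" (default) divides the plasma-equation
#'       exchange and clearance terms for doxorubicin and the antibody by
#'       the plasma compartment volume, as the model equations are written;
#'       "vd" uses the agent's volume of distribution instead (longer
#'       effective elimination half-lives, markedly stronger chemotherapy
#'       exposure). Bolus concentrations use Dose/V_D in both modes.}
#'     \item{B_guard}{tumor volume (cm^3) below which divisions by tumor
#'       sub-volumes are suppressed.}
#'   }
#' @return Object of class `parameter_set`.
#' @export
parameter_set <- function(species = c("mouse", "human"),
                          arm = c("miRNA", "dox", "atezo", "control"),
                          bio = NULL, therapy = NULL, options = NULL) {
  species <- match.arg(species)
  arm <- match.arg(arm)
  ps <- structure(list(
    context = species_context(species),
    bio     = if (is.null(bio)) biological_params(species, arm) else bio,
    therapy = if (is.null(therapy)) therapy_params(species) else therapy,
    options = list(plasma_volume_mode = "vp", B_guard = 1e-12)
  ), class = "parameter_set")
  if (!is.null(options)) ps$options[names(options)] <- options
  validate_parameter_set(ps)
  ps
}

#' @rdname parameter_set
#' @export
mouse_parameters <- function(arm = c("miRNA", "dox", "atezo", "control"), ...) {
  parameter_set("mouse", match.arg(arm), ...)
}

#' @rdname parameter_set
#' @export
human_parameters <- function(...) parameter_set("human", ...)

validate_parameter_set <- function(ps) {
  b <- ps$bio; th <- ps$therapy
  pos_b <- c("A_B_E", "A_M_E", "K_B_E", "delta_E", "g_E0", "A_E_P", "K_E_P",
             "delta_P", "g_P0", "K_E_B", "K_E_D", "sigma", "B_star",
             "delta_B_I", "delta_B_C", "phi_pore", "L", "eta_B_B", "eta_B_I",
             "dx")
  for (nm in pos_b)
    if (!is.finite(b[[nm]]) || b[[nm]] <= 0)
      stop("biological parameter '", nm, "' must be strictly positive")
  for (nm in c("f_v", "f_c", "f_cy"))
    if (b[[nm]] <= 0 || b[[nm]] >= 1)
      stop("volume fraction '", nm, "' must lie in (0, 1)")
  if (b$f_v + b$f_c >= 1)
    stop("f_v + f_c must be < 1 so the interstitial fraction is positive")
  if (b$B_0 < 0) stop("B_0 must be non-negative")
  pos_t <- c("phi_NP", "delta_NP", "M_0", "k_rel", "k_endo", "alpha_NP",
             "EC50_M", "g_M0", "eps_B", "delta_M", "Cl_dox", "V_D_dox",
             "delta_D", "EC50_D", "phi_Ab", "delta_Ab", "Cl_Ab", "V_D_Ab",
             "EC50_Ab", "k_abs", "D_NP", "D_Ab", "D_dox")
  for (nm in pos_t)
    if (!is.finite(th[[nm]]) || th[[nm]] <= 0)
      stop("therapy parameter '", nm, "' must be strictly positive")
  if (th$phi_NP >= b$phi_pore)
    warning("phi_NP >= phi_pore: nanoparticles cannot extravasate")
  invisible(ps)
}

#' Interstitial volume fraction of the tumor
#'
#' The interstitial sub-volume is defined by closure of the volume budget:
#' V_B,I = (1 - f_v - f_c) * B.
#' @param ps A `parameter_set`.
#' @return Dimensionless fraction.
#' @export
interstitial_fraction <- function(ps) 1 - ps$bio$f_v - ps$bio$f_c

# Effective per-NP payload and particle number scale with NP volume:
# at fixed miRNA dose, halving the diameter packs 8x less per particle and
# needs 8x more particles.
np_count_for_dose <- function(dose_mg, phi_NP_nm) {
  dose_mg * NP_PER_MG_REF * (PHI_NP_REF_NM / phi_NP_nm)^3
}
np_payload <- function(M_0_ref, phi_NP_nm) {
  M_0_ref * (phi_NP_nm / PHI_NP_REF_NM)^3
}

# Concentration (nM) contributed by `nmol` dissolved in `vol_mL`.
nmol_to_nM <- function(nmol, vol_mL) nmol * 1000 / vol_mL
mg_to_nmol <- function(mg, mw) mg / mw * 1e6

#' Write / read a parameter set as a YAML file
#'
#' The file stores the species context, biological and therapy parameters
#' and options as a plain-text key/value document with a units block.
#' @param ps A `parameter_set`.
#' @param path File path.
#' @export
write_parameters <- function(ps, path) {
  doc <- list(
    species = ps$context$species,
    context = ps$context[setdiff(names(ps$context), "species")],
    biological = ps$bio,
    therapy = ps$therapy,
    options = ps$options,
    units = list(time = "weeks", volume = "mL", concentration = "nM",
                 diameter = "nm", length = "cm")
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  doc <- yaml::read_yaml(path)
  ctx <- species_context(doc$species)
  for (nm in names(doc$context)) ctx[[nm]] <- doc$context[[nm]]
  ps <- structure(list(context = ctx, bio = doc$biological,
                       therapy = doc$therapy, options = doc$options),
                  class = "parameter_set")
  validate_parameter_set(ps)
  ps
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> species:", x$context$species,
      " sigma:", x$bio$sigma, " B*:", x$bio$B_star, "cm^3\n")
  cat("  ", length(x$bio), "biological and", length(x$therapy),
      "therapy parameters; plasma_volume_mode =",
      x$options$plasma_volume_mode, "\n")
  invisible(x)
}
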
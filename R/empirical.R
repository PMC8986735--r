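# Empirical sub-models: tumor perfusion, vascular surface area, NP
# clearance, hindered-pore permeability, Stokes-Einstein diffusivity and
# the intraperitoneal antibody absorption forcing term.

#' Tumor plasma flow rate per unit tumor volume
#'
#' In mice the perfusion declines exponentially with tumor volume,
#' Q(B) = 2843 exp(-0.65 B) mL/mL/wk; in humans a constant 1512 mL/mL/wk
#' is used irrespective of tumor size.
#'
#' @param B Tumor volume (cm^3), scalar or vector, non-negative.
#' @param ctx A [species_context()].
#' @return Flow rate (mL mL^-1 wk^-1).
#' @export
tumor_plasma_flow <- function(B, ctx) {
  if (any(B < 0)) stop("tumor volume must be non-negative")
  pf <- ctx$plasma_flow
  if (pf$mode == "constant") rep(pf$a, length(B)) else pf$a * exp(-pf$b * B)
}

#' Tumor vascular surface area density
#'
#' Mouse: S(B) = 0.26 exp(-4.5 B) + 138 exp(-0.04 B) cm^2/cm^3 (strictly
#' decreasing in B). Human: constant 135 cm^2/cm^3.
#'
#' @inheritParams tumor_plasma_flow
#' @return Surface area density (cm^2/cm^3).
#' @export
vascular_surface_density <- function(B, ctx) {
  if (any(B < 0)) stop("tumor volume must be non-negative")
  sa <- ctx$surface_area
  if (sa$mode == "constant") rep(sa$a1, length(B))
  else sa$a1 * exp(-sa$b1 * B) + sa$a2 * exp(-sa$b2 * B)
}

#' Size-dependent systemic clearance rate of nanoparticles
#'
#' Mouse clearance follows the empirical half-life law
#' k_Cl = ln(2) / (0.11 exp(-1.33 phi) - 0.001 exp(-9.7 phi)) with the NP
#' diameter phi in cm; the human value is the mouse value scaled
#' allometrically with the standard -0.25 rate-constant exponent.
#'
#' @param phi_NP NP diameter in cm (70 nm = 7e-6 cm).
#' @param ctx A [species_context()].
#' @return Clearance rate (wk^-1).
#' @export
np_clearance_rate <- function(phi_NP, ctx) {
  if (any(phi_NP <= 0)) stop("NP diameter must be positive")
  denom <- 0.11 * exp(-1.33 * phi_NP) - 0.001 * exp(-9.7 * phi_NP)
  if (any(denom <= 0))
    stop("NP clearance half-life formula is outside its calibrated size range")
  k <- log(2) / denom
  if (ctx$species == "human")
    k <- allometric_scale(k, -0.25, bw_src = 0.02, bw_dst = ctx$body_weight)
  k
}

#' Hindered-pore vascular permeability
#'
#' Cylindrical-pore hindered-diffusion permeability
#' P = porosity * (D_free / wall) * (1 - lambda)^2 * H(lambda), with
#' lambda the agent-to-pore diameter ratio, (1 - lambda)^2 the steric
#' partition coefficient and H the Renkin centerline hindrance polynomial
#' H = 1 - 2.104 lambda + 2.09 lambda^3 - 0.95 lambda^5, clamped to [0, 1].
#' P is zero for lambda >= 1 (full steric exclusion).
#'
#' @param phi_agent Agent diameter (nm), >= 0.
#' @param phi_pore Pore diameter (nm), > 0.
#' @param D_free Free diffusivity of the agent (cm^2 wk^-1).
#' @param wall_thickness Vessel wall thickness (cm).
#' @param porosity Dimensionless scaling of the pore area fraction.
#' @return Permeability (cm wk^-1).
#' @export
hindered_permeability <- function(phi_agent, phi_pore, D_free,
                                  wall_thickness, porosity = 1) {
  if (any(phi_agent < 0)) stop("agent diameter must be non-negative")
  if (phi_pore <= 0) stop("pore diameter must be positive")
  lam <- phi_agent / phi_pore
  H <- 1 - 2.104 * lam + 2.09 * lam^3 - 0.95 * lam^5
  H <- pmin(pmax(H, 0), 1)
  P <- porosity * (D_free / wall_thickness) * (1 - lam)^2 * H
  P[lam >= 1] <- 0
  P
}

#' Stokes-Einstein diffusivity
#'
#' D = k_B T / (3 pi eta phi), converted to cm^2 per week. Used when an
#' agent size is perturbed away from its baseline; baseline runs use the
#' printed diffusivity constants.
#'
#' @param phi Hydrodynamic diameter (nm).
#' @param eta Dynamic viscosity (cP).
#' @param T_K Absolute temperature (K), default body temperature.
#' @return Diffusivity (cm^2 wk^-1).
#' @export
stokes_einstein_diffusivity <- function(phi, eta, T_K = 310) {
  if (any(phi <= 0) || any(eta <= 0) || any(T_K <= 0))
    stop("diameter, viscosity and temperature must be positive")
  kB <- 1.380649e-23                       # J/K
  D_m2_s <- kB * T_K / (3 * pi * eta * 1e-3 * phi * 1e-9)
  D_m2_s * 1e4 * 604800                    # m^2/s -> cm^2/wk
}

#' Intraperitoneal antibody absorption input
#'
#' First-order absorption of IP-injected antibody from the peritoneum into
#' plasma: each past dose j contributes
#' k_abs * Dose_Ab / V_pc * exp(-k_abs (t - j)) (concentration per week),
#' so the time-integral per dose equals Dose_Ab / V_pc. The term applies
#' only to the mouse IP route; IV regimens contribute zero (the bolus is
#' handled as an initial-condition jump instead).
#'
#' @param t Time (weeks), scalar.
#' @param regimen A regimen data frame (see [dose_event()]).
#' @param params Therapy parameter list (needs `k_abs`).
#' @param ctx A [species_context()].
#' @return Input rate (nM wk^-1).
#' @export
antibody_absorption_input <- function(t, regimen, params, ctx) {
  ab <- regimen[regimen$agent == "antibody" & regimen$route == "IP", ,
                drop = FALSE]
  if (nrow(ab) == 0) return(0)
  if (ctx$species != "mouse" || !is.finite(ctx$V_pc))
    stop("IP antibody dosing is only defined for the mouse context")
  dose_nmol <- mg_to_nmol(ab$amount * ctx$body_weight, MW_AB)
  conc <- nmol_to_nM(dose_nmol, ctx$V_pc)       # Dose_Ab / V_pc, in nM
  on <- t >= ab$time
  sum(params$k_abs * conc[on] * exp(-params$k_abs * (t - ab$time[on])))
}
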
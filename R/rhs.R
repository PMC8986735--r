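# Right-hand side of the 17-state ODE system.
#
# Two interchangeable implementations are provided: a readable R reference
# (`model_rhs`) and a compiled C version (src/model_rhs.c) used by the
# integrator for speed. Both consume the same packed parameter vector so
# they can be cross-checked state-for-state.

#' @name model_states
#' @title Model state vector
#' @description The 17 states, in order: nanoparticle amounts (counts) in
#' plasma (N_P), tumor vasculature (N_V), interstitium (N_I), cell membrane
#' (N_M) and cytosol (N_C); cytosolic miRNA-22 concentration C_M (nM);
#' anti-PD-L1 antibody concentrations in plasma, vasculature, interstitium
#' and membrane (nM); doxorubicin concentrations in plasma, vasculature,
#' interstitium and cytosol (nM); eEF2K level C_E and PD-L1 level C_P
#' (dimensionless); tumor volume B (cm^3).
#' @export
STATE_NAMES <- c("N_P", "N_V", "N_I", "N_M", "N_C", "C_M",
                 "C_Ab_P", "C_Ab_V", "C_Ab_I", "C_Ab_M",
                 "C_D_P", "C_D_V", "C_D_I", "C_D_C",
                 "C_E", "C_P", "B")

MAXDOSE <- 40L
N_PARMS <- 179L

# Pack everything the right-hand side needs into a flat double vector
# shared by the R and C implementations. Derived transport quantities
# (clearance, permeabilities, diffusivities) are evaluated here, once.
pack_parms <- function(ps, regimen) {
  ctx <- ps$context; b <- ps$bio; th <- ps$therapy
  # size-perturbed runs switch from printed diffusivities to Stokes-Einstein
  D_NP <- if (isTRUE(all.equal(th$phi_NP, PHI_NP_REF_NM))) th$D_NP else
    stokes_einstein_diffusivity(th$phi_NP, b$eta_B_I)
  D_Ab <- if (isTRUE(all.equal(th$phi_Ab, 10))) th$D_Ab else
    stokes_einstein_diffusivity(th$phi_Ab, b$eta_B_I)
  P_NP <- hindered_permeability(th$phi_NP, b$phi_pore, D_NP, b$dx,
                                porosity = th$alpha_NP)
  P_Ab <- hindered_permeability(th$phi_Ab, b$phi_pore, D_Ab, b$dx)
  kCl <- np_clearance_rate(th$phi_NP * 1e-7, ctx)
  vd_mode <- identical(ps$options$plasma_volume_mode, "vd")

  np <- regimen[regimen$agent == "miRNA_NP", , drop = FALSE]
  ip <- regimen[regimen$agent == "antibody" & regimen$route == "IP", ,
                drop = FALSE]
  if (nrow(np) > MAXDOSE || nrow(ip) > MAXDOSE)
    stop("at most ", MAXDOSE, " doses per agent are supported")
  if (nrow(ip) > 0 && (ctx$species != "mouse" || !is.finite(ctx$V_pc)))
    stop("IP antibody dosing is only defined for the mouse context")
  ip_conc <- if (nrow(ip)) nmol_to_nM(
    mg_to_nmol(ip$amount * ctx$body_weight, MW_AB), ctx$V_pc) else numeric(0)

  p <- numeric(N_PARMS)
  pf <- ctx$plasma_flow; sa <- ctx$surface_area
  p[1] <- ctx$V_P
  p[2] <- as.numeric(pf$mode == "constant")
  p[3] <- pf$a
  p[4] <- if (pf$mode == "constant") 0 else pf$b
  p[5] <- as.numeric(sa$mode == "constant")
  p[6] <- sa$a1
  p[7] <- if (sa$mode == "constant") 0 else sa$b1
  p[8] <- if (sa$mode == "constant") 0 else sa$a2
  p[9] <- if (sa$mode == "constant") 0 else sa$b2
  p[10] <- b$f_v
  p[11] <- b$f_c * b$f_cy
  p[12] <- 1 - b$f_v - b$f_c
  p[13] <- kCl
  p[14] <- P_NP
  p[15] <- D_NP / b$L^2
  p[16] <- th$k_endo
  p[17] <- th$delta_NP
  p[18] <- th$g_M0
  p[19] <- th$eps_B
  p[20] <- th$k_rel
  p[21] <- np_payload(th$M_0, th$phi_NP)
  p[22] <- th$delta_M
  p[23] <- th$Cl_Ab
  p[24] <- if (vd_mode) th$V_D_Ab else ctx$V_P
  p[25] <- P_Ab
  p[26] <- D_Ab / b$L^2
  p[27] <- th$delta_Ab
  p[28] <- th$Cl_dox
  p[29] <- if (vd_mode) th$V_D_dox else ctx$V_P
  p[30] <- th$D_dox / b$dx
  p[31] <- th$D_dox / b$L^2
  p[32] <- D_Ab / b$L^2   # cytosolic influx coefficient, as printed
  p[33] <- th$delta_D
  p[34] <- b$g_E0
  p[35] <- b$A_B_E
  p[36] <- b$K_B_E
  p[37] <- b$delta_E
  p[38] <- b$A_M_E
  p[39] <- th$EC50_M
  p[40] <- b$g_P0
  p[41] <- b$A_E_P
  p[42] <- b$K_E_P
  p[43] <- b$delta_P
  p[44] <- b$A_Ab_P
  p[45] <- th$EC50_Ab
  p[46] <- b$sigma
  p[47] <- b$A_E_B
  p[48] <- b$K_E_B
  p[49] <- b$B_star
  p[50] <- b$delta_B_I
  p[51] <- b$eps_P
  p[52] <- b$delta_B_C
  p[53] <- th$EC50_D
  p[54] <- b$A_E_D
  p[55] <- b$K_E_D
  p[56] <- ps$options$B_guard
  p[57] <- nrow(np)
  if (nrow(np)) p[57 + seq_len(nrow(np))] <- np$time
  p[98] <- nrow(ip)
  p[99] <- th$k_abs
  if (nrow(ip)) {
    p[99 + seq_len(nrow(ip))] <- ip$time
    p[139 + seq_len(nrow(ip))] <- ip_conc
  }
  p
}

#' Evaluate the model right-hand side (R reference implementation)
#'
#' Returns d(state)/dt for the 17-state system: NP transport through
#' plasma, tumor vasculature, interstitium, cell membrane and cytosol;
#' intracellular miRNA-22 release and decay; antibody and doxorubicin
#' compartmental PK; eEF2K and PD-L1 protein turnover; and logistic tumor
#' growth with eEF2K stimulation, PD-L1-shielded immune kill and
#' chemotherapy kill with eEF2K-induced resistance.
#'
#' @param t Time (weeks).
#' @param y Named or ordered state vector (see [STATE_NAMES]).
#' @param ps A [parameter_set()].
#' @param regimen A `regimen` (needed for the miRNA release clock and the
#'   mouse IP antibody absorption forcing; IV boluses are applied as
#'   integrator events, not here).
#' @return List with the derivative vector (deSolve convention).
#' @export
model_rhs <- function(t, y, ps, regimen = no_treatment()) {
  p <- pack_parms(ps, regimen)
  rhs_r(t, as.numeric(y), p)
}

# Core R evaluation on a packed parameter vector.
rhs_r <- function(t, y, p) {
  if (any(!is.finite(y))) {
    bad <- STATE_NAMES[!is.finite(y)][1]
    stop("non-finite state encountered: ", bad, " at t = ", t)
  }
  NP <- y[1]; NV <- y[2]; NI <- y[3]; NM <- y[4]; NC <- y[5]; CM <- y[6]
  CAbP <- y[7]; CAbV <- y[8]; CAbI <- y[9]; CAbM <- y[10]
  CDP <- y[11]; CDV <- y[12]; CDI <- y[13]; CDC <- y[14]
  CE <- y[15]; CP <- y[16]; B <- y[17]

  Q <- if (p[2] > 0.5) p[3] else p[3] * exp(-p[4] * B)
  S <- if (p[5] > 0.5) p[6] else p[6] * exp(-p[7] * B) + p[8] * exp(-p[9] * B)
  ok <- B >= p[56]                    # guard against division by ~zero tumor
  VBV <- p[10] * B; VBC <- p[11] * B; VBI <- p[12] * B
  QB <- Q * B

  ex_np  <- if (ok) (NV / VBV - NP / p[1]) * QB else 0
  dNP <- ex_np - p[13] * NP
  dNV <- -ex_np - p[14] * S * NV
  dNI <- p[14] * S * NV - p[15] * NI
  dNM <- p[15] * NI - p[16] * NM
  dNC <- p[16] * NM - p[17] * NC

  n_np <- as.integer(p[57])
  rel <- 0
  if (ok && n_np > 0) {
    tim <- p[57 + seq_len(n_np)]
    past <- tim[tim <= t]
    if (length(past))
      rel <- p[20] * NC * p[21] * exp(-p[20] * (t - max(past))) / VBC
  }
  dCM <- p[18] / (1 + p[19] * B) + rel - p[22] * CM

  n_ip <- as.integer(p[98])
  ip_in <- 0
  if (n_ip > 0) {
    tj <- p[99 + seq_len(n_ip)]; cj <- p[139 + seq_len(n_ip)]
    on <- tj <= t
    if (any(on)) ip_in <- sum(p[99] * cj[on] * exp(-p[99] * (t - tj[on])))
  }
  ex_ab <- if (ok) (CAbV - CAbP) * QB else 0
  dCAbP <- ip_in + (ex_ab - p[23] * CAbP) / p[24]
  dCAbV <- (if (ok) (CAbP - CAbV) * QB / VBV else 0) - p[25] * S * CAbV
  dCAbI <- p[25] * S * CAbV - p[26] * CAbI
  dCAbM <- p[26] * CAbI - p[27] * CAbM

  ex_d <- if (ok) (CDV - CDP) * QB else 0
  dCDP <- (ex_d - p[28] * CDP) / p[29]
  J <- -p[30] * (CDV - CDI)
  dCDV <- if (ok) ((CDP - CDV) * QB + J * S) / VBV else 0
  dCDI <- (if (ok) -J * S / VBI else 0) - p[31] * CDI
  dCDC <- p[32] * CDI - p[33] * CDC

  dCE <- p[34] * (1 + p[35] * B / (p[36] + B)) -
    p[37] * (1 + p[38] * CM / (p[39] + CM)) * CE
  dCP <- p[40] * (1 + p[41] * CE / (p[42] + CE)) -
    p[43] * (1 + p[44] * CAbM / (p[45] + CAbM)) * CP
  dB <- p[46] * (1 + p[47] * CE / (p[48] + CE)) * (1 - B / p[49]) * B -
    p[50] / (1 + p[51] * CP) * B -
    p[52] * (CDC / (p[53] * (1 + p[54] * CE / (p[55] + CE)) + CDC)) * B

  list(c(dNP, dNV, dNI, dNM, dNC, dCM, dCAbP, dCAbV, dCAbI, dCAbM,
         dCDP, dCDV, dCDI, dCDC, dCE, dCP, dB))
}

# Initial conditions as stated per equation: drug states zero, miRNA-22 at
# its production/decay balance, proteins at their fitted initial levels,
# tumor at the inoculum (mouse) or single-cell (human) volume.
initial_state <- function(ps) {
  y <- stats::setNames(numeric(17), STATE_NAMES)
  y["C_M"] <- ps$therapy$g_M0 / ps$therapy$delta_M
  y["C_E"] <- ps$bio$C_E0
  y["C_P"] <- ps$bio$C_P0
  y["B"] <- ps$bio$B_0
  y
}
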
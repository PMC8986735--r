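# Empirical sub-models and the ODE right-hand side.

test_that("tumor plasma flow follows the empirical law and species switch", {
  mouse <- species_context("mouse")
  human <- species_context("human")
  expect_equal(tumor_plasma_flow(0, mouse), 2843)
  expect_equal(tumor_plasma_flow(1, mouse), 1484.176, tolerance = 1e-6)
  expect_equal(tumor_plasma_flow(5, human), 1512)
  expect_equal(tumor_plasma_flow(0.3, human), 1512)
  expect_error(tumor_plasma_flow(-1, mouse), "non-negative")
})

test_that("vascular surface density: two-exponential mouse law, human constant", {
  mouse <- species_context("mouse")
  human <- species_context("human")
  expect_equal(vascular_surface_density(0, mouse), 138.26)
  expect_equal(vascular_surface_density(1e3, mouse), 0, tolerance = 1e-12)
  expect_equal(vascular_surface_density(7, human), 135)
  B <- seq(0, 5, length.out = 50)
  expect_true(all(diff(vascular_surface_density(B, mouse)) < 0))
  expect_error(vascular_surface_density(-0.1, mouse), "non-negative")
})

test_that("NP clearance rate: size law in mouse, allometric in human", {
  mouse <- species_context("mouse")
  human <- species_context("human")
  expect_equal(np_clearance_rate(7e-6, mouse), 6.359204, tolerance = 1e-6)
  # the small-size limit collapses to ln2 / (0.11 - 0.001)
  expect_equal(np_clearance_rate(1e-12, mouse), log(2) / 0.109,
               tolerance = 1e-9)
  expect_equal(np_clearance_rate(7e-6, human), 0.826772, tolerance = 1e-5)
  # larger particles clear faster under the half-life law
  phis <- c(1e-6, 7e-6, 5e-5, 3.5e-5)
  expect_true(all(diff(np_clearance_rate(sort(phis), mouse)) > 0))
  expect_error(np_clearance_rate(0, mouse), "positive")
})

test_that("hindered permeability: free-diffusion and exclusion limits, monotone", {
  D <- 0.0112; dx <- 5e-4
  expect_equal(hindered_permeability(1700, 1700, D, dx), 0)
  expect_equal(hindered_permeability(2000, 1700, D, dx), 0)
  expect_equal(hindered_permeability(0, 1700, D, dx), D / dx)
  lam <- seq(0.005, 0.995, length.out = 100)
  P <- hindered_permeability(lam * 1700, 1700, D, dx)
  expect_true(all(diff(P) < 0))
  expect_true(all(P >= 0))
  # porosity scales linearly
  expect_equal(hindered_permeability(70, 1700, D, dx, porosity = 0.5),
               0.5 * hindered_permeability(70, 1700, D, dx))
})

test_that("Stokes-Einstein diffusivity matches the printed transport constants", {
  expect_equal(stokes_einstein_diffusivity(70, 3.5), 0.0112, tolerance = 0.01)
  expect_equal(stokes_einstein_diffusivity(10, 3.5), 0.0784, tolerance = 0.01)
  # D scales as 1/diameter
  expect_equal(stokes_einstein_diffusivity(140, 3.5),
               stokes_einstein_diffusivity(70, 3.5) / 2)
  expect_error(stokes_einstein_diffusivity(-1, 3.5), "positive")
})

test_that("IP antibody absorption: indicator, peak and mass conservation", {
  ps <- ref_mouse("atezo")
  reg <- build_schedule("mouse_atezo")
  expect_equal(antibody_absorption_input(0.5, reg, ps$therapy, ps$context), 0)
  # instant after the first dose the rate is k_abs * Dose / V_pc
  dose_nM <- mir22sim:::nmol_to_nM(
    mir22sim:::mg_to_nmol(5 * 0.02, mir22sim:::MW_AB), 0.1)
  expect_equal(antibody_absorption_input(1 + 1e-12, reg[1, ], ps$therapy,
                                         ps$context),
               ps$therapy$k_abs * dose_nM, tolerance = 1e-6)
  # integral of the input over all time equals Dose / V_pc per dose
  integ <- stats::integrate(function(t) vapply(t, function(ti)
    antibody_absorption_input(ti, reg[1, ], ps$therapy, ps$context),
    numeric(1)), 0, 10, rel.tol = 1e-10)
  expect_equal(integ$value, dose_nM, tolerance = 1e-6)
  # IV regimens contribute nothing
  iv <- dose_event("antibody", 1, 5, route = "IV_bolus")
  expect_equal(antibody_absorption_input(2, iv, ps$therapy, ps$context), 0)
})

test_that("drug-free steady state of miRNA-22 at B = 0 (closed form)", {
  ps <- ref_human()
  y <- mir22sim:::initial_state(ps)
  y["B"] <- 0
  y["C_M"] <- ps$therapy$g_M0 / ps$therapy$delta_M
  d <- model_rhs(0, y, ps)[[1]]
  expect_equal(d[6], 0, tolerance = 1e-12)  # dC_M/dt
  expect_equal(d[17], 0)                    # dB/dt at B = 0
})

test_that("NP plasma-vascular exchange terms are antisymmetric in amount", {
  ps <- ref_human()
  reg <- build_schedule("human_QW")
  p <- mir22sim:::pack_parms(ps, reg)
  set.seed(42)
  for (i in 1:20) {
    y <- abs(rnorm(17)) * c(rep(1e10, 5), rep(10, 11), 5)
    d <- mir22sim:::rhs_r(85, y, p)[[1]]
    # with clearance and extravasation removed, dN_P = -dN_V exactly
    kCl <- p[13]; PnpS <- p[14]
    S <- 135
    expect_equal(d[1] + kCl * y[1], -(d[2] + PnpS * S * y[2]),
                 tolerance = 1e-9 * max(abs(d[1:2]), 1))
  }
})

test_that("rhs rejects non-finite states naming the offender", {
  ps <- ref_human()
  y <- mir22sim:::initial_state(ps)
  y["C_E"] <- NaN
  expect_error(model_rhs(0, y, ps), "C_E")
})

test_that("compiled and R right-hand sides integrate to the same trajectory", {
  ps <- ref_human()
  reg <- build_schedule("human_QW", duration = 4)
  trC <- simulate_course(ps, reg, t_end = 86, compiled = TRUE)
  trR <- simulate_course(ps, reg, t_end = 86, compiled = FALSE)
  expect_equal(trC$states, trR$states, tolerance = 1e-6)
})

test_that("mass bookkeeping: NP amount conserved with sinks disabled", {
  ps <- ref_human()
  reg <- dose_event("miRNA_NP", 1, 0.026)
  # switch off clearance (13) and extravasation (14) at the packed level
  p <- patched_parms(ps, reg, list(`13` = 0, `14` = 0))
  y0 <- mir22sim:::initial_state(ps)
  ev <- mir22sim:::build_events(ps, reg)
  out <- deSolve::ode(y = y0, times = seq(0, 4, 0.25),
                      func = function(t, y, parms) mir22sim:::rhs_r(t, y, parms),
                      parms = p, events = list(data = ev),
                      rtol = 1e-10, atol = 1e-3)
  total <- out[, "N_P"] + out[, "N_V"]
  n0 <- ev$value[1]
  after <- out[, "time"] > 1
  expect_equal(max(abs(total[after] - n0)) / n0, 0, tolerance = 1e-8)
})

test_that("drug-free protein equilibria match their closed forms", {
  ps <- ref_human()
  ps$bio$B_0 <- 1e-300          # pinned below the B guard: tumor stays off
  ps$options$B_guard <- 1e-100
  tr <- simulate_course(ps, no_treatment(), t_end = 3, dt_out = 0.1)
  yT <- tr$states[nrow(tr$states), ]
  # sequential closed forms: basal miRNA-22 tempers eEF2K degradation
  CM_star <- ps$therapy$g_M0 / ps$therapy$delta_M
  CE_star <- ps$bio$g_E0 / (ps$bio$delta_E *
    (1 + ps$bio$A_M_E * CM_star / (ps$therapy$EC50_M + CM_star)))
  CP_star <- ps$bio$g_P0 *
    (1 + ps$bio$A_E_P * CE_star / (ps$bio$K_E_P + CE_star)) / ps$bio$delta_P
  expect_equal(yT[["C_M"]], CM_star, tolerance = 1e-8)
  expect_equal(yT[["C_E"]], CE_star, tolerance = 1e-6)
  expect_equal(yT[["C_P"]], CP_star, tolerance = 1e-6)
  # without the basal miRNA feedback the eEF2K level would settle at
  # g_E0 / delta_E; the coupled equilibrium sits ~3% below it
  expect_equal(CE_star / (ps$bio$g_E0 / ps$bio$delta_E), 1, tolerance = 0.05)
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(parameter_set("mouse", bio = within(
    biological_params("mouse"), sigma <- -1)), "sigma")
  expect_error(parameter_set("human", bio = within(
    biological_params("human"), f_v <- 1.2)), "f_v")
  expect_error(parameter_set("human", therapy = within(
    therapy_params("human"), delta_M <- 0)), "delta_M")
})

test_that("parameter files round-trip through YAML", {
  ps <- ref_mouse("dox")
  f <- tempfile(fileext = ".yaml")
  write_parameters(ps, f)
  ps2 <- read_parameters(f)
  expect_equal(ps2$bio, ps$bio)
  expect_equal(ps2$therapy, ps$therapy)
  expect_equal(ps2$context$plasma_flow, ps$context$plasma_flow)
  unlink(f)
})

test_that("shipped baseline parameter files equal the in-code defaults", {
  for (case in list(c("mouse_params.yaml", "mouse"),
                    c("human_params.yaml", "human"))) {
    f <- system.file("extdata", case[1], package = "mir22sim")
    ps <- read_parameters(f)
    ref <- if (case[2] == "mouse") ref_mouse("miRNA") else ref_human()
    expect_equal(ps$bio, ref$bio, info = case[1])
    expect_equal(ps$therapy, ref$therapy, info = case[1])
  }
})
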
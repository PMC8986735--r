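# Virtual populations, dose-response and sensitivity analyses.

test_that("LHS places exactly one sample per equal-width stratum", {
  x <- lhs_sample(data.frame(name = "p", lower = 0, upper = 1), n = 4,
                  seed = 1)
  strata <- findInterval(x[, 1], c(0, 0.25, 0.5, 0.75, 1),
                         rightmost.closed = TRUE)
  expect_setequal(strata, 1:4)
  # larger case, shifted range
  y <- lhs_sample(data.frame(name = "q", lower = 2, upper = 12), n = 50,
                  seed = 2)
  strata <- findInterval(y[, 1], seq(2, 12, length.out = 51),
                         rightmost.closed = TRUE)
  expect_setequal(strata, 1:50)
})

test_that("LHS is reproducible by seed and leaves the RNG state alone", {
  set.seed(1234)
  rs <- .Random.seed
  a <- lhs_sample(c("a", "b"), 10, seed = 7, lower = 0, upper = 1)
  expect_identical(.Random.seed, rs)
  b <- lhs_sample(c("a", "b"), 10, seed = 7, lower = 0, upper = 1)
  expect_identical(a, b)
  expect_error(lhs_sample(data.frame(name = character(0), lower = numeric(0),
                                     upper = numeric(0)), 5, 1), "empty")
})

test_that("LHS column marginals are uniform (Kolmogorov-Smirnov)", {
  x <- lhs_sample(paste0("p", 1:5), n = 2000, seed = 3, lower = 0, upper = 1)
  p <- apply(x, 2, function(col)
    suppressWarnings(stats::ks.test(col, "punif")$p.value))
  expect_true(all(p > 0.01))
})

test_that("virtual populations are baseline overrides within the sampled band", {
  ps <- ref_human()
  pop0 <- generate_population(ps, n = 5, frac = 0, seed = 1)
  expect_true(all(pop0$factors == 1))
  expect_equal(patient_params(pop0, 3)$bio, ps$bio)

  pop <- generate_population(ps, n = 100, frac = 0.5, seed = 1)
  expect_equal(dim(pop$factors), c(100, 16))
  expect_true(all(pop$factors >= 0.5 & pop$factors <= 1.5))
  expect_equal(nrow(unique(pop$factors)), 100)
  p7 <- patient_params(pop, 7)
  expect_equal(p7$bio$sigma,
               unname(ps$bio$sigma * pop$factors[7, "sigma"]))
  expect_equal(p7$context$plasma_flow$a,
               unname(ps$context$plasma_flow$a * pop$factors[7, "Q"]))
  expect_error(generate_population(ps, param_names = "bogus"), "unknown")
})

test_that("factor application handles the function-valued and derived parameters", {
  ps <- ref_mouse()
  p2 <- apply_param_factors(ps, c(S = 2, phi_NP = 0.5, delta_M = 3))
  expect_equal(p2$context$surface_area$a1, 0.52)
  expect_equal(p2$context$surface_area$a2, 276)
  expect_equal(p2$therapy$phi_NP, 35)
  expect_equal(p2$therapy$delta_M, 3 * 4.851)
  # dummy is an accepted no-op
  expect_equal(apply_param_factors(ps, c(dummy = 4))$bio, ps$bio)
  expect_error(apply_param_factors(ps, c(nope = 2)), "unknown")
  # a perturbed NP size propagates to the packed transport parameters
  pk1 <- mir22sim:::pack_parms(ps, no_treatment())
  pk2 <- mir22sim:::pack_parms(p2, no_treatment())
  expect_gt(pk2[15], pk1[15])   # smaller NP -> faster diffusion (D_NP/L^2)
})

test_that("dose-response: zero dose exactly zero, monotone, QW above Q2W", {
  ps <- ref_human()
  doses <- c(0, 0.01, 0.05, 0.2)
  qw <- dose_response_curve(ps, doses, "QW")
  q2w <- dose_response_curve(ps, doses, "Q2W")
  expect_identical(qw$tgi[1], 0)
  expect_true(all(diff(qw$tgi) > 0))
  expect_true(all(diff(q2w$tgi) > 0))
  expect_true(all(qw$tgi[-1] >= q2w$tgi[-1]))
})

test_that("slow-growing tumors respond at least 1.5x more than fast-growing", {
  ps <- ref_human()
  slow <- dose_response_curve(ps, 0.026, "QW", growth_ratio = 0.99)$tgi
  fast <- dose_response_curve(ps, 0.026, "QW", growth_ratio = 0.75)$tgi
  expect_gte(slow / fast, 1.5)
})

test_that("virtual trials classify patients and fractions sum to one", {
  ps <- ref_human()
  pop <- generate_population(ps, n = 8, frac = 0.5, seed = 21)
  tr <- run_virtual_trial(pop, build_schedule("human_QW"))
  expect_equal(sum(tr$fractions), 1, tolerance = 1e-12)
  expect_equal(length(tr$tgi), 8)
  expect_true(all(is.finite(tr$tgi)))
  # treated tumors never exceed controls: TGI >= 0 up to solver noise
  expect_true(all(tr$tgi >= -1e-6))
  # zero-dose trial: everyone progressive (TGI <= 0 by the printed bins)
  tr0 <- run_virtual_trial(pop, no_treatment())
  expect_true(all(tr0$classes == "progressive"))
  expect_equal(unname(tr0$fractions["progressive"]), 1)
})

test_that("population dose sweep reuses shared controls and matches per-patient runs", {
  ps <- ref_human()
  pop <- generate_population(ps, n = 4, frac = 0.5, seed = 5)
  sw <- population_dose_sweep(pop, doses = c(0, 0.026))
  expect_identical(unname(sw$tgi[, 1]), rep(0, 4))
  direct <- vapply(1:4, function(i)
    quick_tgi(patient_params(pop, i), build_schedule("human_QW")),
    numeric(1))
  expect_equal(unname(sw$tgi[, 2]), direct, tolerance = 1e-8)
  expect_equal(rowSums(sw$fractions), rep(1, 2), ignore_attr = TRUE)
})

test_that("local sensitivity includes the baseline point and the documented trends", {
  ps <- ref_human()
  d <- local_sensitivity(ps, "delta_M", levels = 6)
  expect_true(1 %in% d$factor)
  expect_true(all(diff(d$tgi) < 0))          # faster miRNA decay, less TGI
  p <- local_sensitivity(ps, "phi_NP", levels = 6)
  expect_true(all(diff(p$tgi) < 0))          # larger NPs, less TGI
})

test_that("global sensitivity: null parameter scores at the noise floor", {
  ps <- ref_human()
  g <- global_sensitivity(ps, params = c("delta_M", "g_P0", "eps_P", "dummy"),
                          n = 120, replicates = 2, seed = 3)
  rk <- g$ranking
  expect_setequal(rk$parameter, c("delta_M", "g_P0", "eps_P", "dummy"))
  expect_equal(rk$parameter[nrow(rk)], "dummy")
  # the null parameter is indistinguishable from zero and far below the
  # active ones
  si_dummy <- g$si[, "dummy"]
  expect_lt(abs(mean(si_dummy)), 0.05)
  expect_lt(mean(abs(si_dummy)) * 5, max(rk$mean_abs_si))
  expect_error(global_sensitivity(ps, params = "delta_M"), "two parameters")
})

test_that("global sensitivity is stable across seeds", {
  ps <- ref_human()
  g1 <- global_sensitivity(ps, params = c("delta_M", "eps_P"), n = 100,
                           replicates = 2, seed = 11)
  g2 <- global_sensitivity(ps, params = c("delta_M", "eps_P"), n = 100,
                           replicates = 2, seed = 99)
  for (p in c("delta_M", "eps_P")) {
    m1 <- mean(g1$si[, p]); m2 <- mean(g2$si[, p])
    se <- sqrt(stats::var(g1$si[, p]) / 2 + stats::var(g2$si[, p]) / 2)
    expect_lt(abs(m1 - m2), max(2 * se, 0.05))
  }
})
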
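# Chou-Talalay median-effect fits and combination indices.

# Exact fractional effect from the median-effect law.
me_fa <- function(D, Dm, m) (D / Dm)^m / (1 + (D / Dm)^m)

test_that("median-effect fit inverts exactly generated data", {
  D <- c(0.1, 0.3, 1, 3, 10)
  fit <- median_effect_fit(D, me_fa(D, Dm = 1, m = 1))
  expect_equal(fit$Dm, 1, tolerance = 1e-10)
  expect_equal(fit$m, 1, tolerance = 1e-10)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  # a point at D = Dm has fa = 0.5 by construction
  expect_equal(me_fa(fit$Dm, fit$Dm, fit$m), 0.5)
  # steeper two-parameter case
  fit2 <- median_effect_fit(D, me_fa(D, Dm = 0.5, m = 2.2))
  expect_equal(fit2$Dm, 0.5, tolerance = 1e-10)
  expect_equal(fit2$m, 2.2, tolerance = 1e-10)
})

test_that("median-effect fit recovers Dm within 10% under 2% noise", {
  set.seed(18)
  # doses span 2^+/-2.5 around Dm so every measured effect stays inside
  # the quantifiable (0, 1) window under multiplicative noise
  D <- 0.03 * 2^seq(-2.5, 2.5, length.out = 8)
  errs <- replicate(40, {
    fa <- pmin(pmax(me_fa(D, 0.03, 2) * rlnorm(8, 0, 0.02), 1e-4), 1 - 1e-4)
    abs(median_effect_fit(D, fa)$Dm / 0.03 - 1)
  })
  expect_lt(median(errs), 0.1)
})

test_that("median-effect fit rejects degenerate input and clips extreme fa", {
  expect_error(median_effect_fit(c(1, 2), c(0, 0.9999999)), "at least 2")
  expect_error(median_effect_fit(c(1, 1, 1), c(0.2, 0.4, 0.6)), "identical")
  # points outside the clip window are dropped, the rest fit normally
  D <- c(0.01, 0.1, 1, 10)
  fa <- c(1e-9, me_fa(c(0.1, 1), 1, 1), 1 - 1e-9)
  fit <- median_effect_fit(D, fa)
  expect_equal(fit$n_points, 2)
  expect_equal(fit$Dm, 1, tolerance = 1e-8)
})

test_that("combination index: self-consistency and the Loewe-additive oracle", {
  fits <- list(
    a = median_effect_fit(c(0.2, 0.5, 1, 2, 5), me_fa(c(0.2, 0.5, 1, 2, 5),
                                                      Dm = 1, m = 1)),
    b = median_effect_fit(c(0.5, 1, 2, 4, 8), me_fa(c(0.5, 1, 2, 4, 8),
                                                    Dm = 2, m = 1.5)))
  # an agent "combined" with zero of the other at its own fitted effect
  pts <- data.frame(dose_a = 1.7, dose_b = 0, fa = me_fa(1.7, 1, 1))
  expect_equal(combination_index(fits, pts)$ci, 1, tolerance = 1e-9)
  # constructed Loewe-additive pair: D1/Dx1 + D2/Dx2 = 1 at fa = 0.6
  fa <- 0.6
  Dx1 <- 1 * (fa / (1 - fa))^(1 / 1)
  Dx2 <- 2 * (fa / (1 - fa))^(1 / 1.5)
  pts2 <- data.frame(dose_a = 0.3 * Dx1, dose_b = 0.7 * Dx2, fa = fa)
  expect_equal(combination_index(fits, pts2)$ci, 1, tolerance = 1e-9)
  # doubling every dose at fixed fa doubles CI
  pts3 <- pts2
  pts3$dose_a <- 2 * pts3$dose_a
  pts3$dose_b <- 2 * pts3$dose_b
  expect_equal(combination_index(fits, pts3)$ci, 2, tolerance = 1e-9)
})

test_that("CI equals the brute-force formula and is unit-scale invariant", {
  fits <- list(
    a = median_effect_fit(c(0.2, 0.5, 1, 2, 5), me_fa(c(0.2, 0.5, 1, 2, 5),
                                                      1, 0.8)),
    b = median_effect_fit(c(1, 2, 4, 8, 16), me_fa(c(1, 2, 4, 8, 16),
                                                   4, 2)),
    c = median_effect_fit(c(0.1, 0.2, 0.4, 0.8), me_fa(c(0.1, 0.2, 0.4, 0.8),
                                                       0.3, 1.2)))
  pts <- data.frame(dose_a = 0.7, dose_b = 3, dose_c = 0.15, fa = 0.45)
  got <- combination_index(fits, pts)$ci
  # independent direct evaluation from the fitted constants
  ratio <- 0.45 / 0.55
  want <- 0.7 / (1 * ratio^(1 / 0.8)) + 3 / (4 * ratio^(1 / 2)) +
    0.15 / (0.3 * ratio^(1 / 1.2))
  expect_equal(got, want, tolerance = 1e-12)
  # rescaling agent b's dose units (doses and fit together) leaves CI fixed
  fits2 <- fits
  fits2$b <- median_effect_fit(1000 * c(1, 2, 4, 8, 16),
                               me_fa(c(1, 2, 4, 8, 16), 4, 2))
  pts2 <- pts
  pts2$dose_b <- 1000 * pts2$dose_b
  expect_equal(combination_index(fits2, pts2)$ci, got, tolerance = 1e-9)
})

test_that("combination points with fa outside (0,1) are skipped with a warning", {
  fits <- list(a = median_effect_fit(c(0.5, 1, 2), me_fa(c(0.5, 1, 2), 1, 1)))
  pts <- data.frame(dose_a = c(1, 2), fa = c(0.5, 1.2))
  expect_warning(res <- combination_index(fits, pts), "outside")
  expect_equal(res$ci[1], 1, tolerance = 1e-9)
  expect_true(is.na(res$ci[2]))
  expect_error(combination_index(fits, data.frame(fa = 0.5)), "lacks column")
})

test_that("a dose-flat monotherapy contributes no dose equivalent above its plateau", {
  flat <- median_effect_fit(c(0.5, 1, 2, 4),
                            c(0.0851, 0.0851 + 1e-9, 0.0851 + 2e-9,
                              0.0851 + 3e-9))
  active <- median_effect_fit(c(0.2, 0.5, 1, 2), me_fa(c(0.2, 0.5, 1, 2),
                                                       1, 1))
  pts <- data.frame(dose_flat = 2, dose_active = 1.5, fa = 0.6)
  ci <- combination_index(list(flat = flat, active = active), pts)$ci
  expect_equal(ci, 1.5 / (1 * 1.5), tolerance = 1e-6)
})

test_that("simulated dose-effect table covers therapies with sane fa values", {
  ps <- ref_human()
  tab <- simulate_dose_response_matrix(
    ps, therapies = c("miRNA_NP", "miRNA_NP+antibody"),
    multipliers = c(0.5, 1))
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$fa >= 0 & tab$fa < 1))
  expect_true(all(tab$dose_antibody[tab$therapy == "miRNA_NP"] == 0))
  mono <- tab$fa[tab$therapy == "miRNA_NP"]
  expect_true(all(diff(mono) > 0))
  expect_error(simulate_dose_response_matrix(ps, therapies = "warpdrive"),
               "unknown agent")
})
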
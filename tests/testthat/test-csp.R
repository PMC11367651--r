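test_that("CCSP formulas match hand-evaluated values and symmetries", {
  expect_equal(ccsp_2d(0, 0), 0)
  expect_equal(ccsp_2d(0.10, 0.50), 0.0906, tolerance = 1e-3)
  expect_equal(ccsp_2d(-0.10, 0.50), ccsp_2d(0.10, 0.50))
  expect_equal(ccsp_2d(0.10, -0.50), ccsp_2d(0.10, 0.50))

  expect_equal(ccsp_3d(0, 0, 0), 0)
  expect_equal(ccsp_3d(0.06, 0.40, 0.20), 0.0509, tolerance = 1e-3)
  # zero carbonyl difference reduces to the 2d formula rescaled by sqrt(2/3)
  expect_equal(ccsp_3d(0.08, 0.3, 0), ccsp_2d(0.08, 0.3) * sqrt(2 / 3))

  # linear under uniform scaling, invariant under global sign flip
  set.seed(1)
  for (i in 1:25) {
    d <- rnorm(3, 0, 0.3)
    k <- runif(1, 0.1, 10)
    expect_equal(ccsp_3d(k * d[1], k * d[2], k * d[3]),
                 k * ccsp_3d(d[1], d[2], d[3]))
    expect_equal(ccsp_2d(-d[1], -d[2]), ccsp_2d(d[1], d[2]))
  }
})

test_that("per-residue CCSP uses bound-minus-free differences and the right formula", {
  free <- toy_peaks(1:3, shift_H = c(8.0, 8.1, 8.2),
                    shift_N = c(118, 119, 120),
                    shift_C = c(176, NA, 175))
  bound <- toy_peaks(1:3, shift_H = c(8.05, 8.1, 8.2),
                     shift_N = c(118.5, 119, 120.4),
                     shift_C = c(176.2, NA, 175))
  d <- compute_ccsp(free, bound)
  expect_equal(d$dH[1], 0.05)
  expect_equal(d$dN[1], 0.5)
  expect_equal(d$ccsp[1], ccsp_3d(0.05, 0.5, 0.2))
  expect_equal(d$ccsp[2], 0)            # no shift change
  expect_equal(d$ccsp[3], ccsp_3d(0, 0.4, 0))  # carbonyl present, unchanged
  d2 <- compute_ccsp(free, bound, mode = "2d")
  expect_equal(d2$ccsp[1], ccsp_2d(0.05, 0.5))
  expect_error(compute_ccsp(toy_peaks(1:3, shift_C = NA),
                            toy_peaks(1:3, shift_C = NA), mode = "3d"),
               "carbonyl")
})

test_that("binding curve matches hand evaluation, limits and the saturation inverse", {
  expect_equal(binding_curve(0, 80e-6, 147e-6, 0.2), 0)
  expect_equal(binding_curve(160e-6, 80e-6, 147e-6, 0.2), 0.0913,
               tolerance = 1e-3)
  # saturation limit
  expect_equal(binding_curve(80e-6 * 1e4, 80e-6, 147e-6, 0.2), 0.2,
               tolerance = 1e-2)
  # monotone non-decreasing, bounded by a
  cs <- seq(0, 2e-3, length.out = 200)
  y <- binding_curve(cs, 80e-6, 147e-6, 0.2)
  expect_true(all(diff(y) >= 0))
  expect_true(all(y <= 0.2 + 1e-12))

  expect_equal(saturation_ccsp(0.0913, 160e-6, 80e-6, 147e-6), 0.2,
               tolerance = 1e-3)
  expect_equal(saturation_ccsp(0, 160e-6, 80e-6, 147e-6), 0)
  # stoichiometric limit: KD -> 0 with c >= p means already fully bound
  expect_equal(saturation_ccsp(0.15, 120e-6, 80e-6, 1e-15), 0.15,
               tolerance = 1e-6)
  expect_error(saturation_ccsp(0.1, 0, 80e-6, 147e-6), "c must be")

  # inverse identity over random valid parameters
  set.seed(5)
  for (i in 1:50) {
    p <- runif(1, 1e-6, 5e-4)
    KD <- 10^runif(1, -8, -2)
    a <- runif(1, 0.01, 1)
    c <- runif(1, 1e-7, 5e-3)
    y <- binding_curve(c, p, KD, a)
    expect_equal(saturation_ccsp(y, c, p, KD), a, tolerance = 1e-8)
  }
})

test_that("noiseless titrations refit to the generating KD and amplitudes", {
  ts <- synth_titration(80e-6, c(40e-6, 80e-6, 160e-6), c("93" = 0.2),
                        KD = 147e-6)
  fit <- fit_kd_titration(ts, n_boot = 0)
  expect_equal(fit$KD, 147e-6, tolerance = 1e-6)
  expect_equal(unname(fit$a), 0.2, tolerance = 1e-6)

  # two residues sharing KD
  ts2 <- synth_titration(80e-6, c(40e-6, 80e-6, 160e-6),
                         c("93" = 0.2, "94" = 0.1), KD = 147e-6)
  fit2 <- fit_kd_titration(ts2, n_boot = 0)
  expect_equal(fit2$KD, 147e-6, tolerance = 1e-6)
  expect_equal(unname(fit2$a), c(0.2, 0.1), tolerance = 1e-6)

  zero <- synth_titration(80e-6, c(40e-6, 80e-6), c("93" = 0), KD = 1e-4)
  expect_error(fit_kd_titration(zero, n_boot = 0), "unidentifiable")
  one_pt <- titration_series(80e-6, 40e-6,
                             matrix(0.1, 1, 1, dimnames = list("93", NULL)))
  expect_error(fit_kd_titration(one_pt, n_boot = 0), "at least 2")
})

test_that("bootstrap KD interval covers the truth and methods behave", {
  ts <- synth_titration(80e-6, c(40e-6, 80e-6, 160e-6),
                        c("93" = 0.2, "94" = 0.15, "95" = 0.1),
                        KD = 147e-6, noise_sd = 0.005, seed = 2)
  fit <- fit_kd_titration(ts, n_boot = 200, seed = 9)
  expect_length(fit$boot, 200)
  expect_true(fit$KD_ci[1] < fit$KD_ci[2])
  expect_named(coef(fit), c("KD", "93", "94", "95"), ignore.order = TRUE)
  pr <- predict(fit)
  expect_equal(dim(pr), c(3, 3))
  expect_output(print(fit), "KD")
})

test_that("phosphorylation degree is the modified-volume fraction", {
  expect_equal(phospho_degree(3, 1), 0.75)
  expect_equal(phospho_degree(0, 5), 0)
  expect_equal(phospho_degree(5, 0), 1)
  expect_error(phospho_degree(0, 0), "both volumes zero")
})

test_that("fast-exchange trajectories are collinear for two-state titrations", {
  f <- binding_curve(c(0, 40e-6, 80e-6, 160e-6), 80e-6, 147e-6, 1)
  tabs <- lapply(f, function(fr)
    toy_peaks(1:3, shift_H = 8 + fr * c(0.2, 0.1, 0.05),
              shift_N = 118 + fr * c(1.5, -0.8, 0.3)))
  lin <- csp_trajectory_linearity(tabs)
  expect_true(all(lin$r2 > 0.999))
})
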
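test_that("noiseless Arrhenius fits are exact for any n >= 3", {
  set.seed(51)
  for (n in c(3, 5, 12, 40)) {
    beta <- runif(1, -3e-3, 3e-3)
    ln_a <- runif(1, -14, -6)
    dg <- sort(runif(n, -300, 3000))
    m <- fit_cell_model(dg, exp(beta * dg + ln_a), "syn")
    expect_equal(m$beta, beta, tolerance = 1e-9)
    expect_equal(m$ln_a, ln_a, tolerance = 1e-9)
    expect_equal(m$r2, 1, tolerance = 1e-9)
    expect_equal(m$n, n)
  }
})

test_that("the fit recovers the generating slope of the STO-style stand-in", {
  st <- synthetic_kexo_standin("STO", seed = 3)
  m <- fit_cell_model(st$dg_change, st$k_exo, "STO")
  expect_lt(m$beta, 0)
  # true generating slope within ~3 standard errors of the estimate
  expect_lt(abs(m$beta - attr(st, "true_beta")), 3 * m$beta_se)
  expect_gt(m$r2, 0.8)
})

test_that("flat response degenerates to a zero slope with R^2 = 0", {
  m <- fit_cell_model(c(100, 500, 900), rep(2e-5, 3), "flat")
  expect_identical(m$beta, 0)
  expect_identical(m$r2, 0)
  expect_equal(exp(m$ln_a), 2e-5)
})

test_that("fit_cell_model guards its domain", {
  expect_error(fit_cell_model(c(1, 2), c(1e-5, 2e-5)), "insufficient")
  expect_error(fit_cell_model(c(5, 5, 5), c(1e-5, 2e-5, 3e-5)), "degenerate")
  expect_error(fit_cell_model(c(1, 2, 3), c(1e-5, 0, 3e-5)), "positive")
})

test_that("predictions reproduce training data on a perfect fit", {
  dg <- c(-100, 250, 700, 1300, 2600)
  k <- exp(-0.002 * dg - 9)
  m <- fit_cell_model(dg, k, "perfect")
  p <- predict_k_exo(m, dg)
  expect_equal(p$k_exo, k, tolerance = 1e-10)
  expect_false(any(p$extrapolated))
})

test_that("interval width grows away from the training mean and flags extrapolation", {
  st <- synthetic_kexo_standin("U937", seed = 9)
  m <- fit_cell_model(st$dg_change, st$k_exo, "U937")
  at_mean <- predict_k_exo(m, m$mean_dg)
  away <- predict_k_exo(m, m$mean_dg + 500)
  w <- function(p) log(p$upper) - log(p$lower)
  expect_lt(w(at_mean), w(away))
  expect_true(predict_k_exo(m, max(m$dg_range) + 1)$extrapolated)
  expect_false(predict_k_exo(m, m$mean_dg)$extrapolated)
  # prediction intervals are wider than confidence intervals
  expect_lt(w(predict_k_exo(m, m$mean_dg)),
            w(predict_k_exo(m, m$mean_dg, interval = "prediction")))
})

test_that("vesicle_fraction follows the Boltzmann form", {
  expect_identical(vesicle_fraction(0), 1)
  expect_equal(vesicle_fraction(rt_kJ_mol(310)), exp(-1))
  # a realistic repulsive energy gives an astronomically small fraction
  expect_equal(vesicle_fraction(248), 1.6e-42, tolerance = 0.05)
  # strictly decreasing
  dgs <- seq(0, 50, by = 5)
  expect_true(all(diff(vesicle_fraction(dgs)) < 0))
  expect_warning(vesicle_fraction(-10), "exceeds 1")
})

test_that("frequency-factor decomposition is an exact algebraic round trip", {
  st <- synthetic_kexo_standin("Hela", seed = 2)
  m <- fit_cell_model(st$dg_change, st$k_exo, "Hela")
  vp <- decompose_frequency(m, dg_np_v = 248)
  expect_equal(vp$ln_a_vesicle + vp$ln_fraction, m$ln_a, tolerance = 1e-12)
  # unit fraction: A_vesicle is the fitted A
  vp0 <- decompose_frequency(m, dg_np_v = 0)
  expect_equal(vp0$fraction, 1)
  expect_equal(vp0$a_vesicle, exp(m$ln_a))
  # combined mechanistic rate collapses to exp(ln_a - dG/RT)
  vp2 <- decompose_frequency(m, dg_np_v = 248, dg_change = 122)
  expect_equal(vp2$ln_k_combined, m$ln_a - 122 / vp2$rt, tolerance = 1e-12)
})

test_that("fitted slopes reproduce the qualitative cell-line sign pattern", {
  fits <- lapply(c("U937", "Hela", "STO", "SNB19", "C166"), function(cl) {
    st <- synthetic_kexo_standin(cl, seed = 17)
    fit_cell_model(st$dg_change, st$k_exo, cl)
  })
  names(fits) <- c("U937", "Hela", "STO", "SNB19", "C166")
  expect_lt(fits$U937$beta, 0)
  expect_lt(fits$Hela$beta, 0)
  expect_lt(fits$STO$beta, 0)
  expect_lt(fits$SNB19$beta, 0)
  expect_gt(fits$C166$beta, 0)
})

test_that("gamma-K_ow regression detects real association, not artefact", {
  # perfectly collinear pairs
  g <- c(10, 20, 30, 40, 50)
  r <- gamma_kow_regression(g, 0.1 * g - 2)
  expect_equal(r$r2, 1, tolerance = 1e-12)
  expect_equal(r$slope, 0.1, tolerance = 1e-12)
  expect_error(gamma_kow_regression(c(1, 2), c(1, 2)), ">= 3")
  # permutation oracle: observed ordering beats shuffled pairings
  set.seed(53)
  gg <- runif(20, 5, 55)
  kow <- 0.08 * gg + rnorm(20, 0, 0.5)
  obs <- gamma_kow_regression(gg, kow)$r2
  perm <- replicate(200, gamma_kow_regression(gg, sample(kow))$r2)
  expect_gt(obs, quantile(perm, 0.95))
})
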
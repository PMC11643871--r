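test_that("coalescence rate is pi * delta_nu / sqrt(2)", {
  expect_equal(rate_at_coalescence(100), 222.1441, tolerance = 1e-6)
  expect_equal(rate_at_coalescence(0), 0)
  expect_equal(rate_at_coalescence(200), 2 * rate_at_coalescence(100))
  expect_error(rate_at_coalescence(-5), "non-negative")
})

test_that("Eyring rate and barrier are exact inverses", {
  expect_equal(eyring_rate(0, 298.15), 6.2124e12, tolerance = 1e-4)
  expect_equal(barrier_from_rate(eyring_rate(11.2, 270), 270), 11.2,
               tolerance = 1e-12)
  # monotone decreasing in the barrier at fixed temperature
  ks <- eyring_rate(c(8, 10, 12, 14), 300)
  expect_true(all(diff(ks) < 0))
  expect_error(eyring_rate(10, -1), "positive")
  expect_error(barrier_from_rate(-1, 300), "positive")
})

test_that("coalescence barrier matches direct evaluation and both constants", {
  res <- coalescence_barrier(298, 100)
  expect_equal(res$dG, 14.24, tolerance = 1e-3)
  expect_equal(res$k_c, rate_at_coalescence(100))
  # explicit-constant form: dG = R Tc ln(kB Tc sqrt(2) / (pi h delta_nu))
  const <- physical_constants()
  direct <- function(Tc, dn)
    const$R_kcal * Tc * log(const$kB * Tc * sqrt(2) / (pi * const$h * dn))
  expect_equal(res$dG, direct(298, 100), tolerance = 1e-6)
  legacy <- coalescence_barrier(298, 100, constant = "legacy")
  expect_lt(legacy$dG, res$dG)    # 22.62 < 22.96 bracket
  expect_error(coalescence_barrier(-270, 100), "positive")
})

test_that("the bracket form is algebraically identical to the explicit form", {
  const <- physical_constants()
  expect_equal(bracket_constant(), 22.96, tolerance = 1e-3)
  set.seed(13)
  Tc <- runif(200, 150, 400)
  dn <- runif(200, 20, 5000)
  direct <- const$R_kcal * Tc * log(const$kB * Tc * sqrt(2) / (pi * const$h * dn))
  bracket <- vapply(seq_along(Tc),
                    function(i) coalescence_barrier(Tc[i], dn[i])$dG,
                    numeric(1))
  expect_lt(max(abs(direct - bracket)), 0.01)
})

test_that("the exchange lineshape reaches its slow and fast limits", {
  grid <- seq(-400, 400, by = 0.25)
  sys <- exchange_system(-100, 100, T2 = 0.5)
  slow <- two_site_lineshape(sys, 0.01, grid)
  pk <- grid[order(slow, decreasing = TRUE)[1:2]]
  expect_equal(sort(pk), c(-100, 100), tolerance = 0.01)

  # fast limit collapses to one line at the population-weighted mean
  sys2 <- exchange_system(-100, 100, pA = 0.7, T2 = 0.5)
  fast <- two_site_lineshape(sys2, 1e7, grid)
  expect_equal(count_modes(fast), 1)
  expect_equal(grid[which.max(fast)], 0.7 * -100 + 0.3 * 100,
               tolerance = 0.5)
  expect_equal(max(fast), 1)   # normalised
  expect_error(two_site_lineshape(sys, -1, grid), "non-negative")
  expect_error(two_site_lineshape(sys, 1, numeric(0)), "empty")
  expect_error(exchange_system(0, 1, pA = 1), "between 0 and 1")
  expect_error(exchange_system(0, 1, T2 = 0), "positive")
})

test_that("the lineshape top is flat at the coalescence rate", {
  sys <- exchange_system(-100, 100, T2 = 0.5)
  grid <- seq(-400, 400, by = 1)
  curv <- function(k) {
    y <- two_site_lineshape(sys, k, grid)
    i <- which(grid == 0)
    y[i - 1] - 2 * y[i] + y[i + 1]
  }
  kc <- rate_at_coalescence(200)
  expect_lt(abs(curv(kc)),
            0.05 * min(abs(curv(0.7 * kc)), abs(curv(1.3 * kc))))
  # below coalescence the centre dips, above it it peaks
  expect_gt(curv(0.7 * kc), 0)
  expect_lt(curv(1.3 * kc), 0)
})

test_that("coalescence detection fails cleanly without a transition", {
  sys <- exchange_system(-250, 250, T2 = 0.1)
  grid <- seq(-900, 900, length.out = 2048)
  merged <- vt_series(c(300, 310, 320), grid,
                      t(vapply(c(300, 310, 320),
                               function(T) two_site_lineshape(sys, 1e6, grid),
                               numeric(length(grid)))))
  expect_error(find_coalescence(merged), "merged")
  split <- vt_series(c(200, 210, 220), grid,
                     t(vapply(c(200, 210, 220),
                              function(T) two_site_lineshape(sys, 1, grid),
                              numeric(length(grid)))))
  expect_error(find_coalescence(split), "split")
})

test_that("barrier recovery from VT series hits the generating truth", {
  cases <- data.frame(dG = c(14.0, 9.5), delta_nu = c(500, 1500))
  for (i in seq_len(nrow(cases))) {
    dG <- cases$dG[i]; dn <- cases$delta_nu[i]
    sys <- exchange_system(-dn / 2, dn / 2)
    Tc_true <- true_coalescence_T(dG, dn)
    vt <- make_vt_series(dG, sys,
                         temps = seq(round(Tc_true) - 40,
                                     round(Tc_true) + 40, by = 2))
    res <- barrier_from_vt(vt)
    expect_equal(res$Tc, Tc_true, tolerance = 0.02)
    expect_equal(res$dG, dG, tolerance = 0.2 / dG)  # within 0.2 kcal/mol
    expect_equal(res$delta_nu, dn, tolerance = 0.005)
  }
})

test_that("recovery is scale invariant and warns for unequal populations", {
  sys <- exchange_system(-400, 400)
  Tc_true <- true_coalescence_T(12, 800)
  vt <- make_vt_series(12, sys, temps = seq(round(Tc_true) - 30,
                                            round(Tc_true) + 30, by = 2))
  res <- barrier_from_vt(vt)
  vt2 <- vt_series(vt$temperatures, vt$frequency, 2 * vt$intensities,
                   true_params = vt$true_params)
  res2 <- barrier_from_vt(vt2)
  expect_equal(res2$dG, res$dG)
  expect_equal(res2$Tc, res$Tc)

  sys_uneq <- exchange_system(-400, 400, pA = 0.6)
  vt3 <- make_vt_series(12, sys_uneq, temps = seq(round(Tc_true) - 30,
                                                  round(Tc_true) + 30, by = 2))
  expect_warning(res3 <- barrier_from_vt(vt3), "unequally populated")
  # the equal-population formula stays a usable estimate
  expect_equal(res3$dG, 12, tolerance = 1 / 12)
})

test_that("noisy replicate series recover the same barrier", {
  sys <- exchange_system(-600, 600)
  Tc_true <- true_coalescence_T(11, 1200)
  temps <- seq(round(Tc_true) - 30, round(Tc_true) + 30, by = 2)
  a <- make_vt_series(11, sys, temps = temps, noise_sd = 0.003, seed = 1)
  b <- make_vt_series(11, sys, temps = temps, noise_sd = 0.003, seed = 2)
  # prominence floor set an order of magnitude above the noise level
  res_a <- barrier_from_vt(a, prominence = 0.03)
  res_b <- barrier_from_vt(b, prominence = 0.03)
  expect_equal(res_a$dG, res_b$dG, tolerance = 0.2 / 11)
  # same seed reproduces the identical series
  a2 <- make_vt_series(11, sys, temps = temps, noise_sd = 0.003, seed = 1)
  expect_identical(a$intensities, a2$intensities)
})
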
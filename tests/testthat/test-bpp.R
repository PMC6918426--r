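test_that("the T1/T2 ratio has the extreme-narrowing identity and is monotone", {
  expect_identical(t1_t2_ratio(0), 1)
  # frozen closed-form value at x = 1: R(1) = 59/26
  expect_equal(t1_t2_ratio(1), 2.26923076923077, tolerance = 1e-12)
  xg <- 10^seq(-3, 3, length.out = 400)
  expect_true(all(diff(t1_t2_ratio(xg)) > 0))
  expect_error(t1_t2_ratio(-0.1), ">= 0")
})

test_that("forward rates match a direct evaluation of the BPP expressions", {
  # frozen independent evaluation at tau_c = 1e-9 s, C = 1e9, 15 MHz
  r <- bpp_rates(1e-9, 1e9)
  expect_equal(r$t1_s, 0.686725975760272, tolerance = 1e-10)
  expect_equal(r$t2_s, 0.674261898284626, tolerance = 1e-10)

  # extreme narrowing: T1/T2 -> 1 as x -> 0
  rn <- bpp_rates(1e-13, 1e9)
  expect_equal(rn$t1_s / rn$t2_s, 1, tolerance = 1e-6)

  # linearity in the coupling constant: doubling C halves both times
  r2 <- bpp_rates(1e-9, 2e9)
  expect_equal(r2$t1_s, r$t1_s / 2, tolerance = 1e-12)
  expect_equal(r2$t2_s, r$t2_s / 2, tolerance = 1e-12)
})

test_that("solve_tau_c matches the dense grid-search oracle", {
  # frozen from a 2e6-point log-grid search on R(x) = 1663/471 at 15 MHz
  res <- solve_tau_c(1663, 471)
  expect_equal(res$tau_c_s, 1.66961358988914e-08, tolerance = 1e-6)
  expect_lt(abs(res$residual), 1e-9)

  # random ratios: solver within one grid step of the brute-force search
  set.seed(61)
  ratios <- exp(runif(40, log(1.01), log(500)))
  grid_n <- 1e5
  step <- 12 / (grid_n - 1) # log10 spacing of the oracle grid
  for (r in ratios) {
    x_solver <- solve_tau_c(1000 * r, 1000)$x
    x_grid <- grid_search_x(r, grid_n)
    expect_lt(abs(log10(x_solver) - log10(x_grid)), step)
  }
})

test_that("forward and inverse maps round-trip over a log grid of (tau_c, C)", {
  taus <- 10^seq(-10.5, -7, length.out = 25)
  cs <- 10^seq(8, 10.5, length.out = 25)
  for (tau in taus) {
    fw <- bpp_rates(tau, cs)
    identifiable <- fw$t1_s / fw$t2_s > 1 + 1e-3
    for (k in which(identifiable)) {
      inv <- solve_tau_c(fw$t1_s[k] * 1000, fw$t2_s[k] * 1000)
      expect_equal(inv$tau_c_s, tau, tolerance = 1e-6)
      expect_equal(inv$coupling, cs[k], tolerance = 1e-6)
    }
  }
})

test_that("degenerate and out-of-bracket inputs are refused", {
  expect_error(solve_tau_c(1000, 1000), class = "retronmr_degenerate")
  expect_error(solve_tau_c(1000.5, 1000), class = "retronmr_degenerate")
  expect_error(solve_tau_c(-1, 500), "positive")
  # at fixed T1, shrinking T2 strictly increases tau_c
  t2s <- c(900, 700, 500, 300, 150)
  taus <- vapply(t2s, function(t2) solve_tau_c(1600, t2)$tau_c_s, numeric(1))
  expect_true(all(diff(taus) > 0))
})

test_that("every reference (T1, T2) pair maps between the water and ice brackets", {
  tab <- corn_starch_relaxation()
  wide <- tidyr::pivot_wider(tab, names_from = "parameter",
                             values_from = c("value_ms", "sd_ms"))
  for (i in seq_len(nrow(wide))) {
    t2s <- c(wide$value_ms_T2[i], wide$value_ms_T2s[i], wide$value_ms_T2l[i])
    for (t2 in t2s[!is.na(t2s)]) {
      tau <- solve_tau_c(wide$value_ms_T1[i], t2)$tau_c_s
      expect_gt(tau, 1e-12)
      expect_lt(tau, 1e-6)
    }
  }
})

test_that("delta-method tau_c intervals behave and match Monte Carlo", {
  # zero SDs give a zero-width interval
  u0 <- tau_c_uncertainty(1663, 0, 471, 0)
  expect_equal(u0$tau_c_lo, u0$tau_c_hi)
  expect_equal(u0$tau_c_sd, 0)

  u <- tau_c_uncertainty(1663, 5, 471, 3)
  expect_true(u$tau_c_lo < u$tau_c_s && u$tau_c_s < u$tau_c_hi)

  # Monte-Carlo propagation oracle for the SD
  set.seed(71)
  n <- 1000
  draws <- vapply(seq_len(n), function(i) {
    solve_tau_c(rnorm(1, 1663, 5), rnorm(1, 471, 3))$tau_c_s
  }, numeric(1))
  expect_equal(u$tau_c_sd, sd(draws), tolerance = 0.1)

  # first-order contract: doubling both SDs doubles the width
  u2 <- tau_c_uncertainty(1663, 10, 471, 6)
  expect_equal(u2$tau_c_hi - u2$tau_c_lo, 2 * (u$tau_c_hi - u$tau_c_lo),
               tolerance = 1e-9)

  # interval straddling the extreme-narrowing boundary is flagged one-sided
  us <- tau_c_uncertainty(1010, 30, 1000, 30)
  expect_true(us$one_sided)
  expect_true(is.na(us$tau_c_lo))
})

test_that("the coupling constant converts to a plausible interproton distance", {
  res <- solve_tau_c(1663, 471)
  r0 <- effective_interproton_distance(res$coupling)
  # intramolecular H-H distances are on the angstrom scale
  expect_gt(r0, 1e-11)
  expect_lt(r0, 1e-9)
})

test_that("tauc_table flags degenerate rows and keeps going", {
  df <- tibble::tibble(
    sample = c("a", "b", "c"),
    t1_ms = c(1663, 1000, 1401), t1_sd = c(5, 5, 4),
    t2_ms = c(471, 1000, 220), t2_sd = c(3, 5, 1))
  out <- tauc_table(df)
  expect_equal(nrow(out), 3)
  expect_true(out$degenerate[2])
  expect_true(is.na(out$tau_c_s[2]))
  expect_false(anyNA(out$tau_c_s[c(1, 3)]))
})
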
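test_that("T1 is recovered exactly from noise-free recovery curves", {
  for (t1 in c(ncs_day1_t1, wcs_day1_t1, ncs_day90_t1, hcs_day1_t1)) {
    cv <- generate_inversion_recovery(t1_truth(t1), ir_default)
    fit <- fit_t1_inversion_recovery(cv)
    expect_true(fit$converged)
    expect_equal(fit$components$time_ms, t1, tolerance = 1e-3)
    expect_equal(fit$m0, 100, tolerance = 1e-3)
  }
})

test_that("null-point identity: a curve crossing zero at t* gives T1 = t*/ln 2", {
  t1 <- 100 / log(2) # null point exactly at 100 ms
  cv <- decay_curve(seq(20, 300, by = 20),
                    inversion_recovery_model(seq(20, 300, by = 20), 50, t1))
  fit <- fit_t1_inversion_recovery(cv)
  expect_equal(fit$components$time_ms, 144.2695, tolerance = 1e-4)
})

test_that("T1 fitter reports honest flags and input errors", {
  expect_error(fit_t1_inversion_recovery(data.frame(t = c(1, 2),
                                                    y = c(-1, 0))),
               "3 points")
  # protocol mismatch is caught
  ct <- generate_cpmg_train(mono_truth(), cpmg_long)
  expect_error(fit_t1_inversion_recovery(ct), "cpmg")
})

test_that("T1 estimator is unbiased at bench noise (Monte-Carlo oracle)", {
  tr <- t1_truth(hcs_day1_t1, noise_sd = 1) # SNR 100
  n_rep <- 120
  set.seed(301)
  est <- replicate(n_rep, {
    fit_t1_inversion_recovery(generate_inversion_recovery(tr, ir_default))$
      components$time_ms
  })
  se <- sd(est) / sqrt(n_rep)
  expect_lt(abs(mean(est) - hcs_day1_t1), 3 * se)
})

test_that("mono- and biexponential T2 fits recover truth on noise-free trains", {
  ct <- generate_cpmg_train(mono_truth(), cpmg_long)
  f1 <- fit_t2_multiexponential(ct, 1)
  expect_equal(f1$components$time_ms, ncs_day1_t2, tolerance = 1e-3)
  expect_equal(f1$components$fraction, 1)

  cb <- generate_cpmg_train(biexp_truth(), cpmg_long)
  f2 <- fit_t2_multiexponential(cb, 2)
  expect_equal(f2$components$time_ms, hcs_day1_t2, tolerance = 1e-2)
  expect_equal(f2$components$fraction, hcs_fractions, tolerance = 1e-3)
  # components come out sorted ascending
  expect_true(all(diff(f2$components$time_ms) > 0))
})

test_that("1-component fit agrees with the closed-form semilog oracle", {
  ct <- generate_cpmg_train(mono_truth(), cpmg_long)
  oracle <- loglinear_t2(ct)
  fit <- fit_t2_multiexponential(ct, 1)
  expect_equal(fit$components$time_ms, oracle$t2_ms, tolerance = 1e-6)
  expect_equal(fit$m0, oracle$m0, tolerance = 1e-6)
})

test_that("every reference-table cell is recovered through the fit path", {
  # exact-recovery invariant over all generating (T1, T2) values
  design <- design_from_reference(snr = Inf)
  sim <- generate_storage_series(design)
  fits <- fit_storage_series(sim, max_components = 2L)
  truth <- dplyr::bind_rows(lapply(seq_len(nrow(sim)), function(i) {
    tibble::tibble(
      starch = sim$starch[i], hydrocolloid = sim$hydrocolloid[i],
      day = sim$day[i],
      kind = c("T1", rep("T2", nrow(sim$t2_components[[i]]))),
      true_ms = c(sim$t1_ms[i], sort(sim$t2_components[[i]]$time_ms)),
      component = c(1L, seq_len(nrow(sim$t2_components[[i]]))))
  }))
  merged <- dplyr::inner_join(
    fits, truth, by = c("starch", "hydrocolloid", "day", "kind", "component"))
  expect_equal(nrow(merged), nrow(fits))
  expect_lt(max(abs(merged$time_ms - merged$true_ms) / merged$true_ms), 1e-3)
})

test_that("fractions always sum to one and estimates ignore point order", {
  cb <- generate_cpmg_train(biexp_truth(noise_sd = 0.5), cpmg_long,
                            seed = 17)
  f2 <- fit_t2_multiexponential(cb, 2)
  expect_equal(sum(f2$components$fraction), 1, tolerance = 1e-6)

  d <- data.frame(t = cb$times_ms, y = cb$amplitudes)
  set.seed(1); shuffled <- d[sample(nrow(d)), ]
  fs <- fit_t2_multiexponential(shuffled, 2)
  expect_equal(fs$components$time_ms, f2$components$time_ms,
               tolerance = 1e-8)

  cv <- generate_inversion_recovery(t1_truth(noise_sd = 1), ir_default,
                                    seed = 18)
  di <- data.frame(t = cv$times_ms, y = cv$amplitudes)
  set.seed(2); shi <- di[sample(nrow(di)), ]
  expect_equal(fit_t1_inversion_recovery(shi)$components$time_ms,
               fit_t1_inversion_recovery(di)$components$time_ms,
               tolerance = 1e-8)
})

test_that("degenerate T2 inputs are rejected or collapsed", {
  zero <- data.frame(t = 2 * (1:30), y = rep(0, 30))
  expect_error(fit_t2_multiexponential(zero, 1), "no signal")
  expect_error(fit_t2_multiexponential(
    generate_cpmg_train(mono_truth(), cpmg_protocol(n_echoes = 4)), 1),
    "too few")
  expect_error(fit_t2_multiexponential(
    generate_cpmg_train(mono_truth(), cpmg_long), 4), "1, 2 or 3")

  # an unidentifiable equal-time split collapses with a diagnostic
  tr <- synthetic_truth(m0 = 100, t2_ms = c(400, 400),
                        fractions = c(0.5, 0.5))
  ct <- generate_cpmg_train(tr, cpmg_long)
  f <- fit_t2_multiexponential(ct, 2)
  expect_equal(f$n_components, 1L)
  expect_true(any(grepl("collapsed", f$diagnostics)))
  expect_equal(f$components$time_ms, 400, tolerance = 1e-3)
})

test_that("spin grouping selects the true component count", {
  ct <- generate_cpmg_train(mono_truth(), cpmg_long)
  s1 <- select_component_count(ct, 3)
  expect_equal(s1$n_components, 1L)
  expect_equal(nrow(s1$selection), 3)

  cb <- generate_cpmg_train(biexp_truth(), cpmg_long)
  s2 <- select_component_count(cb, 3)
  expect_equal(s2$n_components, 2L)

  # equal-time biexponential truth is selected as one pool
  tr <- synthetic_truth(m0 = 100, t2_ms = c(400, 400),
                        fractions = c(0.5, 0.5))
  s3 <- select_component_count(generate_cpmg_train(tr, cpmg_long), 3)
  expect_equal(s3$n_components, 1L)
})

test_that("water-fraction labels follow the short = bound, long = bulk rule", {
  cb <- generate_cpmg_train(biexp_truth(), cpmg_long)
  f2 <- fit_t2_multiexponential(cb, 2)
  lab <- label_water_fractions(f2)
  expect_equal(lab$label[which.min(lab$time_ms)], "bound_s")
  expect_equal(lab$label[which.max(lab$time_ms)], "bulk_l")

  ct <- generate_cpmg_train(mono_truth(), cpmg_long)
  lab1 <- label_water_fractions(fit_t2_multiexponential(ct, 1))
  expect_equal(lab1$label, "bulk_l")

  # labelling is tied to sorted times, not input order
  f_unsorted <- f2
  f_unsorted$components <- f2$components[2:1, ]
  f_unsorted <- retronmr:::new_relaxation_fit(
    "T2", f2$m0, f2$m0_sd, f_unsorted$components, f2$rss, f2$aicc,
    f2$converged, f2$n_points)
  expect_equal(label_water_fractions(f_unsorted)$label,
               c("bound_s", "bulk_l"))

  f1 <- fit_t1_inversion_recovery(
    generate_inversion_recovery(t1_truth(), ir_default))
  expect_error(label_water_fractions(f1), "T2")
})
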
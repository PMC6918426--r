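test_that("noise-free curves match the closed-form decay models exactly", {
  cv <- generate_inversion_recovery(t1_truth(), ir_default)
  expect_equal(cv$times_ms, seq(100, 1000, by = 100))
  expect_equal(cv$amplitudes,
               100 * (1 - 2 * exp(-cv$times_ms / ncs_day1_t1)))
  # frozen direct evaluation of the recovery model at t = 1000 ms
  expect_equal(cv$amplitudes[10], -9.6172174990244, tolerance = 1e-12)

  ct <- generate_cpmg_train(biexp_truth(), cpmg_long)
  expect_equal(ct$times_ms, (1:1024) * 2)
  expect_equal(ct$amplitudes,
               100 * (0.3 * exp(-ct$times_ms / 220) +
                        0.7 * exp(-ct$times_ms / 785)))
  # frozen direct evaluation of the echo model at echo k = 50 (t = 100 ms)
  expect_equal(ct$amplitudes[50], 80.6695005908477, tolerance = 1e-12)
})

test_that("recovery model boundary: amplitude at t = 0 is exactly -M0", {
  expect_identical(inversion_recovery_model(0, 100, 1663), -100)
  expect_identical(inversion_recovery_model(0, 37.5, 5), -37.5)
})

test_that("no-decay limit: first echo equals M0 when T2 is effectively infinite", {
  tr <- synthetic_truth(m0 = 100, t2_ms = 1e12)
  ct <- generate_cpmg_train(tr, cpmg_protocol(n_echoes = 10))
  expect_equal(ct$amplitudes[1], 100, tolerance = 1e-10)
})

test_that("generator validates its physical parameters", {
  expect_error(synthetic_truth(m0 = 100, t1_ms = -5), "positive")
  expect_error(synthetic_truth(m0 = 100, t2_ms = c(200, 800),
                               fractions = c(0.6, 0.6)), "sum to 1")
  expect_error(synthetic_truth(m0 = 100, noise_sd = -1), ">= 0")
  expect_error(ir_protocol(delays_ms = c(100, 50)), "increasing")
  expect_error(cpmg_protocol(te_ms = 0), "te_ms")
  expect_error(cpmg_protocol(n_echoes = 1), "n_echoes")
  expect_error(
    generate_cpmg_train(t1_truth(), cpmg_protocol()), "t2_ms")
  expect_error(
    generate_inversion_recovery(mono_truth(), ir_default), "t1_ms")
  expect_error(
    generate_inversion_recovery(t1_truth(), cpmg_protocol()),
    "inversion-recovery")
})

test_that("seeded generation is reproducible and leaves the caller's RNG alone", {
  tr <- t1_truth(noise_sd = 2)
  a <- generate_inversion_recovery(tr, ir_default, seed = 42)
  set.seed(7); before <- runif(1)
  b <- generate_inversion_recovery(tr, ir_default, seed = 42)
  set.seed(7); after <- runif(1)
  expect_identical(a$amplitudes, b$amplitudes)
  expect_identical(before, after)
  c_ <- generate_inversion_recovery(tr, ir_default, seed = 43)
  expect_false(identical(a$amplitudes, c_$amplitudes))
})

test_that("noise injection is unbiased and scales with accumulation averaging", {
  tr <- mono_truth(noise_sd = 5)
  proto <- cpmg_protocol(n_echoes = 64, n_accumulations = 1L)
  clean <- cpmg_model(protocol_times(proto), 100, tr$t2_ms, tr$fractions)
  n_rep <- 1200
  set.seed(11)
  resid_mean <- replicate(n_rep, {
    mean(generate_cpmg_train(tr, proto)$amplitudes - clean)
  })
  se <- 5 / sqrt(64 * n_rep)
  expect_lt(abs(mean(resid_mean)), 3 * se)

  # averaging 4 accumulations shrinks the amplitude noise SD by ~2
  proto4 <- cpmg_protocol(n_echoes = 64, n_accumulations = 4L)
  set.seed(12)
  sd1 <- sd(generate_cpmg_train(tr, proto)$amplitudes - clean)
  sd4 <- sd(generate_cpmg_train(tr, proto4)$amplitudes - clean)
  expect_lt(sd4, sd1)
})

test_that("storage-series generation mirrors the study design", {
  d <- design_from_reference(hydrocolloids = "none", snr = Inf)
  sim <- generate_storage_series(d, seed = 5)
  expect_equal(nrow(sim), 15) # 3 starches x 5 days
  expect_true(all(vapply(sim$ir_curve, inherits, logical(1), "decay_curve")))
  expect_true(all(vapply(sim$cpmg_curve, inherits, logical(1), "decay_curve")))
  # HCS cells carry two components, NCS/WCS one
  ncomp <- vapply(sim$t2_components, nrow, integer(1))
  expect_equal(ncomp[sim$starch == "HCS"], rep(2L, 5))
  expect_equal(ncomp[sim$starch != "HCS"], rep(1L, 10))

  # empty design: empty collection, no error
  empty <- generate_storage_series(d[0, ])
  expect_equal(nrow(empty), 0)

  # duplicated key is a design error
  expect_error(generate_storage_series(d[c(1, 1), ]), "duplicate")

  # fixed seed: bit-identical amplitudes, including noisy runs
  dn <- design_from_reference(hydrocolloids = "none", snr = 100)
  s1 <- generate_storage_series(dn, seed = 99)
  s2 <- generate_storage_series(dn, seed = 99)
  expect_identical(lapply(s1$cpmg_curve, `[[`, "amplitudes"),
                   lapply(s2$cpmg_curve, `[[`, "amplitudes"))
})

test_that("the bundled reference table has the expected layout", {
  tab <- corn_starch_relaxation()
  expect_equal(nrow(tab), 140)
  expect_setequal(unique(tab$parameter), c("T1", "T2", "T2s", "T2l"))
  # two-pool decomposition only for the high-amylose starch
  expect_setequal(unique(tab$starch[tab$parameter %in% c("T2s", "T2l")]),
                  "HCS")
  expect_true(all(tab$value_ms > 0 & tab$sd_ms > 0))
  expect_equal(sort(unique(tab$day)), c(1, 2, 10, 30, 90))
})
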
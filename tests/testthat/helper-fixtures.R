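# Shared fixtures: generating values follow the bundled reference table
# (corn_starch_relaxation); HCS bound/bulk fractions use the package's
# 0.3/0.7 convention.

ncs_day1_t1 <- 1663
ncs_day1_t2 <- 471
ncs_day90_t1 <- 1280
wcs_day1_t1 <- 1612
wcs_day90_t2 <- 563
hcs_day1_t1 <- 1401
hcs_day1_t2 <- c(220, 785)
hcs_fractions <- c(0.3, 0.7)

ir_default <- ir_protocol()
cpmg_long <- cpmg_protocol(n_echoes = 1024L)

mono_truth <- function(t2 = ncs_day1_t2, noise_sd = 0) {
  synthetic_truth(m0 = 100, t2_ms = t2, noise_sd = noise_sd)
}

biexp_truth <- function(noise_sd = 0) {
  synthetic_truth(m0 = 100, t2_ms = hcs_day1_t2, fractions = hcs_fractions,
                  noise_sd = noise_sd)
}

t1_truth <- function(t1 = ncs_day1_t1, noise_sd = 0) {
  synthetic_truth(m0 = 100, t1_ms = t1, noise_sd = noise_sd)
}

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# independent brute-force inversion of the T1/T2 ratio on a dense log grid
grid_search_x <- function(ratio, n = 1e5) {
  grid <- 10^seq(-6, 6, length.out = n)
  grid[which.min(abs(t1_t2_ratio(grid) - ratio))]
}
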
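test_that("build-up fit recovers a noiseless rate to high precision", {
  s <- simulate_hdx_series(1e-3, I0 = 1, I_inf = 0.05)
  f <- fit_buildup(s)
  expect_equal(f$category, "measured")
  expect_lt(abs(f$k_ex - 1e-3) / 1e-3, 1e-6)
  expect_lt(abs(f$I_inf - 0.05), 1e-6)
  expect_lt(abs(f$I0 - 1), 1e-6)
  expect_error(fit_buildup(s[1:3, ]), "4 distinct")
})

test_that("build-up fit is invariant under intensity and time rescaling", {
  s <- simulate_hdx_series(5e-4, I0 = 1, I_inf = 0.1)
  f <- fit_buildup(s)
  s_i <- s; s_i$intensity <- s_i$intensity * 42
  expect_equal(fit_buildup(s_i)$k_ex, f$k_ex, tolerance = 1e-8)
  # time in hours: rate transforms reciprocally
  s_t <- s; s_t$time_s <- s_t$time_s / 3600
  expect_equal(fit_buildup(s_t)$k_ex, f$k_ex * 3600, tolerance = 1e-6)
})

test_that("flat and already-complete series are censored, not fitted", {
  flat <- simulate_hdx_series(0, I0 = 1, I_inf = 0.05)
  f <- fit_buildup(flat, plateau_ref = 1.05)
  expect_equal(f$category, "slow")
  expect_true(is.na(f$k_ex))

  done <- simulate_hdx_series(0, I0 = 1, I_inf = 1.05) # at plateau level
  f2 <- fit_buildup(done, plateau_ref = 1.05)
  expect_equal(f2$category, "fast")
  expect_true(is.na(f2$k_ex))

  # steep but resolvable build-up stays measured
  steep <- simulate_hdx_series(1.5e-3, I0 = 1, I_inf = 0.05)
  expect_equal(fit_buildup(steep)$category, "measured")

  # noisy baseline-level series (unexchanged residue) must never be
  # promoted to a measured rate, whatever the noise realization
  for (sd in 1:12) {
    lowflat <- simulate_hdx_series(0, I0 = 1, I_inf = 0.02,
                                   noise_sd = 0.002, seed = 7 * sd)
    expect_equal(fit_buildup(lowflat, plateau_ref = 1.02)$category,
                 "slow", label = paste("seed", 7 * sd))
  }
})

test_that("censored lower bound follows its definition and calibration", {
  # definitional anchor: completeness 1 - 1/e at t gives 1/t
  expect_equal(censor_bound(900, 1 - exp(-1)), 1 / 900,
               tolerance = 1e-12)
  # calibrated default reproduces the fast-group bound 2.9e-3 s^-1
  expect_equal(round(censor_bound(900), 4), 0.0029)
  # doubling the first time point halves the bound
  expect_equal(censor_bound(1800), censor_bound(900) / 2)
  # second spectrum near 25.5 min gives the second-group bound 1.7e-3
  expect_equal(round(censor_bound(default_hdx_grid()[2]), 4), 0.0017)
  expect_error(censor_bound(900, 1.2), "between 0 and 1")
})

test_that("intrinsic rates behave per the reference parameterization", {
  # base-catalyzed regime: +1 pH unit is ~10x faster
  k7 <- intrinsic_rates("AAAA", pH = 7, temp_K = 293)$k_int[3]
  k8 <- intrinsic_rates("AAAA", pH = 8, temp_K = 293)$k_int[3]
  expect_lt(abs(k8 / k7 - 10) / 10, 0.01)

  # proline and the chain start carry no amide contribution
  kp <- intrinsic_rates("APGA", pH = 7, temp_K = 293)
  expect_true(is.na(kp$k_int[1]))
  expect_true(is.na(kp$k_int[2]))
  expect_false(is.na(kp$k_int[3]))

  # dual-implementation oracle for an interior alanine (all
  # neighbour corrections zero): direct evaluation of
  # k = kA [H+] + kB [OH-] + kW with Arrhenius scaling from 293 K
  pH <- 7; T <- 331.15
  R <- 8.314462618
  arrh <- function(Ea) exp(-Ea * 4184 / R * (1 / T - 1 / 293))
  pKw <- 13.995 + 13.34 * 4184 / (R * log(10)) * (1 / T - 1 / 298.15)
  k_direct <- 10^2.04 / 60 * arrh(14) * 10^(-pH) +
    10^10.36 / 60 * arrh(17) * 10^(pH - pKw) +
    10^-1.5 / 60 * arrh(19)
  k_pkg <- intrinsic_rates("AAAA", pH = pH, temp_K = T)$k_int[3]
  expect_lt(abs(k_pkg - k_direct) / k_direct, 1e-6)

  # temperature accelerates exchange
  expect_gt(k_pkg, k7)
  # pH and temperature are required
  expect_error(intrinsic_rates("AAA", pH = 7), "required")
  expect_error(intrinsic_rates("AXA", pH = 7, temp_K = 300),
               "unknown residue")
})

test_that("neighbour corrections depend on the flanking residues", {
  kG <- intrinsic_rates("AGAA", pH = 7, temp_K = 293)$k_int[3]
  kI <- intrinsic_rates("AIAA", pH = 7, temp_K = 293)$k_int[3]
  # bulky beta-branched left neighbour slows base catalysis, Gly
  # accelerates it
  expect_gt(kG, kI)
})

test_that("protection factors and plotting categories partition residues", {
  p <- protection(1e-3, 1)
  expect_equal(p$P, 1000)
  expect_equal(p$logP, 3)
  expect_equal(p$logP_display, 3)

  tab <- protection(
    k_ex = c(1e-3, NA, NA, NA, NA),
    k_int = 1,
    category = c("measured", "fast", "second_fastest", "slow", "no_data"))
  expect_equal(tab$logP_display[-1], c(2.5, 2.8, 7.0, -0.1))
  expect_true(all(is.na(tab$P[-1])))
  # exactly one category each
  expect_false(anyNA(tab$category))

  expect_error(protection(0, 1), "positive")
  expect_error(protection(NA, 1, category = "sluggish"), "unknown")
})

test_that("a constant rate offset between cohorts is recovered in the
           fitted means", {
  set.seed(23)
  k_bound <- runif(12, 2e-4, 8e-4)
  offset <- 0.28e-3
  fit_mean <- function(ks, seed0) {
    mean(vapply(seq_along(ks), function(i) {
      s <- simulate_hdx_series(ks[i], I0 = 1, I_inf = 0.05,
                               noise_sd = 0.004, seed = seed0 + i)
      fit_buildup(s)$k_ex
    }, numeric(1)))
  }
  m_bound <- fit_mean(k_bound, 100)
  m_free <- fit_mean(k_bound + offset, 200)
  expect_lt(abs((m_free - m_bound) - offset) / offset, 0.15)
})
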
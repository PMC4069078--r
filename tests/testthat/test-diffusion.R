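test_that("local_tm inverts the forward rigid-rotor ratio", {
  for (field in c(600, 800)) {
    for (tm in c(1e-9, 5e-9, 13e-9, 30e-9)) {
      rho <- local_tm_forward(tm, field)
      expect_lt(abs(local_tm(rho, field) - tm), 1e-13)
    }
  }
})

test_that("R2/R1 is monotone in tau_m over the inversion window", {
  tms <- seq(1e-9, 30e-9, length.out = 40)
  for (field in c(600, 800))
    expect_true(all(diff(local_tm_forward(tms, field)) > 0))
})

test_that("unattainable ratios are flagged, not silently inverted", {
  rmin <- local_tm_forward(0.5e-9, 800)
  expect_warning(out <- local_tm(rmin * 0.5, 800), "outside")
  expect_true(is.na(out))
})

test_that("trim_and_average recovers a common rigid value exactly", {
  tn <- diffusion_tensor(tau_c = 13e-9)
  rec <- mk_rigid_records(tn, gen_bond_vectors(10, seed = 1))
  rec$NOE <- 0.80
  out <- trim_and_average(rec)
  expect_equal(out$tau_c, 13e-9, tolerance = 1e-9)
  expect_equal(out$sd, 0)
  expect_equal(length(out$included), 10)
})

test_that("trimming drops low-NOE residues and R2/R1 outliers", {
  tn <- diffusion_tensor(tau_c = 13e-9)
  rec <- mk_rigid_records(tn, gen_bond_vectors(12, seed = 2))
  rec$NOE <- 0.8
  rec$NOE[3] <- 0.2              # mobile residue
  rec$R2[5] <- rec$R2[5] * 1.5   # exchange-broadened outlier
  out <- trim_and_average(rec)
  expect_false(rec$residue[3] %in% out$included)
  expect_false(rec$residue[5] %in% out$included)
  expect_lt(abs(out$tau_c - 13e-9), 0.05e-9)

  expect_error(trim_and_average(rec[1:4, ]), "at least 5")
})

test_that("global tau_c is recovered within 0.4 ns at study noise", {
  tn <- diffusion_tensor(tau_c = 13e-9)
  vec <- gen_bond_vectors(40, seed = 3)
  rec <- mk_rigid_records(tn, vec, noise = c(R1 = 0.04, R2 = 0.40),
                          seed = 17)
  rec$NOE <- 0.80
  out <- trim_and_average(rec)
  expect_lt(abs(out$tau_c - 13e-9), 0.4e-9)
})

test_that("axial tensor fit returns the isotropic limit on isotropic data", {
  tn <- diffusion_tensor(tau_c = 13e-9)
  vec <- gen_bond_vectors(30, seed = 4)
  rec <- mk_rigid_records(tn, vec)
  fit <- fit_axial_tensor(rec, vec)
  expect_lt(abs(fit$anisotropy - 1), 0.02)
  expect_lt(fit$chi2, 1e-6)
})

test_that("noiseless oblate tensor is recovered including its axis", {
  tn <- diffusion_tensor(tau_c = 13e-9, anisotropy = 0.90,
                         theta = 30, phi = 60)
  vec <- gen_bond_vectors(40, seed = 2)
  rec <- mk_rigid_records(tn, vec)
  fit <- fit_axial_tensor(rec, vec)
  expect_lt(abs(fit$anisotropy - 0.90) / 0.90, 1e-3)
  expect_lt(abs(fit$tensor$D_perp - tn$D_perp) / tn$D_perp, 1e-3)
  expect_lt(abs(fit$tensor$D_par - tn$D_par) / tn$D_par, 1e-3)
  ax_in <- nmrdyn:::.axis_vector(30, 60)
  ax_out <- nmrdyn:::.axis_vector(fit$tensor$theta, fit$tensor$phi)
  expect_lt(acos(abs(sum(ax_in * ax_out))) * 180 / pi, 1)
  # both branches reported, oblate is the first minimum
  expect_equal(fit$minima$branch[1], "oblate")
  expect_equal(nrow(fit$minima), 2)

  expect_error(fit_axial_tensor(rec[1:5, ], vec), "at least 10")
})

test_that("inertia moments match symmetry expectations and are
           rigid-motion invariant", {
  set.seed(8)
  # near-uniform spherical shell
  v <- matrix(rnorm(3000 * 3), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  mom <- inertia_moments(v)$moments
  expect_true(all(abs(mom - 1) < 0.05))

  # thin rod along z: two equal large moments, one tiny
  rod <- cbind(rnorm(500, 0, 1e-4), rnorm(500, 0, 1e-4),
               seq(-1, 1, length.out = 500))
  mrod <- inertia_moments(rod)$moments
  expect_equal(mrod[1], 1)
  expect_lt(abs(mrod[2] - 1), 1e-6)
  expect_lt(mrod[3], 1e-6)

  xyz <- matrix(rnorm(60), ncol = 3)
  m1 <- inertia_moments(xyz)$moments
  m2 <- inertia_moments(rigid_transform(xyz, c(37, 12, -5) * pi / 180,
                                        c(10, 20, 30)))$moments
  expect_equal(m1, m2, tolerance = 1e-10)
})

test_that("viscosity/temperature extrapolation reproduces the
           room-temperature correlation time", {
  tc25 <- tc_extrapolate(c(331.15, 313.15), c(13.0e-9, 18.0e-9), 298.15)
  expect_lt(abs(tc25 * 1e9 - 25.4), 0.5)

  # equal inputs extrapolate to a constant
  expect_equal(tc_extrapolate(c(331.15, 313.15), c(10e-9, 10e-9), 298.15),
               10e-9, tolerance = 1e-12)
  expect_error(tc_extrapolate(331.15, 13e-9, 298.15), "2 points")
})

test_that("theoretical correlation-time estimates match their closed
           forms", {
  expect_equal(round(tc_theoretical(56, "empirical_mw"), 1), 33.8)
  expect_equal(tc_theoretical(0, "empirical_mw"), 0.1674)
  tc_se <- tc_theoretical(56, "stokes_einstein", vbar = 0.73,
                          hydration_A = 3.2, temp_K = 298.15,
                          eta = 0.8900e-3)
  expect_lt(abs(tc_se - 21.0), 0.5)
  # doubling the Stokes radius (x8 volume at zero hydration) scales
  # tau_c by 8
  t1 <- tc_theoretical(56, "stokes_einstein", hydration_A = 0)
  t8 <- tc_theoretical(56 * 8, "stokes_einstein", hydration_A = 0)
  expect_equal(t8 / t1, 8, tolerance = 1e-10)
  expect_error(tc_theoretical(-5, "empirical_mw"))
})

test_that("water viscosity correlation hits its anchor points", {
  expect_equal(water_viscosity(298.15), 0.8900e-3, tolerance = 1e-12)
  expect_lt(abs(water_viscosity(313.15) - 0.6527e-3) / 0.6527e-3, 0.005)
})
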
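tn13 <- diffusion_tensor(tau_c = 13e-9)

test_that("spectral density limits match their closed forms", {
  tm <- 13e-9
  w <- c(0, 5e8, 2e9)
  # rigid limit: internal term vanishes for any te
  expect_equal(spectral_density(w, S2 = 1, te = 5e-9, tensor = tn13),
               0.4 * tm / (1 + (w * tm)^2), tolerance = 1e-12)
  # zero-frequency closed form
  S2 <- 0.8; te <- 100e-12
  tp <- 1 / (1 / tm + 1 / te)
  expect_equal(spectral_density(0, S2, te, tn13),
               0.4 * (S2 * tm + (1 - S2) * tp), tolerance = 1e-12)
})

test_that("axial coefficients sum to one and collapse to isotropic", {
  alphas <- seq(0, pi / 2, length.out = 25)
  tn_ax <- diffusion_tensor(tau_c = 13e-9, anisotropy = 0.9)
  for (a in alphas) {
    terms <- nmrdyn:::.tensor_terms(tn_ax, a)
    expect_equal(sum(terms$A), 1, tolerance = 1e-12)
  }
  # D_par == D_perp reproduces the isotropic value at every angle and
  # frequency
  tn_eq <- diffusion_tensor(tau_c = 13e-9, anisotropy = 1 + 1e-13)
  ws <- c(0, 1e8, 5e8, 2e9, 5e9)
  for (a in alphas[c(1, 7, 13, 19, 25)]) {
    expect_equal(spectral_density(ws, 0.85, 50e-12, tn_eq, alpha = a),
                 spectral_density(ws, 0.85, 50e-12, tn13),
                 tolerance = 1e-9)
  }
})

test_that("back-calculation is consistent with the rigid-rotor oracle", {
  bc <- back_calculate(S2 = 1, te = 0, tensor = tn13, field_MHz = 800)
  expect_equal(bc$R2 / bc$R1, local_tm_forward(13e-9, 800),
               tolerance = 1e-12)
})

test_that("NOE approaches the extreme-narrowing closed form as tau_m -> 0", {
  ic <- nmrdyn:::.interaction_constants(800)
  noe_limit <- 1 + ic$gamma_ratio * 5 * ic$dd / (10 * ic$dd + ic$c2)
  tiny <- diffusion_tensor(tau_c = 1e-12)
  bc <- back_calculate(S2 = 1, te = 0, tensor = tiny, field_MHz = 800)
  expect_equal(bc$NOE, noe_limit, tolerance = 1e-4)
})

test_that("Rex scales with the square of the field ratio", {
  b0 <- back_calculate(0.85, 0, 0, tn13, field_MHz = 600)
  b2 <- back_calculate(0.85, 0, 2, tn13, field_MHz = 600,
                       rex_ref_MHz = 800)
  expect_equal(b2$R2 - b0$R2, 2 * (600 / 800)^2, tolerance = 1e-12)
  expect_equal(b2$R1, b0$R1)
})

test_that("model-free fit recovers noiseless parameters and selects
           parsimonious models", {
  rec <- mk_records(0.85, 50e-12, 0, tn13)
  fit <- fit_modelfree(rec, tn13)
  expect_true(fit$model %in% c(2, 4)) # te-containing model
  expect_lt(abs(fit$S2 - 0.85), 1e-3)
  expect_lt(abs(fit$te - 50e-12) / 50e-12, 0.02)

  rigid <- fit_modelfree(mk_records(1, 0, 0, tn13), tn13)
  expect_equal(rigid$model, 1)
  expect_equal(rigid$S2, 1, tolerance = 1e-6)

  rex_fit <- fit_modelfree(mk_records(0.85, 0, 3, tn13), tn13)
  expect_true(rex_fit$model %in% c(3, 4))
  expect_lt(abs(rex_fit$rex - 3), 0.01)
})

test_that("model selection never prefers a larger model on noiseless
           data from a smaller one", {
  cases <- list(list(S2 = 0.9, te = 0, rex = 0, max_model = 1),
                list(S2 = 0.8, te = 80e-12, rex = 0, max_model = 2),
                list(S2 = 0.88, te = 0, rex = 2.5, max_model = 3))
  for (cs in cases) {
    fit <- fit_modelfree(mk_records(cs$S2, cs$te, cs$rex, tn13), tn13)
    expect_lte(fit$model, cs$max_model)
  }
})

test_that("optimizer matches an exhaustive grid search", {
  set.seed(77)
  truth_S2 <- c(0.62, 0.74, 0.83, 0.91, 0.97)
  truth_te <- c(120, 60, 30, 90, 15) * 1e-12
  for (i in seq_along(truth_S2)) {
    rec <- mk_records(truth_S2[i], truth_te[i], 0, tn13)
    fit <- fit_modelfree(rec, tn13, models = 2)
    # vectorized brute-force grid: S2 step 0.001, te step 1 ps
    grid <- expand.grid(S2 = seq(0.5, 1, by = 0.001),
                        te = seq(0, 200e-12, by = 1e-12))
    chi2 <- 0
    for (f in c(600, 800)) {
      fw <- nmrdyn:::.relax_forward(grid$S2, grid$te, 0, tn13, 0, f)
      ref <- rec[rec$field_MHz == f, ]
      chi2 <- chi2 + ((fw$R1 - ref$R1) / ref$R1_err)^2 +
        ((fw$R2 - ref$R2) / ref$R2_err)^2 +
        ((fw$NOE - ref$NOE) / ref$NOE_err)^2
    }
    best <- grid[which.min(chi2), ]
    expect_lt(abs(fit$S2 - best$S2), 0.0011)
    expect_lt(abs(fit$te - best$te), 1.1e-12)
    expect_lte(fit$chi2, min(chi2) + 1e-6)
  }
})

test_that("Monte Carlo errors are reproducible and plausible", {
  rec <- mk_records(0.85, 50e-12, 0, tn13)
  f1 <- fit_modelfree(rec, tn13, n_mc = 25, seed = 5)
  f2 <- fit_modelfree(rec, tn13, n_mc = 25, seed = 5)
  expect_identical(f1, f2)
  expect_gt(f1$S2_err, 0)
  expect_lt(f1$S2_err, 0.1)
  # absent parameters carry no uncertainty
  expect_true(is.na(f1$rex) && is.na(f1$rex_err))
})

test_that("conformational entropy obeys its identities", {
  # zero for identical states
  expect_equal(conf_entropy(0.8, 0.8)$total, 0)
  # antisymmetry under swapping states
  ab <- conf_entropy(0.85, 0.89)$total
  ba <- conf_entropy(0.89, 0.85)$total
  expect_equal(ab, -ba)
  # closed-form single pair (independent re-derivation)
  R <- 8.314462618
  expected <- R * log((3 - sqrt(1 + 8 * 0.89)) / (3 - sqrt(1 + 8 * 0.85)))
  expect_equal(conf_entropy(0.85, 0.89, 331)$total, expected,
               tolerance = 1e-12)
  # rigidification on binding (S2 up) is an entropy loss
  expect_lt(ab, 0)
  # additivity over disjoint residue sets
  a <- c(0.7, 0.8); b <- c(0.85, 0.9)
  expect_equal(conf_entropy(a, b)$total,
               conf_entropy(a[1], b[1])$total +
                 conf_entropy(a[2], b[2])$total)
  expect_error(conf_entropy(1, 0.9), "singular")
})
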
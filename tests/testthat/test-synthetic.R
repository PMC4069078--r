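test_that("gen_truth handles the empty case and is seed-deterministic", {
  empty <- gen_truth(0, 0, seed = 1)
  expect_equal(nrow(empty$residues), 0)

  a <- gen_truth(50, 20, seed = 7, profile = "bound_58C")
  b <- gen_truth(50, 20, seed = 7, profile = "bound_58C")
  expect_identical(a, b)
  c <- gen_truth(50, 20, seed = 8, profile = "bound_58C")
  expect_false(identical(a$residues$S2, c$residues$S2))

  expect_error(gen_truth(10, 0, seed = 1, profile = "nope"),
               "unknown profile")
  expect_error(gen_truth(-1, 0, seed = 1))
})

test_that("strand S2 sampling concentrates on the preset mean", {
  tr <- gen_truth(1000, 0, seed = 3, profile = "bound_58C")
  expect_true(all(tr$residues$S2 >= 0 & tr$residues$S2 <= 1))
  expect_lt(abs(mean(tr$residues$S2) - 0.89), 0.01)

  # loops are lower and more dispersed
  tr2 <- gen_truth(500, 500, seed = 4, profile = "bound_58C")
  s <- tr2$residues
  expect_lt(mean(s$S2[s$class == "loop"]), mean(s$S2[s$class == "strand"]))
  expect_gt(sd(s$S2[s$class == "loop"]), sd(s$S2[s$class == "strand"]))
})

test_that("hinge option plants one very mobile loop residue", {
  tr <- gen_truth(20, 10, seed = 5, hinge = TRUE)
  s <- tr$residues
  expect_equal(sum(s$S2 < 0.3), 1)
  expect_equal(s$class[s$S2 < 0.3], "loop")
})

test_that("residue numbering honours the sequence gap after 54", {
  tr <- gen_truth(60, 0, seed = 1)
  ids <- tr$residues$residue
  expect_true(54 %in% ids)
  expect_false(any(c(55, 56) %in% ids))
  expect_true(57 %in% ids)
})

test_that("noiseless relaxation simulation is exact back-calculation", {
  tr <- gen_truth(5, 3, seed = 11)
  rec <- simulate_relaxation(tr, noise = FALSE)
  expect_equal(nrow(rec), 2 * 8) # two fields per residue
  i <- match(tr$residues$residue, rec$residue[rec$field_MHz == 800])
  bc <- back_calculate(tr$residues$S2, tr$residues$te, tr$residues$rex,
                       tr$tensor, 0, 800)
  r800 <- rec[rec$field_MHz == 800, ]
  expect_equal(r800$R1[i], bc$R1, tolerance = 1e-12)
  expect_equal(r800$R2[i], bc$R2, tolerance = 1e-12)
  expect_equal(r800$NOE[i], bc$NOE, tolerance = 1e-12)
})

test_that("simulated noise matches the requested sigma", {
  tr <- gen_truth(1, 0, seed = 2)
  draws <- vapply(seq_len(10000), function(i)
    simulate_relaxation(tr, data.frame(field_MHz = 800, temp_K = 331.15),
                        noise = TRUE, seed = i)$R1,
    numeric(1))
  expect_lt(abs(sd(draws) - 0.04) / 0.04, 0.03)
})

test_that("a condition at an unknown temperature is rejected", {
  tr <- gen_truth(3, 0, seed = 2)
  expect_error(
    simulate_relaxation(tr, data.frame(field_MHz = 800, temp_K = 313.15),
                        noise = FALSE),
    "no diffusion tensor")
  # and works once a tensor for it is supplied
  rec <- simulate_relaxation(
    tr, data.frame(field_MHz = 800, temp_K = 313.15), noise = FALSE,
    tensors = list(`313.15` = diffusion_tensor(tau_c = 18e-9)))
  expect_equal(nrow(rec), 3)
})

test_that("decay series uses the documented default grid and round-trips", {
  expect_equal(default_t2_grid(),
               c(10, 30, 50, 70, 90, 110) * 1e-3)
  expect_equal(length(default_t1_grid()), 11)

  s0 <- simulate_decay_series(1, amplitude = 1, timepoints = 0)
  expect_equal(s0$intensity, 1)

  s <- simulate_decay_series(10, timepoints = default_t2_grid())
  expect_lt(abs(fit_rate(s)$rate - 10) / 10, 1e-8)
  expect_error(simulate_decay_series(-1), "rate")
})

test_that("hdx series emits the three-parameter build-up form", {
  flat <- simulate_hdx_series(0, I0 = 1, I_inf = 0.3)
  expect_true(all(flat$intensity == 0.3))
  expect_equal(default_hdx_grid()[1], 900)
  expect_equal(max(default_hdx_grid()), 96 * 3600)

  s <- simulate_hdx_series(1e-3)
  expect_lt(abs(fit_buildup(s)$k_ex - 1e-3) / 1e-3, 1e-6)
  expect_error(simulate_hdx_series(1e-3, timepoints = numeric(0)),
               "empty")
})

test_that("bond vectors are unit, isotropic when asked, deterministic", {
  v <- gen_bond_vectors(50000, seed = 6, mode = "uniform_sphere")
  norms <- sqrt(v$x^2 + v$y^2 + v$z^2)
  expect_true(all(abs(norms - 1) < 1e-12))
  p2 <- mean(1.5 * v$z^2 - 0.5)
  expect_lt(abs(p2), 0.01)

  expect_identical(gen_bond_vectors(100, seed = 3),
                   gen_bond_vectors(100, seed = 3))
  b <- gen_bond_vectors(1000, seed = 4, mode = "barrel_like")
  expect_true(all(abs(sqrt(b$x^2 + b$y^2 + b$z^2) - 1) < 1e-12))
  # polar angles concentrated: |P2| well away from the isotropic 0
  expect_gt(abs(mean(1.5 * b$z^2 - 0.5)), 0.2)
  expect_error(gen_bond_vectors(0))
})
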
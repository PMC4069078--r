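# toy builders ------------------------------------------------------------

toy_atoms <- function(n, chain = "A", resname = "ALA") {
  data.frame(atom = rep("CA", n), residue = seq_len(n),
             resname = resname, chain = chain, element = "C")
}

toy_ensemble <- function(models) {
  n <- nrow(models[[1]])
  xyz <- array(NA_real_, c(length(models), n, 3))
  for (m in seq_along(models)) xyz[m, , ] <- models[[m]]
  structure_ensemble(toy_atoms(n), xyz)
}

test_that("identical and rigidly moved models superpose to RMSD zero", {
  set.seed(5)
  A <- matrix(rnorm(30), ncol = 3)
  ens <- toy_ensemble(list(A, A, A))
  out <- superpose_stats(ens)
  expect_equal(out$per_model, rep(0, 3), tolerance = 1e-10)

  ens2 <- toy_ensemble(list(A, rigid_transform(A)))
  out2 <- superpose_stats(ens2)
  expect_equal(out2$mean, 0, tolerance = 1e-10)
  expect_error(superpose_stats(toy_ensemble(list(A))), "2 models")
  expect_error(superpose_stats(ens, selection = integer(0)), "empty")
})

test_that("cross RMSD matches a closed form when the optimal rotation
           is the identity", {
  # regular tetrahedron, radially scaled: H = c * Q'Q is symmetric
  # positive definite, so the Kabsch rotation is exactly the identity
  # and RMSD = |c - 1| * rms radius
  Q <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  s <- 1.3
  ens <- toy_ensemble(list(s * Q))
  out <- cross_rmsd(ens, Q)
  expect_equal(out$per_model, (s - 1) * sqrt(3), tolerance = 1e-10)
  expect_equal(out$n_pairs, 4)
})

test_that("cross RMSD agrees with an independent superposition
           implementation", {
  set.seed(6)
  ref <- matrix(rnorm(45), ncol = 3)
  mods <- list(ref + matrix(rnorm(45, 0, 0.4), ncol = 3),
               rigid_transform(ref + matrix(rnorm(45, 0, 0.7),
                                            ncol = 3)))
  ens <- toy_ensemble(mods)
  out <- cross_rmsd(ens, ref)
  oracle <- vapply(mods, function(m)
    bio3d::rmsd(as.vector(t(ref)), as.vector(t(m)), fit = TRUE),
    numeric(1))
  # bio3d reports values rounded to three decimals
  expect_lt(max(abs(out$per_model - oracle)), 6e-4)

  # reference identical to the model gives zero
  expect_equal(cross_rmsd(toy_ensemble(list(ref)), ref)$mean, 0,
               tolerance = 1e-10)
  # pairing must match atom for atom
  expect_error(cross_rmsd(ens, ref[1:10, ]), "pairing mismatch")
})

test_that("atom selections behave: backbone, residues, terminal trim", {
  at <- data.frame(
    atom = rep(c("N", "CA", "C", "O", "CB"), times = 10),
    residue = rep(1:10, each = 5),
    resname = "ALA", chain = rep(c("A", "B"), each = 25),
    element = "C")
  ens <- structure_ensemble(at, matrix(rnorm(150), ncol = 3))
  bb <- select_atoms(ens, backbone = TRUE)
  expect_equal(sum(bb), 40)
  trim <- select_atoms(ens, backbone = TRUE, trim_termini = 1)
  # each chain has 5 residues; trimming one per terminus leaves 3
  expect_equal(sum(trim), 2 * 3 * 4)
  sel <- select_atoms(ens, residues = 2:3, chains = "A")
  expect_equal(sum(sel), 10)
})

test_that("N-H vectors are unit, skip prolines, and reconstructed
           hydrogens agree with explicit ones", {
  # two-residue backbone with an explicit amide H on residue 2
  N1 <- c(0, 0, 0); CA1 <- c(1.46, 0, 0); C1 <- c(2.0, 1.4, 0)
  O1 <- C1 + c(0.4, 0.1, 1.1)
  N2 <- c(3.33, 1.45, 0); CA2 <- c(4.2, 2.6, 0)
  u1 <- (CA2 - N2) / sqrt(sum((CA2 - N2)^2))
  u2 <- (C1 - N2) / sqrt(sum((C1 - N2)^2))
  b <- -(u1 + u2); b <- b / sqrt(sum(b^2))
  # explicit H tilted ~3 degrees off the exact bisector
  tilt <- diag(3) + matrix(c(0, -0.05, 0, 0.05, 0, 0, 0, 0, 0), 3, 3)
  bh <- tilt %*% b; bh <- bh / sqrt(sum(bh^2))
  H2 <- N2 + 1.02 * as.vector(bh)

  at <- data.frame(
    atom = c("N", "CA", "C", "O", "N", "CA", "H"),
    residue = c(1, 1, 1, 1, 2, 2, 2),
    resname = c(rep("ALA", 4), rep("GLY", 3)),
    chain = "A", element = c("N", "C", "C", "O", "N", "C", "H"))
  xyz <- rbind(N1, CA1, C1, O1, N2, CA2, H2)
  ens <- structure_ensemble(at, xyz)

  v_explicit <- nh_vectors(ens)
  expect_equal(nrow(v_explicit), 1) # residue 1 has no preceding C
  expect_false(v_explicit$reconstructed)
  expect_equal(sqrt(v_explicit$x^2 + v_explicit$y^2 + v_explicit$z^2), 1,
               tolerance = 1e-12)

  at_noH <- at[at$atom != "H", ]
  ens_noH <- structure_ensemble(at_noH, xyz[1:6, ])
  v_rec <- nh_vectors(ens_noH)
  expect_true(v_rec$reconstructed)
  cosang <- sum(v_rec[, c("x", "y", "z")] *
                  v_explicit[, c("x", "y", "z")])
  expect_lt(acos(min(cosang, 1)) * 180 / pi, 5)

  at_pro <- at
  at_pro$resname[at_pro$residue == 2] <- "PRO"
  expect_equal(nrow(nh_vectors(structure_ensemble(at_pro, xyz))), 0)
})

test_that("multi-model PDB files are read into ensembles", {
  line <- function(i, name, res, x, y, z, el)
    sprintf("ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, name, res, res, x, y, z, el)
  mdl <- function(k, shift) c(
    sprintf("MODEL %8d", k),
    line(1, "N", 1, 0 + shift, 0, 0, "N"),
    line(2, "CA", 1, 1.46 + shift, 0, 0, "C"),
    line(3, "C", 1, 2.0 + shift, 1.4, 0, "C"),
    line(4, "O", 1, 2.4 + shift, 1.5, 1.1, "O"),
    "ENDMDL")
  path <- tempfile(fileext = ".pdb")
  writeLines(c(mdl(1, 0), mdl(2, 0.5), "END"), path)
  ens <- read_pdb_ensemble(path)
  expect_equal(ens$n_models, 2)
  expect_equal(nrow(ens$atoms), 4)
  expect_equal(ens$xyz[2, 1, 1] - ens$xyz[1, 1, 1], 0.5)
  # a pure translation superposes to zero
  expect_equal(superpose_stats(ens)$mean, 0, tolerance = 1e-10)
})

test_that("chemical-shift differences flag at the inclusive threshold
           and keep missing residues as no-data", {
  a <- data.frame(residue = 1:4, CB = c(30, 31, 32, 33))
  b <- data.frame(residue = c(1, 2, 3), CB = c(30, 31.7, 31.5))
  out <- shift_deltas(a, b, "CB", flag_threshold = 0.7)
  expect_equal(out$delta[1:3], c(0, -0.7, 0.5))
  expect_equal(out$flag[1:3], c(FALSE, TRUE, FALSE)) # inclusive >= 0.7
  expect_true(is.na(out$delta[4]))
  expect_false(out$flag[4])
  expect_error(shift_deltas(a, b, "CA"), "absent")
})
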
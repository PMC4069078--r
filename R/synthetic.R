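# Preset parameter sets emulating a thermostable beta-barrel protein in
# its ligand-bound and free forms at the two study temperatures. Strand
# and loop S2 distributions are truncated normals anchored to the
# secondary-structure averages; noise levels per observable and field are
# the average measurement errors of the corresponding condition.
.truth_presets <- list(
  bound_58C = list(
    temp_K = 331.15, tau_c = 13.0e-9,
    strand = c(mean = 0.89, sd = 0.02), loop = c(mean = 0.75, sd = 0.08),
    terminus = c(mean = 0.45, sd = 0.10),
    rex_frac = 0.03, rex_range = c(1.6, 3.1),
    noise = list(`800` = c(R1 = 0.04, R2 = 0.40, NOE = 0.04),
                 `600` = c(R1 = 0.03, R2 = 0.31, NOE = 0.06))),
  free_58C = list(
    temp_K = 331.15, tau_c = 13.2e-9,
    strand = c(mean = 0.87, sd = 0.02), loop = c(mean = 0.74, sd = 0.08),
    terminus = c(mean = 0.45, sd = 0.10),
    rex_frac = 0.08, rex_range = c(2.0, 5.1),
    noise = list(`800` = c(R1 = 0.03, R2 = 0.31, NOE = 0.05),
                 `600` = c(R1 = 0.03, R2 = 0.48, NOE = 0.04))),
  bound_40C = list(
    temp_K = 313.15, tau_c = 18.0e-9,
    strand = c(mean = 0.89, sd = 0.02), loop = c(mean = 0.77, sd = 0.08),
    terminus = c(mean = 0.50, sd = 0.10),
    rex_frac = 0.10, rex_range = c(1.0, 4.0),
    noise = list(`800` = c(R1 = 0.03, R2 = 0.70, NOE = 0.04)))
)

# truncated-normal draws on [lo, hi] by rejection
.rtrunc <- function(n, mean, sd, lo = 0, hi = 1) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

# residue ids starting at `start`, honouring the two-residue numbering
# gap after position 54 (construct numbering: 54 is followed by 57)
.residue_ids <- function(n, start = 3, gap_after = 54, gap_len = 2) {
  ids <- integer(0)
  i <- start
  while (length(ids) < n) {
    ids <- c(ids, i)
    i <- i + 1
    if (i == gap_after + 1) i <- i + gap_len
  }
  ids
}

#' Generate a ground-truth model-free parameter set
#'
#' Draws per-residue S2, te and Rex for a synthetic protein with
#' `n_strand` residues in secondary structure and `n_loop` residues in
#' loops, using a named preset that fixes the sampling distributions,
#' the rotational correlation time and the per-observable noise levels.
#' Strand residues draw S2 near the preset strand mean; loop residues
#' are lower and more dispersed. A configurable fraction of residues
#' receives an exchange contribution Rex > 0, and optionally one
#' designated "hinge" loop residue gets a very low S2 (~0.2) with a
#' nanosecond te, mimicking a mobile glycine hinge.
#'
#' @param n_strand,n_loop residue counts (>= 0)
#' @param seed integer RNG seed; identical seeds give identical truths
#' @param profile preset name: `"bound_58C"`, `"free_58C"`,
#'   `"bound_40C"` or `"custom"` (then supply `preset`)
#' @param n_terminus additional flexible terminal residues (default 0)
#' @param hinge if TRUE, one loop residue becomes a low-S2 hinge
#' @param rex_frac fraction of residues with Rex > 0; default from preset
#' @param anisotropy tensor anisotropy D_par/D_perp (default 1, isotropic)
#' @param theta,phi tensor axis angles (degrees) when anisotropic
#' @param preset full preset list for `profile = "custom"`
#' @return object of class `mf_truth`: list with `residues` (data.frame
#'   `residue`, `class`, `S2`, `te`, `rex`), `tensor`, `temp_K`, `noise`,
#'   `profile`, `seed`
#' @export
#' @examples
#' tr <- gen_truth(50, 20, seed = 7, profile = "bound_58C")
#' head(tr$residues)
gen_truth <- function(n_strand, n_loop, seed, profile = "bound_58C",
                      n_terminus = 0, hinge = FALSE, rex_frac = NULL,
                      anisotropy = 1, theta = 0, phi = 0, preset = NULL) {
  stopifnot(n_strand >= 0, n_loop >= 0, n_terminus >= 0)
  if (profile == "custom") {
    if (is.null(preset)) stop("profile 'custom' needs a preset list")
    p <- preset
  } else {
    if (!profile %in% names(.truth_presets))
      stop(sprintf("unknown profile '%s'", profile))
    p <- .truth_presets[[profile]]
  }
  if (is.null(rex_frac)) rex_frac <- p$rex_frac

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  n <- n_strand + n_loop + n_terminus
  cls <- c(rep("strand", n_strand), rep("loop", n_loop),
           rep("terminus", n_terminus))
  S2 <- c(if (n_strand) .rtrunc(n_strand, p$strand["mean"], p$strand["sd"]),
          if (n_loop) .rtrunc(n_loop, p$loop["mean"], p$loop["sd"]),
          if (n_terminus) .rtrunc(n_terminus, p$terminus["mean"],
                                  p$terminus["sd"]))
  # te: tens of ps in strands, broader (up to ns) in loops and termini
  te <- c(if (n_strand) stats::runif(n_strand, 10e-12, 50e-12),
          if (n_loop) exp(stats::runif(n_loop, log(20e-12), log(2e-9))),
          if (n_terminus) exp(stats::runif(n_terminus, log(100e-12),
                                           log(3e-9))))
  rex <- numeric(n)
  n_rex <- round(rex_frac * n)
  if (n_rex > 0) {
    idx <- sample.int(n, n_rex)
    rex[idx] <- stats::runif(n_rex, p$rex_range[1], p$rex_range[2])
  }
  if (hinge && n_loop > 0) {
    h <- n_strand + sample.int(n_loop, 1)
    S2[h] <- 0.2; te[h] <- 1.5e-9
  }
  residues <- if (n > 0)
    data.frame(residue = .residue_ids(n), class = cls, S2 = S2, te = te,
               rex = rex)
  else
    data.frame(residue = integer(0), class = character(0),
               S2 = numeric(0), te = numeric(0), rex = numeric(0))
  out <- list(residues = residues,
              tensor = diffusion_tensor(tau_c = p$tau_c,
                                        anisotropy = anisotropy,
                                        theta = theta, phi = phi),
              temp_K = p$temp_K, noise = p$noise, profile = profile,
              seed = seed)
  class(out) <- "mf_truth"
  out
}

#' Simulate relaxation records from a ground truth
#'
#' Forward model: [back_calculate()] per residue and condition; in noisy
#' mode independent Gaussian noise with the per-observable sigma of the
#' truth's noise table is added and sigma is recorded as the error. In
#' noiseless mode the exact back-calculated values are returned (errors
#' still carry the nominal sigma so chi-square fitting is well posed).
#'
#' @param truth an `mf_truth` from [gen_truth()]
#' @param conditions data.frame with columns `field_MHz` and `temp_K`;
#'   every temperature must have a tensor (the truth's own temperature
#'   uses `truth$tensor`; others must appear in `tensors`)
#' @param noise logical: add noise?
#' @param seed RNG seed for the noise draws
#' @param tensors named list of [diffusion_tensor()] keyed by temperature
#'   (as character, e.g. `"313.15"`) for conditions at other temperatures
#' @param vectors optional bond vectors (`residue`, `x`, `y`, `z`) for
#'   anisotropic truths
#' @param rex_ref_MHz field the truth's rex values are referenced to
#' @return relaxation table: `residue`, `field_MHz`, `temp_K`, `R1`,
#'   `R1_err`, `R2`, `R2_err`, `NOE`, `NOE_err`
#' @export
simulate_relaxation <- function(truth,
                                conditions = data.frame(
                                  field_MHz = c(600, 800),
                                  temp_K = truth$temp_K),
                                noise = TRUE, seed = truth$seed + 1,
                                tensors = NULL, vectors = NULL,
                                rex_ref_MHz = 800) {
  res <- truth$residues
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- list()
  for (i in seq_len(nrow(conditions))) {
    f <- conditions$field_MHz[i]
    tK <- conditions$temp_K[i]
    tn <- if (abs(tK - truth$temp_K) < 1e-9) truth$tensor
          else tensors[[as.character(tK)]]
    if (is.null(tn))
      stop(sprintf("no diffusion tensor defined for temperature %.2f K", tK))
    alpha <- rep(0, nrow(res))
    if (tn$kind == "axial" && !is.null(vectors)) {
      m <- match(res$residue, vectors$residue)
      alpha <- as.numeric(.angle_to_axis(
        tn, as.matrix(vectors[m, c("x", "y", "z")])))
    }
    fw <- .relax_forward(res$S2, res$te, res$rex, tn, alpha, f,
                         rex_ref_MHz = rex_ref_MHz)
    sig <- truth$noise[[as.character(f)]]
    if (is.null(sig)) sig <- c(R1 = 0.03, R2 = 0.40, NOE = 0.04)
    if (any(sig < 0)) stop("negative noise level")
    n <- nrow(res)
    add <- function(v, s) if (noise) v + stats::rnorm(n, 0, s) else v
    out[[i]] <- data.frame(
      residue = res$residue, field_MHz = f, temp_K = tK,
      R1 = add(fw$R1, sig["R1"]), R1_err = sig[["R1"]],
      R2 = add(fw$R2, sig["R2"]), R2_err = sig[["R2"]],
      NOE = add(fw$NOE, sig["NOE"]), NOE_err = sig[["NOE"]])
  }
  do.call(rbind, out)
}

#' Default relaxation delay grids
#'
#' The inversion-recovery (T1) and CPMG (T2) time-point schedules used
#' throughout: T1 at 10, 60, 110, 330, 660, 900, 1100, 1500, 1800, 2600,
#' 3500 ms; T2 at 10, 30, 50, 70, 90, 110 ms.
#'
#' @return numeric vector of time points in seconds
#' @export
default_t1_grid <- function() {
  c(10, 60, 110, 330, 660, 900, 1100, 1500, 1800, 2600, 3500) * 1e-3
}

#' @rdname default_t1_grid
#' @export
default_t2_grid <- function() c(10, 30, 50, 70, 90, 110) * 1e-3

#' Default H/D exchange sampling grid
#'
#' First point at 900 s (~15 min after dissolution), second near 25.5
#' min, then roughly log-spaced out to 96 h.
#'
#' @return time points in seconds
#' @export
default_hdx_grid <- function() {
  c(900, 1531, 3600, 7200, 14400, 28800, 57600, 115200, 230400, 345600)
}

#' Simulate an exponential decay intensity series
#'
#' I(t) = amplitude * exp(-rate * t) plus optional Gaussian noise.
#' Time points listed in `duplicate_points` are acquired twice and
#' flagged as replicates, mirroring duplicate spectra used for
#' uncertainty estimation.
#'
#' @param rate decay rate (s^-1), > 0
#' @param amplitude initial intensity
#' @param timepoints acquisition times (s)
#' @param noise_sd Gaussian noise s.d. (intensity units)
#' @param duplicate_points subset of `timepoints` acquired in duplicate
#' @param residue residue id stored in the table
#' @param seed RNG seed
#' @return intensity series data.frame: `residue`, `time_s`,
#'   `intensity`, `replicate`
#' @export
#' @examples
#' s <- simulate_decay_series(10, timepoints = default_t2_grid())
#' fit_rate(s)$rate
simulate_decay_series <- function(rate, amplitude = 1,
                                  timepoints = default_t2_grid(),
                                  noise_sd = 0, duplicate_points = NULL,
                                  residue = 1L, seed = 1) {
  stopifnot(rate > 0, length(timepoints) >= 1, noise_sd >= 0)
  tt <- c(timepoints, duplicate_points)
  rep_flag <- c(rep(1L, length(timepoints)),
                rep(2L, length(duplicate_points)))
  o <- order(tt, rep_flag)
  tt <- tt[o]; rep_flag <- rep_flag[o]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  I <- amplitude * exp(-rate * tt) + stats::rnorm(length(tt), 0, noise_sd)
  data.frame(residue = residue, time_s = tt, intensity = I,
             replicate = rep_flag)
}

#' Simulate an H/D exchange build-up intensity series
#'
#' Emits exactly the three-parameter build-up form
#' I(t) = I_inf + I0 * (1 - exp(-k_ex * t)); `k_ex = 0` yields a flat
#' series at `I_inf`.
#'
#' @param k_ex exchange rate (s^-1), >= 0
#' @param I0 build-up amplitude
#' @param I_inf intensity offset at t = 0
#' @param timepoints acquisition times (s)
#' @param noise_sd Gaussian noise s.d.
#' @param residue residue id
#' @param seed RNG seed
#' @return intensity series data.frame as in [simulate_decay_series()]
#' @export
simulate_hdx_series <- function(k_ex, I0 = 1, I_inf = 0,
                                timepoints = default_hdx_grid(),
                                noise_sd = 0, residue = 1L, seed = 1) {
  stopifnot(k_ex >= 0, noise_sd >= 0)
  if (!length(timepoints)) stop("empty time grid")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  I <- I_inf + I0 * (1 - exp(-k_ex * timepoints)) +
    stats::rnorm(length(timepoints), 0, noise_sd)
  data.frame(residue = residue, time_s = timepoints, intensity = I,
             replicate = 1L)
}

#' Generate unit N-H bond vectors
#'
#' `uniform_sphere` draws isotropically distributed unit vectors;
#' `barrel_like` concentrates the polar angle in two bands around the
#' molecular axis, emulating the alternating up/down amide geometry of a
#' beta barrel.
#'
#' @param n number of vectors (>= 1)
#' @param seed RNG seed
#' @param mode `"uniform_sphere"` or `"barrel_like"`
#' @param residues residue ids (default 1:n)
#' @return data.frame `residue`, `x`, `y`, `z` with unit rows
#' @export
gen_bond_vectors <- function(n, seed = 1,
                             mode = c("uniform_sphere", "barrel_like"),
                             residues = NULL) {
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (mode == "uniform_sphere") {
    v <- matrix(stats::rnorm(3 * n), n, 3)
  } else {
    # polar angle ~ 30 deg from the +/- axis, azimuth uniform
    ca <- pmin(1, pmax(-1, stats::rnorm(n, cos(pi / 6), 0.08))) *
      sample(c(-1, 1), n, replace = TRUE)
    sa <- sqrt(1 - ca^2)
    ph <- stats::runif(n, 0, 2 * pi)
    v <- cbind(sa * cos(ph), sa * sin(ph), ca)
  }
  v <- v / sqrt(rowSums(v^2))
  if (is.null(residues)) residues <- .residue_ids(n)
  data.frame(residue = residues, x = v[, 1], y = v[, 2], z = v[, 3])
}
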
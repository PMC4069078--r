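# rigid-rotor R2/R1 ratio for an isotropic tumbler, used both as the
# forward model of local_tm and inside the tensor fit (with axial terms).
.rigid_ratio_iso <- function(tau_m, field_MHz, constants = NULL) {
  tn <- diffusion_tensor(tau_c = tau_m)
  fw <- .relax_forward(S2 = 1, te = 0, rex = 0, tensor = tn, alpha = 0,
                       field_MHz = field_MHz, constants = constants)
  fw$R2 / fw$R1
}

#' Local rotational correlation time from an R2/R1 ratio
#'
#' Solves the rigid-rotor (S2 = 1, te = 0, Rex = 0) isotropic R2/R1 ratio
#' equation for tau_m by bisection on the window 0.5-50 ns, where the
#' ratio is monotonic in tau_m so the root is unique.
#'
#' @param R2_over_R1 observed ratio (dimensionless), may be a vector
#' @param field_MHz spectrometer 1H frequency (MHz)
#' @param constants optional overrides of [nmr_constants]
#' @return tau_m in seconds; NA (with a warning) for ratios outside the
#'   attainable range on the window
#' @export
#' @examples
#' rho <- local_tm_forward(13e-9, 800)
#' local_tm(rho, 800) * 1e9  # 13 ns
local_tm <- function(R2_over_R1, field_MHz, constants = NULL) {
  stopifnot(all(R2_over_R1 > 0, na.rm = TRUE))
  lo <- 0.5e-9; hi <- 50e-9
  rlo <- .rigid_ratio_iso(lo, field_MHz, constants)
  rhi <- .rigid_ratio_iso(hi, field_MHz, constants)
  vapply(R2_over_R1, function(r) {
    if (is.na(r)) return(NA_real_)
    if (r < rlo || r > rhi) {
      warning(sprintf(
        "R2/R1 = %.3f outside attainable range [%.3f, %.3f]; residue excluded",
        r, rlo, rhi))
      return(NA_real_)
    }
    stats::uniroot(function(tm) .rigid_ratio_iso(tm, field_MHz, constants) - r,
                   c(lo, hi), tol = 1e-15)$root
  }, numeric(1))
}

#' Forward rigid-rotor R2/R1 ratio
#'
#' Convenience forward model paired with [local_tm()].
#'
#' @param tau_m isotropic correlation time (s)
#' @inheritParams local_tm
#' @return R2/R1 ratio
#' @export
local_tm_forward <- function(tau_m, field_MHz, constants = NULL) {
  vapply(tau_m, .rigid_ratio_iso, numeric(1), field_MHz = field_MHz,
         constants = constants)
}

#' Global correlation time from trimmed residue-specific values
#'
#' Computes residue-specific local correlation times from R2/R1 and
#' averages them over a trimmed subset: residues with hetNOE below
#' `noe_min` (large-amplitude internal motion) are excluded, then
#' residues whose R2/R1 deviates from the mean by more than `sd_multiple`
#' standard deviations are excluded (one iteration), and the global
#' isotropic correlation time is reported as the mean of the surviving
#' local values.
#'
#' @param records relaxation table (one condition): columns `residue`,
#'   `field_MHz`, `R1`, `R2`, `NOE`
#' @param noe_min hetNOE threshold (default 0.65)
#' @param sd_multiple R2/R1 outlier cut in standard deviations (default 1)
#' @param constants optional overrides of [nmr_constants]
#' @return list with `tau_c` (s), `sd` (s), `included` residue ids and
#'   `local_tm` (named vector, s)
#' @export
trim_and_average <- function(records, noe_min = 0.65, sd_multiple = 1,
                             constants = NULL) {
  stopifnot(length(unique(records$field_MHz)) == 1)
  ok <- !is.na(records$R1) & !is.na(records$R2)
  rec <- records[ok, , drop = FALSE]
  if (nrow(rec) < 5) stop("need at least 5 usable residues")
  keep <- is.na(rec$NOE) | rec$NOE >= noe_min
  rec <- rec[keep, , drop = FALSE]
  ratio <- rec$R2 / rec$R1
  dev <- abs(ratio - mean(ratio))
  keep2 <- dev <= sd_multiple * stats::sd(ratio)
  rec <- rec[keep2, , drop = FALSE]
  if (nrow(rec) < 5)
    stop(sprintf("only %d residues survive trimming; need at least 5",
                 nrow(rec)))
  tm <- local_tm(rec$R2 / rec$R1, rec$field_MHz[1], constants)
  names(tm) <- rec$residue
  tm <- tm[!is.na(tm)]
  if (length(tm) < 5) stop("fewer than 5 residues with invertible R2/R1")
  list(tau_c = mean(tm), sd = stats::sd(tm),
       included = names(tm), local_tm = tm)
}

# chi2 of observed vs back-calculated R2/R1 under a rigid axial tensor.
# par = c(log tau_c [s], log anisotropy, theta [deg], phi [deg])
.tensor_chi2 <- function(par, ratio, sigma, vectors, field_MHz, constants) {
  tn <- diffusion_tensor(tau_c = exp(par[1]), anisotropy = exp(par[2]),
                         theta = par[3], phi = par[4])
  alpha <- as.numeric(.angle_to_axis(tn, vectors))
  fw <- .relax_forward(S2 = 1, te = 0, rex = 0, tensor = tn, alpha = alpha,
                       field_MHz = field_MHz, constants = constants)
  sum(((ratio - fw$R2 / fw$R1) / sigma)^2)
}

#' Fit an axially symmetric rotational diffusion tensor
#'
#' Minimizes the chi-square of observed versus back-calculated R2/R1
#' ratios over (D_perp, D_par, theta, phi), assuming rigid local dynamics
#' for the supplied residues. A multi-start grid over the axis angles and
#' the anisotropy (covering both the oblate and the prolate branch) is
#' followed by local refinement; the two branch minima are reported
#' separately, labelled first/second minimum by chi-square.
#'
#' @param records relaxation table at one field: columns `residue`, `R1`,
#'   `R2`, optionally `R1_err`, `R2_err`, `field_MHz`
#' @param vectors bond-vector data.frame with columns `residue`, `x`,
#'   `y`, `z` (unit N-H vectors in the molecular frame)
#' @param field_MHz spectrometer frequency; defaults to the table's
#' @param constants optional overrides of [nmr_constants]
#' @return list with `tensor` (best [diffusion_tensor()]), `chi2`,
#'   `anisotropy`, `minima` (data.frame of the oblate and prolate
#'   solutions), `n_residues`
#' @export
fit_axial_tensor <- function(records, vectors, field_MHz = NULL,
                             constants = NULL) {
  m <- match(records$residue, vectors$residue)
  ok <- !is.na(m) & !is.na(records$R1) & !is.na(records$R2)
  if (sum(ok) < 10) stop("need at least 10 residues with R1, R2 and vectors")
  rec <- records[ok, , drop = FALSE]
  V <- as.matrix(vectors[m[ok], c("x", "y", "z")])
  if (qr(V)$rank < 2) stop("degenerate (collinear) bond-vector set")
  if (is.null(field_MHz)) field_MHz <- rec$field_MHz[1]
  ratio <- rec$R2 / rec$R1
  sigma <- if (all(c("R1_err", "R2_err") %in% names(rec)) &&
               !anyNA(rec$R1_err) && !anyNA(rec$R2_err) &&
               all(rec$R1_err > 0))
    ratio * sqrt((rec$R1_err / rec$R1)^2 + (rec$R2_err / rec$R2)^2)
  else rep(stats::sd(ratio) / 2 + 1e-6, length(ratio))

  tc0 <- mean(local_tm(ratio, field_MHz, constants), na.rm = TRUE)
  if (is.na(tc0)) tc0 <- 13e-9
  starts <- expand.grid(theta = c(10, 45, 80), phi = c(20, 90, 160),
                        xi = c(0.85, 1.15))
  p0s <- lapply(seq_len(nrow(starts)), function(i)
    c(log(tc0), log(starts$xi[i]), starts$theta[i], starts$phi[i]))
  # cheap pre-screen of the grid, then refine the best starts per branch
  v0 <- vapply(p0s, .tensor_chi2, numeric(1), ratio = ratio,
               sigma = sigma, vectors = V, field_MHz = field_MHz,
               constants = constants)
  br0 <- ifelse(starts$xi < 1, "oblate", "prolate")
  keep <- unlist(lapply(c("oblate", "prolate"), function(b) {
    i <- which(br0 == b)
    i[order(v0[i])[seq_len(min(2, length(i)))]]
  }))
  fits <- lapply(p0s[keep], function(p0)
    stats::optim(p0, .tensor_chi2, ratio = ratio, sigma = sigma,
                 vectors = V, field_MHz = field_MHz, constants = constants,
                 method = "Nelder-Mead",
                 control = list(maxit = 1500, reltol = 1e-13)))
  # refine once more from each candidate to tighten convergence
  fits <- lapply(fits, function(f)
    stats::optim(f$par, .tensor_chi2, ratio = ratio, sigma = sigma,
                 vectors = V, field_MHz = field_MHz, constants = constants,
                 method = "Nelder-Mead",
                 control = list(maxit = 1500, reltol = 1e-14)))
  vals <- vapply(fits, `[[`, numeric(1), "value")
  pars <- t(vapply(fits, `[[`, numeric(4), "par"))
  branch <- ifelse(exp(pars[, 2]) < 1, "oblate", "prolate")
  pick <- function(b) {
    i <- which(branch == b)
    if (!length(i)) return(NULL)
    i[which.min(vals[i])]
  }
  rows <- list()
  for (b in c("oblate", "prolate")) {
    i <- pick(b)
    if (is.null(i)) next
    p <- pars[i, ]
    tn <- diffusion_tensor(tau_c = exp(p[1]), anisotropy = exp(p[2]),
                           theta = p[3] %% 180, phi = p[4] %% 360)
    rows[[b]] <- data.frame(branch = b, chi2 = vals[i],
                            anisotropy = tn$D_par / tn$D_perp,
                            tau_c_ns = tn$tau_c * 1e9,
                            D_perp = tn$D_perp, D_par = tn$D_par,
                            theta = tn$theta, phi = tn$phi)
  }
  minima <- do.call(rbind, rows)
  minima <- minima[order(minima$chi2), , drop = FALSE]
  minima$label <- paste0(seq_len(nrow(minima)),
                         c("st", "nd")[seq_len(nrow(minima))], "_minimum")
  bestp <- pars[which.min(vals), ]
  tensor <- diffusion_tensor(tau_c = exp(bestp[1]),
                             anisotropy = exp(bestp[2]),
                             theta = bestp[3] %% 180, phi = bestp[4] %% 360)
  list(tensor = tensor, chi2 = min(vals),
       anisotropy = tensor$D_par / tensor$D_perp, minima = minima,
       n_residues = nrow(rec), included = rec$residue)
}

#' Relative principal moments of the inertia tensor
#'
#' Center-of-mass inertia tensor eigen-decomposition; moments are sorted
#' descending and normalized to the largest. Invariant under rigid-body
#' motion of the coordinates.
#'
#' @param xyz n x 3 matrix of coordinates (angstrom)
#' @param masses atomic masses; default unit masses
#' @return list with `moments` (length 3, largest = 1) and `axes`
#'   (columns = principal axes, same order)
#' @export
inertia_moments <- function(xyz, masses = NULL) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) >= 4)
  if (is.null(masses)) masses <- rep(1, nrow(xyz))
  com <- colSums(xyz * masses) / sum(masses)
  r <- sweep(xyz, 2, com)
  r2 <- rowSums(r^2)
  I <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    I[i, j] <- sum(masses * ((i == j) * r2 - r[, i] * r[, j]))
  if (qr(r)$rank < 2) stop("degenerate geometry")
  e <- eigen(I, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  mom <- e$values[ord]
  list(moments = mom / mom[1], axes = e$vectors[, ord])
}

#' Extrapolate a rotational correlation time in temperature
#'
#' Fits a least-squares line tau_c = a + b * (eta(T) / T) through the
#' supplied (temperature, tau_c) points, using the pure-water viscosity
#' correlation [water_viscosity()], and evaluates it at `target_T`. With
#' Stokes-Einstein-Debye tumbling tau_c is proportional to eta/T, so two
#' temperatures suffice to pin the line.
#'
#' @param temps_K temperatures (K) of the measured points
#' @param tau_c correlation times (s) at those temperatures
#' @param target_T temperature (K) to extrapolate to
#' @return extrapolated tau_c (s)
#' @export
#' @examples
#' tc_extrapolate(c(331.15, 313.15), c(13.0e-9, 18.0e-9), 298.15) * 1e9
tc_extrapolate <- function(temps_K, tau_c, target_T) {
  stopifnot(length(temps_K) == length(tau_c))
  if (length(unique(temps_K)) < 2)
    stop("need at least 2 points at distinct temperatures")
  if (target_T < 273.15 || target_T > 380)
    warning("target temperature outside the liquid-water sanity window")
  x <- water_viscosity(temps_K) / temps_K
  fit <- stats::lm(tau_c ~ x)
  unname(stats::predict(fit, data.frame(
    x = water_viscosity(target_T) / target_T)))
}

#' Theoretical rotational correlation time estimates
#'
#' Two standard order-of-magnitude estimates of the overall rotational
#' correlation time of a globular protein at room temperature:
#' \describe{
#'   \item{empirical_mw}{the empirical molecular-weight correlation
#'     tau_c = 0.5998 * MW + 0.1674 (tau_c in ns, MW in kDa)}
#'   \item{stokes_einstein}{hard-sphere Stokes-Einstein-Debye
#'     tau_c = 4 pi eta r^3 / (3 k_B T), with
#'     r = (3 MW vbar / (4 pi N_A))^(1/3) + hydration shell}
#' }
#'
#' @param MW_kDa molecular weight in kDa
#' @param method `"empirical_mw"` or `"stokes_einstein"`
#' @param vbar partial specific volume (cm^3/g), default 0.73
#' @param hydration_A hydration shell thickness (angstrom), default 3.2
#' @param temp_K temperature (K), default 298.15
#' @param eta viscosity (Pa s); default pure water at `temp_K`
#' @return tau_c in nanoseconds
#' @export
#' @examples
#' tc_theoretical(56, "empirical_mw")     # 33.76 ns
#' tc_theoretical(56, "stokes_einstein")  # ~21 ns
tc_theoretical <- function(MW_kDa,
                           method = c("empirical_mw", "stokes_einstein"),
                           vbar = 0.73, hydration_A = 3.2,
                           temp_K = 298.15, eta = NULL) {
  method <- match.arg(method)
  stopifnot(MW_kDa >= 0)
  if (method == "empirical_mw") return(0.5998 * MW_kDa + 0.1674)
  stopifnot(vbar > 0, hydration_A >= 0, temp_K > 0)
  if (is.null(eta)) eta <- water_viscosity(temp_K)
  stopifnot(eta > 0)
  cst <- nmr_constants
  # anhydrous molecular volume in m^3 (MW g/mol, vbar cm^3/g)
  V <- MW_kDa * 1000 * vbar / cst$N_A * 1e-6
  r <- (3 * V / (4 * pi))^(1 / 3) + hydration_A * 1e-10
  tau <- 4 * pi * eta * r^3 / (3 * cst$k_B * temp_K)
  tau * 1e9
}
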
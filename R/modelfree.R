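# coefficients and correlation times of the overall-tumbling terms.
# isotropic: single term tau_m = 1/(6 D_iso).
# axial: A1 = (1.5 cos^2 a - 0.5)^2, A2 = 3 sin^2 a cos^2 a,
#        A3 = 0.75 sin^4 a with 1/tau = {6 Dperp, 5 Dperp + Dpar,
#        2 Dperp + 4 Dpar}. A1 + A2 + A3 = 1 for every angle.
.tensor_terms <- function(tensor, alpha = 0) {
  if (tensor$kind == "isotropic" || tensor$D_par == tensor$D_perp) {
    return(list(A = matrix(1, length(alpha), 1),
                tau = 1 / (6 * tensor$D_iso)))
  }
  ca2 <- cos(alpha)^2
  sa2 <- 1 - ca2
  A <- cbind((1.5 * ca2 - 0.5)^2, 3 * sa2 * ca2, 0.75 * sa2^2)
  tau <- 1 / c(6 * tensor$D_perp,
               5 * tensor$D_perp + tensor$D_par,
               2 * tensor$D_perp + 4 * tensor$D_par)
  list(A = A, tau = tau)
}

# model-free J(w) for one angular frequency, vectorized over the rows of
# terms$A (residues). S2, te, Sf2 recycle over residues.
.J_one <- function(w, terms, S2, te, Sf2 = 1) {
  n <- nrow(terms$A)
  acc <- numeric(n)
  for (k in seq_along(terms$tau)) {
    tk <- terms$tau[k]
    tp <- ifelse(te > 0, 1 / (1 / tk + 1 / te), 0)
    acc <- acc + terms$A[, k] *
      (S2 * tk / (1 + (w * tk)^2) + (Sf2 - S2) * tp / (1 + (w * tp)^2))
  }
  0.4 * acc
}

#' Model-free spectral density function
#'
#' Lipari-Szabo spectral density for overall tumbling described by an
#' isotropic or axially symmetric diffusion tensor, augmented by internal
#' motion with squared order parameter `S2` and effective correlation time
#' `te`. For the extended (two-time-scale) form pass `Sf2 < 1`, in which
#' case `S2` is the total order parameter `Sf2 * Ss2` and `te` is the slow
#' internal correlation time.
#'
#' @param omega angular frequency or vector thereof (rad/s)
#' @param S2 squared generalized order parameter in `[0, 1]`
#' @param te effective internal correlation time (s); 0 collapses the
#'   internal term
#' @param tensor a [diffusion_tensor()]
#' @param alpha angle (radians) between the N-H vector and the tensor
#'   symmetry axis; ignored for isotropic tensors
#' @param Sf2 fast-motion order parameter of the extended model (default 1)
#' @return J(omega) in s/rad, same length as `omega`
#' @export
#' @examples
#' tn <- diffusion_tensor(tau_c = 13e-9)
#' spectral_density(0, S2 = 1, te = 0, tensor = tn)  # (2/5) tau_m
spectral_density <- function(omega, S2, te = 0, tensor, alpha = 0, Sf2 = 1) {
  stopifnot(S2 >= 0, S2 <= 1, te >= 0, Sf2 >= S2 - 1e-12, Sf2 <= 1)
  terms <- .tensor_terms(tensor, alpha)
  vapply(omega, .J_one, numeric(1), terms = terms, S2 = S2, te = te,
         Sf2 = Sf2)
}

# dipolar and CSA interaction strengths
.interaction_constants <- function(field_MHz, constants = NULL) {
  cst <- .const(constants)
  w <- .omegas(field_MHz, constants)
  d <- cst$mu0 * cst$hbar * cst$gamma_H * cst$gamma_N /
    (4 * pi * cst$r_NH^3)
  list(dd = d^2 / 4, c2 = w$wN^2 * cst$csa_N^2 / 3, wH = w$wH, wN = w$wN,
       gamma_ratio = cst$gamma_H / cst$gamma_N)
}

# vectorized over residues: rows of `alpha`/`S2`/`te`/`rex`. Returns a
# data.frame R1, R2, NOE.
.relax_forward <- function(S2, te, rex, tensor, alpha, field_MHz,
                           rex_ref_MHz = 800, Sf2 = 1, constants = NULL) {
  ic <- .interaction_constants(field_MHz, constants)
  n <- max(length(S2), length(alpha))
  S2 <- rep_len(S2, n); te <- rep_len(te, n); rex <- rep_len(rex, n)
  Sf2 <- rep_len(Sf2, n); alpha <- rep_len(alpha, n)
  terms <- .tensor_terms(tensor, alpha)
  J0   <- .J_one(0, terms, S2, te, Sf2)
  JN   <- .J_one(ic$wN, terms, S2, te, Sf2)
  JH   <- .J_one(ic$wH, terms, S2, te, Sf2)
  JHmN <- .J_one(ic$wH - ic$wN, terms, S2, te, Sf2)
  JHpN <- .J_one(ic$wH + ic$wN, terms, S2, te, Sf2)
  R1 <- ic$dd * (JHmN + 3 * JN + 6 * JHpN) + ic$c2 * JN
  R2 <- ic$dd / 2 * (4 * J0 + JHmN + 3 * JN + 6 * JH + 6 * JHpN) +
    ic$c2 / 6 * (4 * J0 + 3 * JN) + rex * (field_MHz / rex_ref_MHz)^2
  NOE <- 1 + ic$dd * ic$gamma_ratio * (6 * JHpN - JHmN) / R1
  data.frame(R1 = R1, R2 = R2, NOE = NOE)
}

#' Back-calculate 15N relaxation rates from model-free parameters
#'
#' Standard 15N dipolar + CSA expressions evaluated from the model-free
#' spectral density at frequencies `{0, wN, wH, wH - wN, wH + wN}`. A
#' conformational-exchange term `rex` (referenced to `rex_ref_MHz`) is
#' added to R2 scaled by the square of the field ratio.
#'
#' @inheritParams spectral_density
#' @param rex exchange contribution to R2 (s^-1) at the reference field
#' @param field_MHz spectrometer 1H frequency (MHz)
#' @param rex_ref_MHz 1H frequency at which `rex` is referenced
#' @param constants optional overrides of [nmr_constants]
#' @return named list with elements `R1`, `R2` (s^-1) and `NOE`
#' @export
#' @examples
#' tn <- diffusion_tensor(tau_c = 13e-9)
#' back_calculate(S2 = 0.89, te = 30e-12, tensor = tn, field_MHz = 800)
back_calculate <- function(S2, te = 0, rex = 0, tensor, alpha = 0,
                           field_MHz, rex_ref_MHz = 800, Sf2 = 1,
                           constants = NULL) {
  stopifnot(field_MHz > 0)
  out <- .relax_forward(S2, te, rex, tensor, alpha, field_MHz,
                        rex_ref_MHz, Sf2, constants)
  list(R1 = out$R1, R2 = out$R2, NOE = out$NOE)
}

# ---- model-free fitting -----------------------------------------------

# observation vector and sigma vector from one residue's records
.mf_obs <- function(records) {
  obs <- c(); sig <- c(); what <- c(); fld <- c()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    for (q in c("R1", "R2", "NOE")) {
      v <- r[[q]]; e <- r[[paste0(q, "_err")]]
      if (!is.null(v) && !is.na(v)) {
        obs <- c(obs, v)
        sig <- c(sig, if (is.null(e) || is.na(e) || e <= 0) 1 else e)
        what <- c(what, q); fld <- c(fld, r$field_MHz)
      }
    }
  }
  list(obs = obs, sig = sig, what = what, field = fld)
}

.mf_models <- list(
  `1` = c("S2"),
  `2` = c("S2", "te"),
  `3` = c("S2", "rex"),
  `4` = c("S2", "te", "rex"),
  `5` = c("Sf2", "Ss2", "ts")
)

.mf_bounds <- list(
  S2 = c(0, 1), te = c(0, 5e-9), rex = c(0, 30),
  Sf2 = c(0, 1), Ss2 = c(0, 1), ts = c(0, 5e-9)
)

# chi2 for a parameter vector under one model
.mf_chi2 <- function(par, model, ob, tensor, alpha, rex_ref_MHz, constants) {
  p <- as.list(par)
  names(p) <- .mf_models[[model]]
  if (model == "5") {
    S2 <- p$Sf2 * p$Ss2; te <- p$ts; rex <- 0; Sf2 <- p$Sf2
  } else {
    S2 <- p$S2; te <- if (is.null(p$te)) 0 else p$te
    rex <- if (is.null(p$rex)) 0 else p$rex; Sf2 <- 1
  }
  chi2 <- 0
  for (f in unique(ob$field)) {
    idx <- ob$field == f
    calc <- .relax_forward(S2, te, rex, tensor, alpha, f, rex_ref_MHz,
                           Sf2, constants)
    cv <- c(R1 = calc$R1, R2 = calc$R2, NOE = calc$NOE)
    chi2 <- chi2 + sum(((ob$obs[idx] - cv[ob$what[idx]]) / ob$sig[idx])^2)
  }
  chi2
}

# grid of starting points for one model
.mf_starts <- function(model) {
  grid <- switch(model,
    `1` = expand.grid(S2 = c(0.2, 0.5, 0.7, 0.85, 0.95, 1.0)),
    `2` = expand.grid(S2 = c(0.2, 0.5, 0.7, 0.85, 0.95, 1.0),
                      te = c(20e-12, 100e-12, 500e-12, 2e-9)),
    `3` = expand.grid(S2 = c(0.2, 0.5, 0.7, 0.85, 0.95, 1.0),
                      rex = c(0.5, 3, 8)),
    `4` = expand.grid(S2 = c(0.5, 0.85), te = c(50e-12, 1e-9),
                      rex = c(0.5, 3, 8)),
    `5` = expand.grid(Sf2 = c(0.6, 0.85), Ss2 = c(0.5, 0.8),
                      ts = c(0.5e-9, 2e-9)))
  lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, , drop = FALSE]))
}

# fit one model; returns list(par, chi2)
.mf_fit_model <- function(model, ob, tensor, alpha, rex_ref_MHz, constants,
                          start = NULL) {
  pn <- .mf_models[[model]]
  lo <- vapply(pn, function(p) .mf_bounds[[p]][1], numeric(1))
  hi <- vapply(pn, function(p) .mf_bounds[[p]][2], numeric(1))
  # parameter scaling keeps te (~1e-10 s) workable in L-BFGS-B
  sc <- ifelse(pn %in% c("te", "ts"), 1e-10, 1)
  fn <- function(ps) .mf_chi2(ps * sc, model, ob, tensor, alpha,
                              rex_ref_MHz, constants)
  starts <- if (is.null(start)) .mf_starts(model) else list(start)
  if (is.null(start)) {
    vals <- vapply(starts, function(s) fn(s / sc), numeric(1))
    starts <- starts[order(vals)[seq_len(min(3, length(starts)))]]
  }
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s / sc, fn, method = "L-BFGS-B",
                   lower = lo / sc, upper = hi / sc,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value))
      best <- res
  }
  if (is.null(best)) return(NULL)
  list(par = stats::setNames(best$par * sc, pn), chi2 = best$value)
}

.mf_aicc <- function(chi2, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  chi2 + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Lipari-Szabo model-free fit for one residue
#'
#' Fits the five standard model-free parameterizations (S2; S2, te;
#' S2, Rex; S2, te, Rex; extended Sf2, Ss2, ts) to a residue's relaxation
#' records across one or more fields by chi-square minimization with a
#' multi-start grid followed by local refinement, selects a model by the
#' small-sample corrected information criterion, and estimates parameter
#' uncertainties by Monte Carlo resampling of the observables within
#' their stated errors.
#'
#' @param records data.frame with one row per (field, temperature)
#'   condition and columns `field_MHz`, `R1`, `R1_err`, `R2`, `R2_err`,
#'   `NOE`, `NOE_err` (missing observables as NA)
#' @param tensor [diffusion_tensor()] fixed beforehand (two-stage protocol)
#' @param alpha angle (radians) between this residue's N-H vector and the
#'   tensor axis
#' @param n_mc Monte Carlo resamples for errors (0 skips error estimation)
#' @param seed RNG seed for the resampling
#' @param models subset of model ids to consider (default `1:4`; add 5 for
#'   the extended model when data at two fields warrant it)
#' @param rex_ref_MHz field to which fitted `rex` is referenced
#' @param constants optional overrides of [nmr_constants]
#' @return one-row data.frame: `model`, `S2`, `S2_err`, `te`, `te_err`,
#'   `rex`, `rex_err`, `chi2`, `aicc`, `n_obs`. Parameters absent from the
#'   selected model are NA.
#' @export
fit_modelfree <- function(records, tensor, alpha = 0, n_mc = 0, seed = 1,
                          models = 1:4, rex_ref_MHz = 800,
                          constants = NULL) {
  ob <- .mf_obs(records)
  n <- length(ob$obs)
  if (n < 3) stop("model-free fit needs at least 3 observables")
  fits <- list()
  for (m in as.character(models)) {
    k <- length(.mf_models[[m]])
    fit <- .mf_fit_model(m, ob, tensor, alpha, rex_ref_MHz, constants)
    if (is.null(fit)) next
    fit$aicc <- .mf_aicc(fit$chi2, k, n)
    fits[[m]] <- fit
  }
  if (!length(fits)) stop("no model-free model converged")
  aiccs <- vapply(fits, `[[`, numeric(1), "aicc")
  sel <- names(fits)[which.min(aiccs)]
  best <- fits[[sel]]

  expand <- function(par, model) {
    if (model == "5")
      c(S2 = unname(par["Sf2"] * par["Ss2"]), te = unname(par["ts"]),
        rex = NA_real_)
    else
      c(S2 = unname(par["S2"]),
        te = if ("te" %in% names(par)) unname(par["te"]) else NA_real_,
        rex = if ("rex" %in% names(par)) unname(par["rex"]) else NA_real_)
  }
  pt <- expand(best$par, sel)

  err <- c(S2 = NA_real_, te = NA_real_, rex = NA_real_)
  if (n_mc > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    draws <- matrix(NA_real_, n_mc, 3,
                    dimnames = list(NULL, c("S2", "te", "rex")))
    for (i in seq_len(n_mc)) {
      ob_i <- ob
      ob_i$obs <- stats::rnorm(n, ob$obs, ob$sig)
      fit_i <- .mf_fit_model(sel, ob_i, tensor, alpha, rex_ref_MHz,
                             constants, start = best$par)
      if (!is.null(fit_i)) draws[i, ] <- expand(fit_i$par, sel)
    }
    err <- apply(draws, 2, stats::sd, na.rm = TRUE)
    err[is.na(pt)] <- NA_real_
  }
  data.frame(model = as.integer(sel),
             S2 = pt[["S2"]], S2_err = err[["S2"]],
             te = pt[["te"]], te_err = err[["te"]],
             rex = pt[["rex"]], rex_err = err[["rex"]],
             chi2 = best$chi2, aicc = best$aicc, n_obs = n)
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Model-free analysis of a full relaxation table
#'
#' Applies [fit_modelfree()] to every residue of a relaxation table
#' (two-stage protocol: the diffusion tensor is estimated first and held
#' fixed here).
#'
#' @param records relaxation table as produced by [assemble_records()] or
#'   [simulate_relaxation()]: columns `residue`, `field_MHz`, `temp_K`,
#'   `R1`, `R1_err`, `R2`, `R2_err`, `NOE`, `NOE_err`
#' @param tensor [diffusion_tensor()]
#' @param vectors optional bond-vector set (see [gen_bond_vectors()] /
#'   [nh_vectors()]) supplying per-residue angles for an axial tensor
#' @inheritParams fit_modelfree
#' @return data.frame with one row per residue
#' @export
modelfree_analysis <- function(records, tensor, vectors = NULL, n_mc = 0,
                               seed = 1, models = 1:4, rex_ref_MHz = 800,
                               constants = NULL) {
  residues <- unique(records$residue)
  alphas <- rep(0, length(residues))
  if (!is.null(vectors) && tensor$kind == "axial") {
    m <- match(residues, vectors$residue)
    alphas <- as.numeric(.angle_to_axis(
      tensor, as.matrix(vectors[m, c("x", "y", "z")])))
  }
  out <- vector("list", length(residues))
  for (i in seq_along(residues)) {
    rec <- records[records$residue == residues[i], , drop = FALSE]
    row <- tryCatch(
      fit_modelfree(rec, tensor, alphas[i], n_mc = n_mc,
                    seed = seed + i, models = models,
                    rex_ref_MHz = rex_ref_MHz, constants = constants),
      error = function(e) data.frame(model = NA_integer_, S2 = NA_real_,
        S2_err = NA_real_, te = NA_real_, te_err = NA_real_,
        rex = NA_real_, rex_err = NA_real_, chi2 = NA_real_,
        aicc = NA_real_, n_obs = NA_integer_))
    out[[i]] <- cbind(residue = residues[i], row)
  }
  do.call(rbind, out)
}

#' Conformational entropy change from order parameters
#'
#' Per-residue change in conformational entropy between two states from
#' the diffusion-in-a-cone interpretation of the squared order parameter:
#' \deqn{\Delta S = R \ln\frac{3 - \sqrt{1 + 8 S^2_B}}{3 - \sqrt{1 + 8 S^2_A}}}
#' in J mol^-1 K^-1, with A the free and B the bound state so that a
#' negative sum is a net loss of conformational entropy on binding.
#' The formula is singular at S2 = 1; such residues are rejected.
#'
#' @param S2_A,S2_B squared order parameters of states A (free) and B
#'   (bound), equal-length vectors in `[0, 1)`
#' @param temperature temperature (K), used only to report `T * sum`
#' @return list with `per_residue` (J mol^-1 K^-1), `total`,
#'   `TdS_kJ_mol` (`temperature * total`, kJ/mol) and `n`
#' @export
#' @examples
#' conf_entropy(0.85, 0.89, temperature = 331.15)
conf_entropy <- function(S2_A, S2_B, temperature = 298.15) {
  stopifnot(length(S2_A) == length(S2_B))
  keep <- !is.na(S2_A) & !is.na(S2_B)
  S2_A <- S2_A[keep]; S2_B <- S2_B[keep]
  if (any(S2_A >= 1 | S2_B >= 1))
    stop("conformational entropy is singular at S2 = 1; drop such residues")
  if (any(S2_A < 0 | S2_B < 0)) stop("S2 must lie in [0, 1)")
  R <- nmr_constants$R_gas
  dS <- R * log((3 - sqrt(1 + 8 * S2_B)) / (3 - sqrt(1 + 8 * S2_A)))
  list(per_residue = dS, total = sum(dS),
       TdS_kJ_mol = temperature * sum(dS) / 1000, n = length(dS))
}
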
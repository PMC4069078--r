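#' Total coupling from an apparent multiplet splitting
#'
#' The spin-state-selective coupling measurement scales the apparent
#' 15N-dimension splitting by the selection parameters kappa and lambda:
#' the total coupling is J+D = 2 * apparent / ((1 - kappa) + lambda).
#' With kappa = lambda = 0.5 the apparent splitting is (J+D)/2 (couplings
#' scaled down by a factor of 2); with kappa = 0, lambda = 1 the apparent
#' splitting equals J+D directly.
#'
#' @param apparent_Hz measured apparent splitting (Hz)
#' @param kappa selection parameter, 0 <= kappa < 1
#' @param lambda selection parameter, > 0
#' @return total coupling J+D in Hz
#' @export
#' @examples
#' coupling_from_splittings(46.5, 0.5, 0.5) # 93 Hz
coupling_from_splittings <- function(apparent_Hz, kappa, lambda) {
  stopifnot(all(kappa >= 0), all(kappa < 1), all(lambda > 0))
  denom <- (1 - kappa) + lambda
  if (any(denom == 0)) stop("degenerate scaling: (1 - kappa) + lambda = 0")
  2 * apparent_Hz / denom
}

#' Residual dipolar couplings from splittings in two media
#'
#' D = (J+D) - J, with both couplings recovered from their apparent
#' splittings via [coupling_from_splittings()].
#'
#' @param aligned_Hz apparent splitting in the aligned medium
#' @param isotropic_Hz apparent splitting in the isotropic medium
#' @param kappa,lambda selection parameters used for both spectra
#' @return RDC values in Hz
#' @export
rdc_from_splittings <- function(aligned_Hz, isotropic_Hz, kappa = 0.5,
                                lambda = 0.5) {
  coupling_from_splittings(aligned_Hz, kappa, lambda) -
    coupling_from_splittings(isotropic_Hz, kappa, lambda)
}

#' Fit an alignment tensor to residual dipolar couplings
#'
#' Linear least-squares (SVD) solution for the five independent
#' components of the traceless symmetric alignment tensor A from
#' D_i = v_i' A v_i over unit bond vectors v_i. Reports back-calculated
#' RDCs, the Pearson correlation, and the quality factor
#' Q = rms(D_obs - D_calc) / rms(D_obs), plus the axial magnitude
#' Da = Azz / 2 and rhombicity R = (2/3) (Axx - Ayy) / Azz under the
#' |Azz| >= |Ayy| >= |Axx| eigenvalue ordering.
#'
#' @param rdc observed RDCs (Hz)
#' @param vectors data.frame or matrix of unit bond vectors; columns
#'   `x`, `y`, `z` (rows match `rdc`)
#' @return list with `tensor` (3x3 matrix), `eigenvalues`, `axes`,
#'   `Da`, `rhombicity`, `calc`, `r`, `Q`, `condition`
#' @export
fit_alignment_tensor <- function(rdc, vectors) {
  V <- as.matrix(if (is.data.frame(vectors))
    vectors[, c("x", "y", "z")] else vectors)
  stopifnot(nrow(V) == length(rdc))
  if (length(rdc) < 5)
    stop("alignment tensor is underdetermined: need at least 5 RDCs")
  x <- V[, 1]; y <- V[, 2]; z <- V[, 3]
  # basis: A = {Axx, Ayy, Axy, Axz, Ayz}, Azz = -(Axx + Ayy)
  M <- cbind(x^2 - z^2, y^2 - z^2, 2 * x * y, 2 * x * z, 2 * y * z)
  sv <- svd(M)
  cond <- sv$d[1] / sv$d[5]
  if (sv$d[5] < 1e-10 * sv$d[1])
    stop(sprintf("rank-deficient design (condition number %.3g)", cond))
  coef <- sv$v %*% ((t(sv$u) %*% rdc) / sv$d)
  A <- matrix(c(coef[1], coef[3], coef[4],
                coef[3], coef[2], coef[5],
                coef[4], coef[5], -(coef[1] + coef[2])), 3, 3)
  calc <- as.numeric(M %*% coef)
  resid <- rdc - calc
  Q <- sqrt(mean(resid^2)) / sqrt(mean(rdc^2))
  if (!is.finite(Q)) Q <- 0 # all-zero observations give the zero tensor
  r <- if (stats::sd(rdc) > 0 && stats::sd(calc) > 0)
    stats::cor(rdc, calc) else NA_real_
  e <- eigen(A, symmetric = TRUE)
  ord <- order(abs(e$values), decreasing = TRUE) # |Azz| >= |Ayy| >= |Axx|
  ev <- e$values[ord]
  Da <- ev[1] / 2
  rhomb <- if (ev[1] != 0) (2 / 3) * (ev[3] - ev[2]) / ev[1] else 0
  list(tensor = A, eigenvalues = ev, axes = e$vectors[, ord], Da = Da,
       rhombicity = rhomb, calc = calc, r = r, Q = Q, condition = cond)
}

#' Back-calculate RDCs from an alignment tensor
#'
#' D_i = v_i' A v_i for unit vectors v_i.
#'
#' @param tensor 3x3 traceless symmetric alignment tensor (Hz)
#' @param vectors unit bond vectors (`x`, `y`, `z` columns or matrix)
#' @return RDCs in Hz
#' @export
rdc_back_calculate <- function(tensor, vectors) {
  V <- as.matrix(if (is.data.frame(vectors))
    vectors[, c("x", "y", "z")] else vectors)
  rowSums((V %*% tensor) * V)
}
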
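#' Rotational diffusion tensor
#'
#' Container for isotropic or axially symmetric rotational diffusion.
#' The isotropic rate is `D_iso = (D_par + 2 * D_perp) / 3` and the overall
#' correlation time `tau_c = 1 / (6 * D_iso)`. For an isotropic tensor
#' `D_par == D_perp` exactly. Angles give the orientation of the unique
#' (symmetry) axis in the molecular frame.
#'
#' @param tau_c overall rotational correlation time in seconds; mutually
#'   exclusive with `D_iso`
#' @param D_iso isotropic diffusion coefficient (s^-1)
#' @param anisotropy ratio `D_par / D_per`; 1 gives an isotropic tensor
#' @param theta,phi polar angles (degrees) of the symmetry axis
#' @return object of class `diffusion_tensor` with fields `kind`,
#'   `D_perp`, `D_par`, `D_iso`, `tau_c`, `theta`, `phi`
#' @export
#' @examples
#' diffusion_tensor(tau_c = 13e-9)                    # isotropic, 13 ns
#' diffusion_tensor(tau_c = 13e-9, anisotropy = 0.90) # oblate
diffusion_tensor <- function(tau_c = NULL, D_iso = NULL, anisotropy = 1,
                             theta = 0, phi = 0) {
  if (is.null(D_iso) == is.null(tau_c))
    stop("give exactly one of tau_c and D_iso")
  if (is.null(D_iso)) D_iso <- 1 / (6 * tau_c)
  stopifnot(D_iso > 0, anisotropy > 0)
  # D_iso = (D_par + 2 D_perp)/3 with D_par = anisotropy * D_perp
  D_perp <- 3 * D_iso / (anisotropy + 2)
  D_par <- anisotropy * D_perp
  out <- list(
    kind = if (anisotropy == 1) "isotropic" else "axial",
    D_perp = D_perp, D_par = D_par, D_iso = D_iso,
    tau_c = 1 / (6 * D_iso), theta = theta, phi = phi
  )
  class(out) <- "diffusion_tensor"
  out
}

#' @export
print.diffusion_tensor <- function(x, ...) {
  cat(sprintf("Rotational diffusion tensor (%s)\n", x$kind))
  cat(sprintf("  D_perp %.4f x 1e7 s^-1, D_par %.4f x 1e7 s^-1 (D_par/D_perp %.3f)\n",
              x$D_perp / 1e7, x$D_par / 1e7, x$D_par / x$D_perp))
  cat(sprintf("  tau_c %.2f ns; axis theta %.1f deg, phi %.1f deg\n",
              x$tau_c * 1e9, x$theta, x$phi))
  invisible(x)
}

# unit vector of the tensor symmetry axis (angles in degrees)
.axis_vector <- function(theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

# angle (radians) between unit bond vectors (rows of v) and the tensor axis
.angle_to_axis <- function(tensor, vectors) {
  a <- .axis_vector(tensor$theta, tensor$phi)
  ca <- pmin(1, pmax(-1, as.matrix(vectors) %*% a))
  acos(abs(ca)) # axis is a director: alpha and pi - alpha are equivalent
}
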
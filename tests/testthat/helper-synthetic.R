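# shared fixture builders: noiseless relaxation records from model-free
# parameters, used across the fitting tests

mk_records <- function(S2, te = 0, rex = 0, tensor,
                       fields = c(600, 800),
                       sig = c(R1 = 0.04, R2 = 0.4, NOE = 0.04),
                       residue = 1, alpha = 0, rex_ref_MHz = 800) {
  do.call(rbind, lapply(fields, function(f) {
    bc <- back_calculate(S2, te, rex, tensor, alpha, f,
                         rex_ref_MHz = rex_ref_MHz)
    data.frame(residue = residue, field_MHz = f, temp_K = 331.15,
               R1 = bc$R1, R1_err = sig[["R1"]],
               R2 = bc$R2, R2_err = sig[["R2"]],
               NOE = bc$NOE, NOE_err = sig[["NOE"]])
  }))
}

# rigid records for a set of residues under a (possibly axial) tensor
mk_rigid_records <- function(tensor, vectors, field = 800,
                             noise = c(R1 = 0, R2 = 0),
                             seed = NULL) {
  alpha <- as.numeric(nmrdyn:::.angle_to_axis(
    tensor, as.matrix(vectors[, c("x", "y", "z")])))
  fw <- nmrdyn:::.relax_forward(1, 0, 0, tensor, alpha, field)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(vectors)
  data.frame(residue = vectors$residue, field_MHz = field,
             temp_K = 331.15,
             R1 = fw$R1 + if (noise[["R1"]] > 0)
               rnorm(n, 0, noise[["R1"]]) else 0,
             R1_err = max(noise[["R1"]], 0.04),
             R2 = fw$R2 + if (noise[["R2"]] > 0)
               rnorm(n, 0, noise[["R2"]]) else 0,
             R2_err = max(noise[["R2"]], 0.4),
             NOE = NA_real_, NOE_err = NA_real_)
}

# small rigid-body transform applied to an n x 3 coordinate matrix
rigid_transform <- function(xyz, angles = c(0.3, 0.7, 1.1),
                            shift = c(5, -3, 2)) {
  rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a),
                             0, sin(a), cos(a)), 3, 3, byrow = TRUE)
  rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0,
                             0, 0, 1), 3, 3, byrow = TRUE)
  R <- rz(angles[1]) %*% rx(angles[2]) %*% rz(angles[3])
  sweep(xyz %*% t(R), 2, shift, `+`)
}
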
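#' Structure ensemble container
#'
#' Lightweight container for an ensemble of conformers sharing one atom
#' roster: an atom table plus a coordinate array.
#'
#' @param atoms data.frame with columns `atom` (PDB atom name), `residue`
#'   (number), `resname`, `chain`, `element`
#' @param xyz numeric array `c(n_models, n_atoms, 3)` in angstrom, or an
#'   `n_atoms x 3` matrix for a single model
#' @param source free-text provenance label
#' @return object of class `structure_ensemble`
#' @export
structure_ensemble <- function(atoms, xyz, source = "") {
  if (is.matrix(xyz)) xyz <- array(xyz, c(1, nrow(xyz), 3))
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[2] == nrow(atoms),
            dim(xyz)[3] == 3, all(is.finite(xyz)))
  out <- list(atoms = atoms, xyz = xyz, n_models = dim(xyz)[1],
              source = source)
  class(out) <- "structure_ensemble"
  out
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("Structure ensemble: %d model(s), %d atoms, %d chain(s)%s\n",
              x$n_models, nrow(x$atoms), length(unique(x$atoms$chain)),
              if (nzchar(x$source)) paste0(" [", x$source, "]") else ""))
  invisible(x)
}

#' Read a (multi-model) PDB file into a structure ensemble
#'
#' Standard columnar PDB with MODEL/ENDMDL records for ensembles;
#' coordinates are taken as deposited (no altloc/insertion-code
#' handling).
#'
#' @param path PDB file path
#' @return [structure_ensemble()]
#' @export
read_pdb_ensemble <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  idx <- as.integer(rownames(at))
  atoms <- data.frame(atom = at$elety, residue = at$resno,
                      resname = at$resid, chain = at$chain,
                      element = at$elesy)
  xyzm <- pdb$xyz
  if (is.null(dim(xyzm))) xyzm <- matrix(xyzm, nrow = 1)
  nm <- nrow(xyzm)
  coords <- array(NA_real_, c(nm, nrow(atoms), 3))
  for (m in seq_len(nm)) {
    cm <- matrix(xyzm[m, ], ncol = 3, byrow = TRUE)
    coords[m, , ] <- cm[idx, , drop = FALSE]
  }
  structure_ensemble(atoms, coords, source = path)
}

# optimal rotation (Kabsch, SVD with reflection guard) aligning the
# centered rows of P onto the centered rows of Q; returns rotated,
# translated copy of `apply_to` (defaults to P)
.superpose_onto <- function(P, Q, apply_to = P) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- t(P0) %*% Q0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(sweep(apply_to, 2, cp) %*% t(R), 2, cq, `+`)
}

.rmsd <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

# resolve a selection into atom indices
.resolve_sel <- function(ens, selection) {
  if (is.null(selection)) return(seq_len(nrow(ens$atoms)))
  if (is.logical(selection)) return(which(selection))
  as.integer(selection)
}

#' Atom selection helpers
#'
#' `select_atoms` returns a logical index over an ensemble's atom table.
#' `backbone` restricts to N, CA, C, O; `residues` to a residue-number
#' set; `trim_termini` drops `n_trim` residues at each terminus of each
#' chain.
#'
#' @param ens [structure_ensemble()]
#' @param backbone keep backbone N, CA, C, O atoms only
#' @param residues residue numbers to keep (NULL keeps all)
#' @param chains chains to keep (NULL keeps all)
#' @param trim_termini residues to drop at each end of each chain
#' @return logical vector over atoms
#' @export
select_atoms <- function(ens, backbone = FALSE, residues = NULL,
                         chains = NULL, trim_termini = 0) {
  at <- ens$atoms
  keep <- rep(TRUE, nrow(at))
  if (backbone) keep <- keep & at$atom %in% c("N", "CA", "C", "O")
  if (!is.null(residues)) keep <- keep & at$residue %in% residues
  if (!is.null(chains)) keep <- keep & at$chain %in% chains
  if (trim_termini > 0) {
    for (ch in unique(at$chain)) {
      rs <- sort(unique(at$residue[at$chain == ch]))
      drop <- c(utils::head(rs, trim_termini),
                utils::tail(rs, trim_termini))
      keep <- keep & !(at$chain == ch & at$residue %in% drop)
    }
  }
  keep
}

#' Ensemble superposition and RMSD-to-mean statistics
#'
#' Iterative mean-structure superposition: all models are superposed
#' onto the current mean by optimal least-squares rigid-body fit over
#' the selection, the mean is recomputed, and the cycle repeats until
#' the mean converges. Reports the per-model RMSD to the converged mean
#' over the selection.
#'
#' @param ens [structure_ensemble()] with at least 2 models
#' @param selection atom indices or logical vector (see
#'   [select_atoms()]); NULL selects all atoms
#' @param tol convergence threshold on the mean structure (angstrom)
#' @param max_iter iteration cap
#' @return list with `mean_xyz` (selection atoms x 3), `per_model`
#'   RMSDs, `mean`, `sd`, `n_atoms`
#' @export
superpose_stats <- function(ens, selection = NULL, tol = 1e-8,
                            max_iter = 50) {
  idx <- .resolve_sel(ens, selection)
  if (!length(idx)) stop("empty selection")
  if (length(idx) < 3) stop("selection must contain at least 3 atoms")
  if (ens$n_models < 2) stop("need at least 2 models")
  sel_coords <- function(m) ens$xyz[m, idx, , drop = TRUE]
  mods <- lapply(seq_len(ens$n_models), sel_coords)
  mean_xyz <- mods[[1]]
  for (it in seq_len(max_iter)) {
    fitted <- lapply(mods, .superpose_onto, Q = mean_xyz)
    new_mean <- Reduce(`+`, fitted) / length(fitted)
    if (max(abs(new_mean - mean_xyz)) < tol) { mean_xyz <- new_mean; break }
    mean_xyz <- new_mean
  }
  fitted <- lapply(mods, .superpose_onto, Q = mean_xyz)
  rmsds <- vapply(fitted, .rmsd, numeric(1), B = mean_xyz)
  list(mean_xyz = mean_xyz, per_model = rmsds, mean = mean(rmsds),
       sd = stats::sd(rmsds), n_atoms = length(idx))
}

#' RMSD of ensemble models to a reference structure
#'
#' Superposes every model of `ens` onto a reference structure over an
#' explicit atom pairing and reports per-model and summary RMSDs along
#' with the pair count, so selections are auditable.
#'
#' @param ens [structure_ensemble()]
#' @param ref reference coordinates: `n x 3` matrix, or a single-model
#'   [structure_ensemble()]
#' @param sel_ens atom indices (or logical) into `ens` atoms
#' @param sel_ref matching indices into the reference atoms, same length
#' @return list with `per_model`, `mean`, `sd`, `n_pairs`
#' @export
cross_rmsd <- function(ens, ref, sel_ens = NULL, sel_ref = NULL) {
  if (inherits(ref, "structure_ensemble")) {
    ridx <- .resolve_sel(ref, sel_ref)
    refxyz <- ref$xyz[1, ridx, , drop = TRUE]
  } else {
    refxyz <- as.matrix(ref)
    if (!is.null(sel_ref)) refxyz <- refxyz[.resolve_sel(
      list(atoms = data.frame(i = seq_len(nrow(refxyz)))), sel_ref), ,
      drop = FALSE]
  }
  idx <- .resolve_sel(ens, sel_ens)
  if (length(idx) != nrow(refxyz))
    stop(sprintf("pairing mismatch: %d ensemble atoms vs %d reference atoms",
                 length(idx), nrow(refxyz)))
  rmsds <- vapply(seq_len(ens$n_models), function(m) {
    P <- ens$xyz[m, idx, , drop = TRUE]
    .rmsd(.superpose_onto(P, refxyz), refxyz)
  }, numeric(1))
  list(per_model = rmsds, mean = mean(rmsds), sd = stats::sd(rmsds),
       n_pairs = nrow(refxyz))
}

#' Extract unit N-H bond vectors from a structure
#'
#' One unit vector N -> H per residue. When the amide hydrogen is absent
#' it is reconstructed geometrically on the bisector convention: H lies
#' opposite the bisector of the N-CA and N-C(i-1) directions at 1.02
#' angstrom, and the residue is flagged `reconstructed`. Prolines carry
#' no amide proton and are skipped.
#'
#' @param ens [structure_ensemble()]; the first model is used
#' @param model model index (default 1)
#' @param chain restrict to one chain (default: first chain)
#' @return data.frame `residue`, `x`, `y`, `z`, `reconstructed`
#' @export
nh_vectors <- function(ens, model = 1, chain = NULL) {
  at <- ens$atoms
  if (is.null(chain)) chain <- at$chain[1]
  xyz <- ens$xyz[model, , , drop = TRUE]
  sel <- which(at$chain %in% chain)
  at <- at[sel, , drop = FALSE]; xyz <- xyz[sel, , drop = FALSE]
  res <- sort(unique(at$residue))
  out <- list()
  get_atom <- function(r, name) {
    i <- which(at$residue == r & at$atom %in% name)
    if (!length(i)) return(NULL)
    xyz[i[1], ]
  }
  for (r in res) {
    resname <- at$resname[at$residue == r][1]
    if (identical(resname, "PRO")) next
    N <- get_atom(r, "N")
    if (is.null(N)) stop(sprintf("residue %s has no backbone N", r))
    H <- get_atom(r, c("H", "HN"))
    rec <- FALSE
    if (is.null(H)) {
      CA <- get_atom(r, "CA")
      Cp <- get_atom(r - 1, "C")
      if (is.null(CA) || is.null(Cp)) next # chain start: cannot place H
      u1 <- (CA - N) / sqrt(sum((CA - N)^2))
      u2 <- (Cp - N) / sqrt(sum((Cp - N)^2))
      b <- -(u1 + u2)
      H <- N + 1.02 * b / sqrt(sum(b^2))
      rec <- TRUE
    }
    v <- H - N
    v <- v / sqrt(sum(v^2))
    out[[length(out) + 1]] <- data.frame(residue = r, x = v[1], y = v[2],
                                         z = v[3], reconstructed = rec)
  }
  if (!length(out))
    return(data.frame(residue = numeric(0), x = numeric(0),
                      y = numeric(0), z = numeric(0),
                      reconstructed = logical(0)))
  do.call(rbind, out)
}

#' Chemical-shift differences between two states
#'
#' Per-residue shift difference delta(A) - delta(B) for one nucleus,
#' with |difference| >= `flag_threshold` flagged (inclusive). Residues
#' missing from either table are reported with NA, never as zero.
#'
#' @param tableA,tableB data.frames with a `residue` column and one
#'   column per nucleus
#' @param nucleus column name to compare (e.g. `"CB"`)
#' @param flag_threshold flag cut in ppm (default 0.7)
#' @return data.frame `residue`, `delta`, `flag`
#' @export
shift_deltas <- function(tableA, tableB, nucleus, flag_threshold = 0.7) {
  for (tb in list(tableA, tableB))
    if (!nucleus %in% names(tb))
      stop(sprintf("nucleus '%s' absent from a shift table", nucleus))
  residues <- sort(unique(c(tableA$residue, tableB$residue)))
  a <- tableA[[nucleus]][match(residues, tableA$residue)]
  b <- tableB[[nucleus]][match(residues, tableB$residue)]
  delta <- a - b
  # inclusive threshold, robust to floating-point representation
  data.frame(residue = residues, delta = delta,
             flag = !is.na(delta) &
               abs(delta) >= flag_threshold - 1e-9)
}
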
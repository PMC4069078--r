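# Nearest-neighbour correction factors for intrinsic amide exchange,
# log10 units relative to poly-DL-alanine. `lambda` is the effect of a
# side chain on its own backbone amide, `rho` its effect on the amide of
# the following residue; acid- and base-catalyzed pathways carry separate
# factors. Values transcribed from the reference poly-alanine
# parameterization used by the standard protection-factor spreadsheets.
.hx_factors <- local({
  m <- rbind(
    #          acid_l acid_r base_l base_r
    A      = c( 0.00,  0.00,  0.00,  0.00),
    R      = c(-0.59, -0.32,  0.08,  0.22),
    N      = c(-0.58, -0.13,  0.49,  0.32),
    D      = c( 0.90,  0.58, -0.30, -0.18), # carboxylate
    D_prot = c(-0.90, -0.12,  0.69,  0.60), # protonated carboxyl
    C      = c(-0.54, -0.46,  0.62,  0.55),
    E      = c(-0.90,  0.31, -0.51, -0.15), # carboxylate
    E_prot = c(-0.60, -0.27,  0.24,  0.39),
    F      = c(-0.52, -0.43, -0.24,  0.06),
    G      = c(-0.22,  0.22,  0.27,  0.17),
    H      = c( 0.00,  0.00, -0.10,  0.14), # neutral imidazole
    H_prot = c(-0.80, -0.51,  0.80,  0.83),
    I      = c(-0.91, -0.59, -0.73, -0.23),
    K      = c(-0.56, -0.29, -0.04,  0.12),
    L      = c(-0.57, -0.13, -0.58, -0.21),
    M      = c(-0.64, -0.28, -0.01,  0.11),
    P      = c( 0.00, -0.19,  0.00, -0.24), # trans; no amide of its own
    Q      = c(-0.47, -0.27,  0.06,  0.20),
    S      = c(-0.44, -0.39,  0.37,  0.30),
    T      = c(-0.79, -0.47, -0.07,  0.20),
    V      = c(-0.74, -0.30, -0.70, -0.14),
    W      = c(-0.40, -0.44, -0.41, -0.11),
    Y      = c(-0.41, -0.37, -0.27,  0.05))
  colnames(m) <- c("acid_l", "acid_r", "base_l", "base_r")
  m
})

# terminal group factors: the free amine acts on the second residue's
# amide (right-hand factors), the C-terminal carboxylate on the last
# residue's own amide (left-hand factors)
.hx_nterm <- c(acid_r = -1.32, base_r = 1.62)
.hx_cterm <- c(acid_l = 0.96, base_l = -1.80)

# water ionization constant, van't Hoff around pKw(298.15 K) = 13.995
# with dH_ion = 13.34 kcal/mol
.pKw <- function(temp_K) {
  dH <- 13.34 * 4184
  13.995 + dH / (nmr_constants$R_gas * log(10)) *
    (1 / temp_K - 1 / 298.15)
}

# protonation-state-dependent row lookup
.hx_row <- function(aa, pH) {
  key <- aa
  if (aa == "D" && pH < 3.9) key <- "D_prot"
  if (aa == "E" && pH < 4.3) key <- "E_prot"
  if (aa == "H" && pH < 6.0) key <- "H_prot"
  if (!key %in% rownames(.hx_factors)) stop("unknown residue code: ", aa)
  .hx_factors[key, ]
}

#' Intrinsic amide hydrogen exchange rates
#'
#' Sequence-specific intrinsic (random-coil) exchange rates built from
#' poly-alanine reference rates for the acid-, base- and water-catalyzed
#' pathways with log-additive nearest-neighbour corrections, Arrhenius
#' temperature scaling (activation energies 14, 17 and 19 kcal/mol) and
#' the pH dependence k_int = k_A f_A [H+] + (k_B f_B) [OH-] + k_W f_B.
#' Defaults describe deuteron-to-proton exchange of a deuterated protein
#' dissolved in H2O. The first residue has no backbone amide
#' contribution and prolines carry no amide proton; both report NA.
#' Sample pH and temperature have no defaults: both must be given.
#'
#' @param sequence one-letter amino-acid string or character vector
#' @param pH sample pH (required)
#' @param temp_K temperature in K (required)
#' @param residues residue numbers matching the sequence (supports
#'   numbering gaps); default 1..n. Neighbour corrections follow the
#'   chain order of `sequence`, not the numbering.
#' @param exchange direction: `"DH"` (deuterated amide into H2O,
#'   default) or `"HD"` (protonated amide into D2O)
#' @return data.frame `residue`, `aa`, `k_int` (s^-1; NA for the first
#'   residue and prolines)
#' @export
#' @examples
#' intrinsic_rates("AAA", pH = 7, temp_K = 331.15)
intrinsic_rates <- function(sequence, pH, temp_K, residues = NULL,
                            exchange = c("DH", "HD")) {
  exchange <- match.arg(exchange)
  if (missing(pH) || missing(temp_K))
    stop("pH and temp_K are required inputs with no default")
  aa <- if (length(sequence) == 1 && nchar(sequence[1]) > 1)
    strsplit(sequence, "")[[1]] else as.character(sequence)
  aa <- toupper(aa)
  n <- length(aa)
  if (is.null(residues)) residues <- seq_len(n)
  stopifnot(length(residues) == n)
  bad <- setdiff(aa, rownames(.hx_factors))
  if (length(bad)) stop("unknown residue code: ", bad[1])

  # reference poly-DL-alanine rates at 293 K (log10, per molar per
  # minute for the catalyzed pathways, per minute for water)
  ref <- if (exchange == "DH") c(A = 2.04, B = 10.36, W = -1.5)
         else c(A = 1.62, B = 10.18, W = -1.5)
  Ea <- c(A = 14, B = 17, W = 19) * 4184
  arrh <- exp(-Ea / nmr_constants$R_gas * (1 / temp_K - 1 / 293))
  k_ref <- 10^ref * arrh / 60 # per second
  conc_H <- 10^(-pH)
  conc_OH <- 10^(pH - .pKw(temp_K))

  k <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i == 1 || aa[i] == "P") next
    own <- .hx_row(aa[i], pH)
    left <- .hx_row(aa[i - 1], pH)
    fa <- own["acid_l"] + left["acid_r"]
    fb <- own["base_l"] + left["base_r"]
    if (i == 2) {
      fa <- fa + .hx_nterm["acid_r"]
      fb <- fb + .hx_nterm["base_r"]
    }
    if (i == n) {
      fa <- fa + .hx_cterm["acid_l"]
      fb <- fb + .hx_cterm["base_l"]
    }
    k[i] <- k_ref["A"] * 10^fa * conc_H +
      k_ref["B"] * 10^fb * conc_OH +
      k_ref["W"] * 10^fb
  }
  data.frame(residue = residues, aa = aa, k_int = unname(k))
}
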
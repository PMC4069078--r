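# merge replicate time points by averaging; returns times strictly
# increasing plus a noise-floor estimate from replicate differences
.merge_replicates <- function(time_s, intensity) {
  o <- order(time_s)
  time_s <- time_s[o]; intensity <- intensity[o]
  ut <- unique(time_s)
  I <- vapply(ut, function(t) mean(intensity[time_s == t]), numeric(1))
  diffs <- unlist(lapply(ut, function(t) {
    v <- intensity[time_s == t]
    if (length(v) > 1) diff(range(v)) else NULL
  }))
  floor <- if (length(diffs)) sqrt(mean(diffs^2) / 2) else NA_real_
  list(time_s = ut, intensity = I, noise_floor = floor)
}

# exponential decay fit I(t) = I0 exp(-R t) on merged points; start from
# log-linear regression; returns NULL on failure
.exp_fit <- function(time_s, intensity) {
  pos <- intensity > 0
  if (sum(pos) >= 2) {
    lf <- stats::lm(log(intensity[pos]) ~ time_s[pos])
    R0 <- max(-unname(stats::coef(lf)[2]), 1e-6)
    I0 <- exp(unname(stats::coef(lf)[1]))
  } else {
    R0 <- 1 / max(time_s); I0 <- max(abs(intensity))
  }
  df <- data.frame(t = time_s, I = intensity)
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ A * exp(-R * t), data = df,
                      start = list(A = I0, R = R0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  list(amplitude = unname(cf["A"]), rate = unname(cf["R"]))
}

#' Fit a relaxation rate to an intensity decay series
#'
#' Non-linear least-squares fit of peak intensities to
#' I(t) = I0 * exp(-R * t). Replicate time points are merged by averaging
#' (their pairwise differences provide a noise-floor estimate); parameter
#' uncertainties come from a delete-one jackknife over the merged time
#' points. The decay amplitude is fitted alongside the rate and both are
#' reported.
#'
#' @param series data.frame with columns `time_s` and `intensity`
#'   (optionally `replicate`); an intensity series for one residue
#' @return list with `rate` (s^-1), `rate_err` (jackknife), `amplitude`,
#'   `amplitude_err`, `noise_floor`, `n_times`, `converged` and `flat`
#'   (TRUE when the series shows no decay beyond the noise floor)
#' @export
#' @examples
#' tt <- c(10, 30, 50, 70, 90, 110) * 1e-3
#' fit_rate(data.frame(time_s = tt, intensity = exp(-10 * tt)))
fit_rate <- function(series) {
  m <- .merge_replicates(series$time_s, series$intensity)
  n <- length(m$time_s)
  if (n < 3) stop("rate fit needs at least 3 distinct time points")
  full <- .exp_fit(m$time_s, m$intensity)
  if (is.null(full))
    return(list(rate = NA_real_, rate_err = NA_real_,
                amplitude = NA_real_, amplitude_err = NA_real_,
                noise_floor = m$noise_floor, n_times = n,
                converged = FALSE, flat = FALSE))
  drop_one <- vapply(seq_len(n), function(i) {
    f <- .exp_fit(m$time_s[-i], m$intensity[-i])
    if (is.null(f)) c(NA_real_, NA_real_) else c(f$rate, f$amplitude)
  }, numeric(2))
  jack_sd <- function(x) {
    x <- x[!is.na(x)]
    k <- length(x)
    if (k < 2) return(NA_real_)
    sqrt((k - 1) / k * sum((x - mean(x))^2))
  }
  span <- diff(range(m$intensity))
  flat <- is.finite(m$noise_floor) && span <= 3 * m$noise_floor ||
    abs(full$rate) * diff(range(m$time_s)) < 1e-6
  list(rate = full$rate, rate_err = jack_sd(drop_one[1, ]),
       amplitude = full$amplitude, amplitude_err = jack_sd(drop_one[2, ]),
       noise_floor = m$noise_floor, n_times = n,
       converged = TRUE, flat = flat)
}

#' Heteronuclear NOE from saturated/unsaturated peak intensities
#'
#' NOE = I_sat / I_unsat; the uncertainty is propagated from the rms
#' noise of the two spectra:
#' sigma = |NOE| * sqrt((rms/I_sat)^2 + (rms/I_unsat)^2).
#'
#' @param I_sat peak intensity with 1H saturation
#' @param I_unsat peak intensity without saturation (reference)
#' @param rms_noise rms spectral noise (same units)
#' @return list with `NOE` and `NOE_err`
#' @export
#' @examples
#' compute_hetnoe(0.8, 1.0, 0.05)
compute_hetnoe <- function(I_sat, I_unsat, rms_noise = 0) {
  if (any(I_unsat == 0)) stop("reference intensity must be non-zero")
  noe <- I_sat / I_unsat
  err <- abs(noe) * sqrt((rms_noise / I_sat)^2 + (rms_noise / I_unsat)^2)
  list(NOE = noe, NOE_err = err)
}

#' Assemble per-residue relaxation records for one condition
#'
#' Joins R1, R2 and NOE results into one record per residue at a given
#' (field, temperature) condition. Missing observables stay absent (NA),
#' never imputed; conflicting duplicate entries raise an error naming the
#' residue.
#'
#' @param R1,R2 data.frames with columns `residue`, `rate`, `rate_err`
#'   (either may be NULL)
#' @param NOE data.frame with columns `residue`, `NOE`, `NOE_err` (may be
#'   NULL)
#' @param field_MHz,temp_K condition metadata stored on every record
#' @return data.frame with columns `residue`, `field_MHz`, `temp_K`,
#'   `R1`, `R1_err`, `R2`, `R2_err`, `NOE`, `NOE_err`
#' @export
assemble_records <- function(R1 = NULL, R2 = NULL, NOE = NULL,
                             field_MHz, temp_K) {
  check_dup <- function(d, what) {
    if (is.null(d)) return(invisible())
    dup <- d$residue[duplicated(d$residue)]
    for (r in unique(dup)) {
      v <- d[d$residue == r, -1, drop = FALSE]
      if (nrow(unique(v)) > 1)
        stop(sprintf("conflicting duplicate %s entries for residue %s",
                     what, r))
    }
  }
  check_dup(R1, "R1"); check_dup(R2, "R2"); check_dup(NOE, "NOE")
  residues <- sort(unique(c(R1$residue, R2$residue, NOE$residue)))
  if (!length(residues)) stop("no observables supplied")
  take <- function(d, col, err) {
    if (is.null(d)) return(list(v = rep(NA_real_, length(residues)),
                                e = rep(NA_real_, length(residues))))
    i <- match(residues, d$residue)
    list(v = d[[col]][i], e = d[[err]][i])
  }
  r1 <- take(R1, "rate", "rate_err")
  r2 <- take(R2, "rate", "rate_err")
  nn <- take(NOE, "NOE", "NOE_err")
  out <- data.frame(residue = residues, field_MHz = field_MHz,
                    temp_K = temp_K,
                    R1 = r1$v, R1_err = r1$e, R2 = r2$v, R2_err = r2$e,
                    NOE = nn$v, NOE_err = nn$e)
  slow <- !is.na(out$R1) & !is.na(out$R2) & out$R2 < out$R1
  if (any(slow))
    warning(sprintf("R2 < R1 for residue(s) %s: unexpected for slow tumbling",
                    paste(out$residue[slow], collapse = ", ")))
  out
}

# ---- tabular text I/O --------------------------------------------------

#' Read / write intensity series tables
#'
#' Plain TSV with header `residue, time_s, intensity, replicate`; the
#' format both the synthetic generators write and the fitting functions
#' consume.
#'
#' @param path file path
#' @param x data.frame to write
#' @return `read_intensity_tsv` returns the data.frame
#' @export
read_intensity_tsv <- function(path) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         comment.char = "#")
  stopifnot(all(c("residue", "time_s", "intensity") %in% names(d)))
  if (is.null(d$replicate)) d$replicate <- 1L
  d
}

#' @rdname read_intensity_tsv
#' @export
write_intensity_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write relaxation record tables
#'
#' TSV with header `residue, field_MHz, temp_K, R1, R1_err, R2, R2_err,
#' NOE, NOE_err`.
#'
#' @param path file path
#' @param x data.frame to write
#' @export
read_relaxation_tsv <- function(path) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         comment.char = "#")
  stopifnot(all(c("residue", "field_MHz", "R1", "R2", "NOE") %in% names(d)))
  d
}

#' @rdname read_relaxation_tsv
#' @export
write_relaxation_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
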
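# three-parameter build-up fit I(t) = I_inf + I0 * (1 - exp(-k t));
# returns NULL on failure
.buildup_fit <- function(time_s, intensity) {
  Iinf0 <- intensity[which.min(time_s)]
  I00 <- max(intensity) - min(intensity)
  if (I00 <= 0) I00 <- max(abs(intensity)) + 1e-12
  # crude rate guess: time to half build-up
  half <- Iinf0 + I00 / 2
  th <- time_s[which.min(abs(intensity - half))]
  k0 <- log(2) / max(th, min(time_s[time_s > 0], na.rm = TRUE))
  df <- data.frame(t = time_s, I = intensity)
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ Iinf + I0 * (1 - exp(-k * t)), data = df,
                      start = list(Iinf = Iinf0, I0 = I00, k = k0),
                      lower = c(-Inf, 0, 0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 300, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  as.list(stats::coef(fit))
}

#' Fit H/D exchange build-up kinetics
#'
#' Least-squares fit of peak intensities to the three-parameter build-up
#' equation I(t) = I(inf) + I(0) * (1 - exp(-k_ex * t)), with the rate
#' uncertainty from a delete-one jackknife over time points. Series that
#' show no build-up beyond the noise floor are classified `slow`
#' (unexchanged) rather than fitted; series already at their plateau at
#' the first time point are classified `fast` and should be handed to
#' [censor_bound()]. Distinguishing a fast (complete) from a slow (flat
#' low) series requires a reference full intensity, supplied as
#' `plateau_ref`.
#'
#' @param series data.frame with `time_s`, `intensity`
#' @param noise_floor intensity noise level used for the flatness test
#' @param plateau_ref expected full (completely exchanged) intensity;
#'   used only to classify flat series
#' @return list with `k_ex`, `k_ex_err`, `I_inf`, `I0`, `category`
#'   (`"measured"`, `"fast"` or `"slow"`), `converged`, `n_times`
#' @export
#' @examples
#' s <- simulate_hdx_series(1e-3)
#' fit_buildup(s)$k_ex
fit_buildup <- function(series, noise_floor = 0, plateau_ref = NULL) {
  m <- .merge_replicates(series$time_s, series$intensity)
  n <- length(m$time_s)
  if (n < 4) stop("build-up fit needs at least 4 distinct time points")
  nf <- max(noise_floor, m$noise_floor, 0, na.rm = TRUE)
  span <- diff(range(m$intensity))
  out_censored <- function(cat) list(
    k_ex = NA_real_, k_ex_err = NA_real_, I_inf = m$intensity[1],
    I0 = NA_real_, category = cat, converged = TRUE, n_times = n)
  # flat series: fast if sitting at the full intensity, slow otherwise
  censor_by_level <- function() {
    lvl <- mean(m$intensity)
    if (!is.null(plateau_ref) && lvl >= 0.8 * plateau_ref)
      out_censored("fast")
    else out_censored("slow")
  }
  if (span <= max(3 * nf, 0.02 * max(abs(m$intensity))))
    return(censor_by_level())
  full <- .buildup_fit(m$time_s, m$intensity)
  if (is.null(full))
    return(list(k_ex = NA_real_, k_ex_err = NA_real_, I_inf = NA_real_,
                I0 = NA_real_, category = "slow", converged = FALSE,
                n_times = n))
  # essentially complete before the first point: censored. With a
  # reference full intensity the level decides fast vs slow (a huge
  # fitted rate on a baseline-level series is noise, not exchange);
  # without one the fitted rate is trusted.
  if (full$k * min(m$time_s) > log(20))
    return(if (is.null(plateau_ref)) out_censored("fast")
           else censor_by_level())
  # no build-up beyond the residual noise within the experimental time:
  # censored, not fitted (guards against fitting pure noise)
  fitted_I <- full$Iinf + full$I0 * (1 - exp(-full$k * m$time_s))
  resid_sd <- stats::sd(m$intensity - fitted_I)
  achieved <- full$I0 * (1 - exp(-full$k * max(m$time_s)))
  if (achieved <= 3 * max(resid_sd, nf)) return(censor_by_level())
  # a series that never recovers an appreciable fraction of the full
  # peak intensity and shows no rise beyond noise has not exchanged
  # within the experiment, whatever the unconstrained fit extrapolates
  # below the first time point
  if (!is.null(plateau_ref) &&
      max(m$intensity) < 0.3 * plateau_ref &&
      diff(range(m$intensity)) <= 6 * max(resid_sd, nf, 1e-12))
    return(out_censored("slow"))
  ks <- vapply(seq_len(n), function(i) {
    f <- .buildup_fit(m$time_s[-i], m$intensity[-i])
    if (is.null(f)) NA_real_ else f$k
  }, numeric(1))
  ks <- ks[!is.na(ks)]
  err <- if (length(ks) >= 2)
    sqrt((length(ks) - 1) / length(ks) * sum((ks - mean(ks))^2))
  else NA_real_
  list(k_ex = full$k, k_ex_err = err, I_inf = full$Iinf, I0 = full$I0,
       category = "measured", converged = TRUE, n_times = n)
}

#' Censored lower bound for fast exchange rates
#'
#' Residues fully exchanged before the first spectrum only admit a lower
#' bound on their rate, derived from the exchange completeness reached by
#' the first time point: k_min = -ln(1 - completeness) / t_first. The
#' default completeness 0.926 reproduces the conventional fast-group
#' bound of 2.9e-3 s^-1 for a first spectrum at 900 s.
#'
#' @param first_timepoint_s time of the first spectrum (s)
#' @param completeness exchange fraction assumed reached, in (0, 1)
#' @return lower rate bound (s^-1)
#' @export
#' @examples
#' censor_bound(900)  # ~2.9e-3
censor_bound <- function(first_timepoint_s, completeness = 0.926) {
  stopifnot(first_timepoint_s > 0)
  if (any(completeness <= 0 | completeness >= 1))
    stop("completeness must lie strictly between 0 and 1")
  -log(1 - completeness) / first_timepoint_s
}

#' Protection factors and plotting categories
#'
#' P = k_int / k_ex for measured rates. Censored records receive the
#' conventional log P display codes: 2.5 for the fast group (exchanged
#' before the first spectrum), 2.8 for the second-fastest group
#' (exchanged before the second spectrum), 7.0 for slow/unexchanged
#' residues, and -0.1 for residues with no data. Every residue falls in
#' exactly one category.
#'
#' @param k_ex measured exchange rates (s^-1); NA for censored residues
#' @param k_int intrinsic rates (s^-1), > 0 where a category other than
#'   `no_data` is assigned
#' @param category one of `"measured"`, `"fast"`, `"second_fastest"`,
#'   `"slow"`, `"no_data"` per residue; defaults to `"measured"` where
#'   `k_ex` is finite and `"no_data"` elsewhere
#' @return data.frame with `P`, `logP` (NA when censored), `category`
#'   and `logP_display` (the plotting value)
#' @export
#' @examples
#' protection(1e-3, 1)        # P = 1000, log P = 3
#' protection(NA, 1, category = "fast")
protection <- function(k_ex, k_int,
                       category = ifelse(is.finite(k_ex), "measured",
                                         "no_data")) {
  n <- max(length(k_ex), length(k_int), length(category))
  k_ex <- rep_len(k_ex, n); k_int <- rep_len(k_int, n)
  category <- rep_len(category, n)
  codes <- c(fast = 2.5, second_fastest = 2.8, slow = 7.0,
             no_data = -0.1)
  bad <- !category %in% c("measured", names(codes))
  if (any(bad)) stop("unknown category: ", category[bad][1])
  if (any(category == "measured" &
          (!is.finite(k_ex) | k_ex <= 0 | !is.finite(k_int) | k_int <= 0)))
    stop("measured residues need positive k_ex and k_int")
  P <- ifelse(category == "measured", k_int / k_ex, NA_real_)
  logP <- log10(P)
  display <- ifelse(category == "measured", logP,
                    unname(codes[category]))
  data.frame(P = P, logP = logP, category = category,
             logP_display = display)
}
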
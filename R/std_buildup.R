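# STD build-up analysis: amplification factors, mono-exponential fits,
# STD0 initial rates and normalized epitope-binding maps.

#' STD amplification factor
#'
#' Computes the STD amplification factor
#' \deqn{\eta = \frac{I_0 - I_{STD}}{I_0}\,\varepsilon,}
#' where `i0` is the off-resonance intensity, `istd` the on-resonance
#' intensity and `epsilon` the ligand-to-protein concentration ratio.
#' Negative values (possible under noise when `istd > i0`) are returned
#' unchanged with a warning.
#'
#' @param i0 off-resonance intensity, > 0 (vectorized).
#' @param istd on-resonance intensity, same length.
#' @param epsilon ligand:protein concentration ratio, > 0.
#' @return Dimensionless amplification factor(s).
#' @examples
#' amplification_factor(1000, 975, 40)   # 1.0
#' @export
amplification_factor <- function(i0, istd, epsilon) {
  if (!is.numeric(i0) || !is.numeric(istd) || any(!is.finite(i0)) ||
      any(!is.finite(istd)))
    abort_invalid("intensities must be finite numbers")
  if (any(i0 <= 0))
    abort_invalid("off-resonance intensity i0 must be > 0")
  if (!is_scalar_number(epsilon) || epsilon <= 0)
    abort_invalid("epsilon must be a positive number")
  eta <- (i0 - istd) / i0 * epsilon
  if (any(eta < 0))
    warning("negative amplification factor(s): on-resonance intensity ",
            "exceeds off-resonance (noise)", call. = FALSE)
  eta
}

#' Construct a saturation series for one proton
#'
#' One proton's on/off-resonance intensities over a saturation-time
#' schedule, the unit of input to [fit_buildup()].
#'
#' @param ligand_id,proton_id identifiers.
#' @param chemical_shift chemical shift in ppm (label only).
#' @param times saturation times in seconds; strictly increasing, all > 0.
#' @param i0 off-resonance intensities (> 0), one per time.
#' @param istd on-resonance intensities, one per time.
#' @param epsilon ligand:protein concentration ratio, > 0.
#' @param overlap_flag `TRUE` when the signal is unusable because of
#'   resonance overlap (e.g. with a competition probe).
#' @return An object of class `saturation_series`.
#' @export
saturation_series <- function(ligand_id, proton_id, chemical_shift,
                              times, i0, istd, epsilon,
                              overlap_flag = FALSE) {
  if (length(times) == 0L) abort_invalid("times must be non-empty")
  if (any(times <= 0) || any(diff(times) <= 0))
    abort_invalid("times must be strictly increasing and positive")
  if (length(i0) != length(times) || length(istd) != length(times))
    abort_invalid("times, i0 and istd must have equal length")
  if (any(i0 <= 0)) abort_invalid("i0 must be positive elementwise")
  if (!is_scalar_number(epsilon) || epsilon <= 0)
    abort_invalid("epsilon must be a positive number")
  structure(
    list(ligand_id = as.character(ligand_id),
         proton_id = as.character(proton_id),
         chemical_shift = as.numeric(chemical_shift),
         times = as.numeric(times), i0 = as.numeric(i0),
         istd = as.numeric(istd), epsilon = as.numeric(epsilon),
         overlap_flag = isTRUE(overlap_flag)),
    class = "saturation_series")
}

#' @export
print.saturation_series <- function(x, ...) {
  cat(sprintf("Saturation series %s/%s (%.2f ppm), %d points, epsilon = %g%s\n",
              x$ligand_id, x$proton_id, x$chemical_shift, length(x$times),
              x$epsilon, if (x$overlap_flag) " [overlap]" else ""))
  invisible(x)
}

# Model: eta(t) = STD_max (1 - exp(-k_sat t))
buildup_model <- function(t, std_max, k_sat) std_max * (1 - exp(-k_sat * t))

#' Fit an STD build-up curve
#'
#' Fits the saturating mono-exponential
#' \deqn{\eta(t) = STD_{max}\,(1 - e^{-k_{sat} t})}
#' to one proton's amplification factors by nonlinear least squares and
#' derives the initial growth rate \eqn{STD_0 = STD_{max} k_{sat}}, the
#' transfer measure used for epitope mapping because it is insensitive to
#' per-proton relaxation and spin-diffusion differences. Standard errors
#' come from the fit covariance; the one for STD0 by first-order (delta
#' method) propagation.
#'
#' Starting values are `STD_max = max(eta)` and
#' `k_sat = eta(t1)/(STD_max t1)` clipped to `[1e-3, 10]` 1/s; parameters
#' are bounded by `STD_max <= epsilon` and `k_sat <= 100` 1/s. Negative
#' amplification factors are retained (clipping would bias the fit); a
#' warning is recorded on the result.
#'
#' @param series a [saturation_series()] with at least 3 usable points and
#'   `overlap_flag = FALSE`.
#' @param eta_floor smallest amplification factor regarded as evidence of
#'   transfer; if every eta falls below it a no-binding error is raised.
#' @param weights optional per-point weights (e.g. inverse variances from
#'   replicate spectra); default unweighted.
#' @param k_fixed optional fixed saturation rate (1/s). When supplied, only
#'   the amplitude is estimated (a linear fit of eta on
#'   `1 - exp(-k_fixed t)`). Intended for competition refits: displacement
#'   from a binding site scales the transfer amplitude, not its build-up
#'   rate (fast exchange), so fixing the rate at the reference fit's value
#'   keeps the STD0 ratio well conditioned for strongly attenuated signals.
#' @return An object of class `buildup_fit` with elements `proton_id`,
#'   `chemical_shift`, `std_max`, `k_sat`, `std0`, `se_std_max`, `se_k_sat`,
#'   `se_std0`, `rss`, `converged`, `n_points`, `warnings`.
#' @seealso [epitope_map()], [fit_buildup_set()]
#' @export
fit_buildup <- function(series, eta_floor = 0.05, weights = NULL,
                        k_fixed = NULL) {
  stopifnot(inherits(series, "saturation_series"))
  if (series$overlap_flag)
    stop_stdbind("stdbind_overlap_error",
                 sprintf("proton %s: signal overlap, STD0 cannot be determined",
                         series$proton_id))
  if (length(series$times) < 3L)
    abort_invalid("at least 3 time points are required for the build-up fit")

  eta <- suppressWarnings(
    amplification_factor(series$i0, series$istd, series$epsilon))
  warns <- character(0)
  if (any(eta < 0))
    warns <- c(warns, "negative amplification factors retained in fit")
  if (all(eta < eta_floor))
    stop_stdbind("stdbind_no_binding_error",
                 sprintf("proton %s: no saturation transfer detected (all eta < %g)",
                         series$proton_id, eta_floor))

  t <- series$times
  if (!is.null(k_fixed)) {
    if (!is_scalar_number(k_fixed) || k_fixed <= 0)
      abort_invalid("k_fixed must be a positive rate (1/s)")
    return(fit_amplitude_fixed_rate(series, eta, k_fixed, warns))
  }
  std_max0 <- max(eta)
  k0 <- eta[1L] / (std_max0 * t[1L])
  k0 <- min(max(k0, 1e-3), 10)
  dat <- data.frame(t = t, eta = eta)

  args <- list(
    eta ~ std_max * (1 - exp(-k_sat * t)),
    data = dat,
    start = list(std_max = std_max0, k_sat = k0),
    lower = c(std_max = 1e-12, k_sat = 1e-12),
    upper = c(std_max = series$epsilon, k_sat = 100),
    control = minpack.lm::nls.lm.control(
      maxiter = 1024, ftol = 1e-15, ptol = 1e-15))
  if (!is.null(weights)) args$weights <- weights
  fit <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) e)

  if (inherits(fit, "error")) {
    return(new_buildup_fit(series, std_max = NA_real_, k_sat = NA_real_,
                           cov = NULL, rss = NA_real_, converged = FALSE,
                           warnings = c(warns, conditionMessage(fit))))
  }

  cf <- coef(fit)
  res <- stats::residuals(fit)
  cv <- hc_covariance(t, cf[["std_max"]], cf[["k_sat"]], res) %||%
    tryCatch(vcov(fit), error = function(e) NULL)
  rss <- sum(res^2)
  conv <- isTRUE(fit$convInfo$isConv %||% TRUE)
  # an estimate pinned at the box constraints is not a usable optimum:
  # report it, but flag the fit so downstream ratios exclude it
  at_bound <- cf[["std_max"]] >= 0.999 * series$epsilon ||
    cf[["std_max"]] <= 2e-12 || cf[["k_sat"]] >= 99.9 ||
    cf[["k_sat"]] <= 2e-12
  if (at_bound) {
    warns <- c(warns, "parameter estimate at bound; fit flagged unreliable")
    conv <- FALSE
  }
  new_buildup_fit(series, std_max = unname(cf[["std_max"]]),
                  k_sat = unname(cf[["k_sat"]]), cov = cv, rss = rss,
                  converged = conv, warnings = warns)
}

# Amplitude-only fit at a fixed saturation rate: eta = m (1 - exp(-k t))
# is linear in m, so the estimate is closed-form; the HC3-type variance
# keeps the se honest under intensity-proportional noise.
fit_amplitude_fixed_rate <- function(series, eta, k_fixed, warns) {
  t <- series$times
  f <- 1 - exp(-k_fixed * t)
  sf2 <- sum(f^2)
  m <- sum(f * eta) / sf2
  res <- eta - m * f
  h <- pmin(f^2 / sf2, 0.999)
  var_m <- sum(f^2 * res^2 / (1 - h)^2) / sf2^2
  conv <- TRUE
  if (m <= 0 || m >= 0.999 * series$epsilon) {
    warns <- c(warns,
               "amplitude estimate outside its physical range; fit flagged")
    conv <- FALSE
  }
  out <- new_buildup_fit(series, std_max = m, k_sat = k_fixed,
                         cov = matrix(c(var_m, 0, 0, 0), 2),
                         rss = sum(res^2), converged = conv,
                         warnings = warns)
  out$k_fixed <- TRUE
  out
}

# Heteroscedasticity-consistent (HC3-type) parameter covariance. The
# multiplicative intensity noise makes the eta errors scale with the
# residual signal, so the homoscedastic least-squares covariance is
# miscalibrated; the sandwich with leverage correction is not.
hc_covariance <- function(t, std_max, k_sat, res) {
  e <- exp(-k_sat * t)
  J <- cbind(1 - e, std_max * t * e)
  JtJ <- crossprod(J)
  if (!all(is.finite(JtJ))) return(NULL)
  JtJi <- tryCatch(solve(JtJ), error = function(e) NULL)
  if (is.null(JtJi)) return(NULL)
  h <- pmin(rowSums((J %*% JtJi) * J), 0.999)
  meat <- crossprod(J * (res / (1 - h)), J * (res / (1 - h)))
  V <- JtJi %*% meat %*% JtJi
  if (!all(is.finite(V))) return(NULL)
  V
}

new_buildup_fit <- function(series, std_max, k_sat, cov, rss, converged,
                            warnings = character(0)) {
  std0 <- std_max * k_sat
  se <- c(std_max = NA_real_, k_sat = NA_real_, std0 = NA_real_)
  if (!is.null(cov) && all(is.finite(cov))) {
    se[["std_max"]] <- sqrt(cov[1, 1])
    se[["k_sat"]] <- sqrt(cov[2, 2])
    # delta method: var(m k) = k^2 Vmm + m^2 Vkk + 2 m k Vmk
    v <- k_sat^2 * cov[1, 1] + std_max^2 * cov[2, 2] +
      2 * std_max * k_sat * cov[1, 2]
    se[["std0"]] <- sqrt(max(v, 0))
  }
  structure(
    list(ligand_id = series$ligand_id, proton_id = series$proton_id,
         chemical_shift = series$chemical_shift,
         std_max = std_max, k_sat = k_sat, std0 = std0,
         se_std_max = se[["std_max"]], se_k_sat = se[["k_sat"]],
         se_std0 = se[["std0"]], rss = rss, converged = converged,
         n_points = length(series$times), warnings = warnings),
    class = "buildup_fit")
}

#' @export
print.buildup_fit <- function(x, ...) {
  cat(sprintf("Build-up fit %s/%s (%.2f ppm)%s\n", x$ligand_id, x$proton_id,
              x$chemical_shift, if (x$converged) "" else " [NOT CONVERGED]"))
  cat(sprintf("  STD_max = %.4g +/- %.2g, k_sat = %.4g +/- %.2g 1/s\n",
              x$std_max, x$se_std_max, x$k_sat, x$se_k_sat))
  cat(sprintf("  STD0 = %.4g +/- %.2g 1/s (rss = %.3g, n = %d)\n",
              x$std0, x$se_std0, x$rss, x$n_points))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Predicted build-up curve from a fit
#'
#' @param object a `buildup_fit`.
#' @param t saturation times (s) at which to evaluate the fitted curve.
#' @param ... unused.
#' @return Numeric vector of fitted amplification factors.
#' @export
predict.buildup_fit <- function(object, t, ...) {
  buildup_model(t, object$std_max, object$k_sat)
}

#' Fit build-up curves for a set of protons
#'
#' Applies [fit_buildup()] to each series, collecting successful fits and
#' recording protons that cannot be determined (overlap, no transfer,
#' non-convergence) with their reasons instead of aborting.
#'
#' @param series_list list of [saturation_series()].
#' @param ... passed to [fit_buildup()].
#' @param reference_fits optional fit set (or list of fits) from a
#'   reference condition; each series is then refitted with the saturation
#'   rate fixed at its reference fit's `k_sat` (see `k_fixed` in
#'   [fit_buildup()]). Protons without a converged reference fit fall back
#'   to a free fit.
#' @return List with `fits` (named by proton_id) and `undetermined`
#'   (data frame proton_id, reason).
#' @export
fit_buildup_set <- function(series_list, ..., reference_fits = NULL) {
  ref <- NULL
  if (!is.null(reference_fits)) {
    ref <- if (!is.null(reference_fits$fits)) reference_fits$fits
    else reference_fits
    names(ref) <- vapply(ref, function(f) f$proton_id, character(1))
  }
  fits <- list()
  und <- data.frame(proton_id = character(0), reason = character(0),
                    stringsAsFactors = FALSE)
  for (s in series_list) {
    rf <- if (!is.null(ref)) ref[[s$proton_id]] else NULL
    kf <- if (!is.null(rf) && rf$converged) rf$k_sat else NULL
    res <- tryCatch(fit_buildup(s, ..., k_fixed = kf),
                    stdbind_error = function(e) e)
    if (inherits(res, "buildup_fit") && res$converged) {
      fits[[s$proton_id]] <- res
    } else {
      reason <- if (inherits(res, "stdbind_overlap_error")) "overlap"
      else if (inherits(res, "stdbind_no_binding_error")) "no_transfer"
      else "non_convergence"
      und <- rbind(und, data.frame(proton_id = s$proton_id, reason = reason,
                                   stringsAsFactors = FALSE))
    }
  }
  list(fits = fits, undetermined = und)
}

#' Flat table of build-up fit parameters
#'
#' One row per proton with the fitted parameters, STD0 values and standard
#' errors — the export format for supplementary-style fit tables.
#'
#' @param fits list of `buildup_fit` objects (e.g. `fit_buildup_set()$fits`).
#' @return data frame, one row per fit, ordered by descending STD0.
#' @export
fits_table <- function(fits) {
  if (length(fits) == 0L) abort_invalid("no fits supplied")
  rows <- lapply(fits, function(f)
    data.frame(ligand_id = f$ligand_id, proton_id = f$proton_id,
               chemical_shift_ppm = f$chemical_shift,
               std_max = f$std_max, se_std_max = f$se_std_max,
               k_sat_per_s = f$k_sat, se_k_sat = f$se_k_sat,
               std0_per_s = f$std0, se_std0 = f$se_std0,
               rss = f$rss, converged = f$converged, n_points = f$n_points,
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-out$std0_per_s, out$chemical_shift_ppm), , drop = FALSE]
}

#' Normalized epitope-binding map
#'
#' Normalizes the STD0 of each converged fit to the ligand's largest STD0
#' (= 100 percent). The larger a proton's normalized STD0, the closer its
#' contact with the protein surface. Protons without a converged fit are
#' excluded and listed separately. Ties at the maximum are broken by the
#' lowest chemical shift so the reference proton is deterministic.
#'
#' @param fits list of `buildup_fit` objects for one ligand, or the result
#'   of [fit_buildup_set()].
#' @return Object of class `epitope_map`: a list with `ligand_id`,
#'   `entries` (data frame proton_id, chemical_shift_ppm,
#'   normalized_std0_percent, sorted descending), `reference_proton`, and
#'   `excluded` (data frame proton_id, reason).
#' @examples
#' # STD0 2.0 : 1.0 : 0.5 maps to 100% : 50% : 25%
#' @export
epitope_map <- function(fits) {
  excluded <- data.frame(proton_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  if (is.list(fits) && !is.null(fits$fits)) {
    excluded <- fits$undetermined
    fits <- fits$fits
  }
  ok <- Filter(function(f) inherits(f, "buildup_fit") && f$converged &&
                 is.finite(f$std0) && f$std0 > 0, fits)
  if (length(ok) == 0L)
    stop_stdbind("stdbind_empty_map_error",
                 "no converged fits with positive STD0: cannot build epitope map")
  std0 <- vapply(ok, function(f) f$std0, numeric(1))
  shift <- vapply(ok, function(f) f$chemical_shift, numeric(1))
  pid <- vapply(ok, function(f) f$proton_id, character(1))
  lig <- unique(vapply(ok, function(f) f$ligand_id, character(1)))
  if (length(lig) != 1L)
    abort_invalid("epitope_map expects fits from a single ligand")
  norm <- 100 * std0 / max(std0)
  # reference = proton attaining the maximum; ties -> lowest shift
  at_max <- which(norm >= 100 - 1e-12)
  ref <- pid[at_max[order(shift[at_max])][1L]]
  entries <- data.frame(proton_id = pid, chemical_shift_ppm = shift,
                        normalized_std0_percent = norm,
                        stringsAsFactors = FALSE)
  entries <- entries[order(-entries$normalized_std0_percent,
                           entries$chemical_shift_ppm), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(ligand_id = lig, entries = entries,
                 reference_proton = ref, excluded = excluded),
            class = "epitope_map")
}

#' @export
print.epitope_map <- function(x, ...) {
  cat(sprintf("Epitope-binding map for %s (reference proton: %s)\n",
              x$ligand_id, x$reference_proton))
  for (i in seq_len(nrow(x$entries)))
    cat(sprintf("  %-8s %6.2f ppm  %5.1f%%\n", x$entries$proton_id[i],
                x$entries$chemical_shift_ppm[i],
                x$entries$normalized_std0_percent[i]))
  if (nrow(x$excluded))
    cat("  undetermined:", paste(x$excluded$proton_id, collapse = ", "), "\n")
  invisible(x)
}

#' Plot a build-up curve fit
#'
#' Base-graphics plot of the measured amplification factors and the fitted
#' mono-exponential.
#'
#' @param x a `buildup_fit`.
#' @param series the [saturation_series()] the fit came from (for points).
#' @param ... passed to [plot()].
#' @export
plot_buildup <- function(x, series, ...) {
  eta <- suppressWarnings(
    amplification_factor(series$i0, series$istd, series$epsilon))
  tt <- seq(0, max(series$times), length.out = 200)
  plot(series$times, eta, xlab = "saturation time (s)",
       ylab = expression(eta), pch = 16, ...)
  graphics::lines(tt, predict(x, tt))
}
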
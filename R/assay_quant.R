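# Assay quantification: CD, FRAP, luciferase, condensates, landmarks --------

#' Parameters for mean residue ellipticity conversion
#'
#' @param mw Peptide molecular weight (g/mol).
#' @param n_residues Number of residues `n` (the formula divides by
#'   `n - 1`, the number of peptide bonds; `n >= 2`).
#' @param conc_mg_ml Peptide concentration (mg/mL).
#' @param pathlength_cm Cuvette path length (cm).
#' @return An object of class `mre_params`.
#' @export
mre_params <- function(mw, n_residues, conc_mg_ml, pathlength_cm) {
  if (n_residues < 2) {
    stop("mean residue ellipticity requires n_residues >= 2 (divides by n - 1)",
         call. = FALSE)
  }
  stopifnot(mw > 0, conc_mg_ml > 0, pathlength_cm > 0)
  structure(list(mw = mw, n_residues = n_residues,
                 conc_mg_ml = conc_mg_ml, pathlength_cm = pathlength_cm),
            class = "mre_params")
}

#' Mean residue ellipticity
#'
#' Converts measured ellipticity to per-residue molar ellipticity:
#' `[theta] = theta * mw / (10 * (n - 1) * c * pl)` in
#' deg cm^2 dmol^-1, where `theta` is the measured ellipticity (mdeg),
#' `mw` the peptide molecular weight, `n` the residue count, `c` the
#' concentration (mg/mL) and `pl` the path length (cm).
#'
#' @param theta_mdeg Measured ellipticity (mdeg); vectorized.
#' @param params An [mre_params()].
#' @return Mean residue ellipticity, same length as `theta_mdeg`.
#' @examples
#' mean_residue_ellipticity(20, mre_params(1000, 11, 1, 0.1))  # 2000
#' @export
mean_residue_ellipticity <- function(theta_mdeg, params) {
  stopifnot(inherits(params, "mre_params"))
  theta_mdeg * params$mw /
    (10 * (params$n_residues - 1) * params$conc_mg_ml * params$pathlength_cm)
}

#' A circular dichroism spectrum at one temperature
#'
#' @param wavelengths Strictly increasing wavelength grid (nm).
#' @param ellipticity_mdeg Blank-subtracted ellipticity per wavelength.
#' @param temperature_c Acquisition temperature (deg C).
#' @param params Optional [mre_params()]; if given, the mean residue
#'   ellipticity is computed and stored as `mre`.
#' @return An object of class `cd_spectrum`.
#' @export
cd_spectrum <- function(wavelengths, ellipticity_mdeg, temperature_c,
                        params = NULL) {
  stopifnot(length(wavelengths) == length(ellipticity_mdeg),
            all(diff(wavelengths) > 0))
  mre <- if (!is.null(params)) {
    mean_residue_ellipticity(ellipticity_mdeg, params)
  } else ellipticity_mdeg
  structure(list(wavelengths = wavelengths,
                 ellipticity_mdeg = ellipticity_mdeg,
                 temperature_c = temperature_c, mre = mre),
            class = "cd_spectrum")
}

# nearest grid point within 1 nm, else error
cd_index_at <- function(wavelengths, target) {
  i <- which.min(abs(wavelengths - target))
  if (abs(wavelengths[i] - target) > 1) {
    stop(sprintf("no wavelength grid point within 1 nm of %g nm", target),
         call. = FALSE)
  }
  i
}

#' Spectral features of a CD temperature series
#'
#' Computes (i) the subtraction spectrum, pointwise lowest-temperature
#' minus highest-temperature signal, whose 222/208 nm ellipticity ratio
#' > 1 is the coiled-coil signature; (ii) the 222/208 ratio per spectrum;
#' and (iii) the melt curve of the 222 nm signal normalized to its value
#' at the lowest temperature.
#'
#' @param spectra List of [cd_spectrum()]s sharing one wavelength grid.
#' @return List with `subtraction` (data frame `wavelength`, `delta`),
#'   `ratio_222_208` (named by temperature), `subtraction_ratio_222_208`,
#'   and `melt` (data frame `temperature_c`, `mre_222`, `normalized`).
#' @export
cd_features <- function(spectra) {
  stopifnot(is.list(spectra), length(spectra) >= 2L,
            all(vapply(spectra, inherits, logical(1), "cd_spectrum")))
  w <- spectra[[1L]]$wavelengths
  same <- vapply(spectra, function(s) {
    length(s$wavelengths) == length(w) && all(s$wavelengths == w)
  }, logical(1))
  if (!all(same)) {
    stop("spectra do not share a common wavelength grid", call. = FALSE)
  }
  temps <- vapply(spectra, `[[`, numeric(1), "temperature_c")
  ord <- order(temps)
  spectra <- spectra[ord]; temps <- temps[ord]
  i222 <- cd_index_at(w, 222)
  i208 <- cd_index_at(w, 208)
  low <- spectra[[1L]]$mre
  high <- spectra[[length(spectra)]]$mre
  delta <- low - high
  ratio <- vapply(spectra, function(s) s$mre[i222] / s$mre[i208], numeric(1))
  names(ratio) <- temps
  mre222 <- vapply(spectra, function(s) s$mre[i222], numeric(1))
  if (mre222[1L] == 0) {
    stop("melt normalization: zero 222 nm signal at the lowest temperature",
         call. = FALSE)
  }
  list(
    subtraction = data.frame(wavelength = w, delta = delta),
    ratio_222_208 = ratio,
    subtraction_ratio_222_208 = delta[i222] / delta[i208],
    melt = data.frame(temperature_c = temps, mre_222 = mre222,
                      normalized = mre222 / mre222[1L])
  )
}

#' A FRAP recovery trace
#'
#' @param time_s Strictly increasing acquisition times (s).
#' @param bleached_intensity Raw intensity of the photobleached region.
#' @param control_intensities Matrix (or vector) of raw intensities of one
#'   or more non-photobleached control regions, one column per region.
#' @param n_prebleach Number of pre-bleach frames at the start of the
#'   series (the bleach pulse falls between frames `n_prebleach` and
#'   `n_prebleach + 1`).
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(time_s, bleached_intensity, control_intensities,
                       n_prebleach = 3L) {
  control_intensities <- as.matrix(control_intensities)
  stopifnot(all(diff(time_s) > 0),
            length(bleached_intensity) == length(time_s),
            nrow(control_intensities) == length(time_s),
            n_prebleach >= 1L, n_prebleach < length(time_s))
  structure(list(time_s = time_s, bleached_intensity = bleached_intensity,
                 control_intensities = control_intensities,
                 n_prebleach = as.integer(n_prebleach)),
            class = "frap_trace")
}

#' Double-normalize a FRAP trace
#'
#' Step 1 divides each series (bleached and controls) by its own
#' pre-bleach mean; step 2 divides the bleached series pointwise by the
#' mean of the normalized controls, cancelling acquisition photobleaching
#' shared by all regions. On the resulting scale the pre-bleach level is
#' 1 by construction.
#'
#' @param trace A [frap_trace()].
#' @return Data frame with `time_s` and `normalized`.
#' @export
frap_normalize <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  pre <- seq_len(trace$n_prebleach)
  bl_pre <- mean(trace$bleached_intensity[pre])
  if (bl_pre <= 0) {
    stop("pre-bleach mean of the bleached series must be positive",
         call. = FALSE)
  }
  if (any(trace$control_intensities <= 0)) {
    stop("control intensities must be positive at all times", call. = FALSE)
  }
  bl <- trace$bleached_intensity / bl_pre
  ctrl <- sweep(trace$control_intensities, 2,
                colMeans(trace$control_intensities[pre, , drop = FALSE]),
                "/")
  data.frame(time_s = trace$time_s,
             normalized = bl / rowMeans(ctrl))
}

#' Fit single-exponential recovery to a doubly normalized FRAP trace
#'
#' Post-bleach points (time re-zeroed at the first post-bleach frame) are
#' fitted by bounded least squares to
#' `F(t) = F0 + (P - F0) * (1 - exp(-t / tau))` with `F0` in `[0, 1]`,
#' `P` in `[0, 1.5]`, `tau > 0`, initialized from crude estimates (first
#' post-bleach value, mean of the last 10 points, time to half recovery).
#' Reported: `tau_s`, `t_half_s = tau * log(2)`, `plateau`, and
#' `mobile_fraction = (P - F0) / (1 - F0)` on the doubly normalized scale
#' where pre-bleach is 1.
#'
#' @param trace A [frap_trace()].
#' @return An object of class `frap_fit`: `t_half_s`, `mobile_fraction`,
#'   `tau_s`, `plateau`, `f0`, `residual_rms`, `flags` (contains
#'   `"no_recovery"` when the plateau falls below the post-bleach floor),
#'   and `curve` (time, observed, fitted).
#' @export
frap_normalize_fit <- function(trace) {
  norm <- frap_normalize(trace)
  post <- (trace$n_prebleach + 1L):nrow(norm)
  t_rel <- norm$time_s[post] - norm$time_s[post[1L]]
  y <- norm$normalized[post]
  f0_0 <- max(0, min(1, y[1L]))
  p_0 <- max(f0_0, min(1.5, mean(utils::tail(y, 10L))))
  half <- which(y >= (f0_0 + p_0) / 2)
  tau_0 <- if (length(half) > 0L && t_rel[half[1L]] > 0) {
    t_rel[half[1L]] / log(2)
  } else max(t_rel) / 4
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ f0 + (p - f0) * (1 - exp(-t_rel / tau)),
      start = list(f0 = f0_0, p = p_0, tau = max(tau_0, 1e-3)),
      lower = c(f0 = 0, p = 0, tau = 1e-6),
      upper = c(f0 = 1, p = 1.5, tau = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop(sprintf(
        "FRAP fit did not converge: %s (post-bleach range %.3f-%.3f)",
        conditionMessage(e), min(y), max(y)), call. = FALSE)
    })
  cf <- stats::coef(fit)
  flags <- character(0)
  if (cf[["p"]] < cf[["f0"]]) flags <- c(flags, "no_recovery")
  fitted_y <- stats::fitted(fit)
  structure(
    list(t_half_s = cf[["tau"]] * log(2),
         mobile_fraction = (cf[["p"]] - cf[["f0"]]) / (1 - cf[["f0"]]),
         tau_s = cf[["tau"]], plateau = cf[["p"]], f0 = cf[["f0"]],
         residual_rms = sqrt(mean((y - fitted_y)^2)),
         flags = flags,
         curve = data.frame(time_s = norm$time_s[post], observed = y,
                            fitted = fitted_y)),
    class = "frap_fit"
  )
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit> t-half = %.2f s, mobile fraction = %.3f, plateau = %.3f%s\n",
    x$t_half_s, x$mobile_fraction, x$plateau,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ";"), "]")
    else ""))
  invisible(x)
}

#' Dual-luciferase normalization
#'
#' Firefly luminescence is first normalized against the Renilla
#' luminescence of the same well (transfection control), then all ratios
#' are divided by the mean ratio of the experimental control group, so the
#' control-group mean of the output is exactly 1.
#'
#' @param firefly,renilla Per-well luminescence readings.
#' @param group_labels Group label per well.
#' @param control_group Label of the control group.
#' @return Numeric vector of normalized values per well.
#' @export
luciferase_normalize <- function(firefly, renilla, group_labels,
                                 control_group = "control") {
  stopifnot(length(firefly) == length(renilla),
            length(firefly) == length(group_labels))
  bad <- which(renilla <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("non-positive Renilla reading in well %d", bad[1L]),
         call. = FALSE)
  }
  ctrl <- group_labels == control_group
  if (!any(ctrl)) {
    stop(sprintf("control group '%s' is empty", control_group),
         call. = FALSE)
  }
  ratio <- firefly / renilla
  ratio / mean(ratio[ctrl])
}

#' Relative (and control-normalized) condensate area
#'
#' The proportion of the cell/nuclear area occupied by condensates is the
#' ratio of the two areas; an optional control mean rescales it so the
#' control condition averages 1.
#'
#' @param condensate_area Area occupied by condensates; vectorized.
#' @param reference_area Total cell or nuclear area (must be positive).
#' @param control_mean Optional mean relative area of the control
#'   condition.
#' @return Data frame with `relative` and (if `control_mean` is given)
#'   `normalized`.
#' @examples
#' condensate_relative_area(10, 100)
#' @export
condensate_relative_area <- function(condensate_area, reference_area,
                                     control_mean = NULL) {
  if (any(reference_area <= 0)) {
    stop("reference area must be positive", call. = FALSE)
  }
  out <- data.frame(relative = condensate_area / reference_area)
  if (!is.null(control_mean)) {
    stopifnot(control_mean > 0)
    out$normalized <- out$relative / control_mean
  }
  out
}

#' Cochlear landmark ratios
#'
#' Computes the cochlear-width/basicranial-width (CW/BW) ratio and the
#' cochlear height-to-width ratio from 3-D landmark coordinates. Each
#' ratio is the Euclidean distance between one landmark pair divided by
#' another's.
#'
#' @param landmarks Data frame with columns `label`, `x`, `y`, `z`;
#'   required labels (each exactly twice): `cochlear_width`,
#'   `cochlear_height`, `basicranium_width`.
#' @return Named list with `cw_over_bw` and `height_over_width`.
#' @export
cochlear_ratios <- function(landmarks) {
  stopifnot(is.data.frame(landmarks),
            all(c("label", "x", "y", "z") %in% names(landmarks)))
  if (!all(is.finite(as.matrix(landmarks[, c("x", "y", "z")])))) {
    stop("landmark coordinates must be finite", call. = FALSE)
  }
  pair_dist <- function(lab) {
    pts <- landmarks[landmarks$label == lab, c("x", "y", "z")]
    if (nrow(pts) != 2L) {
      stop(sprintf("landmark '%s' must appear exactly twice (found %d)",
                   lab, nrow(pts)), call. = FALSE)
    }
    sqrt(sum((pts[1L, ] - pts[2L, ])^2))
  }
  cw <- pair_dist("cochlear_width")
  ch <- pair_dist("cochlear_height")
  bw <- pair_dist("basicranium_width")
  if (bw == 0 || cw == 0) {
    stop("zero denominator distance in landmark ratio", call. = FALSE)
  }
  list(cw_over_bw = cw / bw, height_over_width = ch / cw)
}
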
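# Synthetic fixtures with ground truth --------------------------------------
#
# Every generator is deterministic given its seed and returns, alongside
# the generated object, a truth record sufficient to assert the downstream
# call exactly. Flanking sequence excludes Q, P and H so that the
# programmed repeat structure is the only repeat structure present.

FLANK_ALPHABET <- setdiff(c("A", "C", "D", "E", "F", "G", "I", "K", "L",
                            "M", "N", "R", "S", "T", "V", "W", "Y"),
                          character(0))

random_flank <- function(n) {
  if (n == 0L) return("")
  paste(sample(FLANK_ALPHABET, n, replace = TRUE), collapse = "")
}

#' Generate one ortholog sequence with programmed repeat structure
#'
#' Builds `flank + Q1 block + (P + Q fragment)* + hinge + extension +
#' Q2 run + flank`. The Q1 block is a pure Q run of length `q1`, or, with
#' `histidine_in_q1`, a run of total length `q1` with one interior
#' histidine. Proline blocks (one `P` followed by a short fragmented Q
#' run each) sit between the Q1 block and the hinge, so the proline rule
#' truncates Q1 at the programmed length. An extension peptide, e.g. the
#' 22-residue cetacean hinge insertion `"VGSGRLTHAEEGEAGRGPRRPG"`, can be
#' inserted between hinge and Q2.
#'
#' @param q1,q2 Programmed repeat lengths (`q2 >= 2`; `q1 >= 3` when
#'   `histidine_in_q1`, else `>= 2`).
#' @param gene `"FOXP2"` or `"FOXP1"` (selects the canonical hinge).
#' @param proline_fragments Integer vector: lengths of the fragmented Q
#'   runs following each inserted proline (empty for no interruption).
#' @param histidine_in_q1 Embed a single interior histidine in Q1.
#' @param hinge_variant Hinge peptide to use (default canonical for
#'   `gene`).
#' @param extension_peptide Optional peptide inserted between hinge and
#'   Q2 (must not contain Q).
#' @param flank_lengths Lengths of the random N-/C-terminal flanks.
#' @param species_label,sequence_id Labels for the record.
#' @param seed Optional integer seed (restricts determinism to this call).
#' @return List with `record` (an [ortholog_record()]) and `truth`
#'   (programmed `q1`, `q2`, `extension_len`, `n_prolines`,
#'   `histidine_in_q1`).
#' @examples
#' gen_ortholog(40, 10, seed = 1)$truth
#' @export
gen_ortholog <- function(q1, q2, gene = c("FOXP2", "FOXP1"),
                         proline_fragments = integer(0),
                         histidine_in_q1 = FALSE, hinge_variant = NULL,
                         extension_peptide = NULL,
                         flank_lengths = c(30L, 30L),
                         species_label = "synthetic",
                         sequence_id = "syn1", seed = NULL) {
  gene <- match.arg(gene)
  if (!is.null(seed)) set.seed(seed)
  min_q1 <- if (histidine_in_q1) 3L else 2L
  stopifnot(q1 >= min_q1, q2 >= 2L, all(proline_fragments >= 0L),
            length(flank_lengths) == 2L, all(flank_lengths >= 0L))
  hinge <- if (is.null(hinge_variant)) {
    unname(CANONICAL_HINGES[gene])
  } else toupper(hinge_variant)
  ext <- if (is.null(extension_peptide)) "" else toupper(extension_peptide)
  if (grepl("Q", ext, fixed = TRUE)) {
    stop("extension peptide must not contain Q", call. = FALSE)
  }
  q1_block <- if (histidine_in_q1) {
    a <- (q1 - 1L) %/% 2L
    paste0(strrep("Q", a), "H", strrep("Q", q1 - 1L - a))
  } else strrep("Q", q1)
  p_blocks <- paste(vapply(proline_fragments,
                           function(f) paste0("P", strrep("Q", f)),
                           character(1)),
                    collapse = "")
  sequence <- paste0(random_flank(flank_lengths[1L]), q1_block, p_blocks,
                     hinge, ext, strrep("Q", q2),
                     random_flank(flank_lengths[2L]))
  rec <- ortholog_record(species_label, gene, sequence_id, sequence)
  list(record = rec,
       truth = list(q1 = as.integer(q1), q2 = as.integer(q2),
                    extension_len = nchar(ext),
                    n_prolines = length(proline_fragments),
                    histidine_in_q1 = histidine_in_q1))
}

#' Quantize a target ratio to integer (q1, q2) repeat lengths
#'
#' Chooses `q2` in `2..q2_max` (and `q1 = round(ratio * q2)`, at least 2
#' and at most `q1_max`) minimizing `|q1/q2 - ratio|`; ties prefer the
#' smallest `q2`. The default `q1_max` of 60 keeps Q1 within the observed
#' mammalian range and inside the repeat caller's upstream window.
#'
#' @param ratio Target Q1/Q2 ratio (positive).
#' @param q2_max Largest Q2 considered.
#' @param q1_max Largest Q1 considered.
#' @return Integer vector `c(q1, q2)`.
#' @export
quantize_ratio <- function(ratio, q2_max = 20L, q1_max = 60L) {
  stopifnot(ratio > 0)
  q2s <- 2:q2_max
  q1s <- pmax(2L, as.integer(round(ratio * q2s)))
  feasible <- q1s <= q1_max
  if (!any(feasible)) {
    stop(sprintf("ratio %g not representable with q1 <= %d", ratio, q1_max),
         call. = FALSE)
  }
  q2s <- q2s[feasible]; q1s <- q1s[feasible]
  err <- abs(q1s / q2s - ratio)
  i <- which.min(err)  # which.min takes the first (smallest q2) among ties
  c(q1 = q1s[i], q2 = q2s[i])
}

#' Generate a species panel with a programmed ratio-phenotype relationship
#'
#' Draws Q1/Q2 ratios uniformly over `ratio_range`, quantizes each to
#' integer repeat lengths, and programs per-species phenotypes as
#' `log10(freq kHz) = intercept + slope * ratio + N(0, noise_sd)` (and
#' analogously log10 body mass with its own slope). Sequences are built
#' with [gen_ortholog()]. The defaults emulate the magnitude of the
#' mammal-wide trend: frequencies fall from ~100 kHz at ratio 0.5 to the
#' low-kHz range at ratio 6 while body mass rises over four orders of
#' magnitude.
#'
#' @param n_species Panel size.
#' @param ratio_range Range of programmed ratios (low, high).
#' @param slope_logfreq_per_ratio,intercept_logfreq Linear model of log10
#'   frequency (kHz) on ratio.
#' @param slope_logmass_per_ratio,intercept_logmass Linear model of log10
#'   body mass (g) on ratio.
#' @param noise_sd Gaussian noise sd on both log10 scales.
#' @param gene `"FOXP2"` or `"FOXP1"`.
#' @param seed Integer seed; the same seed reproduces the panel exactly.
#' @return List with `records` (ortholog records), `phenotypes` (data
#'   frame: `species_label`, `char_freq_khz`, `min_freq_khz`,
#'   `body_mass_g`) and `truth` (programmed ratios, quantized `q1`, `q2`,
#'   realized ratio, noiseless log-frequency/mass).
#' @export
gen_panel_with_phenotypes <- function(n_species = 200L,
                                      ratio_range = c(0.5, 6),
                                      slope_logfreq_per_ratio = -0.35,
                                      intercept_logfreq = 2.2,
                                      slope_logmass_per_ratio = 0.8,
                                      intercept_logmass = 1.0,
                                      noise_sd = 0.15,
                                      gene = "FOXP2", seed = 1L) {
  stopifnot(n_species >= 2L, ratio_range[1L] < ratio_range[2L],
            ratio_range[1L] > 0, noise_sd >= 0)
  set.seed(seed)
  ratios <- stats::runif(n_species, ratio_range[1L], ratio_range[2L])
  qq <- t(vapply(ratios, quantize_ratio, integer(2)))
  logf <- intercept_logfreq + slope_logfreq_per_ratio * ratios
  logm <- intercept_logmass + slope_logmass_per_ratio * ratios
  freq <- 10^(logf + stats::rnorm(n_species, 0, noise_sd))
  mass <- 10^(logm + stats::rnorm(n_species, 0, noise_sd))
  labels <- sprintf("sp%03d", seq_len(n_species))
  records <- lapply(seq_len(n_species), function(i) {
    gen_ortholog(qq[i, "q1"], qq[i, "q2"], gene = gene,
                 species_label = labels[i],
                 sequence_id = sprintf("%s_seq", labels[i]))$record
  })
  list(
    records = records,
    phenotypes = data.frame(species_label = labels,
                            char_freq_khz = freq, min_freq_khz = freq,
                            body_mass_g = mass, stringsAsFactors = FALSE),
    truth = data.frame(species_label = labels, ratio_programmed = ratios,
                       q1 = qq[, "q1"], q2 = qq[, "q2"],
                       ratio_realized = qq[, "q1"] / qq[, "q2"],
                       logfreq_noiseless = logf, logmass_noiseless = logm,
                       stringsAsFactors = FALSE)
  )
}

#' Generate a synthetic FRAP trace
#'
#' Raw bleached and control series are constructed so that the double
#' normalization of [frap_normalize()] recovers
#' `F(t) = F0 + (P - F0) * (1 - exp(-t / tau))` (pre-bleach level 1) plus
#' optional Gaussian noise; an optional shared multiplicative decay
#' emulates acquisition photobleaching common to all regions.
#'
#' @param tau_s,f0,plateau Programmed recovery parameters on the doubly
#'   normalized scale.
#' @param noise_sd Gaussian noise sd added to the bleached series (on the
#'   normalized scale; must be non-negative).
#' @param n_prebleach,dt_s,t_post_s Sampling: pre-bleach frames, frame
#'   interval, post-bleach duration.
#' @param shared_decay_tau Optional time constant of a multiplicative
#'   exponential decay applied to bleached and control series alike.
#' @param seed Optional integer seed.
#' @return List with `trace` (a [frap_trace()]) and `truth`
#'   (`tau_s`, `t_half_s`, `f0`, `plateau`, `mobile_fraction`).
#' @export
gen_frap_trace <- function(tau_s = 24.28, f0 = 0.1, plateau = 0.802,
                           noise_sd = 0, n_prebleach = 3L, dt_s = 1,
                           t_post_s = 120, shared_decay_tau = NULL,
                           seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_post <- as.integer(round(t_post_s / dt_s))
  time_s <- seq(0, by = dt_s, length.out = n_prebleach + n_post)
  t_rel <- c(rep(NA_real_, n_prebleach),
             time_s[(n_prebleach + 1L):length(time_s)] -
               time_s[n_prebleach + 1L])
  ideal <- ifelse(is.na(t_rel), 1,
                  f0 + (plateau - f0) * (1 - exp(-t_rel / tau_s)))
  noisy <- ideal + c(rep(0, n_prebleach),
                     stats::rnorm(n_post, 0, noise_sd))
  decay <- if (is.null(shared_decay_tau)) rep(1, length(time_s)) else
    exp(-time_s / shared_decay_tau)
  bleached <- noisy * 100 * decay
  controls <- cbind(80 * decay, 120 * decay)
  list(trace = frap_trace(time_s, bleached, controls, n_prebleach),
       truth = list(tau_s = tau_s, t_half_s = tau_s * log(2), f0 = f0,
                    plateau = plateau,
                    mobile_fraction = (plateau - f0) / (1 - f0)))
}

#' Generate a synthetic CD temperature series
#'
#' Two fixed synthetic basis shapes (documented fixtures, no claim of
#' physical realism) share an isodichroic crossing at 203 nm: a
#' "structured" basis with negative lobes near 208 and 222 nm and a
#' "disordered" basis with a single deep minimum near 198 nm. The
#' spectrum at each temperature is `w * structured + (1 - w) *
#' disordered` for the supplied mixture weight.
#'
#' @param weights Mixture weights in `[0, 1]`, one per temperature.
#' @param temperatures_c Temperatures (deg C), same length as `weights`.
#' @param wavelengths Wavelength grid (nm).
#' @param noise_sd Gaussian noise sd added per point.
#' @param seed Optional integer seed.
#' @return List with `spectra` (list of [cd_spectrum()]s), `basis`
#'   (data frame with the two basis curves) and `truth` (the weights).
#' @export
gen_cd_spectra <- function(weights, temperatures_c,
                           wavelengths = seq(190, 260, by = 1),
                           noise_sd = 0, seed = NULL) {
  stopifnot(length(weights) == length(temperatures_c),
            all(weights >= 0 & weights <= 1))
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  w <- wavelengths
  structured <- 30000 * exp(-((w - 193) / 6)^2) -
    28000 * exp(-((w - 209) / 7)^2) - 26000 * exp(-((w - 222) / 7)^2)
  disordered <- -45000 * exp(-((w - 198) / 7)^2) +
    3000 * exp(-((w - 225) / 18)^2)
  at203 <- function(curve) curve[which.min(abs(w - 203))]
  disordered <- disordered + (at203(structured) - at203(disordered))
  spectra <- lapply(seq_along(weights), function(i) {
    signal <- weights[i] * structured + (1 - weights[i]) * disordered +
      stats::rnorm(length(w), 0, noise_sd)
    cd_spectrum(w, signal, temperatures_c[i])
  })
  list(spectra = spectra,
       basis = data.frame(wavelength = w, structured = structured,
                          disordered = disordered),
       truth = data.frame(temperature_c = temperatures_c,
                          weight = weights))
}

#' Generate a synthetic dual-luciferase plate
#'
#' Renilla readings are log-normal per well; firefly readings are
#' `effect * renilla * exp(N(0, noise_sd))`, so the programmed group
#' effect is the expected firefly/Renilla ratio relative to the control
#' group (whose effect should be 1).
#'
#' @param effects Named numeric vector of group effects; must include the
#'   control group.
#' @param wells_per_group Wells per group (recycled over groups).
#' @param noise_sd Log-scale noise sd on the firefly/Renilla ratio.
#' @param control_group Name of the control group within `effects`.
#' @param seed Optional integer seed.
#' @return List with `plate` (data frame: `well`, `group`, `firefly`,
#'   `renilla`) and `truth` (the effects).
#' @export
gen_luc_plate <- function(effects = c(control = 1, treated = 0.79),
                          wells_per_group = 12L, noise_sd = 0.03,
                          control_group = "control", seed = NULL) {
  stopifnot(!is.null(names(effects)), control_group %in% names(effects))
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  wells <- rep(names(effects),
               times = rep(wells_per_group, length.out = length(effects)))
  n <- length(wells)
  renilla <- stats::rlnorm(n, meanlog = log(1e5), sdlog = 0.2)
  firefly <- effects[wells] * renilla * exp(stats::rnorm(n, 0, noise_sd))
  list(plate = data.frame(well = sprintf("w%03d", seq_len(n)),
                          group = wells, firefly = as.numeric(firefly),
                          renilla = renilla, stringsAsFactors = FALSE),
       truth = effects)
}
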
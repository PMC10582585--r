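# Threshold classifiers for vocalization classes ----------------------------
#
# The published decision regions are thresholds on the polyQ sum and ratio:
#   * Chiroptera call types: non-echolocating (NE) species have sum > 60;
#     ultrasound emitters (sum <= 60) split by ratio into CF (< 1),
#     FM2 (1 to 2.1) and FM1 (> 2.1, up to ~3.5).
#   * Mammal-wide FOXP2 bands: low (<= 3.5), intermediate (3.5-4.5,
#     human-like), high (> 4.5, infrasonic specialists).
#   * FOXP1 bands: extreme-low (< 0.2), low (0.2-0.5), mid, high (>= 2).
# Boundary membership is not printed for every edge; the conventions here
# (NE strictly > 60, FM2 owning both endpoints, left-open/right-closed
# FOXP2 bands) are applied consistently and are config-overridable.

#' Thresholds for the repeat-length classifiers
#'
#' @param ne_sum_threshold Q1+Q2 sum above which a bat is non-echolocating.
#' @param cf_ratio_max,fm2_ratio_max,fm1_ratio_max Upper ratio limits of
#'   the CF, FM2 and FM1 regions.
#' @param mammal_low_max,mammal_high_min FOXP2 mammal-wide band edges
#'   (low: ratio <= `mammal_low_max`; high: ratio > `mammal_high_min`).
#' @param foxp1_extreme_max,foxp1_low_max,foxp1_high_min FOXP1 band edges.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(ne_sum_threshold = 60, cf_ratio_max = 1,
                              fm2_ratio_max = 2.1, fm1_ratio_max = 3.5,
                              mammal_low_max = 3.5, mammal_high_min = 4.5,
                              foxp1_extreme_max = 0.2, foxp1_low_max = 0.5,
                              foxp1_high_min = 2) {
  stopifnot(cf_ratio_max < fm2_ratio_max, fm2_ratio_max < fm1_ratio_max,
            mammal_low_max < mammal_high_min,
            foxp1_extreme_max < foxp1_low_max,
            foxp1_low_max < foxp1_high_min)
  structure(
    list(ne_sum_threshold = ne_sum_threshold, cf_ratio_max = cf_ratio_max,
         fm2_ratio_max = fm2_ratio_max, fm1_ratio_max = fm1_ratio_max,
         mammal_low_max = mammal_low_max, mammal_high_min = mammal_high_min,
         foxp1_extreme_max = foxp1_extreme_max,
         foxp1_low_max = foxp1_low_max, foxp1_high_min = foxp1_high_min),
    class = "classifier_config"
  )
}

#' Classify chiropteran call type from polyQ sum and ratio
#'
#' `NE` iff sum > 60; otherwise `CF` iff ratio < 1, `FM2` iff 1 <= ratio
#' <= 2.1, `FM1` iff 2.1 < ratio <= 3.5, else `UNASSIGNED` (ratio above
#' the chiropteran range). Undefined sum/ratio (flagged calls) yield
#' `UNASSIGNED`.
#'
#' @param sum_s Q1+Q2 sums (integer vector, `NA` allowed).
#' @param ratio_r Q1/Q2 ratios (numeric vector, `NA` allowed).
#' @param cfg A [classifier_config()].
#' @return Character vector over
#'   `{"NE","CF","FM2","FM1","UNASSIGNED"}`.
#' @examples
#' classify_usv_type(c(61, 50, 50, 50), c(2.0, 0.8, 1.5, 2.5))
#' @export
classify_usv_type <- function(sum_s, ratio_r, cfg = classifier_config()) {
  stopifnot(length(sum_s) == length(ratio_r))
  out <- rep("UNASSIGNED", length(sum_s))
  ne <- !is.na(sum_s) & sum_s > cfg$ne_sum_threshold
  out[ne] <- "NE"
  usv <- !ne & !is.na(sum_s) & !is.na(ratio_r) & ratio_r > 0
  out[usv & ratio_r < cfg$cf_ratio_max] <- "CF"
  out[usv & ratio_r >= cfg$cf_ratio_max & ratio_r <= cfg$fm2_ratio_max] <- "FM2"
  out[usv & ratio_r > cfg$fm2_ratio_max & ratio_r <= cfg$fm1_ratio_max] <- "FM1"
  out
}

#' Classify a Q1/Q2 ratio into published bands
#'
#' `FOXP2_MAMMAL`: `LOW` iff ratio <= 3.5, `INTERMEDIATE` iff
#' 3.5 < ratio <= 4.5, `HIGH` iff ratio > 4.5. `FOXP1`: `EXTREME_LOW` iff
#' ratio < 0.2, `LOW` iff 0.2 <= ratio < 0.5, `MID` iff 0.5 <= ratio < 2,
#' `HIGH` iff ratio >= 2. Undefined ratios yield `UNASSIGNED`.
#'
#' @param ratio_r Q1/Q2 ratios (numeric vector, `NA` allowed).
#' @param scheme `"FOXP2_MAMMAL"` or `"FOXP1"`.
#' @param cfg A [classifier_config()].
#' @return Character vector of band labels.
#' @examples
#' classify_ratio_band(c(4.0, 4.38, 10, 3.5), "FOXP2_MAMMAL")
#' classify_ratio_band(c(0.15, 0.3, 2.0), "FOXP1")
#' @export
classify_ratio_band <- function(ratio_r,
                                scheme = c("FOXP2_MAMMAL", "FOXP1"),
                                cfg = classifier_config()) {
  scheme <- match.arg(scheme)
  out <- rep("UNASSIGNED", length(ratio_r))
  ok <- !is.na(ratio_r) & ratio_r > 0
  r <- ratio_r
  if (scheme == "FOXP2_MAMMAL") {
    out[ok & r <= cfg$mammal_low_max] <- "LOW"
    out[ok & r > cfg$mammal_low_max & r <= cfg$mammal_high_min] <- "INTERMEDIATE"
    out[ok & r > cfg$mammal_high_min] <- "HIGH"
  } else {
    out[ok & r < cfg$foxp1_extreme_max] <- "EXTREME_LOW"
    out[ok & r >= cfg$foxp1_extreme_max & r < cfg$foxp1_low_max] <- "LOW"
    out[ok & r >= cfg$foxp1_low_max & r < cfg$foxp1_high_min] <- "MID"
    out[ok & r >= cfg$foxp1_high_min] <- "HIGH"
  }
  out
}

#' Map Collen call-type codes to FM groupings
#'
#' Frequency-modulated calls are grouped into `FM1` (single harmonic, or
#' peak harmonic as the fundamental; codes 3, 7, 8, 10) and `FM2`
#' (multi-harmonic; codes 4, 5, 6, 9). Codes outside these sets raise an
#' `unmapped_call_type` error — CF and NE codes are never guessed.
#'
#' @param code Integer vector of call-type codes.
#' @return Character vector over `{"FM1","FM2"}`.
#' @examples
#' call_type_from_collen(c(3, 9))
#' @export
call_type_from_collen <- function(code) {
  fm1 <- c(3L, 7L, 8L, 10L)
  fm2 <- c(4L, 5L, 6L, 9L)
  code <- as.integer(code)
  bad <- which(!code %in% c(fm1, fm2))
  if (length(bad) > 0L) {
    stop(sprintf("unmapped_call_type: code %d has no FM mapping",
                 code[bad[1L]]), call. = FALSE)
  }
  ifelse(code %in% fm1, "FM1", "FM2")
}

#' Classification table for a panel of repeat calls
#'
#' @param calls Data frame from [repeat_call_table()] (columns `species`,
#'   `gene`, `sum`, `ratio`, `flags`).
#' @param cfg A [classifier_config()].
#' @return Data frame with columns `species`, `gene`, `sum`, `ratio`,
#'   `usv_type`, `foxp2_band`, `foxp1_band`, `reasons`.
#' @export
classification_table <- function(calls, cfg = classifier_config()) {
  stopifnot(all(c("species", "gene", "sum", "ratio") %in% names(calls)))
  flags_chr <- if ("flags" %in% names(calls)) {
    f <- as.character(calls$flags)  # CSV round trips read "" as NA
    f[is.na(f)] <- ""
    f
  } else rep("", nrow(calls))
  flagged <- vapply(strsplit(flags_chr, ";", fixed = TRUE),
                    function(f) any(f %in% FATAL_FLAGS), logical(1))
  reasons <- ifelse(flagged, flags_chr, "")
  sum_s <- ifelse(flagged, NA_integer_, calls$sum)
  ratio <- ifelse(flagged, NA_real_, calls$ratio)
  data.frame(
    species = calls$species, gene = calls$gene,
    sum = sum_s, ratio = ratio,
    usv_type = classify_usv_type(sum_s, ratio, cfg),
    foxp2_band = classify_ratio_band(ratio, "FOXP2_MAMMAL", cfg),
    foxp1_band = classify_ratio_band(ratio, "FOXP1", cfg),
    reasons = reasons, stringsAsFactors = FALSE)
}
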
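# Hinge-anchored polyQ repeat calling ---------------------------------------
#
# The two major polyQ repeats of FOXP2/FOXP1 (Q1 upstream, Q2 downstream)
# are anchored on the conserved hinge peptide that separates them:
# 'HPGKQAKE' in FOXP2 and 'ALQVARQLLL' in FOXP1. Calling rules:
#   * Q runs tolerate a single interior histidine (polar, counted in the
#     run length); H may not open or close a run.
#   * If the upstream repeat region contains a proline, Q1 is the run
#     immediately N-terminal to the first proline and the fragmented runs
#     between that proline and the hinge are ignored.
#   * Some predicted cetacean sequences insert a 22-residue peptide between
#     the hinge and Q2 (a likely splice-prediction artifact); gaps larger
#     than a small allowance are reported as a hinge extension and excluded
#     from Q2.

CANONICAL_HINGES <- c(FOXP2 = "HPGKQAKE", FOXP1 = "ALQVARQLLL")

# Quality flags that invalidate a call (no sum/ratio available).
FATAL_FLAGS <- c("no_hinge", "no_q1", "no_q2")

#' Configuration for hinge-anchored repeat calling
#'
#' @param gene `"FOXP2"` or `"FOXP1"`; selects the canonical hinge anchor.
#' @param anchor Hinge anchor peptide; defaults to the canonical hinge of
#'   `gene` (`"HPGKQAKE"` for FOXP2, `"ALQVARQLLL"` for FOXP1).
#' @param max_mismatch Maximum Hamming distance tolerated when locating the
#'   hinge (no indels). Must be smaller than half the anchor length.
#' @param upstream_window Residues scanned upstream of the hinge for Q1.
#' @param downstream_window Residues downstream of the hinge within which
#'   the Q2 run must start.
#' @param min_run Minimum length for a Q run to qualify as a repeat.
#' @param extension_allowance Intervening residues between hinge end and Q2
#'   start treated as canonical context; larger gaps are reported as a
#'   hinge extension and flagged `"hinge_extension"`.
#' @return An object of class `hinge_config`.
#' @examples
#' hinge_config("FOXP2")
#' @export
hinge_config <- function(gene = c("FOXP2", "FOXP1"), anchor = NULL,
                         max_mismatch = 2L, upstream_window = 100L,
                         downstream_window = 60L, min_run = 2L,
                         extension_allowance = 4L) {
  gene <- match.arg(gene)
  if (is.null(anchor)) anchor <- unname(CANONICAL_HINGES[gene])
  anchor <- toupper(anchor)
  stopifnot(nchar(anchor) >= 6L,
            max_mismatch >= 0L, max_mismatch < nchar(anchor) / 2,
            upstream_window >= 1L, downstream_window >= 1L, min_run >= 1L,
            extension_allowance >= 0L)
  structure(
    list(gene = gene, anchor = anchor,
         max_mismatch = as.integer(max_mismatch),
         upstream_window = as.integer(upstream_window),
         downstream_window = as.integer(downstream_window),
         min_run = as.integer(min_run),
         extension_allowance = as.integer(extension_allowance)),
    class = "hinge_config"
  )
}

#' Locate the hinge peptide by minimum-Hamming sliding-window search
#'
#' Scans every window of anchor length and returns the window with the
#' fewest substitutions (ties broken by the leftmost position). Indels are
#' not modelled: the known cetacean insertion lies downstream of the hinge,
#' not inside it.
#'
#' @param seq Uppercase amino-acid sequence (a single string).
#' @param cfg A [hinge_config()].
#' @return An object of class `hinge_match` with fields `start`, `end`
#'   (0-based half-open interval), `mismatches` and `matched_text`.
#' @examples
#' find_hinge("QQQQHPGKQAKEQQ", hinge_config("FOXP2"))
#' @export
find_hinge <- function(seq, cfg = hinge_config()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  a <- strsplit(cfg$anchor, "", fixed = TRUE)[[1L]]
  la <- length(a)
  n_pos <- length(chars) - la + 1L
  if (n_pos < 1L) {
    stop(no_hinge_condition(best_distance = NA_integer_, anchor = cfg$anchor))
  }
  mism <- integer(n_pos)
  for (j in seq_len(la)) {
    mism <- mism + (chars[j:(j + n_pos - 1L)] != a[j])
  }
  best <- which.min(mism)  # leftmost among ties
  if (mism[best] > cfg$max_mismatch) {
    stop(no_hinge_condition(best_distance = mism[best], anchor = cfg$anchor))
  }
  structure(
    list(start = best - 1L, end = best - 1L + la,
         mismatches = as.integer(mism[best]),
         matched_text = substr(seq, best, best + la - 1L)),
    class = "hinge_match"
  )
}

no_hinge_condition <- function(best_distance, anchor) {
  structure(
    class = c("polyqvoc_no_hinge", "error", "condition"),
    list(message = sprintf(
           "no_hinge: no window within mismatch tolerance of anchor '%s' (best distance: %s)",
           anchor, best_distance),
         call = NULL, best_distance = best_distance)
  )
}

# Histidine-tolerant Q runs -------------------------------------------------
#
# Enumerates candidate Q runs in chars[from:to] (1-based, inclusive).
# Candidates are (i) maximal pure Q runs and (ii) merges of two consecutive
# Q runs separated by exactly one H (the H is interior by construction and
# contributes 1 to the run length). Returns a data frame with absolute
# 1-based start/end, length, and has_h.
q_runs <- function(chars, from, to) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), has_h = logical(0))
  if (from > to) return(empty)
  region <- paste(chars[from:to], collapse = "")
  m <- gregexpr("Q+", region)[[1L]]
  if (m[1L] == -1L) return(empty)
  starts <- as.integer(m) + from - 1L
  lens <- attr(m, "match.length")
  ends <- starts + lens - 1L
  runs <- data.frame(start = starts, end = ends, length = lens,
                     has_h = FALSE)
  if (nrow(runs) > 1L) {
    for (i in seq_len(nrow(runs) - 1L)) {
      gap_start <- runs$end[i] + 1L
      gap_end <- runs$start[i + 1L] - 1L
      if (gap_start == gap_end && chars[gap_start] == "H") {
        runs <- rbind(runs, data.frame(
          start = runs$start[i], end = runs$end[i + 1L],
          length = runs$length[i] + 1L + runs$length[i + 1L],
          has_h = TRUE))
      }
    }
  }
  runs[order(runs$start, -runs$length), , drop = FALSE]
}

flagged_call <- function(flags, hinge = NULL) {
  structure(
    list(q1_len = NA_integer_, q2_len = NA_integer_,
         q1_interval = c(NA_integer_, NA_integer_),
         q2_interval = c(NA_integer_, NA_integer_),
         sum_s = NA_integer_, ratio_r = NA_real_, hinge = hinge,
         extension_len = NA_integer_,
         q1_contains_histidine = NA, q1_truncated_by_proline = NA,
         flags = flags),
    class = "repeat_call"
  )
}

#' Is a repeat call valid?
#'
#' A call is valid when none of its quality flags is fatal
#' (`no_hinge`, `no_q1`, `no_q2`).
#'
#' @param call A `repeat_call` object.
#' @return Logical scalar.
#' @export
is_called <- function(call) {
  stopifnot(inherits(call, "repeat_call"))
  !any(call$flags %in% FATAL_FLAGS)
}

#' Call the Q1 and Q2 polyQ repeats anchored on the hinge peptide
#'
#' Locates the hinge via [find_hinge()], then calls:
#' * **Q2** — the longest histidine-tolerant Q run starting within
#'   `downstream_window` residues after the hinge end. Residues between the
#'   hinge end and the Q2 start beyond a small allowance are reported as
#'   `extension_len` (flag `"hinge_extension"`) and excluded from Q2.
#' * **Q1** — within `upstream_window` residues before the hinge, the
#'   repeat region extends from the start of the first Q run of length
#'   `>= min_run` to the hinge start. If the region contains a proline,
#'   Q1 is the run immediately N-terminal to the first proline and all
#'   fragments between that proline and the hinge are ignored
#'   (`q1_truncated_by_proline`); otherwise Q1 is the longest run in the
#'   region. A single interior histidine counts toward the run length
#'   (`q1_contains_histidine`).
#'
#' The sum `S = Q1 + Q2` and ratio `R = Q1/Q2` are stored at full
#' precision. Calls lacking a hinge or a qualifying run are returned
#' flagged (`no_hinge` / `no_q1` / `no_q2`) with undefined sum and ratio.
#'
#' @param seq Uppercase amino-acid sequence (a single string) or an
#'   [ortholog_record()].
#' @param cfg A [hinge_config()].
#' @return An object of class `repeat_call` with fields `q1_len`, `q2_len`,
#'   `q1_interval`, `q2_interval` (0-based half-open), `sum_s`, `ratio_r`,
#'   `hinge`, `extension_len`, `q1_contains_histidine`,
#'   `q1_truncated_by_proline` and `flags`.
#' @examples
#' call_repeats(paste0("M", strrep("Q", 12), "HPGKQAKE", strrep("Q", 5), "AAA"))
#' @export
call_repeats <- function(seq, cfg = hinge_config()) {
  if (inherits(seq, "ortholog_record")) seq <- seq$sequence
  stopifnot(is.character(seq), length(seq) == 1L)
  hinge <- tryCatch(find_hinge(seq, cfg), polyqvoc_no_hinge = function(e) e)
  if (inherits(hinge, "condition")) {
    return(flagged_call("no_hinge"))
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  hinge_start1 <- hinge$start + 1L  # 1-based first hinge residue
  hinge_end1 <- hinge$end          # 1-based last hinge residue
  flags <- character(0)

  # Q2: longest run starting within the downstream window
  down <- q_runs(chars, hinge_end1 + 1L, n)
  down <- down[down$start <= hinge_end1 + cfg$downstream_window &
                 down$length >= cfg$min_run, , drop = FALSE]
  if (nrow(down) == 0L) {
    return(flagged_call("no_q2", hinge = hinge))
  }
  q2 <- down[order(-down$length, down$start), , drop = FALSE][1L, ]
  gap <- q2$start - hinge_end1 - 1L
  if (gap > cfg$extension_allowance) {
    extension_len <- as.integer(gap)
    flags <- c(flags, "hinge_extension")
  } else {
    extension_len <- 0L
  }

  # Q1: repeat region from the first qualifying run to the hinge start
  up_from <- max(1L, hinge_start1 - cfg$upstream_window)
  up <- q_runs(chars, up_from, hinge_start1 - 1L)
  qualifying <- up[up$length >= cfg$min_run, , drop = FALSE]
  if (nrow(qualifying) == 0L) {
    return(flagged_call("no_q1", hinge = hinge))
  }
  region_start <- min(qualifying$start)
  region_chars <- chars[region_start:(hinge_start1 - 1L)]
  p_off <- which(region_chars == "P")
  if (length(p_off) > 0L) {
    first_p <- region_start + p_off[1L] - 1L   # absolute 1-based position
    before_p <- up[up$end < first_p, , drop = FALSE]
    # nearest run ending before the proline; prefer the merged (longest) form
    before_p <- before_p[order(-before_p$end, -before_p$length), , drop = FALSE]
    if (nrow(before_p) == 0L || before_p$length[1L] < cfg$min_run) {
      return(flagged_call("no_q1", hinge = hinge))
    }
    q1 <- before_p[1L, ]
    truncated <- TRUE
  } else {
    q1 <- qualifying[order(-qualifying$length, qualifying$start), ,
                     drop = FALSE][1L, ]
    truncated <- FALSE
  }

  structure(
    list(q1_len = as.integer(q1$length), q2_len = as.integer(q2$length),
         q1_interval = c(q1$start - 1L, q1$end),
         q2_interval = c(q2$start - 1L, q2$end),
         sum_s = as.integer(q1$length + q2$length),
         ratio_r = q1$length / q2$length,
         hinge = hinge, extension_len = extension_len,
         q1_contains_histidine = q1$has_h,
         q1_truncated_by_proline = truncated,
         flags = flags),
    class = "repeat_call"
  )
}

#' @export
print.repeat_call <- function(x, ...) {
  if (is_called(x)) {
    cat(sprintf(
      "<repeat_call> Q1=%d Q2=%d sum=%d ratio=%.2f extension=%d%s\n",
      x$q1_len, x$q2_len, x$sum_s, round(x$ratio_r, 2), x$extension_len,
      if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ";"), "]")
      else ""))
  } else {
    cat(sprintf("<repeat_call> flagged: %s\n", paste(x$flags, collapse = ";")))
  }
  invisible(x)
}

#' Select the isoform with the longest polyQ tracts
#'
#' When several sequences/isoforms are available for one species, the
#' record maximizing the Q1+Q2 sum among successfully called records is
#' retained; flagged records rank below all called records. A tie on the
#' sum keeps the first record in input order and adds the flag
#' `"isoform_tie"`.
#'
#' @param records List of [ortholog_record()]s sharing one species label.
#' @param cfg A [hinge_config()].
#' @return The selected `ortholog_record`, with its `repeat_call` attached
#'   as attribute `"repeat_call"`. If every record is flagged, the first
#'   record is returned carrying its flagged call.
#' @export
select_longest_isoform <- function(records, cfg = hinge_config()) {
  stopifnot(is.list(records), length(records) >= 1L)
  calls <- lapply(records, call_repeats, cfg = cfg)
  sums <- vapply(calls, function(cl) {
    if (is_called(cl)) cl$sum_s else NA_integer_
  }, integer(1))
  if (all(is.na(sums))) {
    rec <- records[[1L]]
    attr(rec, "repeat_call") <- calls[[1L]]
    return(rec)
  }
  best <- max(sums, na.rm = TRUE)
  idx <- which(!is.na(sums) & sums == best)
  call <- calls[[idx[1L]]]
  if (length(idx) > 1L) call$flags <- c(call$flags, "isoform_tie")
  rec <- records[[idx[1L]]]
  attr(rec, "repeat_call") <- call
  rec
}

#' Per-species repeat-call table
#'
#' Runs [select_longest_isoform()] for every species in a panel of ortholog
#' records and tabulates the calls. Every input species appears exactly
#' once, either called or flagged. Species order follows first appearance.
#'
#' @param records List of [ortholog_record()]s (possibly several isoforms
#'   per species).
#' @param cfg A [hinge_config()].
#' @param digits Decimal places for the printed ratio (half-even rounding);
#'   use `NULL` to keep full precision.
#' @return Data frame with columns `species`, `gene`, `sequence_id`, `q1`,
#'   `q2`, `sum`, `ratio`, `extension_len`, `flags` (semicolon-joined).
#' @export
repeat_call_table <- function(records, cfg = hinge_config(), digits = 2) {
  species <- vapply(records, `[[`, character(1), "species_label")
  rows <- lapply(unique(species), function(sp) {
    rec <- select_longest_isoform(records[species == sp], cfg)
    cl <- attr(rec, "repeat_call")
    data.frame(
      species = sp, gene = rec$gene, sequence_id = rec$sequence_id,
      q1 = cl$q1_len, q2 = cl$q2_len, sum = cl$sum_s,
      ratio = if (is.null(digits)) cl$ratio_r else round(cl$ratio_r, digits),
      extension_len = cl$extension_len,
      flags = paste(cl$flags, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
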
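# End-to-end pipeline: FASTA + phenotypes -> tables -------------------------

log_event <- function(level, fmt, ...) {
  message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

#' Run the repeat-calling / classification / correlation pipeline
#'
#' Composes the package end to end: reads ortholog FASTA and an optional
#' phenotype table, calls the polyQ repeats per species (longest isoform),
#' classifies species by the threshold schemes, runs the configured
#' binned group-mean correlations, and writes result tables to an output
#' directory. Every dropped or flagged species is logged with a reason;
#' species present in the phenotype table but absent from the FASTA are
#' logged and excluded from correlations, never fatal.
#'
#' @param config A named list, or the path to a YAML file, with fields:
#'   * `fasta` — FASTA path or text (required)
#'   * `gene` — `"FOXP2"` or `"FOXP1"` (default `"FOXP2"`)
#'   * `outdir` — output directory (required)
#'   * `phenotypes` — optional phenotype table path
#'   * `seed` — optional integer seed recorded in the manifest
#'   * `hinge` — optional list of [hinge_config()] overrides
#'   * `classifier` — optional list of [classifier_config()] overrides
#'   * `correlations` — optional list of entries, each a list with
#'     `name`, `x`/`y` (column: `"ratio"`, `"sum"`, or a phenotype
#'     column), `bin_by` (column whose values define the bins), `scheme`
#'     (a [builtin_bin_schemes()] name), and optional
#'     `transform_x`/`transform_y` (`"identity"`/`"log10"`).
#' @return Invisibly, a list with the computed tables (`repeat_calls`,
#'   `classification`, `correlations`, `group_summaries`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$fasta), !is.null(config$outdir))
  gene <- if (is.null(config$gene)) "FOXP2" else config$gene
  if (!is.null(config$seed)) set.seed(config$seed)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  hcfg <- do.call(hinge_config, c(list(gene = gene),
                                  config$hinge %||% list()))
  ccfg <- do.call(classifier_config, config$classifier %||% list())

  records <- read_fasta(config$fasta, gene = gene)
  log_event("INFO", "read %d sequence records (%d species)",
            length(records),
            length(unique(vapply(records, `[[`, character(1),
                                 "species_label"))))
  calls <- repeat_call_table(records, hcfg)
  for (i in which(nzchar(calls$flags))) {
    log_event("WARN", "species %s flagged: %s",
              calls$species[i], calls$flags[i])
  }
  utils::write.csv(calls, file.path(config$outdir, "repeat_calls.csv"),
                   row.names = FALSE)

  classification <- classification_table(calls, ccfg)
  utils::write.csv(classification,
                   file.path(config$outdir, "classification.csv"),
                   row.names = FALSE)

  correlations <- NULL
  summaries <- NULL
  if (!is.null(config$phenotypes)) {
    phen <- read_phenotype_table(config$phenotypes)
    missing_seq <- setdiff(phen$species_label, calls$species)
    for (sp in missing_seq) {
      log_event("WARN", "species %s in phenotypes but absent from FASTA; excluded",
                sp)
    }
    merged <- merge(calls, phen, by.x = "species", by.y = "species_label")
    entries <- config$correlations %||% default_correlations(phen)
    schemes <- builtin_bin_schemes()
    cres <- list()
    sres <- list()
    for (e in entries) {
      scheme <- schemes[[e$scheme]]
      if (is.null(scheme)) {
        stop(sprintf("unknown bin scheme '%s'", e$scheme), call. = FALSE)
      }
      xv <- merged[[e$x]]
      yv <- merged[[e$y]]
      bv <- merged[[e$bin_by]]
      if (is.null(xv) || is.null(yv) || is.null(bv)) {
        stop(sprintf("correlation '%s': missing column", e$name),
             call. = FALSE)
      }
      labels <- assign_bins(bv, scheme)
      res <- correlate_group_means(
        xv, yv, labels,
        transform_x = e$transform_x %||% "identity",
        transform_y = e$transform_y %||% "identity")
      log_event("INFO", "correlation %s: r = %.3f over %d groups (p = %.3g)",
                e$name, res$r, res$n_groups, res$p_value)
      cres[[e$name]] <- data.frame(
        name = e$name, scheme = e$scheme,
        transform_x = res$transform_x, transform_y = res$transform_y,
        n_groups = res$n_groups, r = res$r, p = res$p_value,
        stringsAsFactors = FALSE)
      s <- res$summaries
      s$name <- e$name
      sres[[e$name]] <- s
    }
    correlations <- do.call(rbind, cres)
    summaries <- do.call(rbind, sres)
    utils::write.csv(correlations,
                     file.path(config$outdir, "correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(summaries,
                     file.path(config$outdir, "group_summaries.csv"),
                     row.names = FALSE)
  }

  manifest <- c(
    sprintf("polyqvoc %s", as.character(utils::packageVersion("polyqvoc"))),
    sprintf("R %s", getRversion()),
    sprintf("seed: %s", config$seed %||% "unset"),
    sprintf("gene: %s", gene),
    sprintf("records: %d", length(records)),
    "config:",
    utils::capture.output(utils::str(config, give.attr = FALSE))
  )
  writeLines(manifest, file.path(config$outdir, "run_manifest.txt"))

  invisible(list(repeat_calls = calls, classification = classification,
                 correlations = correlations, group_summaries = summaries))
}

default_correlations <- function(phen) {
  entries <- list()
  if ("char_freq_khz" %in% names(phen)) {
    entries <- c(entries, list(list(
      name = "ratio_vs_char_freq", x = "char_freq_khz", y = "ratio",
      bin_by = "char_freq_khz", scheme = "char_freq")))
  }
  if ("body_mass_g" %in% names(phen)) {
    entries <- c(entries, list(list(
      name = "ratio_vs_log_body_mass", x = "ratio", y = "body_mass_g",
      bin_by = "ratio", scheme = "ratio_q1q2_10", transform_y = "log10")))
  }
  if (length(entries) == 0L) {
    stop("no phenotype column usable for the default correlations",
         call. = FALSE)
  }
  entries
}

`%||%` <- function(a, b) if (is.null(a)) b else a
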
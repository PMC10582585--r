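# FASTA and phenotype-table input/output ------------------------------------

#' Read protein FASTA into ortholog records
#'
#' Headers follow the grammar: the first whitespace-delimited token after
#' `>` is the sequence id; optional `key=value` tokens supply
#' `species=...` and `taxon=...`. Without a species token the species
#' label defaults to the sequence id. Sequences are uppercased, whitespace
#' is stripped, and residues validated (20 amino acids plus `X`). Entry
#' order is preserved.
#'
#' @param path_or_text Path to a FASTA file, or FASTA-formatted text
#'   (recognized by a leading `>` or embedded newline when no such file
#'   exists).
#' @param gene `"FOXP2"` or `"FOXP1"`, recorded on every record.
#' @return List of [ortholog_record()]s.
#' @examples
#' read_fasta(">a species=Homo_sapiens\nQQQHPG\n", gene = "FOXP2")
#' @export
read_fasta <- function(path_or_text, gene = c("FOXP2", "FOXP1")) {
  gene <- match.arg(gene)
  path <- path_or_text
  if (grepl("\n", path_or_text, fixed = TRUE) ||
      (startsWith(trimws(path_or_text), ">") && !file.exists(path_or_text))) {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path), add = TRUE)
    writeLines(path_or_text, path)
  } else if (!file.exists(path)) {
    stop(sprintf("FASTA input not found: '%s'", path), call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),  # residue validation happens below
    error = function(e) {
      stop(sprintf("not valid FASTA: %s", conditionMessage(e)), call. = FALSE)
    })
  if (length(set) == 0L) {
    stop("format error: FASTA input contains no sequence entries",
         call. = FALSE)
  }
  headers <- names(set)
  seqs <- unname(as.character(set))
  lapply(seq_along(set), function(i) {
    tok <- strsplit(trimws(headers[i]), "[[:space:]]+")[[1L]]
    id <- tok[1L]
    if (is.na(id) || !nzchar(id)) {
      stop(sprintf("format error: FASTA entry %d has an empty header", i),
           call. = FALSE)
    }
    kv <- tok[-1L][grepl("=", tok[-1L], fixed = TRUE)]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    species <- if ("species" %in% keys) vals[match("species", keys)] else id
    taxon <- if ("taxon" %in% keys) vals[match("taxon", keys)] else NA_character_
    ortholog_record(species_label = species, gene = gene, sequence_id = id,
                    sequence = seqs[i], taxon = taxon)
  })
}

#' Write ortholog records to FASTA
#'
#' Emits the same header grammar parsed by [read_fasta()], so that a
#' write/read round trip reproduces the records.
#'
#' @param records List of [ortholog_record()]s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  headers <- vapply(records, function(r) {
    h <- sprintf("%s species=%s", r$sequence_id, r$species_label)
    if (!is.na(r$taxon)) h <- sprintf("%s taxon=%s", h, r$taxon)
    h
  }, character(1))
  set <- Biostrings::AAStringSet(vapply(records, `[[`, character(1),
                                        "sequence"))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

PHENOTYPE_NUMERIC_COLS <- c("collen_type_code", "char_freq_khz",
                            "min_freq_khz", "max_freq_khz", "bandwidth_khz",
                            "cw_over_bw", "cochlear_height_over_width",
                            "body_mass_g", "max_audible_freq_khz")
PHENOTYPE_COLS <- c("species_label", "call_type", PHENOTYPE_NUMERIC_COLS)

#' Read a species phenotype table
#'
#' Reads a delimited table (tab or comma, auto-detected from the header
#' line: tab wins if the header contains one) with a species column
#' (`species` or `species_label`) and any subset of the phenotype columns:
#' `call_type`, `collen_type_code`, `char_freq_khz`, `min_freq_khz`,
#' `max_freq_khz`, `bandwidth_khz`, `cw_over_bw`,
#' `cochlear_height_over_width`, `body_mass_g`, `max_audible_freq_khz`
#' (frequencies in kHz, masses in g). Unknown columns are dropped with a
#' warning. Empty cells become `NA`, never zero.
#'
#' @param path Path to the delimited text file.
#' @return Data frame with one row per species record; missing columns are
#'   absent, missing values are `NA`.
#' @export
read_phenotype_table <- function(path) {
  stopifnot(file.exists(path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character",
                           na.strings = c("", "NA"),
                           stringsAsFactors = FALSE, check.names = TRUE,
                           quote = "\"", comment.char = "")
  names(raw)[names(raw) == "species"] <- "species_label"
  if (!"species_label" %in% names(raw)) {
    stop("format error: no species column (expected 'species' or 'species_label')",
         call. = FALSE)
  }
  unknown <- setdiff(names(raw), PHENOTYPE_COLS)
  if (length(unknown) > 0L) {
    warning(sprintf("ignoring unknown phenotype columns: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
    raw <- raw[, setdiff(names(raw), unknown), drop = FALSE]
  }
  for (col in intersect(PHENOTYPE_NUMERIC_COLS, names(raw))) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(num) & !is.na(raw[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("format error: non-numeric value '%s' in column '%s' at row %d",
                   raw[[col]][bad[1L]], col, bad[1L]), call. = FALSE)
    }
    nonpos <- which(!is.na(num) & num <= 0)
    if (length(nonpos) > 0L && col != "collen_type_code") {
      stop(sprintf("format error: non-positive value in column '%s' at row %d",
                   col, nonpos[1L]), call. = FALSE)
    }
    raw[[col]] <- if (col == "collen_type_code") as.integer(num) else num
  }
  if ("call_type" %in% names(raw)) {
    bad <- which(!is.na(raw$call_type) &
                   !raw$call_type %in% c("NE", "CF", "FM1", "FM2"))
    if (length(bad) > 0L) {
      stop(sprintf("format error: unknown call_type '%s' at row %d",
                   raw$call_type[bad[1L]], bad[1L]), call. = FALSE)
    }
  }
  raw
}
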
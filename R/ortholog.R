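# Ortholog sequence records -------------------------------------------------

#' @keywords internal
AA_ALPHABET_20X <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                     "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Create an ortholog protein sequence record
#'
#' Container for one species' FOXP2 or FOXP1 protein sequence. The sequence
#' is normalized to uppercase with whitespace removed and validated against
#' the 20-letter amino-acid alphabet plus `X`.
#'
#' @param species_label Species label, e.g. `"Homo_sapiens"`.
#' @param gene Either `"FOXP2"` or `"FOXP1"`.
#' @param sequence_id Accession or synthetic identifier.
#' @param sequence Amino-acid sequence (a single string).
#' @param taxon Optional order/suborder/family tag.
#' @return An object of class `ortholog_record`.
#' @examples
#' ortholog_record("Homo_sapiens", "FOXP2", "demo1",
#'                 paste0(strrep("Q", 12), "HPGKQAKE", strrep("Q", 5)))
#' @export
ortholog_record <- function(species_label, gene = c("FOXP2", "FOXP1"),
                            sequence_id, sequence, taxon = NA_character_) {
  gene <- match.arg(gene)
  stopifnot(is.character(species_label), length(species_label) == 1L,
            is.character(sequence_id), length(sequence_id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- normalize_sequence(sequence, id = sequence_id)
  structure(
    list(species_label = species_label, gene = gene,
         sequence_id = sequence_id, taxon = taxon, sequence = sequence),
    class = "ortholog_record"
  )
}

# Uppercase, strip whitespace, validate residues; errors name the record
# and the 1-based position of the first illegal character.
normalize_sequence <- function(sequence, id = "<sequence>") {
  s <- toupper(gsub("[[:space:]]+", "", sequence))
  if (!nzchar(s)) {
    stop(sprintf("record '%s': empty sequence", id), call. = FALSE)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% AA_ALPHABET_20X)
  if (length(bad) > 0L) {
    stop(sprintf("record '%s': illegal residue '%s' at position %d",
                 id, chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  s
}

#' @export
print.ortholog_record <- function(x, ...) {
  cat(sprintf("<ortholog_record> %s %s (%s), %d aa\n",
              x$gene, x$species_label, x$sequence_id, nchar(x$sequence)))
  invisible(x)
}

#' Tabulate a list of ortholog records
#'
#' @param records List of [ortholog_record()] objects.
#' @return A data frame with one row per record.
#' @export
ortholog_table <- function(records) {
  stopifnot(is.list(records))
  do.call(rbind, lapply(records, function(r) {
    data.frame(species_label = r$species_label, gene = r$gene,
               sequence_id = r$sequence_id, taxon = r$taxon,
               length = nchar(r$sequence), stringsAsFactors = FALSE)
  }))
}
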
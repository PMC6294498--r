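# Protein sequences, residue intervals and HSQC-visibility accounting.
#
# Backbone amide HSQC spectra show one peak per non-proline residue:
# proline lacks the amide proton, so a window of n residues containing
# k prolines yields at most n - k assignable amide peaks.

AA_ALPHABET_1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                   "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Read protein sequences from FASTA
#'
#' Sequences are read with Biostrings and validated against the 20
#' standard one-letter amino-acid codes plus `X`; an illegal character is
#' an error naming the character and the record.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences (class
#'   `protein_sequences`), one element per record in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stopf("empty FASTA file: %s", path)
  seqs <- toupper(as.character(set))
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, character(1), 1L)
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "")[[1]]
    bad <- setdiff(unique(chars), AA_ALPHABET_1)
    if (length(bad))
      stopf("illegal residue character '%s' in record '%s'", bad[1], ids[i])
  }
  structure(setNames(seqs, ids), class = "protein_sequences")
}

#' @export
print.protein_sequences <- function(x, ...) {
  cat(sprintf("protein_sequences: %d record(s)\n", length(x)))
  for (i in seq_along(x))
    cat(sprintf("  %s (%d aa)\n", names(x)[i], nchar(x[[i]])))
  invisible(x)
}

#' Define a 1-based inclusive residue interval
#'
#' @param start,end 1-based residue positions, `start <= end`.
#' @return A `domain_interval` object.
#' @examples
#' interval_length(domain_interval(688, 717))  # 30
#' @export
domain_interval <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start)
    stopf("invalid interval: need 1 <= start <= end, got [%s, %s]", start, end)
  structure(list(start = start, end = end), class = "domain_interval")
}

#' Length of a residue interval
#'
#' @param iv A [domain_interval()].
#' @return `end - start + 1`.
#' @export
interval_length <- function(iv) {
  stopifnot(inherits(iv, "domain_interval"))
  iv$end - iv$start + 1L
}

#' Count HSQC-visible residues in a sequence window
#'
#' Prolines have no backbone amide proton and therefore no 1H-15N HSQC
#' peak; every other residue in the window contributes one.
#'
#' @param seq A one-letter amino-acid string (an element of
#'   [read_fasta()] output works directly).
#' @param iv A [domain_interval()] within the sequence.
#' @return A list with `n_visible` and `n_proline`;
#'   `n_visible + n_proline == interval_length(iv)`.
#' @examples
#' hsqc_visible("APPA", domain_interval(1, 4))  # 2 visible, 2 proline
#' @export
hsqc_visible <- function(seq, iv) {
  stopifnot(inherits(iv, "domain_interval"))
  seq <- as.character(seq)
  if (length(seq) != 1L) stopf("seq must be a single sequence string")
  if (iv$end > nchar(seq))
    stopf("interval [%d, %d] exceeds sequence length %d",
          iv$start, iv$end, nchar(seq))
  window <- strsplit(substr(seq, iv$start, iv$end), "")[[1]]
  n_pro <- sum(window == "P")
  list(n_visible = length(window) - n_pro, n_proline = n_pro)
}
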
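#' @importFrom Biostrings GENETIC_CODE DNAStringSet readDNAStringSet writeXStringSet
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Normalize a nucleotide sequence to uppercase DNA
#'
#' Uppercases and maps U to T so that RNA and DNA input share one internal
#' alphabet. Characters outside A/C/G/T/N raise an error; N is retained (it
#' never matches a motif).
#'
#' @param x single character string (DNA or RNA).
#' @return uppercase DNA string.
#' @export
normalize_seq <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- gsub("[ACGTN]", "", x)
  if (nchar(bad) > 0L) {
    stop("sequence contains non-ACGTU characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  x
}

#' Split a sequence into consecutive codons
#'
#' @param x DNA string.
#' @param from 1-based position of the first codon.
#' @param n maximum number of codons to return (default: all complete
#'   codons).
#' @return character vector of 3-letter codons.
#' @export
codons_of <- function(x, from = 1L, n = NULL) {
  len <- nchar(x) - from + 1L
  k <- len %/% 3L
  if (!is.null(n)) k <- min(k, n)
  if (k <= 0L) return(character(0))
  starts <- from + 3L * (seq_len(k) - 1L)
  substring(x, starts, starts + 2L)
}

#' Translate a vector of codons with the standard nuclear code
#'
#' Gap codons ("---") become "-"; stop codons become "*".
#'
#' @param codons character vector of 3-letter codons (or "---").
#' @return character vector of single-letter amino acids.
#' @export
translate_codons <- function(codons) {
  out <- rep(NA_character_, length(codons))
  gap <- codons == "---"
  out[gap] <- "-"
  aa <- Biostrings::GENETIC_CODE[codons[!gap]]
  if (anyNA(aa)) {
    stop("untranslatable codon(s): ",
         paste(unique(codons[!gap][is.na(aa)]), collapse = ", "))
  }
  out[!gap] <- unname(aa)
  out
}

## translate an in-frame DNA string to a protein string (no gaps)
translate_cds <- function(x) {
  paste(translate_codons(codons_of(x)), collapse = "")
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

## first in-frame stop codon at or after `from` (1-based, must be in frame);
## returns 1-based start of the stop codon or NA
first_stop <- function(seq, from) {
  n <- nchar(seq)
  p <- from
  while (p + 2L <= n) {
    if (substr(seq, p, p + 2L) %in% STOP_CODONS) return(p)
    p <- p + 3L
  }
  NA_integer_
}
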
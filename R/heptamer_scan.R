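#' Scan a coding sequence for in-frame +1 frameshift heptamers
#'
#' Locates every occurrence of the supplied heptamer motifs whose first base
#' falls in reading frame 0 relative to `orf_start` (the A of the anchor
#' ATG). Out-of-frame occurrences are excluded: a frameshift heptamer is only
#' meaningful when its P-site codon is an in-frame codon of the translated
#' ORF.
#'
#' Coordinates are 1-based throughout, following R/Bioconductor convention.
#'
#' @param sequence DNA or RNA string (U is mapped to T; N never matches).
#' @param orf_start 1-based position of the anchor ORF start codon.
#' @param motifs heptamer registry data.frame, as from [heptamer_motifs()].
#' @param seq_id identifier recorded in the output.
#' @return data.frame of frameshift sites with columns seq_id, start
#'   (1-based), motif, dna, frame (always 0), sorted by start.
#' @examples
#' scan_heptamers("ATGCTTAGGCTAA")           # Ty1 site at position 4
#' scan_heptamers("ACTTAGGC")                # empty: occurrence out of frame
#' @export
scan_heptamers <- function(sequence, orf_start = 1L,
                           motifs = heptamer_motifs(), seq_id = "seq") {
  sequence <- normalize_seq(sequence)
  orf_start <- as.integer(orf_start)
  if (orf_start < 1L || orf_start > nchar(sequence)) {
    stop("orf_start outside sequence")
  }
  hits <- data.frame(start = integer(0), motif = character(0),
                     dna = character(0))
  for (i in seq_len(nrow(motifs))) {
    m <- gregexpr(motifs$dna[i], sequence, fixed = TRUE)[[1]]
    pos <- as.integer(m[m > 0L])
    if (length(pos)) {
      hits <- rbind(hits, data.frame(start = pos, motif = motifs$name[i],
                                     dna = motifs$dna[i]))
    }
  }
  hits <- hits[(hits$start - orf_start) %% 3L == 0L, , drop = FALSE]
  hits <- hits[order(hits$start), , drop = FALSE]
  out <- data.frame(seq_id = rep(seq_id, nrow(hits)),
                    start = hits$start, motif = hits$motif, dna = hits$dna,
                    frame = rep(0L, nrow(hits)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assemble a dual-ORF gene model around a frameshift site
#'
#' Given an ATG-anchored ORF and one heptamer occurrence, finds the 0-frame
#' stop codon at/after the heptamer and the first +1-frame stop scanned in
#' codon steps from the +1 A-site codon (heptamer base 5). The result
#' describes a coding region made of two overlapping ORFs decoded as one
#' trans-frame protein. For the OAZ1-type heptamer (GCG_T.GA_C) the 0-frame
#' stop is the TGA inside the heptamer itself.
#'
#' @param sequence DNA/RNA string.
#' @param site one-row data.frame (or list) with at least `start`, `motif`,
#'   `dna`, as returned by [scan_heptamers()].
#' @param orf_start 1-based start of the 0-frame ORF (must hold ATG).
#' @param seq_id identifier carried into the model.
#' @return object of class `dual_orf_model`: list with seq_id, orf0_start,
#'   orf0_end, orf1_start, orf1_end (all 1-based, ends inclusive of the stop
#'   codon) and the site.
#' @export
build_dual_orf_model <- function(sequence, site, orf_start = 1L,
                                 seq_id = site$seq_id %||% "seq") {
  sequence <- normalize_seq(sequence)
  start <- as.integer(site$start)
  if (substr(sequence, orf_start, orf_start + 2L) != "ATG") {
    stop("anchor ORF does not start with ATG at position ", orf_start)
  }
  if ((start - orf_start) %% 3L != 0L) {
    stop("heptamer at ", start, " is out of frame relative to orf_start")
  }
  if (substr(sequence, start, start + 6L) != site$dna) {
    stop("sequence does not carry ", site$dna, " at position ", start)
  }
  s0 <- first_stop(sequence, start)
  if (is.na(s0)) stop("open model: no 0-frame stop codon at/after the heptamer")
  orf1_start <- start + 4L
  s1 <- first_stop(sequence, orf1_start)
  if (is.na(s1)) stop("open model: no +1-frame stop codon downstream of the heptamer")
  structure(list(
    seq_id = seq_id,
    orf0_start = as.integer(orf_start),
    orf0_end = s0 + 2L,
    orf1_start = orf1_start,
    orf1_end = s1 + 2L,
    site = list(seq_id = seq_id, start = start,
                motif = as.character(site$motif),
                dna = as.character(site$dna))
  ), class = "dual_orf_model")
}

#' @export
print.dual_orf_model <- function(x, ...) {
  cat("Dual-ORF gene model [", x$seq_id, "]\n", sep = "")
  cat("  0-frame ORF: ", x$orf0_start, "-", x$orf0_end, " (",
      (x$orf0_end - x$orf0_start + 1L) / 3, " codons)\n", sep = "")
  cat("  +1 ORF:      ", x$orf1_start, "-", x$orf1_end, " (",
      (x$orf1_end - x$orf1_start + 1L) / 3, " codons)\n", sep = "")
  cat("  heptamer:    ", x$site$dna, " (", x$site$motif, ") at ",
      x$site$start, "\n", sep = "")
  invisible(x)
}

#' Fuse the two reading frames of a dual-ORF model into one CDS
#'
#' Deletes the single nucleotide at heptamer base 4, joining the 0-frame
#' portion (through the P-site codon) in frame with the +1 ORF. For the
#' Ty1-type heptamer this turns CTTAGGC into CTTGGC, the construction used
#' to build in-frame alignments of frameshifted genes against orthologs that
#' encode the protein in a single frame. Output length is one less than the
#' dual-ORF CDS span.
#'
#' @param sequence DNA/RNA string the model was built on.
#' @param model a `dual_orf_model`.
#' @return fused in-frame coding sequence (character).
#' @export
fuse_frames <- function(sequence, model) {
  sequence <- normalize_seq(sequence)
  st <- model$site$start
  paste0(substr(sequence, model$orf0_start, st + 2L),
         substr(sequence, st + 4L, model$orf1_end))
}

#' Predict the trans-frame protein of a dual-ORF model
#'
#' Translates the fused CDS (see [fuse_frames()]) up to, and excluding, its
#' stop codon. By construction this equals the 0-frame peptide through the
#' P-site codon concatenated with the translation of the +1 ORF.
#'
#' @inheritParams fuse_frames
#' @return amino-acid string (no stop character).
#' @export
trans_frame_protein <- function(sequence, model) {
  fused <- fuse_frames(sequence, model)
  aa <- translate_codons(codons_of(fused))
  stops <- which(aa == "*")
  if (length(stops) == 0L || stops[1] != length(aa)) {
    stop("model inconsistency: fused frame has ",
         if (length(stops)) "an internal stop codon" else "no stop codon")
  }
  paste(aa[-length(aa)], collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
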
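#' The built-in +1 frameshift heptamer registry
#'
#' The four heptamers known to drive efficient +1 ribosomal frameshifting in
#' S. cerevisiae. Each heptamer spans the P-site codon (bases 1-3), the
#' 0-frame A-site codon (bases 4-6) and the +1-frame A-site codon
#' (bases 5-7). `repairing_allowed` records whether the P-site tRNA can
#' re-pair with the overlapping +1 codon (true for the CTT P-site motifs,
#' false for the GCG ones).
#'
#' @param names optional character vector to subset the registry by motif
#'   name (e.g. `"Ty1"`) or by heptamer DNA string.
#' @return data.frame with columns name, dna, p_codon, a0_codon, a1_codon,
#'   repairing_allowed.
#' @examples
#' heptamer_motifs()
#' heptamer_motifs("Ty1")
#' @export
heptamer_motifs <- function(names = NULL) {
  reg <- data.frame(
    name = c("Ty1", "EST3", "Ty3", "OAZ1"),
    dna = c("CTTAGGC", "CTTAGTT", "GCGAGTT", "GCGTGAC"),
    repairing_allowed = c(TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  reg$p_codon <- substr(reg$dna, 1L, 3L)
  reg$a0_codon <- substr(reg$dna, 4L, 6L)
  reg$a1_codon <- substr(reg$dna, 5L, 7L)
  reg <- reg[, c("name", "dna", "p_codon", "a0_codon", "a1_codon",
                 "repairing_allowed")]
  if (!is.null(names)) {
    idx <- match(names, reg$name)
    idx[is.na(idx)] <- match(names[is.na(idx)], reg$dna)
    if (anyNA(idx)) {
      stop("unknown heptamer motif(s): ",
           paste(names[is.na(idx)], collapse = ", "))
    }
    reg <- reg[idx, , drop = FALSE]
    rownames(reg) <- NULL
  }
  reg
}
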
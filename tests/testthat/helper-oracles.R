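# Independent oracles used to check the package implementations.
# These deliberately use naive exhaustive algorithms, not the package's code
# paths.

# exhaustive sliding-window heptamer matcher: compare every length-7 window
# against every motif, then frame-filter
brute_scan <- function(sequence, orf_start = 1L, motifs = heptamer_motifs()) {
  n <- nchar(sequence)
  if (n < 7L) return(data.frame(start = integer(0), motif = character(0)))
  windows <- substring(sequence, 1:(n - 6L), 7:n)
  idx <- match(windows, motifs$dna)
  keep <- !is.na(idx) & (seq_along(windows) - orf_start) %% 3L == 0L
  out <- data.frame(start = which(keep), motif = motifs$name[idx[keep]])
  out[order(out$start), , drop = FALSE]
}

# random test sequence with occasional planted motifs so matches are not
# vanishingly rare
random_seq_with_motifs <- function(len, n_plant = 2L) {
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (n_plant > 0L && len >= 7L) {
    for (k in seq_len(n_plant)) {
      p <- sample.int(len - 6L, 1L)
      chars[p:(p + 6L)] <- strsplit(sample(heptamer_motifs()$dna, 1L), "")[[1]]
    }
  }
  paste(chars, collapse = "")
}

# exhaustive enumeration of all legal single hairpins (for short windows):
# nested pairs, <= 2 interior loops/bulges of <= 3 nt each, terminal loop
# >= 3 nt; scoring +2 WC, +1 GU, -2 per interruption, -3 opening
brute_hairpin_max <- function(seq, allow_gu = TRUE) {
  bases <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  n <- length(bases)
  ps <- function(i, j) {
    key <- paste0(bases[i], bases[j])
    if (key %in% c("AT", "TA", "GC", "CG")) return(2)
    if (allow_gu && key %in% c("GT", "TG")) return(1)
    NA_real_
  }
  best <- -Inf
  extend <- function(i, j, score, n_interrupt) {
    # record if closing loop is legal
    if (j - i - 1L >= 3L) best <<- max(best, score)
    # try all inner continuation pairs
    for (di in 0:3) for (dj in 0:3) {
      if (di + dj > 3L) next
      a <- i + 1L + di; b <- j - 1L - dj
      if (b - a < 1L) next
      p <- ps(a, b)
      if (is.na(p)) next
      ni <- n_interrupt + (di + dj > 0L)
      if (ni > 2L) next
      extend(a, b, score + p + if (di + dj > 0L) -2 else 0, ni)
    }
  }
  for (i in seq_len(max(0L, n - 1L))) for (j in n:(i + 1L)) {
    if (j <= i) next
    p <- ps(i, j)
    if (!is.na(p)) extend(i, j, p - 3, 0L)
  }
  if (best <= 0) NA_real_ else best
}

# position-map oracle for back-translation: independently walk each protein
# row, consuming codons from the CDS
brute_back_translate_row <- function(aa_row, cds) {
  aa <- strsplit(aa_row, "")[[1]]
  out <- character(length(aa))
  k <- 0L
  for (r in seq_along(aa)) {
    if (aa[r] == "-") {
      out[r] <- "---"
    } else {
      out[r] <- substr(cds, 3L * k + 1L, 3L * k + 3L)
      k <- k + 1L
    }
  }
  out
}

random_cds <- function(n_codons, with_stop = TRUE) {
  body <- sample(setdiff(names(Biostrings::GENETIC_CODE)
                         [Biostrings::GENETIC_CODE != "*"], "ATG"),
                 n_codons - 1L, replace = TRUE)
  paste(c("ATG", body, if (with_stop) "TAA"), collapse = "")
}
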
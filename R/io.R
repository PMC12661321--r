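#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of uppercase DNA strings (U mapped to T).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- vapply(as.character(ss), normalize_seq, character(1))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read ORF anchors from a GFF3 file
#'
#' Extracts CDS features; coordinates stay 1-based closed (native GFF3).
#'
#' @param path GFF3 file.
#' @return data.frame with seq_id, start, end, strand, ID.
#' @export
read_gff3_orfs <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  data.frame(seq_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             ID = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
             stringsAsFactors = FALSE)
}

#' Write dual-ORF gene models as GFF3
#'
#' Each model becomes a `gene` feature with two child `CDS` features (the
#' 0-frame and +1 ORFs) carrying a `frameshift=+1` attribute.
#'
#' @param models list of `dual_orf_model` objects.
#' @param path output GFF3 file.
#' @export
write_models_gff3 <- function(models, path) {
  if (inherits(models, "dual_orf_model")) models <- list(models)
  rows <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    id <- paste0(m$seq_id, ".fs", i)
    GenomicRanges::GRanges(
      seqnames = m$seq_id,
      ranges = IRanges::IRanges(
        start = c(m$orf0_start, m$orf0_start, m$orf1_start),
        end = c(m$orf1_end, m$orf0_end, m$orf1_end)),
      strand = "+",
      type = c("gene", "CDS", "CDS"),
      phase = c(NA_integer_, 0L, 0L),
      ID = c(id, paste0(id, ".orf0"), paste0(id, ".orf1")),
      Parent = c(NA, id, id),
      frameshift = c(NA, "+1", "+1"),
      motif = c(NA, m$site$motif, m$site$motif))
  })
  gr <- do.call(c, rows)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a frameshift-site table as TSV
#'
#' @param sites data.frame from [scan_heptamers()].
#' @param models optional list of matching `dual_orf_model` objects to add
#'   ORF boundary columns.
#' @param path output TSV.
#' @export
write_sites_tsv <- function(sites, path, models = NULL) {
  out <- sites
  if (!is.null(models)) {
    out$orf0_start <- vapply(models, function(m) m$orf0_start, integer(1))
    out$orf0_end <- vapply(models, function(m) m$orf0_end, integer(1))
    out$orf1_end <- vapply(models, function(m) m$orf1_end, integer(1))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-nucleotide P-site count track
#'
#' Accepts bedGraph (chrom, start, end, value; 0-based half-open) or a
#' 3-column TSV with header seq_id, pos, count (1-based positions).
#'
#' @param path input file.
#' @param seq_id transcript to extract (default: the first one seen).
#' @param transcript_length profile length; default the largest covered
#'   position.
#' @param format `"auto"` (by extension), `"bedgraph"` or `"tsv"`.
#' @return a [ribo_profile()].
#' @export
read_ribo_counts <- function(path, seq_id = NULL, transcript_length = NULL,
                             format = c("auto", "bedgraph", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE))
      "bedgraph" else "tsv"
  }
  if (format == "bedgraph") {
    gr <- rtracklayer::import(path, format = "bedGraph")
    ids <- as.character(GenomicRanges::seqnames(gr))
    if (is.null(seq_id)) seq_id <- ids[1]
    gr <- gr[ids == seq_id]
    pos <- unlist(mapply(seq, GenomicRanges::start(gr),
                         GenomicRanges::end(gr), SIMPLIFY = FALSE))
    val <- rep(gr$score, GenomicRanges::width(gr))
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    stopifnot(all(c("seq_id", "pos", "count") %in% names(df)))
    if (is.null(seq_id)) seq_id <- df$seq_id[1]
    df <- df[df$seq_id == seq_id, , drop = FALSE]
    pos <- df$pos; val <- df$count
  }
  if (is.null(transcript_length)) transcript_length <- max(pos, 0L)
  counts <- numeric(transcript_length)
  keep <- pos >= 1 & pos <= transcript_length
  counts[pos[keep]] <- val[keep]
  ribo_profile(counts, seq_id = seq_id)
}

#' Write a P-site profile
#'
#' @param profile a [ribo_profile()].
#' @param path output file.
#' @param format `"tsv"` (seq_id, pos, count; 1-based; zero positions
#'   omitted) or `"bedgraph"`.
#' @export
write_ribo_counts <- function(profile, path, format = c("tsv", "bedgraph")) {
  format <- match.arg(format)
  nz <- which(profile$counts > 0)
  if (format == "tsv") {
    df <- data.frame(seq_id = profile$seq_id, pos = nz,
                     count = profile$counts[nz])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    gr <- GenomicRanges::GRanges(profile$seq_id,
                                 IRanges::IRanges(nz, width = 1L),
                                 score = profile$counts[nz])
    rtracklayer::export(gr, path, format = "bedGraph")
  }
  invisible(path)
}

#' Read dual-luciferase replicates from TSV
#'
#' Expects columns sample_id, construct_class, firefly, renilla; classes
#' are `test` and `in_frame_control`.
#'
#' @param path TSV file.
#' @return list(tests, controls) of data.frames.
#' @export
read_luciferase_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "construct_class", "firefly", "renilla")
                %in% names(df)))
  list(tests = df[df$construct_class == "test", , drop = FALSE],
       controls = df[df$construct_class == "in_frame_control", , drop = FALSE])
}

#' Write dual-luciferase replicates as TSV
#'
#' @param reps list(tests, controls) as from [simulate_luciferase()].
#' @param path output TSV.
#' @export
write_luciferase_tsv <- function(reps, path) {
  utils::write.table(rbind(reps$tests, reps$controls), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a DMS reactivity track from TSV
#'
#' Columns pos (1-based), base, reactivity ("NaN"/"NA" allowed).
#'
#' @param path TSV file.
#' @return data.frame(pos, base, reactivity).
#' @export
read_reactivity_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", "NaN"))
  stopifnot(all(c("pos", "base", "reactivity") %in% names(df)))
  df
}

#' Write a DMS reactivity track as TSV
#'
#' @param track data.frame(pos, base, reactivity).
#' @param path output TSV.
#' @export
write_reactivity_tsv <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a codon alignment from gapped FASTA
#'
#' @param path FASTA of gapped nucleotide rows (lengths multiples of 3).
#' @param reference reference row name or index (default first record).
#' @return a `codon_alignment`.
#' @export
read_codon_alignment <- function(path, reference = 1L) {
  ss <- Biostrings::readBStringSet(path)
  rows <- toupper(chartr("U", "T", as.character(ss)))
  names(rows) <- sub("\\s.*$", "", names(ss))
  codon_alignment(rows, reference = reference)
}

#' Write a codon alignment as gapped FASTA
#'
#' @param aln a `codon_alignment`.
#' @param path output FASTA.
#' @export
write_codon_alignment <- function(aln, path) {
  rows <- apply(aln$codons, 1, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::BStringSet(rows), path)
  invisible(path)
}
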
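#' Build a codon alignment object
#'
#' A gapped codon-resolution multiple alignment with a designated reference
#' row. Rows may be supplied as gapped nucleotide strings (length a multiple
#' of 3, gaps as runs of "-") or as a character matrix of 3-letter codons
#' with "---" gaps.
#'
#' @param rows named character vector of gapped nucleotide strings, or a
#'   codon character matrix (rows = sequences).
#' @param reference which row is the reference (index or name); default 1.
#' @return object of class `codon_alignment`: list(names, codons
#'   (matrix), reference_index).
#' @export
codon_alignment <- function(rows, reference = 1L) {
  if (is.matrix(rows)) {
    codons <- rows
    nm <- rownames(rows) %||% paste0("seq", seq_len(nrow(rows)))
  } else {
    stopifnot(is.character(rows), length(rows) >= 1L)
    nm <- names(rows) %||% paste0("seq", seq_along(rows))
    n <- unique(nchar(rows))
    if (length(n) != 1L || n %% 3L != 0L) {
      stop("all rows must share one length divisible by 3")
    }
    codons <- t(vapply(rows, function(r) codons_of(toupper(chartr("U", "T", r))),
                       character(n / 3L)))
    if (n / 3L == 1L) codons <- matrix(codons, ncol = 1L)
  }
  bad <- !(codons == "---" | grepl("^[ACGT]{3}$", codons))
  if (any(bad)) {
    stop("codon alignment contains partial gaps or invalid codons (e.g. ",
         codons[which(bad)[1]], ")")
  }
  ref <- if (is.character(reference)) match(reference, nm) else as.integer(reference)
  if (is.na(ref) || ref < 1L || ref > nrow(codons)) stop("invalid reference row")
  if (any(codons[ref, ] == "---") && all(codons[ref, ] == "---")) {
    stop("reference row is all gaps")
  }
  rownames(codons) <- nm
  structure(list(names = nm, codons = codons, reference_index = ref),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment: ", length(x$names), " rows x ", ncol(x$codons),
      " codons (reference: ", x$names[x$reference_index], ")\n", sep = "")
  invisible(x)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Threads each row's coding sequence through its gapped protein row: every
#' amino acid is replaced by its source codon and every protein gap by
#' "---". Each CDS must translate (standard code, trailing stop stripped) to
#' its ungapped protein row.
#'
#' @param protein_alignment named character vector of gapped amino-acid
#'   rows (gap "-").
#' @param cds_sequences named character vector of ungapped DNA, matched to
#'   protein rows by name (or by position when unnamed).
#' @param reference reference row, passed to [codon_alignment()].
#' @return a `codon_alignment`.
#' @export
back_translate_alignment <- function(protein_alignment, cds_sequences,
                                     reference = 1L) {
  nm <- names(protein_alignment) %||% paste0("seq", seq_along(protein_alignment))
  if (!is.null(names(cds_sequences))) {
    if (!all(nm %in% names(cds_sequences))) {
      stop("cds_sequences missing rows: ",
           paste(setdiff(nm, names(cds_sequences)), collapse = ", "))
    }
    cds_sequences <- cds_sequences[nm]
  }
  L <- unique(nchar(protein_alignment))
  if (length(L) != 1L) stop("protein rows differ in length")
  rows <- matrix("---", nrow = length(nm), ncol = L, dimnames = list(nm, NULL))
  for (i in seq_along(nm)) {
    aa_row <- strsplit(toupper(protein_alignment[[i]]), "")[[1]]
    cds <- normalize_seq(cds_sequences[[i]])
    cod <- codons_of(cds)
    if (length(cod) && translate_codons(cod[length(cod)]) == "*") {
      cod <- cod[-length(cod)]
    }
    res <- which(aa_row != "-")
    if (length(res) != length(cod)) {
      stop("row ", nm[i], ": CDS has ", length(cod),
           " codons but protein row has ", length(res), " residues")
    }
    tr <- translate_codons(cod)
    mm <- which(tr != aa_row[res])
    if (length(mm)) {
      stop("row ", nm[i], ": translation mismatch at residue ", mm[1],
           " (", tr[mm[1]], " vs ", aa_row[res][mm[1]], ")")
    }
    rows[i, res] <- cod
  }
  codon_alignment(rows, reference = reference)
}

#' Classify substitutions against the reference row
#'
#' Each (row != reference, column) cell is called `gap` (either codon
#' gapped), `identical`, `synonymous` (different codons, same amino acid) or
#' `non_synonymous` — the classification behind per-codon alignment
#' colouring (synonymous vs non-synonymous changes).
#'
#' @param aln a `codon_alignment`.
#' @return character matrix with the alignment's dimensions; the reference
#'   row is NA.
#' @export
classify_columns <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  cod <- aln$codons
  ref <- cod[aln$reference_index, ]
  out <- matrix(NA_character_, nrow = nrow(cod), ncol = ncol(cod),
                dimnames = dimnames(cod))
  aa_of <- function(v) {
    a <- rep(NA_character_, length(v))
    ok <- v != "---"
    a[ok] <- translate_codons(v[ok])
    a
  }
  ref_aa <- aa_of(ref)
  for (i in setdiff(seq_len(nrow(cod)), aln$reference_index)) {
    row <- cod[i, ]
    kind <- rep("non_synonymous", length(row))
    kind[row == "---" | ref == "---"] <- "gap"
    same_codon <- row == ref & kind != "gap"
    kind[same_codon] <- "identical"
    syn <- kind == "non_synonymous" & aa_of(row) == ref_aa
    kind[which(syn)] <- "synonymous"
    out[i, ] <- kind
  }
  out
}

#' Sliding-window synonymous-substitution conservation scan
#'
#' Scans a codon alignment for windows whose synonymous substitution count
#' is lower than expected under an alignment-wide null — the signature of an
#' overlapping functional element (such as an RNA structure) constraining
#' synonymous sites. The null rate is the alignment-wide fraction of
#' synonymous calls among eligible (row, column) slots, where a slot is
#' eligible when both codons are ungapped and encode the same amino acid
#' (only such codons could differ synonymously). Each window of `window`
#' codons (default 17, step 1 codon, truncated edge windows skipped) is
#' tested with a one-sided binomial lower tail, P(X <= observed).
#'
#' This is a deliberately simplified alternative to phylogeny-based neutral
#' models: obs/exp ratios and p-values are comparable in kind, not in value,
#' to tree-aware scans.
#'
#' @param aln a `codon_alignment`.
#' @param window window width in codons (default 17).
#' @param p_adjust `"none"` (default; raw p-values, as when plotting against
#'   a 0.05 threshold line) or `"BH"` for Benjamini-Hochberg.
#' @return data.frame with one row per window: center_codon, window_start,
#'   window_end, observed_syn, expected_syn, ratio, p_value (and p_adj when
#'   requested); windows with zero eligible slots have NA statistics.
#' @export
window_synonymy_scan <- function(aln, window = 17L, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(aln, "codon_alignment"))
  L <- ncol(aln$codons)
  window <- as.integer(window)
  if (window < 3L || window > L) {
    stop("window must be between 3 codons and the alignment length (", L, ")")
  }
  calls <- classify_columns(aln)
  nonref <- calls[-aln$reference_index, , drop = FALSE]
  syn_col <- colSums(nonref == "synonymous")
  elig_col <- colSums(nonref == "synonymous" | nonref == "identical")
  total_elig <- sum(elig_col)
  p_null <- if (total_elig > 0) sum(syn_col) / total_elig else NA_real_
  starts <- seq_len(L - window + 1L)
  cs_s <- c(0, cumsum(syn_col))
  cs_e <- c(0, cumsum(elig_col))
  obs <- cs_s[starts + window] - cs_s[starts]
  n_slots <- cs_e[starts + window] - cs_e[starts]
  expected <- n_slots * p_null
  ratio <- ifelse(expected > 0, obs / expected, NA_real_)
  ## a window is testable only when its null expectation is positive: with
  ## no synonymous variation anywhere (or no eligible slots) there is no test
  pv <- rep(NA_real_, length(starts))
  ok <- !is.na(p_null) & p_null > 0 & n_slots > 0
  pv[ok] <- stats::pbinom(obs[ok], n_slots[ok], p_null)
  out <- data.frame(
    center_codon = starts + (window - 1L) %/% 2L,
    window_start = starts, window_end = starts + window - 1L,
    observed_syn = obs, expected_syn = expected, n_slots = n_slots,
    ratio = ratio, p_value = pv
  )
  if (p_adjust == "BH") out$p_adj <- stats::p.adjust(out$p_value, "BH")
  attr(out, "null_rate") <- p_null
  out
}
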
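## codons of the standard code, grouped for the mutation simulators
ALL_CODONS <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                c("T", "C", "A", "G"))[, 3:1], 1, paste,
                    collapse = "")
NON_STOP_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

syn_alternatives <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  setdiff(names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa], codon)
}

nonsyn_neighbours <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  out <- character(0)
  for (p in 1:3) for (b in c("A", "C", "G", "T")) {
    v <- codon
    substr(v, p, p) <- b
    if (v != codon && !(v %in% STOP_CODONS) &&
        Biostrings::GENETIC_CODE[v] != aa) out <- c(out, v)
  }
  out
}

rand_codons <- function(n) sample(NON_STOP_CODONS, n, replace = TRUE)

#' Simulate a dual-ORF frameshift gene
#'
#' Constructs a random coding sequence carrying exactly one frameshift
#' heptamer in frame: a 0-frame ORF of `orf0_codons` codons (ATG through its
#' stop) whose P-site codon sits just upstream of the 0-frame stop, and a +1
#' ORF of `orf1_codons` codons starting at the heptamer's +1 A-site codon
#' and ending at its own +1-frame stop. For the OAZ1-type heptamer the
#' 0-frame stop is the TGA inside the heptamer itself. Candidate sequences
#' with accidental in-frame heptamers or stray stops are rejection-sampled
#' away, so the output always round-trips through [scan_heptamers()] and
#' [build_dual_orf_model()] with exactly one site.
#'
#' @param motif motif name or heptamer DNA (see [heptamer_motifs()]).
#' @param orf0_codons codons in the 0-frame ORF, stop included (>= 6, or
#'   >= 3 for a stop-in-heptamer motif).
#' @param orf1_codons codons in the +1 ORF, stop included (>= 4).
#' @param utr5,utr3 flanking untranslated nucleotides.
#' @param seed optional RNG seed.
#' @param seq_id identifier for the simulated transcript.
#' @return list(sequence, model (`dual_orf_model`), orf_start).
#' @export
simulate_gene <- function(motif = "Ty1", orf0_codons = 60L, orf1_codons = 40L,
                          utr5 = 12L, utr3 = 12L, seed = NULL,
                          seq_id = "simgene") {
  if (!is.null(seed)) set.seed(seed)
  m <- heptamer_motifs(motif)
  stop_in_heptamer <- m$a0_codon %in% STOP_CODONS
  L0 <- as.integer(orf0_codons); L1 <- as.integer(orf1_codons)
  if (L1 < 4L) stop("orf1_codons must be >= 4")
  if (L0 < (if (stop_in_heptamer) 3L else 6L)) stop("orf0_codons too small")
  base7 <- substr(m$dna, 7L, 7L)
  for (try in 1:500) {
    if (stop_in_heptamer) {
      orf0 <- c("ATG", rand_codons(L0 - 3L), m$p_codon, m$a0_codon)
      tail_first <- base7                     # heptamer base 7 is 3'-UTR side
    } else {
      filler <- paste0(base7, paste(sample(c("A", "C", "G", "T"), 2L,
                                           replace = TRUE), collapse = ""))
      while (filler %in% STOP_CODONS) {
        filler <- paste0(base7, paste(sample(c("A", "C", "G", "T"), 2L,
                                             replace = TRUE), collapse = ""))
      }
      orf0 <- c("ATG", rand_codons(L0 - 5L), m$p_codon, m$a0_codon, filler,
                sample(STOP_CODONS, 1L))
      tail_first <- ""
    }
    utr5_s <- paste(sample(c("A", "C", "G", "T"), utr5, replace = TRUE),
                    collapse = "")
    prefix <- paste0(utr5_s, paste(orf0, collapse = ""), tail_first)
    orf_start <- utr5 + 1L
    site_start <- orf_start + 3L * (L0 - (if (stop_in_heptamer) 2L else 4L))
    orf1_start <- site_start + 4L
    ## fill +1 codons; leading ones may straddle already-fixed sequence
    chars <- strsplit(prefix, "")[[1]]
    needed <- orf1_start + 3L * L1 - 1L
    if (length(chars) < needed) {
      chars <- c(chars, sample(c("A", "C", "G", "T"), needed - length(chars),
                               replace = TRUE))
    }
    ok <- TRUE
    for (k in seq_len(L1)) {
      a <- orf1_start + 3L * (k - 1L)
      cod <- paste(chars[a:(a + 2L)], collapse = "")
      if (k < L1) {
        tries <- 0L
        while (cod %in% STOP_CODONS) {          # resample free tail bases only
          free <- (a:(a + 2L)) > nchar(prefix)
          if (!any(free)) { ok <- FALSE; break }
          chars[(a:(a + 2L))[free]] <- sample(c("A", "C", "G", "T"),
                                              sum(free), replace = TRUE)
          cod <- paste(chars[a:(a + 2L)], collapse = "")
          tries <- tries + 1L
          if (tries > 50L) { ok <- FALSE; break }
        }
        if (!ok) break
      } else {
        if (a > nchar(prefix)) {
          chars[a:(a + 2L)] <- strsplit(sample(STOP_CODONS, 1L), "")[[1]]
        } else if (!(cod %in% STOP_CODONS)) { ok <- FALSE }
      }
    }
    if (!ok) next
    chars <- c(chars, sample(c("A", "C", "G", "T"), utr3, replace = TRUE))
    seqs <- paste(chars, collapse = "")
    ## whole-gene validation: exactly the planted site, intended boundaries
    sites <- scan_heptamers(seqs, orf_start = orf_start, seq_id = seq_id)
    if (nrow(sites) != 1L || sites$start != site_start ||
        sites$motif != m$name) next
    model <- tryCatch(build_dual_orf_model(seqs, sites[1, ],
                                           orf_start = orf_start,
                                           seq_id = seq_id),
                      error = function(e) NULL)
    if (is.null(model)) next
    if (model$orf0_end != orf_start + 3L * L0 - 1L) next
    if (model$orf1_end != orf1_start + 3L * L1 - 1L) next
    return(list(sequence = seqs, model = model, orf_start = orf_start))
  }
  stop("failed to simulate a valid gene in 500 attempts")
}

#' Simulate a P-site footprint profile over a dual-ORF gene
#'
#' Ribosomes initiate on the 0-frame ORF; at the heptamer a fraction
#' `theta` continues into the +1 ORF while the remainder terminates at the
#' 0-frame stop. Per-codon footprint counts are Poisson with
#' gamma-distributed codon rates (shape `per_codon_dispersion`), and each
#' footprint's P-site lands on the first nucleotide of its codon with
#' probability `frame_fidelity`, otherwise 1 nt to either side.
#'
#' @param gene output of [simulate_gene()] (or a list with `sequence` and
#'   `model`).
#' @param theta true frameshifting efficiency in \[0, 1\].
#' @param depth expected total footprint count.
#' @param frame_fidelity probability a P-site lands in its true frame.
#' @param per_codon_dispersion gamma shape for codon-level rate variation
#'   (larger = more uniform).
#' @param seed optional RNG seed.
#' @return [ribo_profile()] with attribute `truth` recording the simulation
#'   parameters.
#' @export
simulate_ribo_profile <- function(gene, theta = 0.4, depth = 1e5,
                                  frame_fidelity = 0.9,
                                  per_codon_dispersion = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(theta >= 0, theta <= 1, depth > 0)
  model <- gene$model
  n0 <- (model$orf0_end - model$orf0_start + 1L) %/% 3L
  n1 <- (model$orf1_end - model$orf1_start + 1L) %/% 3L
  starts0 <- model$orf0_start + 3L * (seq_len(n0) - 1L)
  starts1 <- model$orf1_start + 3L * (seq_len(n1) - 1L)
  ip <- (model$site$start - model$orf0_start) %/% 3L + 1L  # P-site codon index
  rel <- c(rep(1, ip), rep(1 - theta, n0 - ip), rep(theta, n1))
  g <- stats::rgamma(n0 + n1, shape = per_codon_dispersion,
                     rate = per_codon_dispersion)
  lam <- rel * g
  lam <- depth * lam / sum(lam)
  cnt <- stats::rpois(n0 + n1, lam)
  starts <- c(starts0, starts1)
  stay <- stats::rbinom(length(cnt), cnt, frame_fidelity)
  left <- stats::rbinom(length(cnt), cnt - stay, 0.5)
  right <- cnt - stay - left
  counts <- numeric(nchar(gene$sequence))
  add_at <- function(counts, pos, val) {
    keep <- pos >= 1L & pos <= length(counts)
    idx <- pos[keep]
    counts[idx] <- counts[idx] + val[keep]
    counts
  }
  counts <- add_at(counts, starts, stay)
  counts <- add_at(counts, starts - 1L, left)
  counts <- add_at(counts, starts + 1L, right)
  p <- ribo_profile(counts, seq_id = model$seq_id)
  attr(p, "truth") <- list(theta = theta, depth = depth,
                           frame_fidelity = frame_fidelity,
                           per_codon_dispersion = per_codon_dispersion)
  p
}

#' Simulate a codon alignment with a locally constrained synonymous rate
#'
#' Each non-reference row mutates each reference codon to a random
#' synonymous alternative with probability `syn_rate` (multiplied by
#' `constraint_factor` inside `constraint_window`) and, independently, to a
#' single-nucleotide non-synonymous neighbour with probability
#' `nonsyn_rate`. Columns listed in `freeze_columns` (e.g. the heptamer
#' codons, which are universally conserved at genuine frameshift loci) are
#' never mutated.
#'
#' @param reference_cds ungapped in-frame DNA string (reference row).
#' @param n_rows total rows including the reference.
#' @param syn_rate per-(row, codon) synonymous substitution probability.
#' @param nonsyn_rate per-(row, codon) non-synonymous substitution
#'   probability.
#' @param constraint_window optional c(first, last) codon interval with a
#'   reduced synonymous rate.
#' @param constraint_factor multiplier on `syn_rate` inside the window.
#' @param freeze_columns codon indices exempt from all mutation.
#' @param seed optional RNG seed.
#' @return a `codon_alignment` (reference = row 1) with attribute `truth`.
#' @export
simulate_codon_alignment <- function(reference_cds, n_rows = 20L,
                                     syn_rate = 0.3, nonsyn_rate = 0.02,
                                     constraint_window = NULL,
                                     constraint_factor = 1,
                                     freeze_columns = integer(0),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ref <- codons_of(normalize_seq(reference_cds))
  L <- length(ref)
  rate <- rep(syn_rate, L)
  if (!is.null(constraint_window)) {
    w <- constraint_window[1]:constraint_window[2]
    rate[w] <- rate[w] * constraint_factor
  }
  rate[freeze_columns] <- 0
  ns_rate <- rep(nonsyn_rate, L)
  ns_rate[freeze_columns] <- 0
  syn_sets <- lapply(ref, syn_alternatives)
  ns_sets <- lapply(ref, nonsyn_neighbours)
  rows <- matrix(rep(ref, each = n_rows), nrow = n_rows)
  for (i in 2:n_rows) {
    do_syn <- stats::runif(L) < rate & lengths(syn_sets) > 0
    do_ns <- stats::runif(L) < ns_rate & lengths(ns_sets) > 0
    for (j in which(do_syn)) {
      rows[i, j] <- sample(syn_sets[[j]], 1L)
    }
    for (j in which(do_ns & !do_syn)) {
      rows[i, j] <- sample(ns_sets[[j]], 1L)
    }
  }
  rownames(rows) <- c("reference", paste0("ortholog", seq_len(n_rows - 1L)))
  aln <- codon_alignment(rows, reference = 1L)
  attr(aln, "truth") <- list(syn_rate = syn_rate, nonsyn_rate = nonsyn_rate,
                             constraint_window = constraint_window,
                             constraint_factor = constraint_factor)
  aln
}

#' Simulate dual-luciferase replicate readings
#'
#' In-frame controls get firefly/Renilla ratios lognormally scattered
#' around `base_ratio`; test constructs around `base_ratio * theta`, the
#' paired test/in-frame-control design of recoding reporter assays.
#'
#' @param theta true frameshifting efficiency in \[0, 1\].
#' @param n_replicates wells per class.
#' @param luc_sigma lognormal sd of replicate noise.
#' @param base_ratio in-frame firefly/Renilla ratio.
#' @param base_renilla mean Renilla luminescence.
#' @param seed optional RNG seed.
#' @return list(tests, controls): data.frames with sample_id,
#'   construct_class, firefly, renilla.
#' @export
simulate_luciferase <- function(theta = 0.4, n_replicates = 8L,
                                luc_sigma = 0.1, base_ratio = 0.5,
                                base_renilla = 1e6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  one_class <- function(class, ratio) {
    ren <- stats::rlnorm(n_replicates, log(base_renilla), luc_sigma)
    fir <- ren * ratio * stats::rlnorm(n_replicates, 0, luc_sigma)
    data.frame(sample_id = paste0(class, "_", seq_len(n_replicates)),
               construct_class = class, firefly = fir, renilla = ren,
               stringsAsFactors = FALSE)
  }
  list(tests = one_class("test", base_ratio * theta),
       controls = one_class("in_frame_control", base_ratio))
}

#' Simulate a DMS reactivity track for a hairpin
#'
#' Unpaired A/C positions draw exponential reactivities with mean
#' `dms_snr`; paired A/C positions with mean 1; G and U/T positions are NaN
#' (DMS does not probe them).
#'
#' @param stem a `stem_loop`.
#' @param sequence the folded sequence.
#' @param dms_snr mean unpaired/paired reactivity ratio.
#' @param seed optional RNG seed.
#' @return data.frame(pos, base, reactivity) covering the fold window.
#' @export
simulate_dms <- function(stem, sequence, dms_snr = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sequence <- normalize_seq(sequence)
  pos <- stem$window[1]:stem$window[2]
  base <- strsplit(substr(sequence, stem$window[1], stem$window[2]), "")[[1]]
  paired <- pos %in% as.integer(stem$pairs)
  ac <- base %in% c("A", "C")
  react <- rep(NaN, length(pos))
  mu <- ifelse(paired, 1, dms_snr)
  react[ac] <- stats::rexp(sum(ac), rate = 1 / mu[ac])
  data.frame(pos = pos, base = base, reactivity = react,
             stringsAsFactors = FALSE)
}
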
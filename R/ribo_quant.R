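#' Construct a per-nucleotide P-site profile
#'
#' @param counts non-negative integer vector, one entry per transcript
#'   nucleotide (P-site assigned counts).
#' @param seq_id transcript identifier.
#' @return object of class `ribo_profile`.
#' @export
ribo_profile <- function(counts, seq_id = "seq") {
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative and complete")
  }
  structure(list(seq_id = seq_id, counts = counts), class = "ribo_profile")
}

#' @export
print.ribo_profile <- function(x, ...) {
  cat("P-site profile [", x$seq_id, "]: ", length(x$counts), " nt, ",
      sum(x$counts), " counts\n", sep = "")
  invisible(x)
}

#' Reading-frame composition of a profile region
#'
#' Fractions of the region's counts falling at positions congruent to 0, 1
#' and 2 (mod 3) relative to `anchor` — the frame-periodicity diagnostic
#' used to colour footprint tracks by supported reading frame.
#'
#' @param profile a [ribo_profile()].
#' @param region length-2 integer vector, 1-based closed interval.
#' @param anchor 1-based position defining frame 0 (e.g. the ORF start).
#' @return named numeric vector c(frame0, frame1, frame2); all NaN (with a
#'   warning) when the region holds no counts.
#' @export
frame_composition <- function(profile, region, anchor = 1L) {
  stopifnot(inherits(profile, "ribo_profile"), length(region) == 2L)
  n <- length(profile$counts)
  if (region[1] < 1L || region[2] > n || region[1] > region[2]) {
    stop("region out of profile bounds")
  }
  pos <- region[1]:region[2]
  cnt <- profile$counts[pos]
  tot <- sum(cnt)
  if (tot == 0) {
    warning("region has zero counts; frame composition undefined")
    return(c(frame0 = NaN, frame1 = NaN, frame2 = NaN))
  }
  f <- (pos - anchor) %% 3L
  out <- vapply(0:2, function(k) sum(cnt[f == k]) / tot, numeric(1))
  names(out) <- c("frame0", "frame1", "frame2")
  out
}

## region geometry shared by fs_efficiency: 1-based closed codon-aligned
## intervals, trimmed by `trim_codons` at both ends
fs_regions <- function(model, trim_codons = 1L) {
  st <- model$site$start
  ## 0-frame region: start codon through the heptamer P-site codon
  r0 <- c(model$orf0_start, st + 2L)
  ## +1 region: first +1 codon entirely after the 0-frame stop, to orf1_end
  k <- ceiling((model$orf0_end + 1L - model$orf1_start) / 3)
  s1 <- model$orf1_start + 3L * max(0L, as.integer(k))
  r1 <- c(s1, model$orf1_end)
  t <- 3L * as.integer(trim_codons)
  r0 <- c(r0[1] + t, r0[2] - t)
  r1 <- c(r1[1] + t, r1[2] - t)
  if (r0[2] - r0[1] + 1L < 3L) stop("0-frame region shorter than 1 codon after trimming")
  if (r1[2] - r1[1] + 1L < 3L) stop("+1-frame region shorter than 1 codon after trimming")
  list(region0 = r0, region1 = r1,
       frame_anchor0 = model$orf0_start, frame_anchor1 = model$orf1_start)
}

#' Frameshifting efficiency from a P-site profile
#'
#' The density-ratio statistic: footprint counts in each region are
#' normalized by the region's codon count, and the +1-ORF density is divided
#' by the 0-frame density and multiplied by 100. Region 0 runs from the
#' start codon to the heptamer P-site codon; region 1 from the first +1
#' codon after the 0-frame stop to the end of the +1 ORF; both are trimmed
#' by `trim_codons` codons at each end to avoid initiation/termination peak
#' artefacts.
#'
#' @param profile a [ribo_profile()] covering the model.
#' @param model a `dual_orf_model`.
#' @param trim_codons codons removed from both ends of each region
#'   (default 1).
#' @param mode `"region"` counts every position inside a region; `"frame"`
#'   counts only positions in the region's own reading frame.
#' @return object of class `fs_estimate`: list with efficiency_pct (NA with
#'   `defined = FALSE` when the 0-frame region has no counts), rpf0, rpf1,
#'   codons0, codons1, region0, region1, mode.
#' @export
fs_efficiency <- function(profile, model, trim_codons = 1L,
                          mode = c("region", "frame")) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "ribo_profile"),
            inherits(model, "dual_orf_model"))
  if (trim_codons < 0L) stop("trim_codons must be >= 0")
  rg <- fs_regions(model, trim_codons)
  if (rg$region1[2] > length(profile$counts)) {
    stop("profile does not cover the model")
  }
  region_sum <- function(region, anchor) {
    pos <- region[1]:region[2]
    if (mode == "frame") pos <- pos[(pos - anchor) %% 3L == 0L]
    sum(profile$counts[pos])
  }
  rpf0 <- region_sum(rg$region0, rg$frame_anchor0)
  rpf1 <- region_sum(rg$region1, rg$frame_anchor1)
  codons0 <- (rg$region0[2] - rg$region0[1] + 1L) / 3
  codons1 <- (rg$region1[2] - rg$region1[1] + 1L) / 3
  defined <- rpf0 > 0
  eff <- if (defined) 100 * (rpf1 / codons1) / (rpf0 / codons0) else NA_real_
  if (!defined) warning("no 0-frame signal: efficiency undefined")
  structure(list(seq_id = profile$seq_id, efficiency_pct = eff,
                 defined = defined, rpf0 = rpf0, rpf1 = rpf1,
                 codons0 = codons0, codons1 = codons1,
                 region0 = rg$region0, region1 = rg$region1, mode = mode),
            class = "fs_estimate")
}

#' @export
print.fs_estimate <- function(x, ...) {
  cat("Frameshifting efficiency [", x$seq_id, "]: ",
      if (x$defined) sprintf("%.2f%%", x$efficiency_pct) else "undefined",
      "  (rpf0=", x$rpf0, "/", x$codons0, " codons; rpf1=", x$rpf1, "/",
      x$codons1, " codons; mode=", x$mode, ")\n", sep = "")
  invisible(x)
}

#' Aggregate frameshifting-efficiency estimates across datasets
#'
#' Box-plot style summary: median, quartiles by linear interpolation
#' (`stats::quantile` type 7) and whiskers extending to the most extreme
#' values within 1.5 times the interquartile range of the quartiles.
#' Undefined estimates are dropped and counted.
#'
#' @param estimates list of `fs_estimate` objects, or a numeric vector of
#'   efficiencies (NA = undefined).
#' @return object of class `fs_aggregate`: list with n_datasets, n_dropped,
#'   median, q25, q75, whisker_low, whisker_high, values.
#' @export
aggregate_fs <- function(estimates) {
  if (is.list(estimates) && length(estimates) &&
      inherits(estimates[[1]], "fs_estimate")) {
    vals <- vapply(estimates, function(e) {
      if (isTRUE(e$defined)) e$efficiency_pct else NA_real_
    }, numeric(1))
  } else {
    vals <- as.numeric(estimates)
  }
  dropped <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("no defined estimates to aggregate")
  if (dropped > 0L) message(dropped, " undefined estimate(s) dropped")
  q <- unname(stats::quantile(vals, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_f <- q[1] - 1.5 * iqr
  hi_f <- q[3] + 1.5 * iqr
  structure(list(
    n_datasets = length(vals), n_dropped = dropped,
    median = q[2], q25 = q[1], q75 = q[3],
    whisker_low = min(vals[vals >= lo_f]),
    whisker_high = max(vals[vals <= hi_f]),
    values = vals
  ), class = "fs_aggregate")
}

#' @export
print.fs_aggregate <- function(x, ...) {
  cat("FS efficiency across ", x$n_datasets, " dataset(s)",
      if (x$n_dropped) paste0(" (", x$n_dropped, " undefined dropped)"),
      ":\n  median ", sprintf("%.2f", x$median),
      "  IQR [", sprintf("%.2f", x$q25), ", ", sprintf("%.2f", x$q75),
      "]  whiskers [", sprintf("%.2f", x$whisker_low), ", ",
      sprintf("%.2f", x$whisker_high), "]\n", sep = "")
  invisible(x)
}

#' Assign P-sites to footprint 5' ends
#'
#' Shifts each read's 5' position by a read-length-specific offset and
#' accumulates counts. Reads of a length with no offset, or whose shifted
#' position falls outside the transcript, are dropped and counted.
#'
#' @param reads data.frame with columns `position` (1-based 5' end) and
#'   `read_length`.
#' @param transcript_length transcript length in nt.
#' @param offsets named numeric vector, names = read lengths; default 12 nt
#'   for lengths 28-30 (the usual yeast monosome offsets).
#' @param seq_id transcript identifier.
#' @return [ribo_profile()] with attribute `n_dropped`.
#' @export
assign_psite <- function(reads, transcript_length,
                         offsets = c("28" = 12, "29" = 12, "30" = 12),
                         seq_id = "seq") {
  stopifnot(all(c("position", "read_length") %in% names(reads)))
  counts <- numeric(transcript_length)
  off <- offsets[as.character(reads$read_length)]
  shifted <- reads$position + as.numeric(off)
  keep <- !is.na(shifted) & shifted >= 1 & shifted <= transcript_length
  if (any(keep)) {
    tab <- table(shifted[keep])
    counts[as.integer(names(tab))] <- as.numeric(tab)
  }
  p <- ribo_profile(counts, seq_id = seq_id)
  attr(p, "n_dropped") <- sum(!keep)
  p
}
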
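## pair scores: Watson-Crick = 2, G.U wobble = 1, otherwise unpairable
pair_score_matrix <- function(bases, allow_gu = TRUE) {
  key <- outer(bases, bases, paste0)
  P <- matrix(NA_real_, length(bases), length(bases))
  P[key %in% c("AT", "TA", "GC", "CG")] <- 2
  if (allow_gu) P[key %in% c("GT", "TG")] <- 1
  P
}

#' Find the most stable single hairpin in a sequence window
#'
#' Dynamic program over single-helix hairpins: one stack of nested pairs,
#' interrupted by at most two internal loops/bulges of at most 3 unpaired
#' nucleotides each, closing a terminal loop of at least 3 nt. Scoring is an
#' ordinal stacking score, not a free energy: +2 per Watson-Crick pair, +1
#' per G·U wobble pair, -2 per internal loop/bulge, -3 to open the helix.
#' Returns NULL when no hairpin scores above 0. Ties are broken towards the
#' longer helix, then the 5'-most one.
#'
#' @param sequence DNA or RNA string.
#' @param search_window optional c(start, end), 1-based closed interval to
#'   fold (at most 200 nt); default the whole sequence.
#' @param allow_gu allow G·U wobble pairs (default TRUE).
#' @return object of class `stem_loop` (pairs matrix in sequence
#'   coordinates, loop and span intervals, score, n_pairs) or NULL.
#' @examples
#' find_best_hairpin("GGGAAACCC")   # 3-bp stem closing the AAA loop
#' @export
find_best_hairpin <- function(sequence, search_window = NULL,
                              allow_gu = TRUE) {
  sequence <- normalize_seq(sequence)
  if (is.null(search_window)) search_window <- c(1L, nchar(sequence))
  w0 <- as.integer(search_window[1]); w1 <- as.integer(search_window[2])
  if (w0 < 1L || w1 > nchar(sequence) || w0 > w1) stop("invalid search window")
  n <- w1 - w0 + 1L
  if (n > 200L) stop("search window exceeds 200 nt; fold sub-windows instead")
  bases <- strsplit(substr(sequence, w0, w1), "")[[1]]
  P <- pair_score_matrix(bases, allow_gu)
  if (n < 5L || !any(!is.na(P))) return(NULL)

  NEG <- -Inf
  S <- array(NEG, c(n, n, 3))    # best score, innermost pair (i,j), k gaps
  NP <- array(0L, c(n, n, 3))    # helix length (pairs)
  OI <- array(0L, c(n, n, 3))    # outermost pair's 5' position
  PRED <- array(0L, c(n, n, 3, 3))  # predecessor (a, b, k'); 0 = opening

  better <- function(v1, np1, oi1, v2, np2, oi2) {
    if (v1 != v2) return(v1 > v2)
    if (np1 != np2) return(np1 > np2)
    oi1 < oi2
  }
  for (i in seq_len(n - 1L)) {
    for (j in n:(i + 1L)) {
      p <- P[i, j]
      if (is.na(p)) next
      for (k in 0:2) {
        bv <- NEG; bnp <- 0L; boi <- i; bpred <- c(0L, 0L, 0L)
        if (k == 0L) { bv <- -3; bnp <- 0L; boi <- i }  # open here
        if (i > 1L && j < n && S[i - 1L, j + 1L, k + 1L] > NEG) {
          v <- S[i - 1L, j + 1L, k + 1L]
          if (better(v, NP[i - 1L, j + 1L, k + 1L], OI[i - 1L, j + 1L, k + 1L],
                     bv, bnp, boi)) {
            bv <- v; bnp <- NP[i - 1L, j + 1L, k + 1L]
            boi <- OI[i - 1L, j + 1L, k + 1L]
            bpred <- c(i - 1L, j + 1L, k)
          }
        }
        if (k >= 1L) {
          for (di in 0:3) {
            a <- i - 1L - di
            if (a < 1L) break
            for (dj in 0:(3 - di)) {
              if (di + dj < 1L) next
              b <- j + 1L + dj
              if (b > n) break
              if (S[a, b, k] > NEG) {
                v <- S[a, b, k] - 2
                if (better(v, NP[a, b, k], OI[a, b, k], bv, bnp, boi)) {
                  bv <- v; bnp <- NP[a, b, k]; boi <- OI[a, b, k]
                  bpred <- c(a, b, k - 1L)
                }
              }
            }
          }
        }
        if (bv > NEG) {
          S[i, j, k + 1L] <- p + bv
          NP[i, j, k + 1L] <- bnp + 1L
          OI[i, j, k + 1L] <- boi
          PRED[i, j, k + 1L, ] <- bpred
        }
      }
    }
  }
  ## select best closing pair with a legal terminal loop
  best <- NULL
  for (i in seq_len(n - 4L)) {
    for (j in (i + 4L):n) {
      for (k in 1:3) {
        v <- S[i, j, k]
        if (v > 0 &&
            (is.null(best) ||
             better(v, NP[i, j, k], OI[i, j, k],
                    best$v, best$np, best$oi))) {
          best <- list(i = i, j = j, k = k, v = v,
                       np = NP[i, j, k], oi = OI[i, j, k])
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  ## traceback inner -> outer
  pairs <- matrix(0L, nrow = best$np, ncol = 2L)
  cur <- c(best$i, best$j, best$k - 1L)
  for (r in seq_len(best$np)) {
    pairs[r, ] <- cur[1:2]
    cur <- PRED[cur[1], cur[2], cur[3] + 1L, ]
  }
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  pairs_global <- pairs + (w0 - 1L)
  colnames(pairs_global) <- c("i", "j")
  structure(list(
    pairs = pairs_global,
    loop = c(best$i + 1L, best$j - 1L) + (w0 - 1L),
    span = c(min(pairs_global), max(pairs_global)),
    score = best$v,
    n_pairs = best$np,
    window = c(w0, w1)
  ), class = "stem_loop")
}

#' @export
print.stem_loop <- function(x, ...) {
  cat("Stem-loop: ", x$n_pairs, " bp, span ", x$span[1], "-", x$span[2],
      ", loop ", x$loop[1], "-", x$loop[2], ", score ", x$score, "\n",
      sep = "")
  invisible(x)
}

#' Spacer between a stem-loop and a frameshift site
#'
#' Number of nucleotides strictly between the 3' base of the hairpin span
#' and the first base of the heptamer (and the same distance in codons when
#' it is a whole number of codons). The ABP140 stimulator sits 6 nt — two
#' codons — upstream of its heptamer.
#'
#' @param stem a `stem_loop`.
#' @param site frameshift site (row from [scan_heptamers()] or the `site`
#'   element of a model).
#' @return list(spacer_nt, spacer_codons); spacer_codons is NA when the
#'   spacer is not a whole number of codons.
#' @export
spacer_to_site <- function(stem, site) {
  stopifnot(inherits(stem, "stem_loop"))
  start <- as.integer(site$start)
  if (stem$span[2] >= start) stop("stem-loop is not upstream of the site")
  nt <- start - stem$span[2] - 1L
  list(spacer_nt = nt,
       spacer_codons = if (nt %% 3L == 0L) nt %/% 3L else NA_integer_)
}

#' Agreement between a hairpin and DMS reactivities
#'
#' DMS methylates unpaired A and C bases, so a real hairpin should show low
#' reactivity on paired A/C positions relative to unpaired ones. The score
#' is the rank-based separation: the probability that a randomly chosen
#' unpaired A/C within the hairpin span has higher reactivity than a
#' randomly chosen paired A/C (ties count 0.5) — a scale-free statistic,
#' robust to the normalisation differences between probing experiments.
#'
#' @param stem a `stem_loop`.
#' @param track data.frame with columns pos (1-based), base, reactivity
#'   (NA/NaN ignored).
#' @return score in \[0, 1\], or NA (with a warning) when either class has
#'   no eligible base.
#' @export
dms_consistency <- function(stem, track) {
  stopifnot(inherits(stem, "stem_loop"),
            all(c("pos", "base", "reactivity") %in% names(track)))
  span <- stem$span[1]:stem$span[2]
  paired_pos <- as.integer(stem$pairs)
  tr <- track[track$pos %in% span & toupper(track$base) %in% c("A", "C") &
                is.finite(track$reactivity), , drop = FALSE]
  up <- tr$reactivity[!(tr$pos %in% paired_pos)]
  pp <- tr$reactivity[tr$pos %in% paired_pos]
  if (length(up) == 0L || length(pp) == 0L) {
    warning("no eligible paired and unpaired A/C bases: score undefined")
    return(NA_real_)
  }
  cmp <- outer(up, pp, ">") + 0.5 * outer(up, pp, "==")
  mean(cmp)
}

#' Dot-bracket string for a stem-loop
#'
#' @param stem a `stem_loop`.
#' @param sequence the folded sequence (structure string spans the fold
#'   window).
#' @return two-element character vector: window sequence and dot-bracket
#'   string.
#' @export
stem_to_dotbracket <- function(stem, sequence) {
  sequence <- normalize_seq(sequence)
  w <- stem$window
  db <- rep(".", w[2] - w[1] + 1L)
  db[stem$pairs[, 1] - w[1] + 1L] <- "("
  db[stem$pairs[, 2] - w[1] + 1L] <- ")"
  c(sequence = substr(sequence, w[1], w[2]),
    structure = paste(db, collapse = ""))
}
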
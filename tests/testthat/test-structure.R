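test_that("a perfect stem is found with its loop and score", {
  hp <- find_best_hairpin("GGGAAACCC")
  expect_equal(hp$n_pairs, 3L)
  expect_equal(hp$pairs[, "i"], c(1L, 2L, 3L))
  expect_equal(hp$pairs[, "j"], c(9L, 8L, 7L))
  expect_equal(hp$loop, c(4L, 6L))
  expect_equal(hp$span, c(1L, 9L))
  expect_equal(hp$score, 3 * 2 - 3)
  # RNA spelling and lowercase are accepted
  expect_equal(find_best_hairpin("AAGGAAACCUU")$score,
               find_best_hairpin("AAGGAAACCTT")$score)
  expect_equal(find_best_hairpin("gggaaaccc")$score, 3)
})

test_that("unfoldable sequences return NULL", {
  expect_null(find_best_hairpin("AAAAAAAAA"))
  expect_null(find_best_hairpin("ACGT"))
  # a single weak pair cannot pay the opening penalty
  expect_null(find_best_hairpin("GAAATT", allow_gu = TRUE))
})

test_that("window handling: offsets respected, oversize windows rejected", {
  s <- paste0(strrep("A", 10), "GGGAAACCC", strrep("A", 10))
  hp <- find_best_hairpin(s, search_window = c(11L, 19L))
  expect_equal(hp$span, c(11L, 19L))
  expect_error(find_best_hairpin(strrep("A", 300)), "200 nt")
  expect_error(find_best_hairpin("ACGT", search_window = c(0L, 4L)),
               "window")
})

test_that("DP equals exhaustive enumeration on short random windows", {
  set.seed(90)
  for (rep in 1:200) {
    len <- sample(6:12, 1L)
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    hp <- find_best_hairpin(s)
    dp <- if (is.null(hp)) NA_real_ else hp$score
    expect_identical(dp, brute_hairpin_max(s), label = s)
  }
})

test_that("Watson-Crick-only folding is mirror symmetric under reverse complement", {
  set.seed(91)
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  for (rep in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
               collapse = "")
    a <- find_best_hairpin(s, allow_gu = FALSE)
    b <- find_best_hairpin(rc(s), allow_gu = FALSE)
    expect_identical(is.null(a), is.null(b))
    if (!is.null(a)) {
      # score and helix length are mirror invariants; the exact pair list is
      # not, because equal-scoring ties break towards the 5' end on each
      # strand
      expect_equal(a$score, b$score)
      expect_equal(a$n_pairs, b$n_pairs)
      # the mirrored structure is itself a legal hairpin of the same score:
      # check its pairs are valid WC pairs of the original sequence
      n <- nchar(s)
      bases <- strsplit(s, "")[[1]]
      mi <- n + 1L - b$pairs[, "j"]; mj <- n + 1L - b$pairs[, "i"]
      expect_true(all(paste0(bases[mi], bases[mj]) %in%
                        c("AT", "TA", "GC", "CG")))
    }
  }
})

test_that("spacer arithmetic matches the stem/heptamer geometry", {
  # hairpin base 6 nt upstream of the heptamer: 6 nt = 2 codons
  s <- paste0("GGGGAAACCCC", "TTTGGA", "CTTAGGC", "AAA")
  site <- list(start = 18L)
  hp <- find_best_hairpin(s, search_window = c(1L, 11L))
  expect_equal(hp$span, c(1L, 11L))
  sp <- spacer_to_site(hp, site)
  expect_equal(sp$spacer_nt, 6L)
  expect_equal(sp$spacer_codons, 2L)
  # abutting: zero spacer
  expect_equal(spacer_to_site(hp, list(start = 12L))$spacer_nt, 0L)
  # inserting k codons widens the spacer by k codons
  for (k in 1:5) {
    expect_equal(spacer_to_site(hp, list(start = 18L + 3L * k))$spacer_codons,
                 2L + k)
  }
  # non-codon spacers are reported in nt only
  expect_true(is.na(spacer_to_site(hp, list(start = 19L))$spacer_codons))
  expect_error(spacer_to_site(hp, list(start = 5L)), "upstream")
})

test_that("DMS consistency is the all-pairs rank separation", {
  hp <- find_best_hairpin("GGGCAAAACGCCC")
  track <- data.frame(pos = hp$window[1]:hp$window[2],
                      base = strsplit("GGGCAAAACGCCC", "")[[1]],
                      reactivity = 0)
  paired <- track$pos %in% as.integer(hp$pairs)
  # perfectly separated: all unpaired A/C hot, all paired A/C cold
  track$reactivity[!paired] <- 1
  expect_equal(dms_consistency(hp, track), 1)
  # reversed
  track$reactivity <- as.numeric(paired)
  expect_equal(dms_consistency(hp, track), 0)
  # mixed toy track equals the brute-force pairwise average
  set.seed(92)
  track$reactivity <- round(runif(nrow(track)), 1)
  ac <- track$base %in% c("A", "C")
  up <- track$reactivity[ac & !paired]; pp <- track$reactivity[ac & paired]
  brute <- mean(outer(up, pp, ">") + 0.5 * outer(up, pp, "=="))
  expect_equal(dms_consistency(hp, track), brute)
  # NaN reactivities are ignored; all-NaN is undefined
  track$reactivity[ac] <- NaN
  expect_warning(x <- dms_consistency(hp, track), "undefined")
  expect_true(is.na(x))
})

test_that("simulated reactivities separate as the signal-to-noise predicts", {
  set.seed(93)
  # 12-bp A/C-rich stem with an 11-nt A/C loop: >= 10 eligible bases per
  # class so the rank statistic is well resolved
  s <- paste0("CACCACCACCAC", "AAAAACAAAAA", "GTGGTGGTGGTG")
  hp <- find_best_hairpin(s)
  expect_gte(hp$n_pairs, 10L)
  # with exponential reactivities the expected rank separation is
  # snr / (snr + 1): ~2/3 at snr 2, -> 1 as snr grows, 1/2 when exchangeable
  sc2 <- replicate(200, dms_consistency(hp, simulate_dms(hp, s, dms_snr = 2)))
  expect_lt(abs(mean(sc2) - 2 / 3), 0.05)
  sc20 <- replicate(200, dms_consistency(hp, simulate_dms(hp, s, dms_snr = 20)))
  expect_gt(mean(sc20), 0.9)          # expected separation 20/21
  sc1 <- replicate(200, dms_consistency(hp, simulate_dms(hp, s, dms_snr = 1)))
  expect_lt(abs(mean(sc1) - 0.5), 0.05)
})

test_that("dot-bracket export matches the pair list", {
  hp <- find_best_hairpin("GGGAAACCC")
  db <- stem_to_dotbracket(hp, "GGGAAACCC")
  expect_equal(db[["structure"]], "(((...)))")
  expect_equal(db[["sequence"]], "GGGAAACCC")
})
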
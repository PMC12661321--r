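test_that("back-translation threads codons through protein gaps", {
  aln <- back_translate_alignment(c(a = "M-K", b = "MLK"),
                                  c(a = "ATGAAA", b = "ATGCTTAAG"))
  expect_equal(unname(aln$codons[1, ]), c("ATG", "---", "AAA"))
  expect_equal(unname(aln$codons[2, ]), c("ATG", "CTT", "AAG"))
  # trailing stop on the CDS is tolerated
  aln2 <- back_translate_alignment(c(a = "MK"), c(a = "ATGAAATAA"))
  expect_equal(unname(aln2$codons[1, ]), c("ATG", "AAA"))
  expect_error(back_translate_alignment(c(a = "MQ"), c(a = "ATGAAA")),
               "mismatch at residue 2")
  expect_error(back_translate_alignment(c(a = "MKK"), c(a = "ATGAAA")),
               "codons")
})

test_that("back-translation matches the position-map oracle and round-trips", {
  set.seed(55)
  for (rep in 1:20) {
    n <- sample(10:40, 1L)
    cds <- vapply(1:4, function(i) random_cds(n, with_stop = FALSE),
                  character(1))
    names(cds) <- paste0("s", 1:4)
    prots <- vapply(cds, function(x)
      paste(translate_codons(codons_of(x)), collapse = ""), character(1))
    # inject gap columns at shared random points to mimic an aligner
    gapify <- function(p, at) paste0(substr(p, 1, at), "-",
                                     substr(p, at + 1, nchar(p)))
    at <- sample(0:n, 1L)
    victims <- sample(1:4, 2L)
    prots[victims] <- vapply(prots[victims], gapify, character(1), at = at)
    prots[-victims] <- vapply(prots[-victims], function(p)
      gapify(p, sample(0:n, 1L)), character(1))
    aln <- back_translate_alignment(prots, cds)
    for (i in 1:4) {
      expect_equal(unname(aln$codons[i, ]),
                   brute_back_translate_row(prots[[i]], cds[[i]]))
      # degap + concatenate reproduces the CDS
      row <- aln$codons[i, ]
      expect_equal(paste(row[row != "---"], collapse = ""), unname(cds[i]))
    }
  }
})

test_that("substitution calls follow the codon table", {
  aln <- codon_alignment(c(ref = "CTGATTGGC", x = "CTTATTAGC",
                           y = "CTG---GGC"))
  calls <- classify_columns(aln)
  expect_equal(unname(calls["x", ]),
               c("synonymous", "identical", "non_synonymous"))
  expect_equal(unname(calls["y", ]), c("identical", "gap", "identical"))
  expect_true(all(is.na(calls["ref", ])))
})

test_that("substitution kinds are symmetric under reference/row swap", {
  set.seed(66)
  cds <- random_cds(60, with_stop = FALSE)
  aln <- simulate_codon_alignment(cds, n_rows = 5L, syn_rate = 0.3,
                                  nonsyn_rate = 0.1)
  c12 <- classify_columns(aln)
  aln$reference_index <- 2L
  c21 <- classify_columns(aln)
  expect_equal(unname(c12[2, ]), unname(c21[1, ]))
})

test_that("classification matches brute-force translation comparison", {
  set.seed(67)
  cod <- sample(names(Biostrings::GENETIC_CODE), 400, replace = TRUE)
  m <- matrix(cod, nrow = 4)
  m[sample(length(m), 20)] <- "---"
  m[1, ] <- sample(setdiff(names(Biostrings::GENETIC_CODE), ""),
                   ncol(m), replace = TRUE)
  aln <- codon_alignment(m)
  calls <- classify_columns(aln)
  gc <- Biostrings::GENETIC_CODE
  for (i in 2:4) for (j in seq_len(ncol(m))) {
    expected <- if (m[i, j] == "---" || m[1, j] == "---") "gap"
      else if (m[i, j] == m[1, j]) "identical"
      else if (gc[[m[i, j]]] == gc[[m[1, j]]]) "synonymous"
      else "non_synonymous"
    expect_equal(unname(calls[i, j]), expected)
  }
})

test_that("identical alignments yield undefined window statistics", {
  cds <- random_cds(30, with_stop = FALSE)
  aln <- simulate_codon_alignment(cds, n_rows = 6L, syn_rate = 0,
                                  nonsyn_rate = 0, seed = 1L)
  sc <- window_synonymy_scan(aln, window = 17L)
  expect_true(all(sc$observed_syn == 0))
  expect_true(all(is.na(sc$p_value)))   # null rate is 0: no test possible
})

test_that("window scan geometry and bookkeeping are consistent", {
  set.seed(68)
  cds <- random_cds(80, with_stop = FALSE)
  aln <- simulate_codon_alignment(cds, n_rows = 10L, syn_rate = 0.3)
  w <- 17L
  sc <- window_synonymy_scan(aln, window = w)
  expect_equal(nrow(sc), ncol(aln$codons) - w + 1L)
  expect_equal(sc$center_codon, sc$window_start + (w - 1L) %/% 2L)
  calls <- classify_columns(aln)
  syn_col <- colSums(calls == "synonymous", na.rm = TRUE)
  # each window total equals the sum of its per-column synonymous counts
  for (r in c(1L, nrow(sc) %/% 2L, nrow(sc))) {
    expect_equal(sc$observed_syn[r],
                 sum(syn_col[sc$window_start[r]:sc$window_end[r]]))
  }
  expect_true(all(sc$ratio >= 0, na.rm = TRUE))
  expect_true(all(sc$expected_syn[!is.na(sc$p_value)] > 0 |
                    sc$observed_syn[!is.na(sc$p_value)] == 0))
  expect_error(window_synonymy_scan(aln, window = 2L), "window")
  expect_error(window_synonymy_scan(aln, window = 100L), "window")
  # BH adjustment adds a monotone column
  scb <- window_synonymy_scan(aln, window = w, p_adjust = "BH")
  expect_true(all(scb$p_adj >= scb$p_value, na.rm = TRUE))
})

test_that("null p-values are conservative and constraint is localized", {
  set.seed(69)
  cds <- random_cds(120, with_stop = FALSE)
  # null: no constrained window
  fpr <- replicate(40, {
    aln <- simulate_codon_alignment(cds, n_rows = 12L, syn_rate = 0.3)
    sc <- window_synonymy_scan(aln)
    mean(sc$p_value < 0.05, na.rm = TRUE)
  })
  expect_lt(mean(fpr), 0.10)
  # strong constraint: minimum-p window sits on the planted window
  hits <- replicate(40, {
    aln <- simulate_codon_alignment(cds, n_rows = 12L, syn_rate = 0.3,
                                    constraint_window = c(50, 66),
                                    constraint_factor = 0.2)
    sc <- window_synonymy_scan(aln)
    abs(sc$center_codon[which.min(sc$p_value)] - 58) <= 3
  })
  expect_gte(mean(hits), 0.85)
})
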
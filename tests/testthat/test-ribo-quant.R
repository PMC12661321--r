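test_that("frame composition partitions counts by codon position", {
  p <- ribo_profile(rep(1, 12))
  expect_equal(unname(frame_composition(p, c(1, 12))), rep(1 / 3, 3))
  p2 <- ribo_profile(c(1, 0, 0, 1, 0, 0))
  expect_equal(unname(frame_composition(p2, c(1, 6))), c(1, 0, 0))
  p3 <- ribo_profile(c(3, 1, 0, 3, 1, 0))
  expect_equal(unname(frame_composition(p3, c(1, 6))), c(0.75, 0.25, 0))
  # anchor shifts the frame assignment
  expect_equal(unname(frame_composition(p2, c(1, 6), anchor = 2L)),
               c(0, 0, 1))
  expect_warning(res <- frame_composition(ribo_profile(rep(0, 6)), c(1, 6)),
                 "zero counts")
  expect_true(all(is.nan(res)))
  expect_error(frame_composition(p, c(0, 12)), "bounds")
})

make_toy_gene <- function(seed = 77L) {
  # orf0 13 codons -> untrimmed 0-frame region = 10 codons (ATG..P-site);
  # orf1 8 codons -> untrimmed +1 region = 5 codons past the 0-frame stop
  simulate_gene(orf0_codons = 13L, orf1_codons = 8L, seed = seed)
}

test_that("efficiency is the codon-normalized density ratio times 100", {
  g <- make_toy_gene()
  m <- g$model
  counts <- numeric(nchar(g$sequence))
  # 5 counts on each 0-frame codon start through the P-site: rpf0 = 50
  starts0 <- seq(m$orf0_start, m$site$start, by = 3L)
  counts[starts0] <- 5
  # 2 counts on each +1 codon fully past the 0-frame stop: rpf1 = 10
  s1 <- m$orf1_start + 3L * ceiling((m$orf0_end + 1L - m$orf1_start) / 3)
  counts[seq(s1, m$orf1_end, by = 3L)] <- 2
  est <- fs_efficiency(ribo_profile(counts), m, trim_codons = 0L)
  expect_equal(est$rpf0, 50)
  expect_equal(est$rpf1, 10)
  expect_equal(est$codons0, 10)
  expect_equal(est$codons1, 5)
  expect_equal(est$efficiency_pct, 100 * (10 / 5) / (50 / 10))  # 40%
  # no +1 signal -> 0%
  counts1 <- counts; counts1[seq(s1, m$orf1_end, by = 3L)] <- 0
  expect_equal(fs_efficiency(ribo_profile(counts1), m,
                             trim_codons = 0L)$efficiency_pct, 0)
  # equal densities -> 100%
  counts2 <- counts; counts2[seq(s1, m$orf1_end, by = 3L)] <- 5
  expect_equal(fs_efficiency(ribo_profile(counts2), m,
                             trim_codons = 0L)$efficiency_pct, 100)
  # no 0-frame signal -> undefined, not zero
  counts3 <- numeric(nchar(g$sequence))
  counts3[seq(s1, m$orf1_end, by = 3L)] <- 2
  expect_warning(und <- fs_efficiency(ribo_profile(counts3), m,
                                      trim_codons = 0L), "undefined")
  expect_false(und$defined)
  expect_true(is.na(und$efficiency_pct))
})

test_that("efficiency is invariant to uniform count scaling", {
  g <- make_toy_gene(78L)
  p <- simulate_ribo_profile(g, theta = 0.3, depth = 2e4, seed = 3L)
  e1 <- fs_efficiency(p, g$model)
  e2 <- fs_efficiency(ribo_profile(p$counts * 7.5, p$seq_id), g$model)
  expect_equal(e1$efficiency_pct, e2$efficiency_pct)
})

test_that("region and frame modes agree at perfect frame fidelity", {
  g <- simulate_gene(seed = 79L)
  p <- simulate_ribo_profile(g, theta = 0.25, depth = 5e4,
                             frame_fidelity = 1, seed = 4L)
  er <- fs_efficiency(p, g$model, mode = "region")
  ef <- fs_efficiency(p, g$model, mode = "frame")
  expect_equal(er$efficiency_pct, ef$efficiency_pct)
  # with frame noise they differ
  pn <- simulate_ribo_profile(g, theta = 0.25, depth = 5e4,
                              frame_fidelity = 0.8, seed = 5L)
  expect_false(isTRUE(all.equal(
    fs_efficiency(pn, g$model, mode = "region")$efficiency_pct,
    fs_efficiency(pn, g$model, mode = "frame")$efficiency_pct)))
})

test_that("over-trimming a region raises a region-naming error", {
  g <- make_toy_gene(80L)
  p <- simulate_ribo_profile(g, theta = 0.3, depth = 1e4, seed = 6L)
  expect_error(fs_efficiency(p, g$model, trim_codons = 10L), "region")
})

test_that("aggregation follows box-plot conventions", {
  a <- aggregate_fs(c(40))
  expect_equal(a$median, 40); expect_equal(a$q75 - a$q25, 0)
  b <- aggregate_fs(c(10, 20, 30, 40, 50))
  expect_equal(b$median, 30)
  expect_equal(b$q25, 20)             # linear interpolation convention
  expect_equal(b$q75, 40)
  expect_equal(b$whisker_low, 10)
  expect_equal(b$whisker_high, 50)
  # whiskers clamp to most extreme values within 1.5 IQR
  d <- aggregate_fs(c(10, 20, 30, 40, 200))
  expect_equal(d$whisker_high, 40)
  # permutation invariance
  v <- c(5, 80, 33, 12, 47, 21)
  x <- aggregate_fs(v); y <- aggregate_fs(sample(v))
  expect_equal(x[c("median", "q25", "q75", "whisker_low", "whisker_high")],
               y[c("median", "q25", "q75", "whisker_low", "whisker_high")])
  # undefined estimates dropped with a message; empty input errors
  expect_message(z <- aggregate_fs(c(40, NA, 20)), "dropped")
  expect_equal(z$n_datasets, 2L)
  expect_error(suppressMessages(aggregate_fs(c(NA_real_))), "no defined")
})

test_that("P-site assignment shifts 5' ends by length-specific offsets", {
  reads <- data.frame(position = c(1L, 1L, 5L, 9L),
                      read_length = c(28L, 29L, 31L, 30L))
  p <- assign_psite(reads, transcript_length = 30L)
  expect_equal(p$counts[13], 2)       # two reads shifted by 12
  expect_equal(p$counts[21], 1)
  expect_equal(attr(p, "n_dropped"), 1L)  # length 31 has no offset
  # custom offsets and out-of-range shifts
  p2 <- assign_psite(data.frame(position = 29L, read_length = 28L),
                     transcript_length = 30L)
  expect_equal(attr(p2, "n_dropped"), 1L)
  expect_equal(sum(p2$counts), 0)
  p3 <- assign_psite(data.frame(position = integer(0),
                                read_length = integer(0)), 10L)
  expect_equal(sum(p3$counts), 0)
})
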
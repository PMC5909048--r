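test_that("assign_windows tiles 1-anchored windows and flags unsorted input", {
  aw <- assign_windows(c(1, 40000, 40001), 40000)
  expect_equal(aw$index, c(1L, 1L, 2L))
  expect_equal(aw$windows$start, c(1, 40001))
  expect_equal(aw$windows$end, c(40000, 80000))

  aw2 <- assign_windows(200001, 200000)
  expect_equal(aw2$index, 2L)
  expect_equal(aw2$windows[2, c("start", "end")],
               data.frame(start = 200001, end = 400000, row.names = 2L))

  # brute-force assignment oracle incl. empty interior windows
  aw3 <- assign_windows(c(150, 250, 3250), 1000)
  counts <- tabulate(aw3$index, nrow(aw3$windows))
  expect_equal(counts, c(2L, 0L, 0L, 1L))
  expect_equal(aw3$windows$start, c(1, 1001, 2001, 3001))

  expect_error(assign_windows(c(10, 5, 20), 100), "element 2")
})

test_that("window_peaks reports modal bin midpoints with count censoring", {
  # single occupied bin: all values in (0.66, 0.68]
  v <- c(0.665, 0.67, 0.675, 0.68)
  wp <- window_peaks(v, pos = c(10, 20, 30, 40), window_size = 1000,
                     bin_width = 0.02, min_count = 1)
  expect_equal(wp$peaks[1, 1], 0.67)
  expect_equal(wp$counts[1, 1], 4L)

  # clear mode: 4 values in (0.48,0.50], 9 in (0.64,0.66]
  v2 <- c(rep(0.49, 4), rep(0.65, 9))
  wp2 <- window_peaks(v2, pos = seq_along(v2), window_size = 1000,
                      bin_width = 0.02, min_count = 1)
  expect_equal(wp2$peaks[1, 1], 0.65)

  # min_count censors the peak but the count is still reported
  wp3 <- window_peaks(v2, pos = seq_along(v2), window_size = 1000,
                      bin_width = 0.02, min_count = 20)
  expect_true(is.na(wp3$peaks[1, 1]))
  expect_equal(wp3$counts[1, 1], 13L)

  expect_error(window_peaks(v2, seq_along(v2), bin_width = 0.7), "bin_width")
})

test_that("half-open bins: exactly 1/2 falls in the bin ending at 0.5", {
  wp <- window_peaks(c(0.5, 0.5, 0.52), pos = c(1, 2, 3), window_size = 10,
                     bin_width = 0.02, min_count = 1)
  expect_equal(wp$peaks[1, 1], 0.49)
  b <- bin_balance(c(0.5, 0.5, 0.52), 0.02)
  expect_equal(sum(b$counts), 3L)
  expect_equal(b$counts[25], 2L)
  expect_equal(b$counts[26], 1L)
  # exact zero falls in no bin
  expect_equal(sum(bin_balance(c(0, 0.3), 0.1)$counts), 1L)
})

test_that("bin ties resolve toward 0.5, then to the lower bin", {
  # bins at 0.455 and 0.545 are equidistant from 0.5 -> the lower bin wins
  wp <- window_peaks(c(0.455, 0.545), pos = c(1, 2), window_size = 10,
                     bin_width = 0.01, min_count = 1)
  expect_equal(wp$peaks[1, 1], 0.455)
  # bins at 0.425 vs 0.545: the one nearer 0.5 wins
  wp2 <- window_peaks(c(0.425, 0.545), pos = c(1, 2), window_size = 10,
                      bin_width = 0.01, min_count = 1)
  expect_equal(wp2$peaks[1, 1], 0.545)
})

test_that("a seeded 2/3 dosage sample peaks at the expected ratio", {
  set.seed(101)
  d_alt <- rbinom(500, 100, 2 / 3)
  bal <- pmax(d_alt, 100 - d_alt) / 100
  wp <- window_peaks(bal, pos = sort(sample.int(40000, 500)),
                     window_size = 40000, bin_width = 0.02)
  occ <- oracle_bins(bal, 0.02)
  expect_equal(wp$peaks[1, 1], oracle_peak(occ, 0.02))
  # binomial depth-100 sampling splits 2/3 across the two flanking bins,
  # so the modal midpoint lands within one bin width of the truth
  expect_lt(abs(wp$peaks[1, 1] - 2 / 3), 0.02)
})

test_that("windows restart per chromosome and conserve counts", {
  set.seed(5)
  chrom <- rep(c("a", "b"), each = 30)
  pos <- c(sort(sample.int(5000, 30)), sort(sample.int(3000, 30)))
  bal <- matrix(runif(120, 0.4, 0.9), ncol = 2)
  bal[sample(120, 15)] <- NA
  wp <- window_peaks(bal, pos, chrom, window_size = 1000, bin_width = 0.05,
                     min_count = 1)
  expect_true(all(wp$windows$start[wp$windows$chrom == "b"][1] == 1))
  for (w in seq_len(nrow(wp$windows))) {
    sel <- chrom == wp$windows$chrom[w] &
      pos >= wp$windows$start[w] & pos <= wp$windows$end[w]
    for (j in 1:2) {
      vals <- bal[sel, j]
      expect_equal(wp$counts[w, j], sum(oracle_bins(vals, 0.05)))
    }
  }
  # zero-variant windows never produce a peak
  expect_true(all(is.na(wp$peaks[wp$counts == 0])))
})

test_that("peak is invariant to within-window variant permutation", {
  set.seed(9)
  vals <- runif(200, 0.3, 0.95)
  pos <- seq_len(200)
  wp1 <- window_peaks(vals, pos, window_size = 500, bin_width = 0.02,
                      min_count = 1)
  # same multiset within each window, different order along pos
  perm <- sample(200)
  wp3 <- window_peaks(vals[perm], pos, window_size = 500, bin_width = 0.02,
                      min_count = 1)
  expect_equal(wp1$peaks, wp3$peaks)
  expect_equal(wp1$counts, wp3$counts)
})

test_that("window_peaks matches the vcfR reference on tie-free data", {
  set.seed(23)
  n <- 300
  ab <- matrix(runif(2 * n, 0.5, 0.99), ncol = 2)
  pos <- sort(sample.int(120000, n))
  wp <- window_peaks(ab, pos, window_size = 40000, bin_width = 0.02,
                     min_count = 1)
  fp <- vcfR::freq_peak(ab, pos, winsize = 40000, bin_width = 0.02)
  expect_equal(unname(wp$counts), unname(fp$counts))
  # compare only windows whose modal bin is unique (tie rules differ)
  for (w in seq_len(nrow(wp$windows))) {
    sel <- pos >= wp$windows$start[w] & pos <= wp$windows$end[w]
    for (j in 1:2) {
      occ <- oracle_bins(ab[sel, j], 0.02)
      if (sum(occ == max(occ)) == 1L) {
        # vcfR computes midpoints in single precision; compare loosely
        expect_equal(unname(wp$peaks[w, j]), unname(fp$peaks[w, j]),
                     tolerance = 1e-6)
      }
    }
  }
  expect_equal(wp$windows$first_pos, unname(fp$wins[, "START_pos"]))
  expect_equal(wp$windows$last_pos, unname(fp$wins[, "END_pos"]))
})

test_that("genomic_positions accumulates chromosome offsets", {
  expect_equal(genomic_positions(c("A", "A", "B"), c(50, 100, 5)),
               c(50, 100, 105))
  expect_equal(genomic_positions(c("A", "B"), c(100, 5), buffer = 10),
               c(100, 115))
  # cumulative-sum oracle with declared lengths
  lens <- c(A = 1000, B = 500, C = 800)
  got <- genomic_positions(c("A", "B", "C"), c(1, 1, 1), chrom_lengths = lens)
  expect_equal(got, c(1, 1001, 1501))
  # within-chromosome order preserved on random data
  set.seed(2)
  chrom <- rep(c("A", "B"), each = 20)
  pos <- c(sort(sample.int(900, 20)), sort(sample.int(400, 20)))
  g <- genomic_positions(chrom, pos, chrom_lengths = lens)
  expect_false(is.unsorted(g))
})
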
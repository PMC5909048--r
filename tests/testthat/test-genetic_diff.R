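test_that("count_alleles counts every observed allele once, any ploidy", {
  gt <- matrix(c("0/1/1", "0/0", "0/1", "./."), 2, 2,
               dimnames = list(NULL, c("s1", "s2")))
  pops <- c(s1 = "a", s2 = "b")
  ca <- count_alleles(gt, pops)
  expect_equal(ca$n[1, ], c(a = 3L, b = 2L))   # triploid + missing-free diploid
  expect_equal(ca$n[2, ], c(a = 2L, b = 0L))   # "./." contributes nothing
  expect_equal(ca$freq[1, , "a"], c(`0` = 1 / 3, `1` = 2 / 3))
  expect_true(all(is.na(ca$freq[2, , "b"])))
  # frequencies sum to 1 wherever alleles were observed
  expect_equal(sum(ca$freq[2, , "a"]), 1)

  expect_error(count_alleles(gt, c(s1 = "a", sX = "b")), "s2")
  # spec example: {"0/1/1", "0/0"} in one pop -> n 5, freq(1) = 0.4
  gt2 <- matrix(c("0/1/1", "0/0", "0/1"), 1, 3,
                dimnames = list(NULL, c("x", "y", "z")))
  ca2 <- count_alleles(gt2, c(x = "p", y = "p", z = "q"))
  expect_equal(unname(ca2$n[1, "p"]), 5L)
  expect_equal(unname(ca2$freq[1, "1", "p"]), 0.4)
})

test_that("ten fully called diploids give n = 20", {
  gt <- matrix("0/1", 1, 20,
               dimnames = list(NULL, paste0("s", 1:20)))
  pops <- setNames(rep(c("a", "b"), each = 10), colnames(gt))
  d <- genetic_diff(gt, pops)
  expect_equal(d$n_a, 20L)
  expect_equal(d$n_b, 20L)
})

test_that("gst_stats reproduces its closed forms and handles degenerate input", {
  s <- gst_stats(hs = c(0.42, 0.42), n = c(20, 20))
  expect_equal(s$Htmax, 1 - 2 * 0.25 * 0.58)
  expect_equal(s$Gstmax, (s$Htmax - 0.42) / s$Htmax)
  expect_true(is.na(s$Gst))  # no Ht supplied
  # equal weights reduce to Hedrick's HT(max) = (k - 1 + Hs) / k
  expect_equal(s$Htmax, (2 - 1 + 0.42) / 2)
  # monomorphic: Ht = 0 -> Gst missing, not 0
  s0 <- gst_stats(hs = c(0, 0), n = c(10, 10), ht = 0)
  expect_true(is.na(s0$Gst))
})

test_that("fixed differences give maximal differentiation", {
  gt <- matrix(c(rep("0/0", 4), rep("1/1", 4)), 1, 8,
               dimnames = list(NULL, paste0("s", 1:8)))
  pops <- setNames(rep(c("a", "b"), each = 4), colnames(gt))
  d <- genetic_diff(gt, pops)
  expect_equal(d$Hs_a, 0)
  expect_equal(d$Hs_b, 0)
  expect_equal(d$Ht, 0.5)
  expect_equal(d$Gst, 1)
  expect_equal(d$Gprimest, 1)
})

test_that("equal-ploidy equal-n data reproduces textbook Nei Gst", {
  set.seed(17)
  for (rep_i in 1:5) {
    sim <- simulate_populations(
      freqs = list(a = as.vector(prop.table(runif(3) + 0.1)),
                   b = as.vector(prop.table(runif(3) + 0.1))),
      n_samples = 12, ploidy = 2, n_variants = 8, seed = 100 + rep_i)
    d <- genetic_diff(sim$gt, sim$pops)
    for (v in seq_len(nrow(d))) {
      # per-population frequencies on the common allele space, by loops
      alleles <- sort(unique(unlist(strsplit(sim$gt[v, ], "/"))))
      pad <- function(g) {
        tab <- table(factor(unlist(strsplit(g, "/")), levels = alleles))
        as.numeric(tab) / sum(tab)
      }
      o <- oracle_nei_gst(list(pad(sim$gt[v, sim$pops[colnames(sim$gt)] == "a"]),
                               pad(sim$gt[v, sim$pops[colnames(sim$gt)] == "b"])))
      expect_equal(d$Ht[v], o$Ht)
      expect_equal(d$Gst[v], o$Gst, tolerance = 1e-12)
    }
  }
})

test_that("statistics are invariant to sample order and mixed ploidy counts", {
  sim <- simulate_populations(
    freqs = list(a = c(0.7, 0.3), b = c(0.2, 0.8)),
    n_samples = c(10, 10), ploidy = c(2, 4), n_variants = 6, seed = 5)
  d <- genetic_diff(sim$gt, sim$pops)
  # a fully called diploid pop gives 20 alleles, tetraploid pop 40
  expect_equal(d$n_a, rep(20L, 6))
  expect_equal(d$n_b, rep(40L, 6))
  perm <- sample(ncol(sim$gt))
  d2 <- genetic_diff(sim$gt[, perm], sim$pops[colnames(sim$gt)[perm]])
  expect_equal(d2[order(names(d2))], d[order(names(d))])
})

test_that("genetic_diff matches the vcfR reference on mixed-ploidy data", {
  sim <- simulate_populations(
    freqs = list(a = c(0.6, 0.3, 0.1), b = c(0.1, 0.5, 0.4)),
    n_samples = c(8, 6), ploidy = c(2, 3), n_variants = 12, seed = 77)
  # push through a VCF file and vcfR's own reader
  variants <- data.frame(chrom = "chr1", pos = seq_len(12) * 10)
  p <- tempfile(fileext = ".vcf")
  write_vcf(variants, list(GT = sim$gt), p)
  vr <- vcfR::read.vcfR(p, verbose = FALSE)
  ref <- vcfR::genetic_diff(vr, pops = factor(unname(sim$pops)),
                            method = "nei")
  mine <- genetic_diff(sim$gt, sim$pops,
                       chrom = variants$chrom, pos = variants$pos)
  expect_equal(mine$Hs_a, ref$Hs_a, tolerance = 1e-12)
  expect_equal(mine$Hs_b, ref$Hs_b, tolerance = 1e-12)
  expect_equal(mine$Ht, ref$Ht, tolerance = 1e-12)
  expect_equal(mine$n_a, ref$n_a)
  expect_equal(mine$n_b, ref$n_b)
  expect_equal(mine$Gst, ref$Gst, tolerance = 1e-12)
  expect_equal(mine$Htmax, ref$Htmax, tolerance = 1e-12)
  expect_equal(mine$Gstmax, ref$Gstmax, tolerance = 1e-12)
  expect_equal(mine$Gprimest, ref$Gprimest, tolerance = 1e-12)
})

test_that("read_populations parses whitespace and comma layouts", {
  p <- tempfile()
  writeLines(c("s1\tpopA", "s2 popA", "s3,popB", ""), p)
  pops <- read_populations(p)
  expect_equal(pops, c(s1 = "popA", s2 = "popA", s3 = "popB"))
  bad <- tempfile()
  writeLines("only_one_column", bad)
  expect_error(read_populations(bad), "two columns")
})
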
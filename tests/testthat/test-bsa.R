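# bulk segregant analysis: bulk frequencies, Z-test, smoothing, regions

test_that("in-silico bulk frequencies count alleles over non-missing calls", {
  d <- matrix(c(0L, 1L, 2L,      # alt freq 0.5 -> ref freq 0.5
                NA, NA, NA,      # uncallable
                2L, 2L, NA), nrow = 3)
  g <- toy_geno(d)
  bf <- insilico_bulk_freq(g, individual_ids(g), "tall")
  expect_equal(bf$ref_freq[1], 0.5)
  expect_equal(bf$n_alleles[1], 6)
  expect_true(is.na(bf$ref_freq[2]))
  expect_equal(bf$ref_freq[3], 0)
  expect_equal(bf$n_alleles[3], 4)
  # a 192-plant bulk yields at most 384 alleles per marker
  set.seed(8)
  big <- toy_geno(matrix(sample(c(0L, 1L, 2L, NA), 192 * 10, replace = TRUE),
                         192, 10))
  bf2 <- insilico_bulk_freq(big, individual_ids(big), "tall")
  expect_true(all(bf2$n_alleles <= 384))
  expect_error(insilico_bulk_freq(g, c("nope"), "tall"), "unknown")
  expect_error(insilico_bulk_freq(g, character(0), "tall"), "empty")
})

test_that("the pooled Z-test matches the Pearson chi-square identity", {
  expect_error(
    ztest_scan(data.frame(id = "a", ref_freq = 0.5, n_alleles = 10),
               data.frame(id = "b", ref_freq = 0.5, n_alleles = 10)),
    "mismatched")
  # equal frequencies: Z = 0, p = 1
  t1 <- data.frame(id = "a", chrom = "1", pos = 1, ref_freq = 0.4,
                   n_alleles = 100)
  s1 <- t1
  sc <- ztest_scan(t1, s1)
  expect_equal(sc$z, 0)
  expect_equal(sc$p_value, 1)
  # Z^2 equals the 2x2 contingency chi-square over 1000 random tables
  set.seed(9)
  for (i in 1:1000) {
    mT <- 2 * sample(50:400, 1); mS <- 2 * sample(50:400, 1)
    cT <- rbinom(1, mT, runif(1, 0.05, 0.95))
    cS <- rbinom(1, mS, runif(1, 0.05, 0.95))
    if (cT + cS == 0 || cT + cS == mT + mS) next
    tall <- data.frame(id = "x", chrom = "1", pos = 1, ref_freq = cT / mT,
                       n_alleles = mT)
    short <- data.frame(id = "x", chrom = "1", pos = 1, ref_freq = cS / mS,
                        n_alleles = mS)
    z <- ztest_scan(tall, short)$z
    tab <- matrix(c(cT, mT - cT, cS, mS - cS), 2)
    x2 <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
    expect_lt(abs(z^2 - unname(x2)), 1e-9)
  }
})

test_that("null bulks from one population give calibrated p-value fractions", {
  cfg <- sim_config(n_chromosomes = 5, markers_per_chromosome = 2000,
                    founder_ld = NULL, seed = 12)
  g <- simulate_founders(cfg, n = 384, seed = 55)
  ids <- individual_ids(g)
  sc <- ztest_scan(insilico_bulk_freq(g, ids[1:192], "tall"),
                   insilico_bulk_freq(g, ids[193:384], "short"))
  expect_gt(mean(sc$p_value < 0.05), 0.04)
  expect_lt(mean(sc$p_value < 0.05), 0.06)
})

test_that("markers uncallable in either bulk are dropped with a message", {
  d <- rbind(c(0L, NA, 1L), c(2L, NA, 1L))
  rownames(d) <- c("i1", "i2")
  g <- toy_geno(d)
  tall <- insilico_bulk_freq(g, "i1", "tall")
  short <- insilico_bulk_freq(g, "i2", "short")
  expect_message(sc <- ztest_scan(tall, short), "dropped")
  expect_equal(nrow(sc), 2)
})

test_that("the outlier threshold is the empirical upper quantile", {
  set.seed(13)
  x <- sample(seq(0.001, 10, length.out = 1000))
  thr <- outlier_threshold(x, q = 0.005)
  expect_equal(sum(x > thr), 5)              # exactly 0.5% of 1000 strictly above
  expect_equal(outlier_threshold(x, q = 0.5), median(x))
  expect_equal(sum(rep(2, 100) > suppressWarnings(outlier_threshold(rep(2, 100)))), 0)
  expect_error(outlier_threshold(numeric(0)), "no values")
  expect_warning(outlier_threshold(1:10, q = 0.005), "unstable")
})

test_that("sliding-window smoothing is a truncated per-chromosome mean", {
  # constant vector unchanged
  expect_equal(smooth_scan(rep(3, 40), rep("1", 40)), rep(3, 40))
  # single interior spike of height s: maximum smoothed value s/15
  x <- rep(0, 61); x[31] <- 9
  sm <- smooth_scan(x, rep("1", 61))
  expect_equal(max(sm), 9 / 15)
  # 15-marker chromosome: middle value is the global mean
  set.seed(14)
  x2 <- runif(15)
  expect_equal(smooth_scan(x2, rep("1", 15))[8], mean(x2))
  # never crosses a chromosome boundary
  x3 <- c(rep(10, 15), rep(0, 15))
  sm3 <- smooth_scan(x3, rep(c("1", "2"), each = 15))
  expect_equal(sm3[1:15], rep(10, 15))
  expect_equal(sm3[16:30], rep(0, 15))
  expect_error(smooth_scan(1:10, rep("1", 10), window = 4), "odd")
})

test_that("region calling matches brute-force run enumeration", {
  # single run at indices 10..20
  n <- 60
  sm <- rep(0, n); sm[10:20] <- 5
  raw <- sm
  mk <- data.frame(chrom = "1", pos = seq(1000, by = 1000, length.out = n))
  reg <- call_regions(sm, raw, 1, mk)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$left_pos, mk$pos[10])
  expect_equal(reg$right_pos, mk$pos[20])
  # two runs separated by 100 sub-threshold markers stay separate
  n2 <- 140
  sm2 <- rep(0, n2); sm2[c(5:10, 111:115)] <- 5
  mk2 <- data.frame(chrom = "1", pos = seq(1e3, by = 1e3, length.out = n2))
  expect_equal(nrow(call_regions(sm2, sm2, 1, mk2)), 2)
  # nothing above threshold: empty
  expect_equal(nrow(call_regions(rep(0, 30), rep(0, 30), 1,
                                 mk[1:30, ])), 0)
  # runs closer than the gap are merged
  sm3 <- rep(0, n); sm3[c(10:12, 20:22)] <- 5
  expect_equal(nrow(call_regions(sm3, sm3, 1, mk, gap = 15)), 1)
  expect_equal(nrow(call_regions(sm3, sm3, 1, mk, gap = 5)), 2)
  # a region needs at least one raw outlier
  raw4 <- rep(0, n)
  expect_equal(nrow(call_regions(sm, raw4, 1, mk)), 0)
  # peak is the smallest raw p, ties to the leftmost
  raw5 <- rep(0, n); raw5[12] <- 7; raw5[15] <- 7
  reg5 <- call_regions(sm, raw5, 1, mk)
  expect_equal(reg5$peak_pos, mk$pos[12])
  expect_equal(reg5$peak_p, 1e-7)
  expect_equal(reg5$length_kb, (reg5$right_pos - reg5$left_pos) / 1000)
  # randomized equivalence with the independent brute-force enumerator
  set.seed(15)
  for (rep in 1:200) {
    nn <- sample(40:120, 1)
    chrom <- sort(sample(c("1", "2"), nn, replace = TRUE))
    pos <- unlist(lapply(split(seq_len(nn), chrom), function(i)
      sort(sample.int(1e6, length(i)))))
    mkr <- data.frame(chrom = chrom, pos = as.vector(pos))
    smr <- pmax(rnorm(nn, 0.5, 1), 0)
    rawr <- pmax(smr + rnorm(nn, 0, 0.5), 0)
    thr <- quantile(smr, 0.8)
    gap <- sample(c(3, 15), 1)
    got <- call_regions(smr, rawr, thr, mkr, gap = gap)
    want <- brute_regions(smr, rawr, thr, mkr, gap = gap)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$left_pos, want$left_pos)
      expect_equal(got$right_pos, want$right_pos)
      expect_equal(got$peak_pos, want$peak_pos)
    }
  }
})

test_that("a strong frequency shift produces a region containing the QTL", {
  # a large-effect QTL against a quiet genome: the divergent bulks differ
  # strongly at the QTL and the called region covers it (the multi-seed
  # power property is exercised in the acceptance suite)
  cfg <- sim_config(n_chromosomes = 5, markers_per_chromosome = 400,
                    founder_ld = list(ld_range_cM = 1.0),
                    n_plants_per_plot = 2000, n_sampled_per_plot = 96,
                    n_qtl = 2,
                    qtl_effect_law = list(dist = "fixed", values = c(10, -10)),
                    seed = 501)
  sim <- simulate_experiment(cfg)
  res <- suppressMessages(bsa_scan(sim$geno_true, sim$bulks$tall,
                                   sim$bulks$short))
  mk <- sim$geno_true$markers
  qi <- match(sim$truth$qtl$marker_id, mk$id)
  shift <- abs(sim$truth$qtl_freq_shift$gen1_tall -
                 sim$truth$qtl_freq_shift$gen1_short)
  expect_gt(mean(shift), 0.15)
  for (k in seq_along(qi)) {
    expect_true(any(res$regions$chrom == mk$chrom[qi[k]] &
                      res$regions$left_pos <= mk$pos[qi[k]] &
                      res$regions$right_pos >= mk$pos[qi[k]]))
  }
  # regions are within-chromosome, ordered, and sized consistently
  expect_true(all(res$regions$left_pos <= res$regions$peak_pos))
  expect_true(all(res$regions$peak_pos <= res$regions$right_pos))
  expect_equal(res$regions$length_kb,
               (res$regions$right_pos - res$regions$left_pos) / 1000)
})
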
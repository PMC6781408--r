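# forward simulator: founders, phenotypes, selection, mating, GBS observation

test_that("founder genotypes follow binomial sampling at the set frequency", {
  cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 20,
                    n_qtl = 2, seed = 1)
  m <- 20
  # degenerate frequency: all dosages 0
  g0 <- simulate_founders(cfg, n = 50, freqs = rep(0, m), seed = 1)
  expect_true(all(g0$dosage == 0))
  # freq 0.5, n = 10000: sample alt frequency within 3 binomial SE
  g <- simulate_founders(cfg, n = 10000, freqs = rep(0.5, m), seed = 2)
  phat <- mean(g$dosage[, 1]) / 2
  se <- sqrt(0.5 * 0.5 / (2 * 10000))
  expect_lt(abs(phat - 0.5), 3 * se)
  # HWE: genotype counts match p^2, 2pq, q^2 expectations loosely
  tab <- tabulate(g$dosage[, 2] + 1L, 3) / 10000
  expect_lt(max(abs(tab - c(0.25, 0.5, 0.25))), 0.02)
})

test_that("the default design plants 4 plots of 5000 (20,000 individuals)", {
  cfg <- sim_config(seed = 1)
  expect_equal(cfg$n_plots * cfg$n_plants_per_plot, 20000)
  g <- simulate_founders(cfg)
  expect_equal(nrow(g$dosage), 20000)
  # markers carry chromosome, 1-based position and genetic-map coordinate
  expect_true(all(c("chrom", "pos", "cM") %in% names(g$markers)))
  expect_true(all(g$markers$pos >= 1))
})

test_that("founder haplotypes carry LD that decays with map distance", {
  cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 400, seed = 4)
  g <- simulate_founders(cfg, n = 500)
  d <- g$dosage
  v <- apply(d, 2, var)
  idx <- seq(1, 350, by = 13)
  r_adj <- mean(sapply(idx, function(j)
    if (v[j] > 0 && v[j + 1] > 0) abs(cor(d[, j], d[, j + 1])) else NA),
    na.rm = TRUE)
  r_mid <- mean(sapply(idx, function(j)
    if (v[j] > 0 && v[j + 10] > 0) abs(cor(d[, j], d[, j + 10])) else NA),
    na.rm = TRUE)
  r_far <- mean(sapply(idx, function(j)
    if (v[j] > 0 && v[j + 401] > 0) abs(cor(d[, j], d[, j + 401])) else NA),
    na.rm = TRUE)  # other chromosome: no LD
  expect_gt(r_adj, 0.4)     # spacing 0.35 cM, range 1 cM
  expect_gt(r_adj, r_mid)   # monotone decay on average
  expect_lt(r_far, 0.15)
})

test_that("phenotypes realize the target heritability and fixed effects", {
  cfg1 <- sim_config(n_chromosomes = 1, markers_per_chromosome = 30,
                     n_qtl = 10, target_h2 = 1, plot_effects = c(0, 10),
                     n_plots = 2, seed = 5)
  g <- simulate_founders(cfg1, n = 400)
  qtl <- tailscan:::draw_qtl(cfg1, g$markers, 11)
  # h2 = 1: no noise, height is plot effect + genetic value
  ph <- simulate_phenotypes(g, qtl, cfg1, plot = "p1", seed = 12)
  expect_equal(cor(ph$height_cm, ph$genetic_value), 1)
  # plot effects (0, +10): plot means differ by ~10 given equal genetics
  ph2 <- simulate_phenotypes(g, qtl, cfg1,
                             plot = rep(c("p1", "p2"), each = 200), seed = 13)
  gap <- mean(ph2$height_cm[ph2$plot == "p2"] - ph2$genetic_value[ph2$plot == "p2"]) -
    mean(ph2$height_cm[ph2$plot == "p1"] - ph2$genetic_value[ph2$plot == "p1"])
  expect_equal(gap, 10)
  # target 0.75 at n = 10000: realized variance ratio in [0.70, 0.80]
  cfg2 <- sim_config(n_chromosomes = 1, markers_per_chromosome = 30,
                     n_qtl = 10, target_h2 = 0.75, plot_effects = c(0),
                     n_plots = 1, seed = 6)
  gl <- simulate_founders(cfg2, n = 10000)
  qtl2 <- tailscan:::draw_qtl(cfg2, gl$markers, 14)
  ph3 <- simulate_phenotypes(gl, qtl2, cfg2, plot = "p1", seed = 15)
  ratio <- var(ph3$genetic_value) /
    (var(ph3$genetic_value) + var(ph3$height_cm - ph3$genetic_value))
  expect_gt(ratio, 0.70)
  expect_lt(ratio, 0.80)
  # h2 = 0 with nonzero effects warns and drops genetic values
  cfg0 <- sim_config(n_chromosomes = 1, markers_per_chromosome = 30,
                     n_qtl = 10, target_h2 = 0, n_plots = 1,
                     plot_effects = c(0), seed = 7)
  expect_warning(ph0 <- simulate_phenotypes(g, qtl, cfg0, seed = 16),
                 "ignored")
  expect_true(all(ph0$genetic_value == 0))
})

test_that("truncation selection picks the phenotypic tail per plot", {
  ph <- data.frame(plant_id = paste0("p", 1:5), plot = "A",
                   height_cm = c(150, 160, 170, 180, 190))
  top <- truncation_select(ph, 0.2, "tall")
  expect_equal(top$selected_ids, "p5")
  expect_equal(top$thresholds$n_selected, 1)
  # fraction 1: everyone selected
  all_sel <- truncation_select(ph, 1, "tall")
  expect_setequal(all_sel$selected_ids, ph$plant_id)
  # short selection mirrors tall
  bottom <- truncation_select(ph, 0.2, "short")
  expect_equal(bottom$selected_ids, "p1")
  # ~5% of 5000 plants: 250 selected (continuous phenotypes, per plot)
  set.seed(31)
  big <- data.frame(plant_id = paste0("q", 1:5000), plot = "B",
                    height_cm = rnorm(5000, 180, 20))
  sel <- truncation_select(big, 0.05, "tall")
  expect_equal(length(sel$selected_ids), 250)
  expect_error(truncation_select(big[0, ], 0.05, "tall"), "empty")
  expect_error(truncation_select(big, 0, "tall"), "fraction")
})

test_that("random mating conserves allele frequencies and respects linkage", {
  # fixation: all parents homozygous alt -> all offspring dosage 2
  hap <- matrix(1L, 4, 3)
  g_fix <- toy_geno(matrix(2L, 4, 3), cM = c(0, 1, 2),
                    haplotypes = list(h1 = hap, h2 = hap))
  off <- random_mate(g_fix, 20, seed = 1)
  expect_true(all(off$dosage == 2L))
  # frequency conservation: parental alt freq ~0.6, mean offspring freq
  # over 50 seeds within 3 SE of the parental frequency
  cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 20,
                    n_qtl = 2, seed = 8)
  par <- simulate_founders(cfg, n = 40, freqs = rep(0.6, 20), seed = 3)
  p_par <- mean(par$dosage[, 1]) / 2
  offf <- sapply(1:50, function(s)
    mean(random_mate(par, 100, seed = s)$dosage[, 1]) / 2)
  se <- sqrt(p_par * (1 - p_par) / (2 * 100)) / sqrt(50)
  expect_lt(abs(mean(offf) - p_par), 3 * se)
  # complete linkage: markers 0 cM apart never recombine
  h1 <- cbind(rep(1L, 6), rep(1L, 6))
  h2 <- cbind(rep(0L, 6), rep(0L, 6))
  g_link <- toy_geno(h1 + h2, cM = c(5, 5),
                     haplotypes = list(h1 = h1, h2 = h2))
  off2 <- random_mate(g_link, 300, seed = 9)
  # every gamete is all-1 or all-0, so dosages at the two markers are equal
  expect_true(all(off2$dosage[, 1] == off2$dosage[, 2]))
  expect_error(random_mate(subset_genotypes(g_link, individuals = 1),
                           10, seed = 1), "2 parents")
})

test_that("GBS observation matches the depth-driven miscall model", {
  # mean_depth = 0: everything missing
  g <- toy_geno(matrix(1L, 30, 10))
  obs0 <- observe_gbs(g, 0, seed = 1)
  expect_true(all(is.na(obs0$dosage)))
  expect_error(observe_gbs(g, -1, seed = 1), ">= 0")
  # homozygotes observed correctly when covered
  ghom <- toy_geno(matrix(rep(c(0L, 2L), each = 25), 50, 4))
  obs_h <- observe_gbs(ghom, 3, seed = 2)
  ok <- !is.na(obs_h$dosage)
  expect_true(all(obs_h$dosage[ok] == ghom$dosage[ok]))
  # heterozygote miscall fraction at depth ~2 matches the closed form
  # sum_d Pois(d; 2) 2^(1-d) / (1 - Pois(0; 2))
  ghet <- toy_geno(matrix(1L, 400, 300))
  obs <- observe_gbs(ghet, 2, seed = 3)
  called <- !is.na(obs$dosage)
  miscall <- mean(obs$dosage[called] != 1L)
  expected <- 2 * exp(-2) * (exp(1) - 1) / (1 - exp(-2))
  se <- sqrt(expected * (1 - expected) / sum(called))
  expect_lt(abs(miscall - expected), 3 * se)
  # read counts recorded per marker
  expect_equal(length(obs$markers$total_reads), 300)
  expect_gt(mean(obs$markers$total_reads), 0)
})

test_that("the experiment driver is seed-reproducible with full truth", {
  cfg <- sim_config(n_plants_per_plot = 300, n_sampled_per_plot = 40,
                    markers_per_chromosome = 30, n_chromosomes = 2,
                    n_qtl = 4, seed = 21)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$geno_obs$dosage, s2$geno_obs$dosage)
  expect_identical(s1$phenos$height_cm, s2$phenos$height_cm)
  cfg3 <- sim_config(n_plants_per_plot = 300, n_sampled_per_plot = 40,
                     markers_per_chromosome = 30, n_chromosomes = 2,
                     n_qtl = 4, seed = 22)
  s3 <- simulate_experiment(cfg3)
  expect_false(identical(s1$geno_obs$dosage, s3$geno_obs$dosage))
  # truth record is coherent
  expect_true(all(s1$truth$qtl$marker_id %in% s1$geno_true$markers$id))
  expect_equal(s1$truth$true_h2, 0.75, tolerance = 0.02)
  expect_equal(nrow(s1$phenos), 2 * 2 * 2 * 40)
  expect_equal(length(s1$bulks$tall), 40 * 1 * 2)  # gen-1 tall plots
})

test_that("tall selection raises +effect QTL allele frequencies", {
  shifts <- sapply(1:20, function(s) {
    cfg <- sim_config(n_plants_per_plot = 400, n_sampled_per_plot = 40,
                      markers_per_chromosome = 20, n_chromosomes = 2,
                      n_qtl = 4,
                      qtl_effect_law = list(dist = "normal", mean = 0, sd = 4),
                      seed = 100 + s)
    sim <- simulate_experiment(cfg)
    fs <- sim$truth$qtl_freq_shift
    sgn <- sign(sim$truth$qtl$effect_cm)
    mean(sgn * (fs$gen1_tall - fs$gen0))
  })
  expect_gt(mean(shifts), 0)
  expect_gt(mean(shifts > 0), 0.8)
})

test_that("with no selection Generation-1 frequencies match Generation-0", {
  cfg <- sim_config(n_plants_per_plot = 2000, n_plots = 1, n_qtl = 2,
                    markers_per_chromosome = 40, n_chromosomes = 1,
                    selection_fraction = 1, plot_effects = c(0), seed = 33)
  founders <- simulate_founders(cfg, n = 2000)
  off <- random_mate(founders, 2000, seed = 34)
  p0 <- colMeans(founders$dosage) / 2
  p1 <- colMeans(off$dosage) / 2
  se <- sqrt(pmax(p0 * (1 - p0), 1e-9) / (2 * 2000))
  # binomial sampling error bound at every marker (allow 4 SE genome-wide)
  expect_true(all(abs(p1 - p0) < 4 * se + 1e-9))
})
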
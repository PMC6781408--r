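# toy builders and independent brute-force oracles shared across tests

# GenotypeMatrix from a dosage matrix with evenly spaced markers
toy_geno <- function(dosage, chrom = NULL, pos = NULL, total_reads = NULL,
                     cM = NULL, diallelic = NULL, haplotypes = NULL,
                     imputed = FALSE) {
  m <- ncol(dosage)
  markers <- data.frame(
    id = sprintf("m%d", seq_len(m)),
    chrom = chrom %||% rep("chr1", m),
    pos = pos %||% seq_len(m) * 1e5,
    ref = rep("A", m), alt = rep("T", m), stringsAsFactors = FALSE)
  if (!is.null(total_reads)) markers$total_reads <- total_reads
  if (!is.null(cM)) markers$cM <- cM
  if (!is.null(diallelic)) markers$diallelic <- diallelic
  genotype_matrix(dosage, markers, haplotypes = haplotypes, imputed = imputed)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# dosage matrix with exact per-marker alt-allele counts (n individuals)
dosage_with_freq <- function(n, alt_freqs) {
  sapply(alt_freqs, function(f) {
    n_alt <- round(2 * n * f)
    d <- integer(n)
    d[seq_len(n_alt %/% 2)] <- 2L
    if (n_alt %% 2 == 1) d[n_alt %/% 2 + 1] <- 1L
    d
  })
}

# independent brute-force marker filter (the two published rules + diallelic)
brute_filter_ids <- function(g, min_maf = 0.05, min_reads = 40) {
  keep <- character(0)
  for (j in seq_len(ncol(g$dosage))) {
    d <- g$dosage[, j]
    d <- d[!is.na(d)]
    if (!length(d)) next
    p <- sum(d) / (2 * length(d))
    maf <- min(p, 1 - p)
    tr <- g$markers$total_reads[j]
    ok_reads <- is.na(tr) || tr >= min_reads
    if (g$markers$diallelic[j] && maf >= min_maf && ok_reads)
      keep <- c(keep, g$markers$id[j])
  }
  keep
}

# independent brute-force region finder: runs of smoothed > threshold per
# chromosome, gap-merged, raw-outlier membership required
brute_regions <- function(smoothed, raw, threshold, markers, gap = 15) {
  out <- list()
  for (ch in unique(markers$chrom)) {
    i <- which(markers$chrom == ch)
    runs <- list()
    cur <- c()
    for (k in i) {
      if (smoothed[k] > threshold) {
        cur <- c(cur, k)
      } else if (length(cur)) {
        runs[[length(runs) + 1]] <- cur
        cur <- c()
      }
    }
    if (length(cur)) runs[[length(runs) + 1]] <- cur
    if (!length(runs)) next
    merged <- list(runs[[1]])
    for (r in runs[-1]) {
      last <- merged[[length(merged)]]
      if (min(r) - max(last) - 1 < gap) {
        merged[[length(merged)]] <- c(last, r)
      } else merged[[length(merged) + 1]] <- r
    }
    for (r in merged) {
      idx <- min(r):max(r)
      if (!any(raw[idx] > threshold)) next
      peak <- idx[which(raw[idx] == max(raw[idx]))[1]]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, left_pos = markers$pos[min(idx)],
        right_pos = markers$pos[max(idx)], peak_pos = markers$pos[peak])
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), left_pos = numeric(0),
                      right_pos = numeric(0), peak_pos = numeric(0)))
  do.call(rbind, out)
}

# replicate truncation-selection experiments and return mean R/S estimate
breeders_replicates <- function(true_h2, n_plants, n_reps, seed,
                                fraction = 0.05) {
  est <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 60,
                      n_plants_per_plot = n_plants, n_plots = 1, n_qtl = 20,
                      qtl_effect_law = list(dist = "normal", mean = 0, sd = 3),
                      target_h2 = true_h2, plot_effects = c(0),
                      selection_fraction = fraction, seed = seed + r)
    founders <- simulate_founders(cfg, n = n_plants)
    qtl <- tailscan:::draw_qtl(cfg, founders$markers, seed + 1000 + r)
    ph0 <- simulate_phenotypes(founders, qtl, cfg, plot = "p1",
                               seed = seed + 2000 + r)
    sel <- truncation_select(ph0, fraction, "tall")
    parents <- subset_genotypes(founders, individuals = sel$selected_ids)
    off <- random_mate(parents, n_plants, seed + 3000 + r)
    ph1 <- simulate_phenotypes(off, qtl, cfg, plot = "p1", generation = 1L,
                               var_e = attr(ph0, "var_e"),
                               seed = seed + 4000 + r)
    # same plot-year effect for both generations in this harness
    S <- mean(ph0$height_cm[ph0$plant_id %in% sel$selected_ids]) -
      mean(ph0$height_cm)
    R <- (mean(ph1$height_cm) - cfg$plot_effects[1, 2]) -
      (mean(ph0$height_cm) - cfg$plot_effects[1, 1])
    est[r] <- realized_h2(S, R)$raw
  }
  mean(est)
}

# polygenic GREML recovery harness: trait built from all markers at a true
# heritability, estimated back from the GRM of the same genotypes
greml_recovery <- function(n, m, true_h2, seed) {
  cfg <- sim_config(n_chromosomes = 5, markers_per_chromosome = ceiling(m / 5),
                    founder_ld = NULL, seed = seed)
  g <- simulate_founders(cfg, n = n)
  D <- g$dosage[, apply(g$dosage, 2, stats::var) > 0, drop = FALSE]
  g <- toy_geno(D, imputed = TRUE)
  grm <- compute_grm(g)
  set.seed(seed + 1)
  Z <- scale(D)
  gval <- as.vector(Z %*% rnorm(ncol(Z), 0, sqrt(true_h2 / ncol(Z))))
  y <- gval + rnorm(n, 0, sqrt(1 - true_h2))
  greml_h2(grm, y)
}
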
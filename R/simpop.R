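#' Configuration for the divergent truncation-selection simulator
#'
#' Defines the simulated experiment: a heterogeneous random-mating founder
#' population planted in several plots, phenotyped for a quantitative trait
#' controlled by additive QTL at a target narrow-sense heritability, divergent
#' ~5% truncation selection (half the plots selected tall, half short), one
#' generation of open-pollinated random mating, and low-depth GBS-like
#' genotype observation of a 96-plant sample per plot.
#'
#' Defaults mirror the field design the toolkit targets: 4 plots of 5000
#' plants (20,000 total), 96 plants sampled per plot, a ~5% truncation
#' threshold per plot, and a mean sequencing depth of 2.01 reads per site.
#' Genome size (chromosome count and markers per chromosome) is a desk-scale
#' stand-in: enough linked markers that multi-megabase regions exist, small
#' enough to simulate quickly.
#'
#' @param n_chromosomes number of chromosomes.
#' @param markers_per_chromosome markers per chromosome (>= 15 so the 15-SNP
#'   smoothing window fits).
#' @param chromosome_length chromosome length in base pairs.
#' @param genetic_map_density cM per Mb (maize-like default 0.7).
#' @param founder_freq_law distribution of base alt-allele frequencies;
#'   `list(dist = "uniform", min, max)`.
#' @param founder_ld linkage disequilibrium of the founder haplotypes:
#'   `list(ld_range_cM)` generates each haplotype as a first-order Markov
#'   chain along the genetic map, with correlation exp(-d / ld_range_cM)
#'   between markers d cM apart. This reproduces the regime of dense
#'   reduced-representation marker data, where neighboring markers sit in
#'   strong LD and selection signal spans blocks of markers (without LD the
#'   signal would be confined to the causal markers themselves and no
#'   regions could exist). `NULL` draws founders in linkage equilibrium
#'   (useful for sampling-theory checks).
#' @param n_plants_per_plot plants grown per plot.
#' @param n_sampled_per_plot plants genotyped and phenotyped per plot.
#' @param n_plots number of plots; the first half are selected tall, the
#'   second half short.
#' @param n_qtl number of additive QTL.
#' @param qtl_effect_law distribution of additive effects in cm per alt
#'   allele; `list(dist = "normal", mean, sd)` or
#'   `list(dist = "fixed", values)` to plant known effects.
#' @param target_h2 target narrow-sense heritability in \[0, 1\].
#' @param plot_effects cm offsets per plot-year cell: a `n_plots` x 2 matrix
#'   (columns = generation 0, 1), or a length-`n_plots` vector used for both
#'   years. Default: modest spread of -6..6 cm re-drawn as fixed offsets.
#' @param selection_fraction truncated tail fraction in (0, 1].
#' @param mean_depth mean GBS read depth per individual-site.
#' @param baseline_cm intercept of the trait in cm.
#' @param round_to_5cm round simulated heights to 5-cm increments, mimicking
#'   field measurement.
#' @param seed master seed; all per-stage seeds are derived from it.
#' @return object of class `SimConfig` (a validated list).
#' @export
sim_config <- function(n_chromosomes = 5,
                       markers_per_chromosome = 400,
                       chromosome_length = 2e8,
                       genetic_map_density = 0.7,
                       founder_freq_law = list(dist = "uniform",
                                               min = 0.05, max = 0.95),
                       founder_ld = list(ld_range_cM = 1),
                       n_plants_per_plot = 5000,
                       n_sampled_per_plot = 96,
                       n_plots = 4,
                       n_qtl = 40,
                       qtl_effect_law = list(dist = "normal",
                                             mean = 0, sd = 2),
                       target_h2 = 0.75,
                       plot_effects = NULL,
                       selection_fraction = 0.05,
                       mean_depth = 2.01,
                       baseline_cm = 180,
                       round_to_5cm = FALSE,
                       seed = 1) {
  cfg <- list(n_chromosomes = n_chromosomes,
              markers_per_chromosome = markers_per_chromosome,
              chromosome_length = chromosome_length,
              genetic_map_density = genetic_map_density,
              founder_freq_law = founder_freq_law,
              founder_ld = founder_ld,
              n_plants_per_plot = n_plants_per_plot,
              n_sampled_per_plot = n_sampled_per_plot,
              n_plots = n_plots,
              n_qtl = n_qtl,
              qtl_effect_law = qtl_effect_law,
              target_h2 = target_h2,
              plot_effects = plot_effects,
              selection_fraction = selection_fraction,
              mean_depth = mean_depth,
              baseline_cm = baseline_cm,
              round_to_5cm = round_to_5cm,
              seed = seed)
  counts <- c("n_chromosomes", "markers_per_chromosome", "chromosome_length",
              "n_plants_per_plot", "n_sampled_per_plot", "n_plots", "n_qtl")
  for (nm in counts)
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] < 1)
      stop("'", nm, "' must be a positive count")
  if (markers_per_chromosome < 15)
    stop("markers_per_chromosome must be >= 15 (smoothing window must fit)")
  if (!is.numeric(selection_fraction) || selection_fraction <= 0 ||
      selection_fraction > 1)
    stop("selection_fraction must be in (0, 1]")
  if (!is.numeric(target_h2) || target_h2 < 0 || target_h2 > 1)
    stop("target_h2 must be in [0, 1]")
  if (mean_depth < 0) stop("mean_depth must be >= 0")
  if (n_sampled_per_plot > n_plants_per_plot)
    stop("cannot sample more plants than are planted")
  if (!is.list(founder_freq_law) ||
      !identical(founder_freq_law$dist, "uniform") ||
      is.null(founder_freq_law$min) || is.null(founder_freq_law$max) ||
      founder_freq_law$min < 0 || founder_freq_law$max > 1 ||
      founder_freq_law$min > founder_freq_law$max)
    stop("founder_freq_law must be list(dist = 'uniform', min, max) with ",
         "0 <= min <= max <= 1")
  if (!is.list(qtl_effect_law) ||
      !(identical(qtl_effect_law$dist, "normal") ||
        identical(qtl_effect_law$dist, "fixed")))
    stop("qtl_effect_law must be list(dist = 'normal', mean, sd) or ",
         "list(dist = 'fixed', values)")
  if (identical(qtl_effect_law$dist, "normal") &&
      (is.null(qtl_effect_law$sd) || qtl_effect_law$sd < 0))
    stop("normal qtl_effect_law needs sd >= 0")
  if (identical(qtl_effect_law$dist, "fixed") &&
      length(qtl_effect_law$values) != n_qtl)
    stop("fixed qtl_effect_law needs exactly n_qtl values")
  if (n_qtl > n_chromosomes * markers_per_chromosome)
    stop("n_qtl exceeds the number of markers")
  if (!is.null(founder_ld) &&
      (is.null(founder_ld$ld_range_cM) || founder_ld$ld_range_cM <= 0))
    stop("founder_ld must be NULL or list(ld_range_cM > 0)")
  if (is.null(plot_effects)) {
    plot_effects <- matrix(rep(seq(-6, 6, length.out = n_plots), 2),
                           nrow = n_plots)
  } else if (is.matrix(plot_effects)) {
    if (!all(dim(plot_effects) == c(n_plots, 2)))
      stop("plot_effects matrix must be n_plots x 2")
  } else {
    if (length(plot_effects) != n_plots)
      stop("plot_effects vector must have length n_plots")
    plot_effects <- matrix(rep(plot_effects, 2), nrow = n_plots)
  }
  cfg$plot_effects <- plot_effects
  class(cfg) <- "SimConfig"
  cfg
}

# marker map shared by all simulated individuals: evenly spaced positions,
# genetic coordinate = pos/1e6 * density (cM)
sim_marker_map <- function(config) {
  m_per <- config$markers_per_chromosome
  pos <- round(seq(1, config$chromosome_length, length.out = m_per))
  markers <- data.frame(
    id = paste0("chr", rep(seq_len(config$n_chromosomes), each = m_per),
                "_", rep(pos, config$n_chromosomes)),
    chrom = paste0("chr", rep(seq_len(config$n_chromosomes), each = m_per)),
    pos = rep(pos, config$n_chromosomes),
    ref = "A", alt = "T",
    stringsAsFactors = FALSE)
  markers$cM <- markers$pos / 1e6 * config$genetic_map_density
  markers
}

#' Simulate a random-mating founder population
#'
#' Draws a base alt-allele frequency per marker from the configured founder
#' law and samples phased haplotypes per individual, giving Hardy-Weinberg
#' genotypes in a random-mating population: dosage at marker j is
#' Binomial(2, freq_j) given the realized founder frequency. With the
#' default `founder_ld`, each haplotype is a first-order Markov chain along
#' the genetic map (allele correlation exp(-d / ld_range_cM) at distance d
#' cM, independent across chromosomes), so markers in linkage carry
#' landrace-like LD blocks; with `founder_ld = NULL`, haplotypes are drawn
#' independently per marker (linkage equilibrium). Markers carry
#' chromosome, 1-based position and a genetic-map coordinate.
#'
#' @param config a [sim_config()] object.
#' @param n number of individuals; default `n_plots * n_plants_per_plot`.
#' @param freqs optional vector of founder frequencies (one per marker)
#'   overriding the frequency law; haplotypes are then drawn in linkage
#'   equilibrium at exactly those frequencies (used for degenerate and
#'   sampling-theory checks).
#' @param seed RNG seed; default derived from `config$seed`.
#' @return `GenotypeMatrix` with phased haplotypes attached and realized
#'   founder frequencies in `attr(, "founder_freqs")`.
#' @export
simulate_founders <- function(config, n = NULL, freqs = NULL, seed = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  n <- n %||% (config$n_plots * config$n_plants_per_plot)
  seed <- seed %||% derive_seeds(config$seed, 1L)
  markers <- sim_marker_map(config)
  m <- nrow(markers)
  freqs_given <- !is.null(freqs)
  if (is.null(freqs)) {
    law <- config$founder_freq_law
    freqs <- with_seed(seed, stats::runif(m, law$min, law$max))
  } else {
    if (length(freqs) != m) stop("freqs must have one entry per marker")
    if (any(freqs < 0 | freqs > 1)) stop("founder frequencies must be in [0, 1]")
  }
  ld <- config$founder_ld
  if (freqs_given) ld <- NULL
  if (is.null(ld)) {
    haps <- with_seed(seed + 1L, {
      h1 <- matrix(stats::rbinom(n * m, 1L, rep(freqs, each = n)), nrow = n)
      h2 <- matrix(stats::rbinom(n * m, 1L, rep(freqs, each = n)), nrow = n)
      list(h1 = h1, h2 = h2)
    })
  } else {
    haps <- with_seed(seed + 1L, {
      list(h1 = markov_haplotypes(freqs, n, markers, ld$ld_range_cM),
           h2 = markov_haplotypes(freqs, n, markers, ld$ld_range_cM))
    })
  }
  dos <- haps$h1 + haps$h2
  rownames(dos) <- sprintf("plant_%05d", seq_len(n))
  g <- genotype_matrix(dos, markers, haplotypes = haps)
  attr(g, "founder_freqs") <- colMeans(dos) / 2
  g
}

# n haplotypes as first-order Markov chains along the genetic map: marker
# margins follow `freqs` (up to clamping) and the allele correlation between
# markers d cM apart is exp(-d / ld_range); chromosomes are independent
markov_haplotypes <- function(freqs, n, markers, ld_range) {
  m <- length(freqs)
  rho <- exp(-diff(markers$cM) / ld_range)
  rho[markers$chrom[-1] != markers$chrom[-m]] <- 0
  out <- matrix(0L, n, m)
  cur <- stats::rbinom(n, 1L, freqs[1L])
  out[, 1L] <- cur
  if (m > 1L) {
    for (j in 2:m) {
      f0 <- freqs[j - 1L]; f1 <- freqs[j]
      slope <- rho[j - 1L] * sqrt(f1 * (1 - f1) / max(f0 * (1 - f0), 1e-12))
      p <- pmin(pmax(f1 + slope * (cur - f0), 0), 1)
      cur <- as.integer(stats::runif(n) < p)
      out[, j] <- cur
    }
  }
  out
}

# draw QTL markers and additive effects for a simulated genome
draw_qtl <- function(config, markers, seed) {
  with_seed(seed, {
    idx <- sort(sample.int(nrow(markers), config$n_qtl))
    law <- config$qtl_effect_law
    effects <- if (identical(law$dist, "fixed")) law$values
               else stats::rnorm(config$n_qtl, law$mean %||% 0, law$sd)
    data.frame(marker_id = markers$id[idx], index = idx, effect_cm = effects,
               stringsAsFactors = FALSE)
  })
}

#' Simulate single-plant phenotypes from additive QTL
#'
#' height = baseline + plot-year effect + sum of dosage x QTL effect +
#' Gaussian noise. The environmental variance is solved so that
#' Var(G) / (Var(G) + Var(E)) equals `config$target_h2` in the simulated
#' individuals; with `target_h2 = 1` there is no noise, and with
#' `target_h2 = 0` genetic values are ignored in the variance scaling
#' (a warning is raised if QTL effects are nonzero).
#'
#' @param geno `GenotypeMatrix` of the individuals to phenotype.
#' @param qtl data.frame with `marker_id` and `effect_cm` (a truth record's
#'   QTL table, e.g. from the simulator driver).
#' @param config a [sim_config()] object.
#' @param plot plot label per individual (recycled if length 1).
#' @param generation generation label (0 or 1) per individual or scalar.
#' @param regime selection regime label ("tall"/"short") per individual or
#'   scalar.
#' @param var_e optional fixed environmental variance (cm^2). Use to carry
#'   the Generation-0 noise variance into later generations, where selection
#'   has changed the genetic variance; by default the variance is re-solved
#'   from the genetic values of `geno`.
#' @param seed RNG seed for the noise draw.
#' @return data.frame (a phenotype table): `plant_id`, `plot`, `year`,
#'   `generation`, `regime`, `height_cm`, plus the latent `genetic_value`
#'   used by truth checks. `attr(, "var_e")` records the solved noise
#'   variance.
#' @export
simulate_phenotypes <- function(geno, qtl, config, plot = "plot1",
                                generation = 0L, regime = "tall",
                                var_e = NULL, seed = NULL) {
  stopifnot(inherits(geno, "GenotypeMatrix"), inherits(config, "SimConfig"))
  seed <- seed %||% derive_seeds(config$seed, 2L)[1L]
  n <- nrow(geno$dosage)
  idx <- match(qtl$marker_id, geno$markers$id)
  if (anyNA(idx)) stop("QTL marker id(s) absent from genotype matrix")
  gvalue <- as.vector(geno$dosage[, idx, drop = FALSE] %*% qtl$effect_cm)
  var_g <- stats::var(gvalue)
  h2 <- config$target_h2
  if (!is.null(var_e)) {
    stopifnot(is.numeric(var_e), var_e >= 0)
  } else if (h2 == 0) {
    if (any(qtl$effect_cm != 0))
      warning("target_h2 = 0 with nonzero QTL effects: genetic values are ",
              "ignored in variance scaling")
    var_e <- if (var_g > 0) var_g else 1
    gvalue <- gvalue * 0
  } else if (h2 == 1) {
    var_e <- 0
  } else {
    var_e <- var_g * (1 - h2) / h2
    if (var_g == 0) var_e <- 1  # pure-noise trait when no genetic variance
  }
  plot <- rep_len(as.character(plot), n)
  generation <- rep_len(as.integer(generation), n)
  regime <- rep_len(as.character(regime), n)
  pe <- config$plot_effects
  plot_levels <- unique(plot)
  plot_idx <- match(plot, plot_levels)
  # plot-year effect: row by plot (modulo configured plots), column by gen
  pe_row <- ((plot_idx - 1L) %% nrow(pe)) + 1L
  plot_eff <- pe[cbind(pe_row, generation + 1L)]
  noise <- with_seed(seed, stats::rnorm(n, 0, sqrt(var_e)))
  height <- config$baseline_cm + plot_eff + gvalue + noise
  if (config$round_to_5cm) height <- round(height / 5) * 5
  out <- data.frame(plant_id = individual_ids(geno),
                    plot = plot,
                    year = ifelse(generation == 0L, "year1", "year2"),
                    generation = generation,
                    regime = regime,
                    height_cm = height,
                    genetic_value = gvalue,
                    stringsAsFactors = FALSE)
  attr(out, "var_e") <- var_e
  out
}

#' Truncation selection within a plot
#'
#' Identifies the empirical truncation threshold of a phenotype vector and
#' the plants beyond it. For tall selection the threshold is the
#' (1 - fraction) quantile and plants with height >= threshold are selected;
#' for short selection the fraction quantile and height <= threshold.
#' Inclusive comparison is the documented tie rule: with `fraction = 1` the
#' threshold is the extreme value of the sample and every plant is selected.
#'
#' @param phenos phenotype table (needs `plant_id`, `plot`, `height_cm`).
#' @param fraction selected tail fraction in (0, 1].
#' @param direction `"tall"` or `"short"`.
#' @return list with `selected_ids` (character), and `thresholds`
#'   (data.frame: `plot`, `direction`, `threshold_cm`, `n_selected`).
#' @export
truncation_select <- function(phenos, fraction, direction = c("tall", "short")) {
  direction <- match.arg(direction)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  if (nrow(phenos) == 0) stop("empty phenotype table")
  sel <- character(0)
  th <- lapply(split(phenos, phenos$plot), function(pp) {
    if (nrow(pp) == 0) stop("empty plot")
    if (direction == "tall") {
      cut <- stats::quantile(pp$height_cm, 1 - fraction, names = FALSE,
                             type = 7)
      keep <- pp$plant_id[pp$height_cm >= cut]
    } else {
      cut <- stats::quantile(pp$height_cm, fraction, names = FALSE, type = 7)
      keep <- pp$plant_id[pp$height_cm <= cut]
    }
    sel <<- c(sel, keep)
    data.frame(plot = pp$plot[1], direction = direction, threshold_cm = cut,
               n_selected = length(keep), stringsAsFactors = FALSE)
  })
  list(selected_ids = sel, thresholds = do.call(rbind, c(th, make.row.names = FALSE)))
}

# one gamete per row of parent_idx: meiosis with recombination between
# adjacent markers (Haldane map function); free recombination across
# chromosome boundaries
make_gametes <- function(h1, h2, parent_idx, markers) {
  n <- length(parent_idx)
  m <- nrow(markers)
  d_cM <- diff(markers$cM)
  r <- 0.5 * (1 - exp(-2 * d_cM / 100))
  r[markers$chrom[-1] != markers$chrom[-m]] <- 0.5
  choice <- matrix(0L, n, m)
  choice[, 1L] <- stats::rbinom(n, 1L, 0.5)
  if (m > 1L) {
    cross <- matrix(stats::runif(n * (m - 1L)), nrow = n) <
      matrix(r, nrow = n, ncol = m - 1L, byrow = TRUE)
    for (j in 2:m)
      choice[, j] <- (choice[, j - 1L] + cross[, j - 1L]) %% 2L
  }
  gam <- h1[parent_idx, , drop = FALSE]
  other <- h2[parent_idx, , drop = FALSE]
  pick <- choice == 1L
  gam[pick] <- other[pick]
  gam
}

#' Random mating among selected parents
#'
#' Each offspring draws two parents uniformly with replacement (selfing
#' allowed, as under open pollination) and receives one recombinant gamete
#' from each. Recombination between adjacent markers follows the Haldane map
#' function on the genetic-map distance; markers on different chromosomes
#' assort independently. The expected offspring allele frequency equals the
#' selected-parent frequency.
#'
#' @param selected `GenotypeMatrix` of the parents; must carry phased
#'   haplotypes (simulated genotypes do).
#' @param n_offspring number of offspring to produce.
#' @param seed RNG seed.
#' @param id_prefix prefix for offspring ids.
#' @return `GenotypeMatrix` of the offspring, with haplotypes.
#' @export
random_mate <- function(selected, n_offspring, seed, id_prefix = "off") {
  stopifnot(inherits(selected, "GenotypeMatrix"))
  if (is.null(selected$haplotypes))
    stop("random_mate needs phased haplotypes (simulated genotypes carry them)")
  n_par <- nrow(selected$dosage)
  if (n_par < 2) stop("need at least 2 parents")
  with_seed(seed, {
    p1 <- sample.int(n_par, n_offspring, replace = TRUE)
    p2 <- sample.int(n_par, n_offspring, replace = TRUE)
    h1 <- make_gametes(selected$haplotypes$h1, selected$haplotypes$h2, p1,
                       selected$markers)
    h2 <- make_gametes(selected$haplotypes$h1, selected$haplotypes$h2, p2,
                       selected$markers)
    dos <- h1 + h2
    rownames(dos) <- sprintf("%s_%05d", id_prefix, seq_len(n_offspring))
    genotype_matrix(dos, selected$markers, haplotypes = list(h1 = h1, h2 = h2))
  })
}

#' Observe genotypes through low-depth GBS-like sequencing
#'
#' Per individual-site read depth is Poisson(`mean_depth`). Sites with zero
#' reads are missing. Homozygotes are always called correctly when covered;
#' a heterozygote is miscalled as a homozygote when all sampled reads carry
#' the same allele, which happens with probability 2^(1 - d) at depth d > 0
#' (split equally between the two homozygous calls). Sequencing error is not
#' modeled. Per-marker total read counts (summed over individuals) are
#' recorded in the marker table for read-count filtering.
#'
#' @param geno true `GenotypeMatrix`.
#' @param mean_depth mean reads per individual-site (>= 0).
#' @param seed RNG seed.
#' @return observed `GenotypeMatrix` (haplotypes dropped, `total_reads`
#'   filled in).
#' @export
observe_gbs <- function(geno, mean_depth, seed) {
  stopifnot(inherits(geno, "GenotypeMatrix"))
  if (mean_depth < 0) stop("mean_depth must be >= 0")
  d <- geno$dosage
  n <- nrow(d); m <- ncol(d)
  with_seed(seed, {
    depth <- matrix(stats::rpois(n * m, mean_depth), n, m)
    obs <- d
    obs[depth == 0L] <- NA_integer_
    het <- which(d == 1L & depth > 0L)
    if (length(het)) {
      dh <- depth[het]
      u <- stats::runif(length(het))
      p_hom <- 0.5^dh                       # all reads ref / all reads alt
      obs[het] <- ifelse(u < p_hom, 0L, ifelse(u < 2 * p_hom, 2L, 1L))
    }
    markers <- geno$markers
    markers$total_reads <- colSums(depth)
    out <- genotype_matrix(obs, markers)
    out
  })
}

#' Simulate the full divergent-selection experiment
#'
#' Drives the whole design: founders split into plots, Generation-0
#' phenotypes, per-plot ~5% truncation selection (first half of the plots
#' tall, second half short), random mating to Generation-1 within each plot,
#' Generation-1 phenotypes, random sampling of `n_sampled_per_plot` plants
#' per plot-generation, and GBS-like observation of the sampled plants.
#'
#' @param config a [sim_config()] object.
#' @return list with:
#'   * `geno_obs`: observed (GBS) `GenotypeMatrix` of all sampled plants,
#'   * `geno_true`: true genotypes of the sampled plants,
#'   * `phenos`: phenotype table of the sampled plants,
#'   * `phenos_all`: phenotype table of every simulated plant,
#'   * `bulks`: list `tall` / `short` of sampled Generation-1 plant ids,
#'   * `truth`: ground-truth record (`qtl`, `true_h2`, `var_e`,
#'     `thresholds`, `selected_ids`, `founder_freqs`, per-regime expected
#'     frequency shifts `qtl_freq_shift`).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  seeds <- derive_seeds(config$seed, 8L)
  founders <- simulate_founders(config, seed = seeds[1L])
  markers <- founders$markers
  qtl <- draw_qtl(config, markers, seeds[2L])

  n_pp <- config$n_plants_per_plot
  n_plots <- config$n_plots
  plot_labels <- paste0("plot", seq_len(n_plots))
  regimes <- rep(c("tall", "short"), each = ceiling(n_plots / 2))[seq_len(n_plots)]
  plot_of <- rep(plot_labels, each = n_pp)
  regime_of <- rep(regimes, each = n_pp)

  ph0 <- simulate_phenotypes(founders, qtl, config, plot = plot_of,
                             generation = 0L, regime = regime_of,
                             seed = seeds[3L])
  # per-plot truncation in the plot's own direction
  sel_ids <- character(0)
  thresholds <- list()
  for (k in seq_len(n_plots)) {
    pp <- ph0[ph0$plot == plot_labels[k], , drop = FALSE]
    ts <- truncation_select(pp, config$selection_fraction, regimes[k])
    sel_ids <- c(sel_ids, ts$selected_ids)
    thresholds[[k]] <- ts$thresholds
  }
  thresholds <- do.call(rbind, c(thresholds, make.row.names = FALSE))

  # mate within plot, grow Generation-1 plots of the same size
  gen1 <- vector("list", n_plots)
  mate_seeds <- derive_seeds(seeds[4L], n_plots)
  for (k in seq_len(n_plots)) {
    pp <- ph0[ph0$plot == plot_labels[k], , drop = FALSE]
    par_ids <- intersect(sel_ids, pp$plant_id)
    parents <- subset_genotypes(founders, individuals = par_ids)
    gen1[[k]] <- random_mate(parents, n_pp, mate_seeds[k],
                             id_prefix = paste0("g1", plot_labels[k]))
  }
  g1_dos <- do.call(rbind, lapply(gen1, function(g) g$dosage))
  g1_h1 <- do.call(rbind, lapply(gen1, function(g) g$haplotypes$h1))
  g1_h2 <- do.call(rbind, lapply(gen1, function(g) g$haplotypes$h2))
  geno1 <- genotype_matrix(g1_dos, markers,
                           haplotypes = list(h1 = g1_h1, h2 = g1_h2))
  ph1 <- simulate_phenotypes(geno1, qtl, config, plot = plot_of,
                             generation = 1L, regime = regime_of,
                             var_e = attr(ph0, "var_e"), seed = seeds[5L])

  # sample n_sampled_per_plot per plot-generation for genotyping/phenotyping
  samp_seeds <- derive_seeds(seeds[6L], 2L * n_plots)
  sampled0 <- sampled1 <- character(0)
  for (k in seq_len(n_plots)) {
    ids0 <- ph0$plant_id[ph0$plot == plot_labels[k]]
    ids1 <- ph1$plant_id[ph1$plot == plot_labels[k]]
    sampled0 <- c(sampled0, with_seed(samp_seeds[k],
      sample(ids0, config$n_sampled_per_plot)))
    sampled1 <- c(sampled1, with_seed(samp_seeds[n_plots + k],
      sample(ids1, config$n_sampled_per_plot)))
  }
  g_true0 <- subset_genotypes(founders, individuals = sampled0)
  g_true1 <- subset_genotypes(geno1, individuals = sampled1)
  true_dos <- rbind(g_true0$dosage, g_true1$dosage)
  geno_true <- genotype_matrix(true_dos, markers)
  geno_obs <- observe_gbs(geno_true, config$mean_depth, seeds[7L])

  phenos <- rbind(ph0[match(sampled0, ph0$plant_id), , drop = FALSE],
                  ph1[match(sampled1, ph1$plant_id), , drop = FALSE])
  rownames(phenos) <- NULL
  phenos_all <- rbind(ph0, ph1)
  rownames(phenos_all) <- NULL

  bulk_tall <- phenos$plant_id[phenos$generation == 1L &
                                 phenos$regime == "tall"]
  bulk_short <- phenos$plant_id[phenos$generation == 1L &
                                  phenos$regime == "short"]

  # realized h2 in the founder generation (variance-ratio truth)
  var_g <- stats::var(ph0$genetic_value)
  true_h2 <- if (var_g + attr(ph0, "var_e") > 0)
    var_g / (var_g + attr(ph0, "var_e")) else 0
  qidx <- match(qtl$marker_id, markers$id)
  f0 <- colMeans(founders$dosage[, qidx, drop = FALSE]) / 2
  f1t <- colMeans(geno1$dosage[regime_of == "tall", qidx, drop = FALSE]) / 2
  f1s <- colMeans(geno1$dosage[regime_of == "short", qidx, drop = FALSE]) / 2
  truth <- list(qtl = qtl,
                true_h2 = true_h2,
                var_e = attr(ph0, "var_e"),
                thresholds = thresholds,
                selected_ids = sel_ids,
                founder_freqs = attr(founders, "founder_freqs"),
                qtl_freq_shift = data.frame(marker_id = qtl$marker_id,
                                            gen0 = f0, gen1_tall = f1t,
                                            gen1_short = f1s,
                                            row.names = NULL))
  list(geno_obs = geno_obs, geno_true = geno_true, phenos = phenos,
       phenos_all = phenos_all,
       bulks = list(tall = bulk_tall, short = bulk_short),
       truth = truth)
}
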
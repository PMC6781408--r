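#' Pipeline run configuration
#'
#' Bundles every stage's settings and the master seed. All thresholds default
#' to the field-standard values: MAF 0.05, read count 40, GWAS alpha 1e-5,
#' BSA outlier fraction 0.005, 15-SNP smoothing window, 150 kb annotation
#' window, 5% truncation.
#'
#' @param mode `"simulate"` (run the forward simulator) or `"real-data"`
#'   (read genotypes/phenotypes/bulks from files).
#' @param out_dir output directory (created if absent).
#' @param sim a [sim_config()] (simulate mode).
#' @param gwas a [gwas_config()].
#' @param seed master seed; overrides `sim$seed` in simulate mode.
#' @param min_maf,min_reads marker filter thresholds.
#' @param bsa_q,bsa_window,bsa_gap BSA outlier fraction, smoothing window
#'   and region merge gap.
#' @param overlap_window candidate-gene window in bp.
#' @param vcf_path,pheno_path,bulk_path,gff_path input files (real-data
#'   mode; `gff_path` optional in both modes).
#' @param greml_covariates include generation/regime covariates in the
#'   GREML model.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(mode = c("simulate", "real-data"),
                       out_dir = tempfile("tailscan_run_"),
                       sim = sim_config(),
                       gwas = gwas_config(),
                       seed = 1,
                       min_maf = 0.05, min_reads = 40,
                       bsa_q = 0.005, bsa_window = 15, bsa_gap = 15,
                       overlap_window = 150000,
                       vcf_path = NULL, pheno_path = NULL,
                       bulk_path = NULL, gff_path = NULL,
                       greml_covariates = TRUE) {
  mode <- match.arg(mode)
  if (mode == "real-data") {
    for (p in c(vcf_path, pheno_path, bulk_path))
      if (is.null(p) || !file.exists(p))
        stop("real-data mode needs existing vcf_path, pheno_path and ",
             "bulk_path; missing: ", if (is.null(p)) "(unset)" else p)
  }
  sim$seed <- seed
  structure(list(mode = mode, out_dir = out_dir, sim = sim, gwas = gwas,
                 seed = seed, min_maf = min_maf, min_reads = min_reads,
                 bsa_q = bsa_q, bsa_window = bsa_window, bsa_gap = bsa_gap,
                 overlap_window = overlap_window, vcf_path = vcf_path,
                 pheno_path = pheno_path, bulk_path = bulk_path,
                 gff_path = gff_path, greml_covariates = greml_covariates),
            class = "RunConfig")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full mapping pipeline
#'
#' simulate (or load) -> filter -> standardize -> heritability -> GWAS ->
#' BSA -> overlap. Every stage writes a TSV under `cfg$out_dir`, a
#' `summary.json` collects the headline numbers, `config.yaml` echoes the
#' configuration, and `log.txt` records stage timings. The same
#' configuration and seed reproduce byte-identical numerical outputs.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) list with `summary`, `scan`, `significant`, `bsa`,
#'   `overlap`, `h2`, `describe`, `out_dir`, plus `truth` in simulate mode.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "log.txt")
  cat("", file = logf)
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    cat(sprintf("%-14s %8.2fs\n", name, proc.time()[["elapsed"]] - s),
        file = logf, append = TRUE)
    out
  }

  truth <- NULL
  if (cfg$mode == "simulate") {
    sim <- stage("simulate", simulate_experiment(cfg$sim))
    geno_raw <- sim$geno_obs
    phenos <- sim$phenos
    bulks <- sim$bulks
    truth <- sim$truth
    stage("write-inputs", {
      write_vcf(geno_raw, file.path(cfg$out_dir, "genotypes.vcf"))
      write_tsv(phenos[, c("plant_id", "plot", "year", "generation",
                           "regime", "height_cm")],
                file.path(cfg$out_dir, "phenotypes.tsv"))
      write_tsv(data.frame(plant_id = c(bulks$tall, bulks$short),
                           bulk = rep(c("tall", "short"),
                                      c(length(bulks$tall),
                                        length(bulks$short)))),
                file.path(cfg$out_dir, "bulks.tsv"))
      write_tsv(truth$qtl, file.path(cfg$out_dir, "truth_qtl.tsv"))
      write_tsv(truth$thresholds,
                file.path(cfg$out_dir, "truth_thresholds.tsv"))
    })
  } else {
    geno_raw <- stage("read-vcf", read_vcf(cfg$vcf_path))
    phenos <- stage("read-phenotypes", read_phenotypes(cfg$pheno_path))
    bt <- utils::read.delim(cfg$bulk_path, stringsAsFactors = FALSE)
    bulks <- list(tall = bt$plant_id[bt$bulk == "tall"],
                  short = bt$plant_id[bt$bulk == "short"])
  }
  n_initial <- ncol(geno_raw$dosage)

  geno_filt <- stage("filter", filter_markers(geno_raw, cfg$min_maf,
                                              cfg$min_reads))
  n_filtered <- ncol(geno_filt$dosage)

  phenos <- stage("standardize", standardize_phenotypes(phenos))
  desc <- describe_phenotypes(phenos)
  write_tsv(desc, file.path(cfg$out_dir, "descriptives.tsv"))

  # genotyped plants and phenotypes in matched order
  common <- intersect(individual_ids(geno_filt), phenos$plant_id)
  geno_filt <- subset_genotypes(geno_filt, individuals = common)
  phenos <- phenos[match(common, phenos$plant_id), , drop = FALSE]

  geno_imp <- stage("impute", impute_missing(geno_filt))
  grm <- stage("grm", compute_grm(geno_imp))
  write_grm(grm, file.path(cfg$out_dir, "grm.tsv"))

  covars <- scan_covariates(phenos)
  h2g <- stage("greml", greml_h2(grm, phenos$residual,
                                 covariates = if (cfg$greml_covariates)
                                   covars else NULL))
  h2r <- NULL
  if (!is.null(truth)) {
    # breeder's-equation h2 from the simulated selection response, averaged
    # over plots on the standardized scale
    ph <- phenos
    rs <- lapply(unique(ph$plot), function(pl) {
      g0 <- ph$height_cm[ph$plot == pl & ph$generation == 0]
      g1 <- ph$height_cm[ph$plot == pl & ph$generation == 1]
      thr <- truth$thresholds[truth$thresholds$plot == pl, ]
      sel <- if (thr$direction == "tall") g0[g0 >= thr$threshold_cm]
             else g0[g0 <= thr$threshold_cm]
      if (!length(sel)) return(NULL)
      # orient by selection direction so divergent plots average coherently
      sgn <- if (thr$direction == "tall") 1 else -1
      c(S = sgn * (mean(sel) - mean(g0)), R = sgn * (mean(g1) - mean(g0)))
    })
    rs <- do.call(rbind, rs)
    if (!is.null(rs) && abs(sum(rs[, "S"])) > 0)
      h2r <- realized_h2(mean(rs[, "S"]), mean(rs[, "R"]))
  }

  gw <- stage("gwas", pseudo_qtn_scan(geno_imp, phenos$residual,
                                      covariates = covars, cfg = cfg$gwas))
  scan <- gw$scan
  write_tsv(scan[, c("chrom", "pos", "effect", "se", "p_value",
                     "neg_log10_p", "significant")],
            file.path(cfg$out_dir, "gwas_scan.tsv"))
  sig <- call_significant(scan, cfg$gwas$alpha)
  write_tsv(sig[, c("chrom", "pos", "effect", "se", "p_value")],
            file.path(cfg$out_dir, "gwas_significant.tsv"))
  qq <- qq_data(scan)

  bsa <- stage("bsa", bsa_scan(geno_filt, bulks$tall, bulks$short,
                               q = cfg$bsa_q, window = cfg$bsa_window,
                               gap = cfg$bsa_gap))
  write_tsv(bsa$scan, file.path(cfg$out_dir, "bsa_scan.tsv"))
  regions_out <- bsa$regions
  names(regions_out) <- c("Chr", "Left_Position", "Right_Position",
                          "Length_kb", "Most_significant_SNP", "P_value",
                          "n_markers", "n_significant")[seq_along(regions_out)]
  write_tsv(regions_out, file.path(cfg$out_dir, "bsa_regions.tsv"))

  ov <- stage("overlap", overlap_snps_regions(
    sig[, c("chrom", "pos", "p_value")], bsa$regions))
  write_tsv(ov$snps, file.path(cfg$out_dir, "overlap.tsv"))

  annot <- NULL
  if (!is.null(cfg$gff_path) && file.exists(cfg$gff_path)) {
    annot <- stage("annotate", annotate_nearby_genes(
      sig[, c("chrom", "pos")], cfg$gff_path, cfg$overlap_window))
    write_tsv(annot, file.path(cfg$out_dir, "candidate_genes.tsv"))
  }

  summary <- list(
    mode = cfg$mode, seed = cfg$seed,
    n_individuals = nrow(geno_imp$dosage),
    n_markers_initial = n_initial,
    n_markers_filtered = n_filtered,
    n_markers_tested = nrow(scan),
    h2_greml = h2g$h2,
    h2_realized = if (!is.null(h2r)) h2r$h2 else NA,
    gwas_lambda = qq$lambda,
    n_significant_snps = nrow(sig),
    expected_false_positives = cfg$gwas$alpha * nrow(scan),
    bsa_threshold = bsa$threshold,
    n_bsa_significant_markers = sum(bsa$scan$neg_log10_p > bsa$threshold),
    n_bsa_regions = nrow(bsa$regions),
    n_overlaps = ov$totals$n_overlaps,
    pseudo_qtn = gw$pseudo_qtn)
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_echo <- cfg
  cfg_echo$sim$plot_effects <- as.vector(cfg_echo$sim$plot_effects)
  yaml::write_yaml(lapply(unclass(cfg_echo), function(x)
    if (is.list(x)) unclass(x) else x),
    file.path(cfg$out_dir, "config.yaml"))
  cat(sprintf("%-14s %8.2fs\n", "total", proc.time()[["elapsed"]] - t0),
      file = logf, append = TRUE)
  invisible(list(summary = summary, scan = scan, significant = sig,
                 bsa = bsa, overlap = ov, h2 = list(greml = h2g,
                                                    realized = h2r),
                 describe = desc, annot = annot, truth = truth,
                 out_dir = cfg$out_dir))
}
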
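#' Read genotypes from a VCF file
#'
#' Reads biallelic diploid GT calls into a [genotype_matrix()]. Genotypes are
#' coded as alt-allele dosage: 0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2, ./. ->
#' missing. Records with more than one ALT allele are kept but flagged
#' `diallelic = FALSE` (and their calls set missing) so that
#' [filter_markers()] removes them. Per-marker total read counts are taken
#' from the site INFO `DP` field when present, otherwise from the sum of
#' per-sample FORMAT `DP`.
#'
#' @param path path to a VCF (v4.x) file with a GT FORMAT field.
#' @return a `GenotypeMatrix`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (nrow(fix) == 0) stop("no variant records in ", path)
  if (!"FORMAT" %in% colnames(v@gt))
    stop("VCF has no FORMAT/sample columns: ", path)
  if (!any(grepl("(^|:)GT(:|$)", v@gt[, "FORMAT"])))
    stop("VCF FORMAT has no GT field: ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  map <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2, "./." = NA_real_)
  dos <- matrix(unname(map[gt]), nrow = nrow(gt))
  # unknown codes (multiallelic calls like 0/2, half calls) -> missing
  alt <- fix[, "ALT"]
  diallelic <- !grepl(",", alt, fixed = TRUE) & !is.na(alt) & alt != "."
  dos[!diallelic, ] <- NA_real_
  info <- fix[, "INFO"]
  dp_info <- suppressWarnings(as.numeric(sub(".*DP=([0-9]+).*", "\\1",
                                             info)))
  dp_info[!grepl("DP=", info)] <- NA_real_
  total_reads <- dp_info
  if (all(is.na(total_reads)) &&
      any(grepl("(^|:)DP(:|$)", v@gt[, "FORMAT"]))) {
    dp <- suppressWarnings(
      apply(vcfR::extract.gt(v, element = "DP"), 1,
            function(x) sum(as.numeric(x), na.rm = TRUE)))
    total_reads <- dp
  }
  markers <- data.frame(
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], "_", fix[, "POS"]), fix[, "ID"]),
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = alt,
    total_reads = total_reads,
    diallelic = diallelic,
    stringsAsFactors = FALSE)
  if (anyDuplicated(markers$id))
    markers$id <- make.unique(markers$id)
  if (!identical(order(markers$chrom, markers$pos), seq_len(nrow(markers))))
    stop("VCF records are not sorted by chromosome and position: ", path)
  dosage <- t(dos)
  rownames(dosage) <- colnames(gt)
  genotype_matrix(dosage, markers)
}

#' Write a GenotypeMatrix as uncompressed VCF v4.2
#'
#' Emits GT calls ("0/0", "0/1", "1/1", "./.") and the per-marker total read
#' count as an INFO `DP` field when available. Only raw (unimputed, integer)
#' dosages can be written.
#'
#' @param g a `GenotypeMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  if (g$imputed)
    stop("cannot write fractional (imputed) dosages as GT calls")
  mk <- g$markers
  has_dp <- !is.null(mk$total_reads) && !all(is.na(mk$total_reads))
  hdr <- c("##fileformat=VCFv4.2",
           if (has_dp)
             "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth across samples\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", individual_ids(g)), collapse = "\t"))
  code <- c("0/0", "0/1", "1/1")
  d <- t(g$dosage)                      # markers x individuals
  calls <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(d)
  calls[ok] <- code[d[ok] + 1L]
  info <- if (has_dp) paste0("DP=", mk$total_reads) else rep(".", nrow(mk))
  body <- paste(mk$chrom, mk$pos, mk$id, mk$ref, mk$alt, ".", "PASS", info,
                "GT", apply(calls, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Filter markers on diallelic status, MAF and read count
#'
#' Keeps diallelic markers with minor allele frequency >= `min_maf` (MAF is
#' computed on non-missing calls; the boundary is kept because exclusion is
#' for MAF strictly below the threshold) and total read count >= `min_reads`.
#' Markers without read-count information pass the read rule (with a
#' message). Removing everything yields an empty matrix with a warning.
#'
#' @param g a `GenotypeMatrix`.
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @param min_reads minimum total read count across samples (default 40).
#' @return filtered `GenotypeMatrix`.
#' @export
filter_markers <- function(g, min_maf = 0.05, min_reads = 40) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  m <- ncol(g$dosage)
  if (m == 0) return(g)
  fr <- marker_freqs(g)
  maf <- fr$maf
  maf[is.na(maf)] <- -Inf               # uncallable markers never pass
  keep <- g$markers$diallelic & maf >= min_maf
  tr <- g$markers$total_reads
  if (is.null(tr) || all(is.na(tr))) {
    message("no read-count information; read-count rule not applied")
  } else {
    tr[is.na(tr)] <- Inf
    keep <- keep & tr >= min_reads
  }
  message(sum(keep), " of ", m, " markers survive filtering (min_maf = ",
          min_maf, ", min_reads = ", min_reads, ")")
  if (!any(keep)) {
    warning("all markers removed by filtering")
  }
  subset_genotypes(g, markers = keep)
}

#' Replace missing dosages by the marker mean
#'
#' Naive imputation: each missing call becomes the mean dosage of the
#' marker's non-missing calls, so dosages become real-valued. Non-missing
#' entries are unchanged.
#'
#' @param g a `GenotypeMatrix`.
#' @return imputed `GenotypeMatrix` (`imputed = TRUE`, no missing values).
#' @export
impute_missing <- function(g) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  d <- g$dosage
  n_called <- colSums(!is.na(d))
  if (any(n_called == 0L))
    stop("marker(s) with all calls missing cannot be imputed: ",
         paste(utils::head(g$markers$id[n_called == 0L], 5), collapse = ", "))
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- mu[idx[, 2L]]
  genotype_matrix(d, g$markers, imputed = TRUE)
}

#' Genomic relationship matrix from standardized dosages
#'
#' GRM = Z Z' / m where Z holds per-marker standardized dosages
#' (d - 2p) / sqrt(2 p (1 - p)) with p the alt-allele frequency, and m the
#' number of markers used. Markers with zero variance (fixed alleles) are
#' dropped before standardization.
#'
#' @param g an imputed (no missing) `GenotypeMatrix`.
#' @return symmetric n x n matrix with individual ids as dimnames and the
#'   number of markers used in `attr(, "n_markers")`.
#' @export
compute_grm <- function(g) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  d <- g$dosage
  if (anyNA(d)) stop("GRM needs a complete matrix; run impute_missing() first")
  p <- colMeans(d) / 2
  v <- apply(d, 2, stats::var)
  use <- p > 0 & p < 1 & v > 0
  if (!any(use)) stop("no polymorphic markers left for the GRM")
  if (any(!use))
    message(sum(!use), " zero-variance marker(s) dropped from the GRM")
  d <- d[, use, drop = FALSE]
  p <- p[use]
  z <- sweep(d, 2, 2 * p)
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  m <- ncol(z)
  grm <- tcrossprod(z) / m
  dimnames(grm) <- list(individual_ids(g), individual_ids(g))
  attr(grm, "n_markers") <- m
  grm
}

#' Principal components of a genomic relationship matrix
#'
#' Eigendecomposition of the (symmetric) GRM; coordinates are eigenvectors
#' scaled by the square root of their eigenvalue, in descending eigenvalue
#' order.
#'
#' @param grm symmetric GRM from [compute_grm()].
#' @param k number of components to return.
#' @param tol asymmetry tolerance.
#' @return list with `scores` (n x k), `values` (all eigenvalues) and
#'   `var_explained` (eigenvalue fractions of the trace).
#' @export
grm_pca <- function(grm, k = 10, tol = 1e-8) {
  stopifnot(is.matrix(grm), nrow(grm) == ncol(grm))
  if (max(abs(grm - t(grm))) > tol) stop("GRM is not symmetric")
  k <- min(k, nrow(grm))
  e <- eigen(grm, symmetric = TRUE)
  vals <- e$values
  scores <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(vals[seq_len(k)], 0)), k)
  rownames(scores) <- rownames(grm)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, values = vals,
       var_explained = vals / sum(vals))
}

#' Write a GRM as a delimited matrix with id header row and column
#'
#' @param grm GRM matrix.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_grm <- function(grm, path) {
  df <- data.frame(id = rownames(grm), grm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
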
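#' Genotype matrix container
#'
#' Individuals-by-markers matrix of alt-allele dosages (0, 1, 2, or `NA` for
#' missing; real-valued after mean imputation) plus per-marker metadata.
#' This is the common currency of the toolkit: the simulator produces one,
#' [read_vcf()] builds one from a VCF, and the filtering, GRM, GWAS and BSA
#' stages consume one.
#'
#' @param dosage numeric matrix, individuals x markers. Row names are taken
#'   as individual ids (generated if absent).
#' @param markers data.frame with one row per marker: columns `id`, `chrom`,
#'   `pos` (1-based bp), `ref`, `alt` required; optional `cM` (genetic-map
#'   coordinate), `total_reads` (site read count summed over samples) and
#'   `diallelic` (logical, default `TRUE`).
#' @param haplotypes optional list with integer matrices `h1`, `h2` (phased
#'   0/1 alt carriage) used by the simulator's mating step.
#' @param imputed logical; `TRUE` once dosages may be fractional.
#' @return object of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(dosage, markers, haplotypes = NULL,
                            imputed = FALSE) {
  stopifnot(is.matrix(dosage), is.data.frame(markers))
  need <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(markers))
  if (length(miss))
    stop("markers is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(markers) != ncol(dosage))
    stop("marker table has ", nrow(markers), " rows but dosage has ",
         ncol(dosage), " columns")
  if (anyDuplicated(markers$id))
    stop("marker ids must be unique")
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("ind_", seq_len(nrow(dosage)))
  if (anyDuplicated(rownames(dosage)))
    stop("individual ids must be unique")
  if (any(markers$pos < 1)) stop("positions are 1-based; found pos < 1")
  if (!imputed) {
    vals <- dosage[!is.na(dosage)]
    if (length(vals) && !all(vals %in% c(0, 1, 2)))
      stop("raw dosages must be 0, 1, 2 or NA")
  }
  if (is.null(markers$diallelic))
    markers$diallelic <- rep(TRUE, nrow(markers))
  # canonical order: chromosome, then position
  ord <- order(markers$chrom, markers$pos)
  if (!identical(ord, seq_len(nrow(markers)))) {
    markers <- markers[ord, , drop = FALSE]
    dosage <- dosage[, ord, drop = FALSE]
    if (!is.null(haplotypes)) {
      haplotypes$h1 <- haplotypes$h1[, ord, drop = FALSE]
      haplotypes$h2 <- haplotypes$h2[, ord, drop = FALSE]
    }
  }
  rownames(markers) <- NULL
  colnames(dosage) <- markers$id
  structure(list(dosage = dosage, markers = markers,
                 haplotypes = haplotypes, imputed = imputed),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat("GenotypeMatrix:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "markers\n")
  cat("  chromosomes:", paste(unique(x$markers$chrom), collapse = ", "), "\n")
  nmiss <- sum(is.na(x$dosage))
  cat("  missing calls:", nmiss,
      sprintf("(%.1f%%)", 100 * nmiss / length(x$dosage)), "\n")
  if (x$imputed) cat("  dosages imputed (real-valued)\n")
  if (!is.null(x$haplotypes)) cat("  phased haplotypes attached\n")
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$dosage)

#' Individual ids of a GenotypeMatrix
#' @param g a `GenotypeMatrix`.
#' @return character vector of ids.
#' @export
individual_ids <- function(g) rownames(g$dosage)

#' Subset a GenotypeMatrix by individuals and/or markers
#'
#' @param g a `GenotypeMatrix`.
#' @param individuals ids or indices of individuals to keep.
#' @param markers ids or logical/integer index of markers to keep.
#' @return a `GenotypeMatrix`.
#' @export
subset_genotypes <- function(g, individuals = NULL, markers = NULL) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  ri <- seq_len(nrow(g$dosage))
  if (!is.null(individuals)) {
    if (is.character(individuals)) {
      ri <- match(individuals, rownames(g$dosage))
      if (anyNA(ri))
        stop("unknown individual id(s): ",
             paste(individuals[is.na(ri)], collapse = ", "))
    } else ri <- individuals
  }
  ci <- seq_len(ncol(g$dosage))
  if (!is.null(markers)) {
    if (is.character(markers)) {
      ci <- match(markers, g$markers$id)
      if (anyNA(ci))
        stop("unknown marker id(s): ", paste(markers[is.na(ci)], collapse = ", "))
    } else if (is.logical(markers)) ci <- which(markers)
    else ci <- markers
  }
  hap <- g$haplotypes
  if (!is.null(hap))
    hap <- list(h1 = hap$h1[ri, ci, drop = FALSE],
                h2 = hap$h2[ri, ci, drop = FALSE])
  genotype_matrix(g$dosage[ri, ci, drop = FALSE],
                  g$markers[ci, , drop = FALSE],
                  haplotypes = hap, imputed = g$imputed)
}

#' Per-marker allele summaries
#'
#' Alt-allele frequency, minor allele frequency and the number of non-missing
#' calls, all computed on non-missing genotypes only.
#'
#' @param g a `GenotypeMatrix`.
#' @return data.frame with columns `id`, `n_called`, `alt_freq`, `maf`.
#' @export
marker_freqs <- function(g) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  d <- g$dosage
  n_called <- colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  alt[n_called == 0L] <- NA_real_
  data.frame(id = g$markers$id, n_called = n_called, alt_freq = alt,
             maf = pmin(alt, 1 - alt), row.names = NULL)
}
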
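#' Overlap significant GWAS SNPs with BSA regions
#'
#' A SNP overlaps a region when it lies on the same chromosome and
#' left_pos <= pos <= right_pos (both boundaries inclusive; 1-based
#' coordinates throughout).
#'
#' @param snps data.frame of significant GWAS SNPs (`chrom`, `pos`,
#'   `p_value`).
#' @param regions `BsaRegion` data.frame from [call_regions()].
#' @return list of class `OverlapReport`: `snps` (per-SNP rows with
#'   `region_left`, `region_right`, `overlapped`), and `totals`
#'   (`n_snps`, `n_regions`, `n_overlaps`).
#' @export
overlap_snps_regions <- function(snps, regions) {
  stopifnot(is.data.frame(snps), is.data.frame(regions))
  if (nrow(snps) > 0 && nrow(regions) > 0 &&
      !length(intersect(unique(snps$chrom), unique(regions$chrom))))
    stop("chromosome labels of SNPs and regions do not match: SNPs use {",
         paste(unique(snps$chrom), collapse = ", "), "}, regions use {",
         paste(unique(regions$chrom), collapse = ", "), "}")
  out <- snps
  out$region_left <- rep(NA_real_, nrow(out))
  out$region_right <- rep(NA_real_, nrow(out))
  out$overlapped <- rep(FALSE, nrow(out))
  for (i in seq_len(nrow(out))) {
    hit <- which(regions$chrom == out$chrom[i] &
                   regions$left_pos <= out$pos[i] &
                   regions$right_pos >= out$pos[i])
    if (length(hit)) {
      out$region_left[i] <- regions$left_pos[hit[1L]]
      out$region_right[i] <- regions$right_pos[hit[1L]]
      out$overlapped[i] <- TRUE
    }
  }
  structure(list(snps = out,
                 totals = list(n_snps = nrow(snps),
                               n_regions = nrow(regions),
                               n_overlaps = sum(out$overlapped))),
            class = "OverlapReport")
}

#' @export
print.OverlapReport <- function(x, ...) {
  cat("Overlap report:", x$totals$n_snps, "significant SNPs,",
      x$totals$n_regions, "regions,", x$totals$n_overlaps, "overlaps\n")
  invisible(x)
}

#' Annotate genes near significant SNPs from a GFF3 file
#'
#' Reports every gene whose span intersects \[pos - window, pos + window\]
#' around each SNP (default window 150 kb). Distance is 0 when the SNP lies
#' inside the gene span ("SNP in candidate"), otherwise the distance from
#' the SNP to the nearest gene boundary. Lines without nine tab-separated
#' fields are skipped with a warning before parsing.
#'
#' @param snps data.frame with `chrom` and `pos`.
#' @param gff_path path to a GFF3 file with gene features.
#' @param window half-width of the search window in bp (default 150000).
#' @return data.frame: `snp_chrom`, `snp_pos`, `gene_id`, `gene_start`,
#'   `gene_end`, `distance`, `in_gene`.
#' @export
annotate_nearby_genes <- function(snps, gff_path, window = 150000) {
  if (!file.exists(gff_path)) stop("GFF3 not found: ", gff_path)
  lines <- readLines(gff_path)
  body <- !grepl("^#", lines) & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(body)[nfield != 9L]
  if (length(bad)) {
    warning(length(bad), " malformed GFF line(s) skipped")
    lines <- lines[-bad]
  }
  tmp <- tempfile(fileext = ".gff3")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  gr <- rtracklayer::import(tmp, format = "gff3")
  genes <- gr[gr$type == "gene"]
  if (!length(genes)) {
    warning("no gene features in ", gff_path)
    return(data.frame(snp_chrom = character(0), snp_pos = numeric(0),
                      gene_id = character(0), gene_start = numeric(0),
                      gene_end = numeric(0), distance = numeric(0),
                      in_gene = logical(0)))
  }
  win <- GenomicRanges::GRanges(
    snps$chrom,
    IRanges::IRanges(pmax(snps$pos - window, 1), snps$pos + window))
  hits <- GenomicRanges::findOverlaps(win, genes, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  gid <- genes$ID
  if (is.null(gid)) gid <- genes$Name
  if (is.null(gid)) gid <- paste0("gene_", seq_along(genes))
  gstart <- GenomicRanges::start(genes)[si]
  gend <- GenomicRanges::end(genes)[si]
  pos <- snps$pos[qi]
  dist <- ifelse(pos >= gstart & pos <= gend, 0,
                 pmin(abs(pos - gstart), abs(pos - gend)))
  data.frame(snp_chrom = snps$chrom[qi], snp_pos = pos,
             gene_id = as.character(gid[si]), gene_start = gstart,
             gene_end = gend, distance = dist, in_gene = dist == 0,
             stringsAsFactors = FALSE)
}
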
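#' Allele frequencies of an in-silico bulk
#'
#' Estimates the reference-allele frequency per marker over the non-missing
#' calls of the bulk members: ref_freq = 1 - (sum of alt dosages) / m with
#' m = 2 x non-missing individuals. Markers with no informative call get a
#' missing frequency and are excluded downstream.
#'
#' @param g `GenotypeMatrix` (raw calls; missing allowed).
#' @param bulk_ids plant ids forming the bulk.
#' @param label bulk label (e.g. "tall" or "short").
#' @return `BulkFreqs` data.frame: `id`, `chrom`, `pos`, `ref_freq`,
#'   `n_alleles`, `bulk`.
#' @export
insilico_bulk_freq <- function(g, bulk_ids, label = "bulk") {
  stopifnot(inherits(g, "GenotypeMatrix"))
  if (!length(bulk_ids)) stop("bulk_ids is empty")
  gb <- subset_genotypes(g, individuals = bulk_ids)
  d <- gb$dosage
  m_alleles <- 2 * colSums(!is.na(d))
  ref <- 1 - colSums(d, na.rm = TRUE) / pmax(m_alleles, 1L)
  ref[m_alleles == 0L] <- NA_real_
  data.frame(id = g$markers$id, chrom = g$markers$chrom, pos = g$markers$pos,
             ref_freq = ref, n_alleles = m_alleles, bulk = label,
             stringsAsFactors = FALSE)
}

#' Two-sided Z-test scan between two bulks
#'
#' Pooled two-proportion Z test per marker:
#' Z = (pT - pS) / sqrt(pbar (1 - pbar) (1/mT + 1/mS)) with
#' pbar = (pT mT + pS mS) / (mT + mS); p = 2 Phi(-|Z|). Markers monomorphic
#' in the pooled sample (pbar 0 or 1) get Z = 0, p = 1. Markers with a
#' missing frequency in either bulk are dropped (and counted in a message).
#'
#' @param tall `BulkFreqs` of the first bulk.
#' @param short `BulkFreqs` of the second bulk.
#' @return `ScanResult` data.frame: `id`, `chrom`, `pos`, `delta_freq`
#'   (tall - short ref-allele frequency), `z`, `p_value`, `neg_log10_p`.
#' @export
ztest_scan <- function(tall, short) {
  if (!identical(tall$id, short$id))
    stop("bulks have mismatched marker lists")
  ok <- !is.na(tall$ref_freq) & !is.na(short$ref_freq) &
    tall$n_alleles > 0 & short$n_alleles > 0
  if (any(!ok))
    message(sum(!ok), " marker(s) without informative calls in both bulks ",
            "dropped from the scan")
  pT <- tall$ref_freq[ok]; mT <- tall$n_alleles[ok]
  pS <- short$ref_freq[ok]; mS <- short$n_alleles[ok]
  pbar <- (pT * mT + pS * mS) / (mT + mS)
  se <- sqrt(pbar * (1 - pbar) * (1 / mT + 1 / mS))
  z <- ifelse(pbar <= 0 | pbar >= 1, 0, (pT - pS) / se)
  p <- 2 * stats::pnorm(-abs(z))
  p <- pmax(p, .Machine$double.xmin)
  data.frame(id = tall$id[ok], chrom = tall$chrom[ok], pos = tall$pos[ok],
             delta_freq = pT - pS, z = z, p_value = p,
             neg_log10_p = -log10(p), stringsAsFactors = FALSE)
}

#' Empirical outlier threshold on -log10 p
#'
#' The (1 - q) empirical quantile (type 7) of the genome-wide -log10
#' p-values; with the default q = 0.005, markers above it are the 0.5%
#' outliers.
#'
#' @param neglog10p numeric vector of -log10 p values.
#' @param q outlier fraction (default 0.005).
#' @return threshold (single number).
#' @export
outlier_threshold <- function(neglog10p, q = 0.005) {
  x <- neglog10p[!is.na(neglog10p)]
  if (!length(x)) stop("no values to compute a threshold from")
  if (length(x) < 1 / q)
    warning("fewer than 1/q = ", ceiling(1 / q),
            " values; the outlier threshold is unstable")
  stats::quantile(x, 1 - q, names = FALSE, type = 7)
}

#' Sliding-window smoothing of a per-marker statistic
#'
#' Centered moving average over `window` markers (default 15), computed
#' within each chromosome; the window is truncated at chromosome edges and
#' never crosses a chromosome boundary. Markers must be position-sorted
#' within chromosome (the `GenotypeMatrix` order).
#'
#' @param x numeric per-marker values (e.g. -log10 p).
#' @param chrom chromosome label per marker.
#' @param window odd window size in markers.
#' @return numeric vector of smoothed values, same length as `x`.
#' @export
smooth_scan <- function(x, chrom, window = 15) {
  if (window %% 2 == 0) stop("window must be odd (the center is undefined)")
  if (window < 1) stop("window must be >= 1")
  if (length(x) != length(chrom)) stop("x and chrom lengths differ")
  h <- (window - 1) / 2
  out <- numeric(length(x))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    n <- length(i)
    cs <- cumsum(c(0, x[i]))
    lo <- pmax(seq_len(n) - h, 1)
    hi <- pmin(seq_len(n) + h, n)
    out[i] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  out
}

#' Call significant regions from a smoothed scan
#'
#' Finds maximal runs of consecutive markers whose smoothed value exceeds
#' the threshold, within chromosomes. Runs separated by fewer than `gap`
#' sub-threshold markers are merged. A region is kept only if it contains at
#' least one marker whose raw -log10 p exceeds the threshold. Each region
#' reports its left/right marker positions, length in kb, the peak marker
#' (smallest raw p, ties to the leftmost) and the peak p-value.
#'
#' @param smoothed smoothed -log10 p per marker.
#' @param raw raw -log10 p per marker.
#' @param threshold threshold from [outlier_threshold()].
#' @param markers data.frame with `chrom` and `pos` per marker (same order).
#' @param gap merge runs separated by fewer than this many markers
#'   (default 15).
#' @return `BsaRegion` data.frame: `chrom`, `left_pos`, `right_pos`,
#'   `length_kb`, `peak_pos`, `peak_p`, `n_markers`, `n_significant`.
#' @export
call_regions <- function(smoothed, raw, threshold, markers, gap = 15) {
  stopifnot(length(smoothed) == length(raw),
            length(smoothed) == nrow(markers))
  regions <- list()
  for (ch in unique(markers$chrom)) {
    i <- which(markers$chrom == ch)
    above <- smoothed[i] > threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    # merge runs separated by fewer than `gap` sub-threshold markers
    merged <- runs[1, , drop = FALSE]
    if (nrow(runs) > 1) {
      for (k in 2:nrow(runs)) {
        sep <- runs$start[k] - merged$end[nrow(merged)] - 1L
        if (sep < gap) {
          merged$end[nrow(merged)] <- runs$end[k]
        } else {
          merged <- rbind(merged, runs[k, ])
        }
      }
    }
    for (k in seq_len(nrow(merged))) {
      idx <- i[merged$start[k]:merged$end[k]]
      n_sig <- sum(raw[idx] > threshold)
      if (n_sig == 0) next               # no raw outlier inside: not a region
      peak <- idx[which.max(raw[idx])]   # ties -> leftmost (first max)
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch,
        left_pos = markers$pos[idx[1L]],
        right_pos = markers$pos[idx[length(idx)]],
        length_kb = (markers$pos[idx[length(idx)]] - markers$pos[idx[1L]]) / 1000,
        peak_pos = markers$pos[peak],
        peak_p = 10^(-raw[peak]),
        n_markers = length(idx),
        n_significant = n_sig,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(regions))
    return(data.frame(chrom = character(0), left_pos = numeric(0),
                      right_pos = numeric(0), length_kb = numeric(0),
                      peak_pos = numeric(0), peak_p = numeric(0),
                      n_markers = integer(0), n_significant = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(regions, make.row.names = FALSE))
}

#' Run the full bulk segregant scan
#'
#' Convenience driver: in-silico bulk frequencies for the two bulks, pooled
#' Z-test scan, outlier threshold on the raw -log10 p, sliding-window
#' smoothing, and region calling.
#'
#' @param g `GenotypeMatrix` (raw calls).
#' @param tall_ids,short_ids plant ids of the two bulks.
#' @param q outlier fraction (default 0.005).
#' @param window smoothing window in markers (default 15).
#' @param gap region merge gap in markers (default 15).
#' @return list: `scan` (with `smoothed` column), `threshold`, `regions`.
#' @export
bsa_scan <- function(g, tall_ids, short_ids, q = 0.005, window = 15,
                     gap = 15) {
  tall <- insilico_bulk_freq(g, tall_ids, "tall")
  short <- insilico_bulk_freq(g, short_ids, "short")
  scan <- ztest_scan(tall, short)
  threshold <- outlier_threshold(scan$neg_log10_p, q)
  scan$smoothed <- smooth_scan(scan$neg_log10_p, scan$chrom, window)
  regions <- call_regions(scan$smoothed, scan$neg_log10_p, threshold,
                          scan[, c("chrom", "pos")], gap)
  list(scan = scan, threshold = threshold, regions = regions)
}
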
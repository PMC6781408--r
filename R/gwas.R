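#' GWAS configuration
#'
#' @param alpha per-marker significance threshold (default 1e-5; at ~300,000
#'   markers this implies fewer than three expected false positives
#'   genome-wide).
#' @param pseudo_qtn use the iterative pseudo-QTN refinement.
#' @param max_iter maximum pseudo-QTN iterations.
#' @param min_qtn_distance minimum distance in bp between pseudo-QTNs on the
#'   same chromosome (greedy pruning).
#' @return list of class `GwasConfig`.
#' @export
gwas_config <- function(alpha = 1e-5, pseudo_qtn = TRUE, max_iter = 10,
                        min_qtn_distance = 1e6) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (max_iter < 1) stop("max_iter must be >= 1")
  structure(list(alpha = alpha, pseudo_qtn = pseudo_qtn,
                 max_iter = max_iter, min_qtn_distance = min_qtn_distance),
            class = "GwasConfig")
}

#' Build the 0/1 covariate matrix used by the association scan
#'
#' Generation (0/1) and selection regime (short = 0 / tall = 1) indicators,
#' matching the plants of a phenotype table.
#'
#' @param phenos phenotype table with `generation` and `regime`.
#' @return numeric matrix with columns `generation`, `regime_tall`.
#' @export
scan_covariates <- function(phenos) {
  cbind(generation = as.numeric(phenos$generation),
        regime_tall = as.numeric(phenos$regime == "tall"))
}

#' Per-marker fixed-effect association scan
#'
#' Ordinary least squares of the response on (intercept, covariates, any
#' extra covariate markers, marker dosage), one marker at a time, with a
#' two-sided t test on the marker coefficient. Computed by
#' Frisch-Waugh-Lovell residualization, so the scan is a handful of matrix
#' products. Markers collinear with the covariates get p = 1 and a
#' `collinear` flag.
#'
#' @param g imputed `GenotypeMatrix`.
#' @param y response vector (standardized residuals), one per individual.
#' @param covariates optional numeric covariate matrix (no intercept).
#' @param extra_markers ids of markers forced into the model as covariates
#'   (pseudo-QTNs); these markers are skipped in the scan output unless
#'   `test_extra = TRUE`, in which case each is tested with itself removed
#'   from the covariate set.
#' @param alpha significance threshold used for the `significant` flag.
#' @return `ScanResult` data.frame: `id`, `chrom`, `pos`, `effect`, `se`,
#'   `t`, `p_value`, `neg_log10_p`, `collinear`, `significant`.
#' @export
glm_scan <- function(g, y, covariates = NULL, extra_markers = NULL,
                     alpha = 1e-5, test_extra = TRUE) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  D <- g$dosage
  n <- nrow(D)
  if (length(y) != n) stop("length(y) (", length(y),
                           ") does not match individuals (", n, ")")
  if (anyNA(D)) stop("scan needs a complete matrix; run impute_missing()")
  X0 <- cbind(intercept = rep(1, n), covariates)
  if (length(extra_markers)) {
    xi <- match(extra_markers, g$markers$id)
    if (anyNA(xi)) stop("unknown extra covariate marker id(s)")
    X0 <- cbind(X0, D[, xi, drop = FALSE])
  }
  if (n < ncol(X0) + 3) stop("too few individuals for the model")
  res <- scan_core(D, y, X0)
  out <- data.frame(id = g$markers$id, chrom = g$markers$chrom,
                    pos = g$markers$pos, effect = res$beta, se = res$se,
                    t = res$t, p_value = res$p,
                    collinear = res$collinear, stringsAsFactors = FALSE)
  if (length(extra_markers) && test_extra) {
    # a marker already in the covariate set is tested with itself removed
    for (mid in extra_markers) {
      others <- setdiff(extra_markers, mid)
      Xm <- cbind(intercept = rep(1, n), covariates)
      if (length(others))
        Xm <- cbind(Xm, D[, match(others, g$markers$id), drop = FALSE])
      j <- match(mid, g$markers$id)
      r1 <- scan_core(D[, j, drop = FALSE], y, Xm)
      out[j, c("effect", "se", "t", "p_value", "collinear")] <-
        list(r1$beta, r1$se, r1$t, r1$p, r1$collinear)
    }
  }
  out$neg_log10_p <- -log10(out$p_value)
  out$significant <- out$p_value < alpha
  out
}

# OLS of y on (X0, marker j) for every column of D, via residualization
scan_core <- function(D, y, X0) {
  n <- nrow(D)
  qx <- qr(X0)
  df <- n - qx$rank - 1L
  ry <- qr.resid(qx, y)
  RG <- qr.resid(qx, D)
  sxx <- colSums(RG^2)
  # collinear with covariates: no residual variance left in the marker
  scale <- colSums(D^2)
  collinear <- sxx <= 1e-10 * pmax(scale, 1)
  sxy <- as.vector(crossprod(RG, ry))
  syy <- sum(ry^2)
  beta <- sxy / sxx
  rss <- pmax(syy - beta * sxy, 0)
  sigma2 <- rss / df
  se <- sqrt(sigma2 / sxx)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  p <- pmax(p, .Machine$double.xmin)    # p in (0, 1]
  beta[collinear] <- NA_real_
  se[collinear] <- NA_real_
  tval[collinear] <- NA_real_
  p[collinear] <- 1
  list(beta = beta, se = se, t = tval, p = p, collinear = collinear)
}

#' Iterative association scan with pseudo-QTN covariates
#'
#' A simplified fixed-effect analogue of iterative multi-locus scans: each
#' iteration (1) runs [glm_scan()] with the current pseudo-QTNs as extra
#' covariates (a marker in the set is tested with itself removed), (2) forms
#' a candidate set of markers passing `cfg$alpha`, sorted by p-value and
#' greedily pruned so no two lie within `cfg$min_qtn_distance` on one
#' chromosome, and (3) retains candidates whose addition lowers the BIC of
#' the joint fixed-effect model. Iteration stops when the pseudo-QTN set is
#' unchanged or `cfg$max_iter` is reached (then flagged unconverged). Under
#' the null the set stays empty and the result equals the base scan.
#'
#' @param g imputed `GenotypeMatrix`.
#' @param y response vector.
#' @param covariates optional covariate matrix.
#' @param cfg a [gwas_config()].
#' @return list: `scan` (final `ScanResult`), `pseudo_qtn` (marker ids),
#'   `iterations`, `converged`.
#' @export
pseudo_qtn_scan <- function(g, y, covariates = NULL, cfg = gwas_config()) {
  stopifnot(inherits(cfg, "GwasConfig"))
  if (!cfg$pseudo_qtn)
    return(list(scan = glm_scan(g, y, covariates, alpha = cfg$alpha),
                pseudo_qtn = character(0), iterations = 0L,
                converged = TRUE))
  qtn <- character(0)
  converged <- FALSE
  scan <- NULL
  n <- nrow(g$dosage)
  for (it in seq_len(cfg$max_iter)) {
    scan <- glm_scan(g, y, covariates, extra_markers = qtn,
                     alpha = cfg$alpha)
    cand <- scan[scan$p_value < cfg$alpha & !scan$collinear, , drop = FALSE]
    cand <- cand[order(cand$p_value, cand$chrom, cand$pos), , drop = FALSE]
    picked <- integer(0)
    for (i in seq_len(nrow(cand))) {
      ok <- TRUE
      for (j in picked)
        if (cand$chrom[i] == cand$chrom[j] &&
            abs(cand$pos[i] - cand$pos[j]) < cfg$min_qtn_distance) {
          ok <- FALSE; break
        }
      if (ok) picked <- c(picked, i)
    }
    cand <- cand[picked, , drop = FALSE]
    # forward BIC retention on the joint model
    new_qtn <- character(0)
    X <- cbind(rep(1, n), covariates)
    bic0 <- n * log(sum(qr.resid(qr(X), y)^2) / n) + ncol(X) * log(n)
    for (mid in cand$id) {
      Xtry <- cbind(X, g$dosage[, match(mid, g$markers$id)])
      bic1 <- n * log(sum(qr.resid(qr(Xtry), y)^2) / n) + ncol(Xtry) * log(n)
      if (bic1 < bic0) {
        new_qtn <- c(new_qtn, mid)
        X <- Xtry
        bic0 <- bic1
      }
    }
    if (setequal(new_qtn, qtn)) {
      converged <- TRUE
      qtn <- new_qtn
      break
    }
    qtn <- new_qtn
  }
  if (!converged) {
    warning("pseudo-QTN iteration did not converge in ", cfg$max_iter,
            " iterations; returning last scan")
    scan <- glm_scan(g, y, covariates, extra_markers = qtn, alpha = cfg$alpha)
  }
  list(scan = scan, pseudo_qtn = qtn, iterations = it, converged = converged)
}

#' Subset a scan to significant markers
#'
#' @param res `ScanResult` data.frame.
#' @param alpha significance threshold (default 1e-5).
#' @return significant rows of `res`; the expected false-positive count
#'   `alpha * nrow(res)` is reported in a message and attached as
#'   `attr(, "expected_false_positives")`.
#' @export
call_significant <- function(res, alpha = 1e-5) {
  stopifnot(is.data.frame(res), "p_value" %in% names(res))
  sig <- res[res$p_value < alpha, , drop = FALSE]
  efp <- alpha * nrow(res)
  message(nrow(sig), " significant marker(s) at alpha = ", alpha,
          " (expected false positives: ", signif(efp, 3), ")")
  attr(sig, "expected_false_positives") <- efp
  sig
}

#' Quantile-quantile data and genomic inflation factor
#'
#' Observed -log10 p sorted against uniform expectation
#' -log10((i - 0.5) / m), and the genomic inflation factor
#' lambda = median(chi-square) / qchisq(0.5, 1) (the conventional 0.456
#' denominator).
#'
#' @param res `ScanResult` data.frame (needs `p_value`).
#' @return list: `data` (data.frame `expected`, `observed`), `lambda`.
#' @export
qq_data <- function(res) {
  stopifnot(is.data.frame(res), "p_value" %in% names(res))
  p <- res$p_value[!is.na(res$p_value)]
  if (!length(p)) stop("no p-values")
  m <- length(p)
  obs <- sort(-log10(p), decreasing = TRUE)
  exp_ <- -log10((seq_len(m) - 0.5) / m)
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  list(data = data.frame(expected = sort(exp_), observed = sort(obs)),
       lambda = lambda)
}
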
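#' Read a phenotype table from a tab-separated file
#'
#' Expected columns: `plant_id`, `plot`, `year`, `generation`, `regime`,
#' `height_cm` (extra columns are kept).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("plant_id", "plot", "year", "generation", "regime", "height_cm")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("phenotype table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(p$plant_id)) stop("plant_id values must be unique")
  if (any(p$height_cm <= 0)) stop("height_cm must be positive")
  p
}

#' Standardize phenotypes across environments
#'
#' Fits a one-factor fixed-effect linear model of height on the
#' location-year cell (plot x year interaction) with [stats::lm()] and
#' stores the residuals. The residuals — height minus the fitted cell mean —
#' are the response variable used by the association and bulk segregant
#' scans; within every cell they sum to zero.
#'
#' @param p phenotype table (needs `plot`, `year`, `height_cm`).
#' @return `p` with a `residual` column added.
#' @export
standardize_phenotypes <- function(p) {
  stopifnot(is.data.frame(p), all(c("plot", "year", "height_cm") %in% names(p)))
  cell <- interaction(p$plot, p$year, drop = TRUE)
  sizes <- table(cell)
  if (any(sizes < 2))
    warning("location-year cell(s) with a single plant: ",
            paste(names(sizes)[sizes < 2], collapse = ", "),
            "; their residuals are 0")
  fit <- stats::lm(height_cm ~ cell, data = data.frame(height_cm = p$height_cm,
                                                       cell = cell))
  p$residual <- stats::residuals(fit)
  p
}

#' Descriptive statistics per group of a phenotype table
#'
#' @param p phenotype table.
#' @param by grouping columns (default plot within generation).
#' @return data.frame with per-group `n`, `min`, `max`, `range`, `median`,
#'   `mean`, `sd` (cm; `sd` is the n-1 sample version and `NA` for single
#'   plants).
#' @export
describe_phenotypes <- function(p, by = c("generation", "plot")) {
  stopifnot(is.data.frame(p), "height_cm" %in% names(p),
            all(by %in% names(p)))
  key <- interaction(p[by], drop = TRUE, sep = ":")
  rows <- lapply(split(p, key), function(pp) {
    h <- pp$height_cm
    cbind(pp[1, by, drop = FALSE],
          data.frame(n = length(h), min = min(h), max = max(h),
                     range = max(h) - min(h), median = stats::median(h),
                     mean = mean(h),
                     sd = if (length(h) > 1) stats::sd(h) else NA_real_))
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(out[[by[1]]], if (length(by) > 1) out[[by[2]]]), , drop = FALSE]
}

#' Realized heritability from the breeder's equation
#'
#' h2 = R / S, where S is the selection differential (mean of the selected
#' parents minus the base-population mean) and R the response (offspring
#' mean minus the base-population mean). Estimates outside \[0, 1\] are
#' clamped, and the clamping is reported via a message and a flag.
#'
#' @param S selection differential in cm (nonzero).
#' @param R response to selection in cm.
#' @return list of class `H2Estimate`: `h2`, `method = "breeders"`, `raw`
#'   (unclamped ratio), `clamped`.
#' @export
realized_h2 <- function(S, R) {
  stopifnot(is.numeric(S), is.numeric(R), length(S) == 1L, length(R) == 1L)
  if (S == 0) stop("selection differential S must be nonzero")
  raw <- R / S
  h2 <- min(max(raw, 0), 1)
  if (h2 != raw)
    message("realized h2 ", signif(raw, 4), " clamped to ", h2)
  structure(list(h2 = h2, method = "breeders", raw = raw,
                 clamped = h2 != raw),
            class = "H2Estimate")
}

#' @export
print.H2Estimate <- function(x, ...) {
  cat("h2 =", signif(x$h2, 4), sprintf("(%s)", x$method))
  if (isTRUE(x$clamped)) cat(" [clamped]")
  if (isTRUE(x$boundary)) cat(" [boundary]")
  cat("\n")
  if (!is.null(x$sigma2_g))
    cat("  sigma2_g =", signif(x$sigma2_g, 4),
        " sigma2_e =", signif(x$sigma2_e, 4), "\n")
  invisible(x)
}

# restricted log-likelihood of the one-component model in the GRM
# eigenbasis, profiled over beta and sigma2_e, as a function of log(lambda):
# d = GRM eigenvalues, ys/Xs = rotated response and design
greml_profile <- function(d, ys, Xs) {
  n <- length(ys)
  p <- ncol(Xs)
  function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (lam * d + 1)
    XtWX <- crossprod(Xs, Xs * w)
    XtWy <- crossprod(Xs, ys * w)
    beta <- solve(XtWX, XtWy)
    r <- ys - Xs %*% beta
    rss <- sum(w * r^2)
    -0.5 * ((n - p) * log(rss / (n - p)) + sum(log(lam * d + 1)) +
              determinant(XtWX, logarithm = TRUE)$modulus[1])
  }
}

#' GREML heritability from a genomic relationship matrix
#'
#' REML estimation of the single-component model y = X b + g + e with
#' g ~ N(0, sigma2_g K) and e ~ N(0, sigma2_e I). The GRM is eigendecomposed
#' once; the restricted log-likelihood is profiled in
#' lambda = sigma2_g / sigma2_e and maximized by a bounded 1-D search on
#' log(lambda) in \[-10, 10\] (tolerance 1e-6). h2 = sigma2_g /
#' (sigma2_g + sigma2_e). A flat likelihood or an optimum at the search
#' boundary raises the `boundary` flag.
#'
#' @param grm positive semi-definite GRM.
#' @param y response vector (typically standardized residuals).
#' @param covariates optional numeric matrix of fixed covariates (an
#'   intercept is always included).
#' @param psd_tol tolerance for negative GRM eigenvalues relative to the
#'   largest (beyond it, an error).
#' @return list of class `H2Estimate`: `h2`, `sigma2_g`, `sigma2_e`,
#'   `lambda`, `loglik`, `boundary`, `method = "greml"`.
#' @export
greml_h2 <- function(grm, y, covariates = NULL, psd_tol = 1e-6) {
  stopifnot(is.matrix(grm), nrow(grm) == ncol(grm))
  n <- length(y)
  if (nrow(grm) != n) stop("GRM dimension does not match length(y)")
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  qx <- qr(X)
  X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  p <- ncol(X)
  e <- eigen(grm, symmetric = TRUE)
  d <- e$values
  if (min(d) < -psd_tol * max(abs(d)))
    stop("GRM is not positive semi-definite (min eigenvalue ",
         signif(min(d), 3), ")")
  d <- pmax(d, 0)
  U <- e$vectors
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)
  rll <- greml_profile(d, ys, Xs)
  lo <- -10; hi <- 10
  grid <- seq(lo, hi, length.out = 21)
  gval <- vapply(grid, rll, numeric(1))
  flat <- (max(gval) - min(gval)) < 1e-6
  if (flat) {
    opt <- list(maximum = 0, objective = rll(0))
    boundary <- TRUE
  } else {
    opt <- stats::optimize(rll, c(lo, hi), maximum = TRUE, tol = 1e-6)
    boundary <- opt$maximum < lo + 0.05 || opt$maximum > hi - 0.05
  }
  lam <- exp(opt$maximum)
  w <- 1 / (lam * d + 1)
  XtWX <- crossprod(Xs, Xs * w)
  beta <- solve(XtWX, crossprod(Xs, ys * w))
  rss <- sum(w * (ys - Xs %*% beta)^2)
  sigma2_e <- rss / (n - p)
  sigma2_g <- lam * sigma2_e
  h2 <- sigma2_g / (sigma2_g + sigma2_e)
  if (flat) h2 <- NA_real_
  if (boundary && !flat)
    message("GREML optimum at the lambda search boundary; estimate flagged")
  structure(list(h2 = h2, sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 lambda = lam, loglik = opt$objective, boundary = boundary,
                 method = "greml"),
            class = "H2Estimate")
}
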
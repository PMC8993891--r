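# Statistical primitives used throughout the pipeline: Welch's t-test,
# Benjamini-Yekutieli FDR, Tukey bisquare robust regression, scaled MAD,
# and McNemar's chi-square with a clamped Yates correction.

#' Two-sample Welch's t-test
#'
#' Welch's unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom and a two-tailed p-value. Used by the single-trial detector as
#' the elementary comparison of evoked samples against baseline samples.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return A list of class `hfb_test` with `statistic`, `df`, `p`.
#' @examples
#' welch_t(c(1.1, 2.3, 0.8, 1.9), c(3.0, 2.8, 3.5))
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stopf("welch_t: each sample needs >= 2 observations (got %d, %d)",
          length(x), length(y))
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0)
    stopf("welch_t: both samples have zero variance; test undefined")
  nx <- length(x); ny <- length(y)
  sx <- vx / nx; sy <- vy / ny
  se2 <- sx + sy
  stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (sx^2 / (nx - 1) + sy^2 / (ny - 1))
  structure(list(statistic = stat, df = df, p = 2 * pt(-abs(stat), df)),
            class = "hfb_test")
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up FDR adjustment valid under arbitrary dependence: raw p-values
#' are multiplied by `m * c(m) / rank` with the harmonic factor
#' `c(m) = sum(1/i)`, enforced monotone and clipped to 1. Input order is
#' preserved; `NA`s propagate.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' fdr_by(rep(0.01, 4)) # all 0.0208333...
#' @export
fdr_by <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stopf("fdr_by: p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(out)
  cm <- sum(1 / seq_len(m))
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(cm * m / (m:1) * pv[o]))[ro]
  out[ok] <- adj
  out
}

#' Scaled median absolute deviation
#'
#' `1.4826 * median(|v - median(v)|)`: a robust estimate of the standard
#' deviation, consistent at the gaussian.
#'
#' @param values Numeric vector, length >= 1.
#' @return Scalar scaled MAD.
#' @export
mad_scaled <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 1) stopf("mad_scaled: empty input")
  1.4826 * median(abs(values - median(values)))
}

#' Tukey bisquare robust regression
#'
#' Iteratively reweighted least squares with redescending Tukey bisquare
#' weights (tuning constant 4.685 by default), residual scale re-estimated
#' each iteration by the scaled MAD. Standard errors come from the
#' Huber-type robust covariance and two-tailed p-values from the t
#' distribution on `n - k` degrees of freedom.
#'
#' @param design Numeric design matrix (rows = observations). An intercept
#'   column is NOT added automatically.
#' @param y Response vector.
#' @param tuning Bisquare tuning constant; `Inf` reduces the fit to
#'   ordinary least squares (all weights 1).
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param max_iter Maximum IRLS iterations; non-convergence is flagged in
#'   the result, not raised.
#' @return A list of class `hfb_robustfit`: `coefficients`, `se`, `p`,
#'   `df`, `residuals`, `scale`, `weights`, `converged`, `n_iter`.
#' @export
bisquare_regress <- function(design, y, tuning = 4.685, tol = 1e-8,
                             max_iter = 50L) {
  X <- as.matrix(design)
  y <- as.numeric(y)
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stopf("bisquare_regress: nrow(design) != length(y)")
  if (n < k + 2) stopf("bisquare_regress: need >= %d rows, got %d", k + 2, n)
  if (qr(X)$rank < k) stopf("bisquare_regress: design is rank deficient")

  beta <- qr.solve(X, y)              # OLS start
  w <- rep(1, n)
  converged <- FALSE
  it <- 0L
  # residual scale: zero-centered scaled MAD (robust-regression convention)
  rscale <- function(r) 1.4826 * median(abs(r))
  scale <- rscale(y - X %*% beta)
  repeat {
    it <- it + 1L
    r <- as.numeric(y - X %*% beta)
    scale <- rscale(r)
    if (scale == 0) { converged <- TRUE; w <- as.numeric(abs(r) < .Machine$double.eps^0.5); break }
    u <- r / (tuning * scale)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (!is.finite(tuning)) w <- rep(1, n)
    if (sum(w > 0) < k) { converged <- FALSE; break }
    XW <- X * w
    beta_new <- solve(crossprod(XW, X), crossprod(XW, y))
    delta <- max(abs(beta_new - beta))
    beta <- as.numeric(beta_new)
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  r <- as.numeric(y - X %*% beta)

  # Huber-type robust covariance: psi = r * w for the bisquare.
  if (scale > 0) {
    u <- r / (tuning * scale)
    psi <- ifelse(abs(u) < 1 & is.finite(tuning), r * (1 - u^2)^2, 0)
    dpsi <- ifelse(abs(u) < 1, (1 - u^2) * (1 - 5 * u^2), 0)
    if (!is.finite(tuning)) { psi <- r; dpsi <- rep(1, n) }
    num <- sum(psi^2) / (n - k)
    den <- (mean(dpsi))^2
    vb <- if (den > 0) num / den * solve(crossprod(X)) else
      matrix(NA_real_, k, k)
  } else {
    vb <- matrix(0, k, k)
  }
  se <- sqrt(pmax(diag(vb), 0))
  tval <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf))
  pval <- 2 * pt(-abs(tval), n - k)
  names(beta) <- colnames(X) %||% paste0("b", seq_len(k))
  structure(list(coefficients = beta, se = se, p = pval, df = n - k,
                 residuals = r, scale = scale, weights = w,
                 converged = converged, n_iter = it),
            class = "hfb_robustfit")
}

#' McNemar's chi-square with clamped Yates correction
#'
#' For discordant counts `n01`, `n10`, computes
#' `chi2 = max(|n01 - n10| - 1, 0)^2 / (n01 + n10)` (0 when both counts
#' are 0), with a p-value from the chi-square distribution on 1 df. The
#' continuity correction is clamped at zero so equal discordant counts
#' give exactly `chi2 = 0` rather than a spurious positive statistic.
#'
#' @param n01,n10 Non-negative discordant counts.
#' @return A list of class `hfb_test` with `statistic`, `df`, `p`.
#' @examples
#' mcnemar_yates(10, 2) # chi2 = 49/12
#' @export
mcnemar_yates <- function(n01, n10) {
  if (n01 < 0 || n10 < 0) stopf("mcnemar_yates: counts must be >= 0")
  tot <- n01 + n10
  stat <- if (tot == 0) 0 else max(abs(n01 - n10) - 1, 0)^2 / tot
  structure(list(statistic = stat, df = 1,
                 p = pchisq(stat, df = 1, lower.tail = FALSE)),
            class = "hfb_test")
}

#' @export
print.hfb_test <- function(x, ...) {
  cat(sprintf("statistic = %.4g, df = %.3g, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' @export
print.hfb_robustfit <- function(x, ...) {
  cat("Bisquare robust regression",
      if (!x$converged) "(NOT converged)" else "", "\n")
  tab <- data.frame(b = x$coefficients, se = x$se, p = x$p)
  print(tab, digits = 4)
  cat(sprintf("scale (MAD) = %.4g, iterations = %d\n", x$scale, x$n_iter))
  invisible(x)
}

# Effect-estimate record shared by classification/inference/behavior.
#' @noRd
effect_estimate <- function(name, b, se, p, df, or = FALSE) {
  data.frame(name = name, b = b, se = se, p = p, df = df,
             or_value = if (or) exp(b) else NA_real_,
             stringsAsFactors = FALSE)
}
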
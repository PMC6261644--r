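# Negative-binomial differential activity testing.
#
# Per-variant activity (log2 dex / vehicle) is estimated with a
# reconstruction of the standard RNA-seq NB workflow: median-of-ratios size
# factors, per-variant ML dispersions moderated toward a locally fitted
# mean-dispersion trend, a Wald test on the condition coefficient of an NB
# GLM, and Benjamini-Hochberg adjustment.  The machinery is implemented
# in-package (see the methods vignette for the exact moderation rule);
# exact numerical parity with any external tool release is not promised.

DISPERSION_FLOOR <- 1e-8

#' Median-of-ratios size factors
#'
#' @param counts count matrix (variants x samples).
#' @return numeric vector of per-sample factors, rescaled to geometric
#'   mean 1.
#' @export
size_factors <- function(counts) {
  if (ncol(counts) == 1L) return(stats::setNames(1, colnames(counts)))
  use <- rowSums(counts > 0) == ncol(counts)
  if (!any(use)) {
    stop(paste("no variant has nonzero counts in every sample;",
               "consider a pseudo-reference (e.g. filter low-coverage",
               "variants first)"), call. = FALSE)
  }
  logc <- log(counts[use, , drop = FALSE])
  ref <- rowMeans(logc)  # log geometric mean per variant
  sf <- exp(apply(logc - ref, 2L, stats::median))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

# Cox-Reid adjusted NB log-likelihood of one variant's counts at dispersion
# alpha, given per-sample means mu (condition-wise fitted means) and the
# design matrix x.  The adjustment -0.5 log det(X'WX), W = mu/(1 + alpha mu),
# removes the downward bias of plug-in ML dispersions at small sample size.
nb_loglik <- function(k, mu, alpha, x) {
  size <- if (alpha <= 0) 1e8 else 1 / alpha
  w <- mu / (1 + alpha * mu)
  # tiny ridge keeps the information matrix invertible when a condition
  # mean is zero
  xtwx <- crossprod(x * sqrt(w)) + diag(1e-8, ncol(x))
  ld <- determinant(xtwx, logarithm = TRUE)$modulus
  sum(stats::dnbinom(k, mu = mu, size = size, log = TRUE)) - 0.5 * ld
}

# Per-sample fitted means from condition-wise means of normalised counts.
fitted_means <- function(k, sf, condition) {
  q <- tapply(k / sf, condition, mean)
  as.numeric(q[condition]) * sf
}

#' Fit per-variant dispersions with a local trend and shrinkage
#'
#' Raw dispersions are NB maximum-likelihood estimates given the
#' condition-wise fitted means; a robust loess of log dispersion on log base
#' mean gives the trend; final dispersions maximise the likelihood penalised
#' by a normal prior on log dispersion centred at the trend, with prior
#' width taken from the median absolute residual.  Dispersions are floored
#' at 1e-8.
#'
#' @param counts count matrix.
#' @param sf size factors from [size_factors()].
#' @param condition character/factor of per-sample conditions.
#' @param span loess span for the trend.
#' @return a `dispersion_fit`: data.frame with `baseMean`, `raw`, `trend`,
#'   `final` per variant plus a `prior_sd` attribute.  All-zero variants are
#'   flagged with NA dispersions.
#' @export
fit_dispersions <- function(counts, sf, condition, span = 0.5) {
  stopifnot(length(sf) == ncol(counts), length(condition) == ncol(counts))
  if (min(table(condition)) < 2L) {
    stop("need >= 2 samples per condition for dispersion estimation",
         call. = FALSE)
  }
  x <- stats::model.matrix(~ factor(condition))
  norm <- sweep(counts, 2L, sf, "/")
  base_mean <- rowMeans(norm)
  n_var <- nrow(counts)
  raw <- rep(NA_real_, n_var)
  log_bounds <- log(c(DISPERSION_FLOOR, 30))
  for (v in seq_len(n_var)) {
    k <- counts[v, ]
    if (all(k == 0L)) next
    mu <- fitted_means(k, sf, condition)
    opt <- stats::optimize(function(la) -nb_loglik(k, mu, exp(la), x),
                           interval = log_bounds)
    raw[v] <- exp(opt$minimum)
  }
  ok <- !is.na(raw)
  # fit the trend on variants with informative (above-floor) raw estimates
  informative <- ok & raw > DISPERSION_FLOOR * 10 & base_mean > 0
  trend <- rep(NA_real_, n_var)
  if (sum(informative) >= 10L) {
    lo <- stats::loess(log(raw[informative]) ~ log(base_mean[informative]),
                       span = span, family = "symmetric",
                       control = stats::loess.control(surface = "direct"))
    lx <- log(pmax(base_mean[ok], min(base_mean[informative])))
    lx <- pmin(lx, max(log(base_mean[informative])))
    trend[ok] <- exp(stats::predict(lo, lx))
  } else {
    # too few informative variants: fall back to their median (or floor)
    trend[ok] <- if (any(informative)) stats::median(raw[informative])
                 else DISPERSION_FLOOR
  }
  trend <- pmax(trend, DISPERSION_FLOOR)
  resid <- log(pmax(raw, DISPERSION_FLOOR)) - log(trend)
  resid_sd <- stats::mad(resid[informative], na.rm = TRUE)
  if (!is.finite(resid_sd)) resid_sd <- 1
  # prior width: spread of the log residuals in excess of the sampling
  # variance of a log-dispersion estimate at this sample size
  m <- ncol(counts); p <- ncol(x)
  prior_sd <- sqrt(max(resid_sd^2 - trigamma((m - p) / 2), 0.25))
  final <- rep(NA_real_, n_var)
  for (v in which(ok)) {
    k <- counts[v, ]
    if (resid[v] > 2 * resid_sd) {
      # dispersion outlier far above the trend: shrinking it would be
      # anti-conservative, keep the raw estimate
      final[v] <- max(raw[v], DISPERSION_FLOOR)
      next
    }
    mu <- fitted_means(k, sf, condition)
    lt <- log(trend[v])
    opt <- stats::optimize(
      function(la) -nb_loglik(k, mu, exp(la), x) +
        (la - lt)^2 / (2 * prior_sd^2),
      interval = log_bounds)
    final[v] <- max(exp(opt$minimum), DISPERSION_FLOOR)
  }
  out <- data.frame(key = rownames(counts), baseMean = base_mean,
                    raw = raw, trend = trend, final = final,
                    stringsAsFactors = FALSE)
  attr(out, "prior_sd") <- prior_sd
  class(out) <- c("dispersion_fit", "data.frame")
  out
}

#' Per-variant NB Wald test of condition effect
#'
#' Fits an NB GLM with log link and design `~ condition` (vehicle as
#' reference) per variant at the moderated dispersion, with log size factors
#' as offset, and Wald-tests the condition coefficient.  Fold changes are
#' reported in log2.  Variants that are all-zero in one condition get a
#' finite display estimate via a 0.5 pseudo-count (testing itself uses the
#' raw GLM) and are flagged.
#'
#' @param counts count matrix.
#' @param samples sample sheet (columns sample_id, condition) with
#'   conditions `dex` and `vehicle`.
#' @param fit a [fit_dispersions()] result.
#' @param sf size factors.
#' @return data.frame with key, baseMean, log2FoldChange, lfcSE, stat,
#'   pvalue, padj and `zero_condition` flag.
#' @export
test_differential <- function(counts, samples, fit, sf) {
  condition <- samples$condition[match(colnames(counts), samples$sample_id)]
  if (any(is.na(condition))) stop("sample sheet does not cover all columns",
                                  call. = FALSE)
  if (!all(sort(unique(condition)) == c("dex", "vehicle"))) {
    stop("conditions must be exactly {dex, vehicle}", call. = FALSE)
  }
  x <- stats::model.matrix(~ factor(condition, levels = c("vehicle", "dex")))
  colnames(x) <- c("intercept", "dex")
  off <- log(sf)
  n_var <- nrow(counts)
  beta <- se <- rep(NA_real_, n_var)
  zero_cond <- rep(FALSE, n_var)
  for (v in seq_len(n_var)) {
    k <- counts[v, ]
    if (all(k == 0L)) next
    alpha <- fit$final[v]
    zero_cond[v] <- any(tapply(k, condition, sum) == 0)
    fam <- MASS::negative.binomial(theta = 1 / max(alpha, DISPERSION_FLOOR))
    g <- tryCatch(
      suppressWarnings(stats::glm.fit(x, k, family = fam, offset = off,
                                      control = list(maxit = 50))),
      error = function(e) NULL)
    if (is.null(g) || any(is.na(g$coefficients))) next
    b <- g$coefficients["dex"]
    # Fisher information from the final IRLS weights: Var = (X'WX)^{-1}
    xw <- x * sqrt(g$weights)
    cov <- tryCatch(chol2inv(chol(crossprod(xw))), error = function(e) NULL)
    if (is.null(cov)) next
    beta[v] <- b / log(2)
    se[v] <- sqrt(cov[2, 2]) / log(2)
  }
  stat <- beta / se
  pvalue <- 2 * stats::pnorm(-abs(stat))
  padj <- rep(NA_real_, n_var)
  tested <- !is.na(pvalue)
  padj[tested] <- bh_adjust(pvalue[tested])
  # display-only moderation of infinite-looking effects for zero conditions
  if (any(zero_cond)) {
    for (v in which(zero_cond & !is.na(beta))) {
      k <- counts[v, ]
      m <- tapply((k + 0.5) / sf, condition, mean)
      beta[v] <- log2(m[["dex"]] / m[["vehicle"]])
    }
  }
  data.frame(key = rownames(counts), baseMean = fit$baseMean,
             log2FoldChange = beta, lfcSE = se, stat = stat,
             pvalue = pvalue, padj = padj, zero_condition = zero_cond,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector in [0, 1]; NaN is an error.
#' @return adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.nan(pvalues))) stop("NaN p-values", call. = FALSE)
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  n <- length(pvalues)
  if (n == 0L) return(numeric(0))
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * pvalues[o]))[ro]
}

#' Classify variants by significance and effect direction
#'
#' Flank mode: enhancing (padj < alpha, log2FC > 0), blunting (padj < alpha,
#' log2FC < 0), else neutral.  Because every flank construct carries a
#' functional binding site, "blunting" means lower activity relative to the
#' pool, not absolute repression (the pool-fraction normalisation makes
#' weak variants appear repressed); a warning records this caveat.
#'
#' Half-site mode bins significant variants by log2FC: `activated`
#' (>= 2), `weak` (0 < FC < 2) and `repressed` (< -2, flagged unreliable:
#' apparent repression in the screen was not recapitulated for individually
#' assayed variants), plus `other_significant` and `not_significant`.
#'
#' @param results a [test_differential()] data.frame.
#' @param alpha adjusted-p cutoff (default 0.01).
#' @param mode `"flank"` or `"halfsite"`.
#' @return `results` with a `class` column; class counts in the
#'   `class_counts` attribute.
#' @export
classify_variants <- function(results, alpha = 0.01,
                              mode = c("flank", "halfsite")) {
  mode <- match.arg(mode)
  sig <- !is.na(results$padj) & results$padj < alpha
  lfc <- results$log2FoldChange
  if (mode == "flank") {
    cls <- ifelse(sig & lfc > 0, "enhancing",
                  ifelse(sig & lfc < 0, "blunting", "neutral"))
    warning(paste("flank mode: 'blunting' is relative to the pool of",
                  "active constructs, not absolute repression"),
            call. = FALSE)
  } else {
    cls <- rep("not_significant", nrow(results))
    cls[sig & lfc >= 2] <- "activated"
    cls[sig & lfc > 0 & lfc < 2] <- "weak"
    cls[sig & lfc < -2] <- "repressed"
    cls[sig & !(lfc >= 2 | (lfc > 0 & lfc < 2) | lfc < -2)] <-
      "other_significant"
    if (any(cls == "repressed")) {
      warning("'repressed' half-site calls are flagged unreliable",
              call. = FALSE)
    }
  }
  results$class <- cls
  attr(results, "class_counts") <- table(cls)
  results
}

#' Pearson correlations between replicate pairs
#'
#' QC statistic: correlation of log10(count + 1) between every pair of
#' replicates within each condition.  Reported, never gating.
#'
#' @param counts count matrix.
#' @param samples sample sheet.
#' @return data.frame with condition, sample pair and correlation r.
#' @export
replicate_correlations <- function(counts, samples) {
  out <- list()
  for (cond in unique(samples$condition)) {
    ids <- samples$sample_id[samples$condition == cond]
    if (length(ids) < 2L) next
    pairs <- utils::combn(ids, 2L)
    for (p in seq_len(ncol(pairs))) {
      r <- stats::cor(log10(counts[, pairs[1, p]] + 1),
                      log10(counts[, pairs[2, p]] + 1))
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, sample1 = pairs[1, p], sample2 = pairs[2, p],
        r = r, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Full differential-activity pipeline on a count matrix
#'
#' Convenience wrapper: size factors, dispersion fit, Wald tests,
#' classification.
#'
#' @param counts count matrix.
#' @param samples sample sheet.
#' @param alpha adjusted-p cutoff.
#' @param mode classification mode (see [classify_variants()]).
#' @return classified results data.frame (see [classify_variants()]).
#' @export
differential_activity <- function(counts, samples, alpha = 0.01,
                                  mode = "flank") {
  sf <- size_factors(counts)
  condition <- samples$condition[match(colnames(counts), samples$sample_id)]
  fit <- fit_dispersions(counts, sf, condition)
  res <- test_differential(counts, samples, fit, sf)
  suppressWarnings(classify_variants(res, alpha = alpha, mode = mode))
}
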
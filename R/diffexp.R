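# Differential expression between two unreplicated pooled libraries.
#
# The two libraries are first equalized to the geometric-mean library size
# (deterministic round-half-even scaling). Conditional on the equalized total
# s = a' + b', each side is modeled as an independent negative binomial with
# mean s/2 and dispersion phi; the two-sided p-value is the total conditional
# probability of all outcomes x in 0..s whose probability does not exceed
# that of the observed split (the probability-mass criterion). At phi = 0 the
# conditional law is Binomial(s, 1/2) and the test reduces to the binomial
# conditional exact test. The design has no replicates, so phi cannot be
# estimated from the data; it is an explicit, documented parameter and all
# results are conditional on its value.

#' Differential-expression configuration
#'
#' @param phi Negative-binomial dispersion assumed by the exact test
#'   (0 = Poisson/binomial limit). With single pooled libraries per group the
#'   dispersion is not estimable from the data; the default 0.1 is a
#'   conventional value for biological-replicate-free designs and results
#'   should be read as conditional on it.
#' @param alpha_p P-value threshold.
#' @param alpha_fdr FDR threshold.
#' @param min_abs_log2fc Minimum absolute log2 fold change.
#' @param pseudo Pseudo-count added to RPM before log2 transforms.
#' @return A list of class `de_config`.
#' @export
de_config <- function(phi = 0.1, alpha_p = 0.05, alpha_fdr = 0.05,
                      min_abs_log2fc = 1, pseudo = 0.1) {
  stopifnot(phi >= 0, alpha_p > 0, alpha_p < 1, alpha_fdr > 0, alpha_fdr < 1,
            min_abs_log2fc >= 0, pseudo > 0)
  structure(list(phi = phi, alpha_p = alpha_p, alpha_fdr = alpha_fdr,
                 min_abs_log2fc = min_abs_log2fc, pseudo = pseudo),
            class = "de_config")
}

#' Conditional exact test for a pair of counts
#'
#' @param countA,countB Observed counts (nonnegative integers).
#' @param libA,libB Library sizes (clean-read totals, > 0).
#' @param phi Negative-binomial dispersion (0 for the binomial limit).
#' @return Two-sided p-value in (0, 1].
#' @examples
#' exact_nb_test(5, 5, 1e6, 1e6, phi = 0.1)   # 1: observed split is the mode
#' exact_nb_test(0, 20, 1e6, 1e6, phi = 0)    # binomial conditional test
#' @export
exact_nb_test <- function(countA, countB, libA, libB, phi = 0.1) {
  if (countA < 0 || countB < 0) stop("counts must be nonnegative")
  if (libA <= 0 || libB <= 0) stop("library sizes must be positive")
  if (phi < 0) stop("phi must be nonnegative")
  g <- sqrt(libA * libB)
  a <- round(countA * g / libA)  # round-half-even
  b <- round(countB * g / libB)
  s <- a + b
  if (s == 0) return(1)
  x <- 0:s
  pr <- conditional_probs(x, s, phi)
  obs <- pr[a + 1L]
  # include exact symmetric ties; tolerance guards float noise only
  p <- sum(pr[pr <= obs * (1 + 1e-12)])
  min(1, max(p, .Machine$double.xmin))
}

# unnormalized-then-normalized conditional probabilities of x given x+y=s
conditional_probs <- function(x, s, phi) {
  if (phi == 0) {
    pr <- dbinom(x, size = s, prob = 0.5)
  } else {
    size <- 1 / phi
    mu <- s / 2
    pr <- dnbinom(x, size = size, mu = mu) *
      dnbinom(s - x, size = size, mu = mu)
    tot <- sum(pr)
    if (tot <= 0) stop("conditional probabilities underflowed at s = ", s)
    pr <- pr / tot
  }
  pr
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' MA values of a feature
#'
#' M = log2((rpmA + pseudo) / (rpmB + pseudo));
#' A = mean of the two log2(RPM + pseudo) values.
#'
#' @param rpmA,rpmB Nonnegative RPM values (vectorized).
#' @param pseudo Pseudo-count (default 0.1).
#' @return List with numeric vectors `M` and `A`.
#' @export
ma_values <- function(rpmA, rpmB, pseudo = 0.1) {
  stopifnot(all(rpmA >= 0), all(rpmB >= 0), pseudo > 0)
  la <- log2(rpmA + pseudo)
  lb <- log2(rpmB + pseudo)
  list(M = la - lb, A = (la + lb) / 2)
}

#' Heatmap-ready expression matrix
#'
#' Drops features whose RPM is below `min_rpm` in every group, then
#' transforms the remaining cells as log2(RPM + pseudo).
#'
#' @param expression An `expression_matrix` (see
#'   [build_expression_matrix()]) or a numeric RPM matrix.
#' @param pseudo Pseudo-count (default 0.1).
#' @param min_rpm Low-abundance floor (default 1 RPM).
#' @return Numeric matrix of log2(RPM + pseudo) values.
#' @export
heatmap_matrix <- function(expression, pseudo = 0.1, min_rpm = 1) {
  rpm <- if (inherits(expression, "expression_matrix")) expression$rpm else expression
  stopifnot(is.matrix(rpm), all(rpm >= 0))
  keep <- apply(rpm, 1L, function(r) any(r >= min_rpm))
  log2(rpm[keep, , drop = FALSE] + pseudo)
}

#' Cumulative frequency of feature abundances
#'
#' Empirical cumulative distribution over log2(RPM + pseudo), plus the
#' fraction of features below 1 RPM.
#'
#' @param rpms Nonempty numeric vector of RPM values.
#' @param pseudo Pseudo-count (default 0.1).
#' @return List with `ecdf` (a function, from [stats::ecdf()]), `table`
#'   (data frame `log2_rpm`, `cum_frequency`) and `frac_below_1rpm`.
#' @export
cumulative_frequency <- function(rpms, pseudo = 0.1) {
  if (!length(rpms)) stop("empty input")
  stopifnot(all(rpms >= 0))
  v <- sort(log2(rpms + pseudo))
  fn <- ecdf(v)
  list(ecdf = fn,
       table = data.frame(log2_rpm = v, cum_frequency = fn(v)),
       frac_below_1rpm = mean(rpms < 1))
}

#' Pearson correlation of two RPM profiles
#'
#' @param rpmsA,rpmsB Equal-length numeric vectors (n >= 2), raw RPM by
#'   default.
#' @param log Transform both sides as log2(RPM + pseudo) first.
#' @param pseudo Pseudo-count for the log option.
#' @return Product-moment correlation coefficient.
#' @export
pearson_correlation <- function(rpmsA, rpmsB, log = FALSE, pseudo = 0.1) {
  if (length(rpmsA) != length(rpmsB)) stop("length mismatch")
  if (length(rpmsA) < 2L) stop("need at least two features")
  if (log) {
    rpmsA <- log2(rpmsA + pseudo)
    rpmsB <- log2(rpmsB + pseudo)
  }
  if (sd(rpmsA) == 0 || sd(rpmsB) == 0) stop("zero variance")
  cor(rpmsA, rpmsB, method = "pearson")
}

#' Flag significant features
#'
#' A feature is significant when p < alpha_p, FDR < alpha_fdr and
#' |M| >= min_abs_log2fc.
#'
#' @param results Data frame with columns `p`, `fdr`, `M`.
#' @param config A [de_config()].
#' @return The data frame with `significant` and `direction`
#'   (`"up"`/`"down"`/`"ns"`, sign of M read as A over B) plus a summary
#'   attribute `de_summary` (n up / n down).
#' @export
call_significant <- function(results, config = de_config()) {
  stopifnot(all(c("p", "fdr", "M") %in% names(results)))
  sig <- results$p < config$alpha_p &
    results$fdr < config$alpha_fdr &
    abs(results$M) >= config$min_abs_log2fc
  results$significant <- sig
  results$direction <- ifelse(!sig, "ns", ifelse(results$M > 0, "up", "down"))
  attr(results, "de_summary") <- c(up = sum(sig & results$M > 0),
                                   down = sum(sig & results$M < 0))
  results
}

#' Differential expression between two pooled libraries
#'
#' Runs the conditional exact test per feature, adjusts with
#' Benjamini-Hochberg, computes RPM-based M/A values and applies the
#' significance thresholds.
#'
#' @param countsA,countsB Named integer vectors of per-feature counts
#'   (features are unioned; absent = 0).
#' @param libA,libB Clean-read totals of the two libraries.
#' @param config A [de_config()].
#' @return Data frame (one row per feature): `feature_id`, `countA`,
#'   `countB`, `rpmA`, `rpmB`, `M`, `A`, `p`, `fdr`, `significant`,
#'   `direction`; with the `de_summary` attribute of [call_significant()].
#' @export
run_diffexp <- function(countsA, countsB, libA, libB, config = de_config()) {
  features <- sort(union(names(countsA), names(countsB)))
  if (!length(features)) stop("no features")
  a <- setNames(rep(0L, length(features)), features)
  b <- a
  a[names(countsA)] <- countsA
  b[names(countsB)] <- countsB
  rpmA <- rpm_normalize(a, libA)
  rpmB <- rpm_normalize(b, libB)
  ma <- ma_values(rpmA, rpmB, pseudo = config$pseudo)
  p <- vapply(seq_along(features), function(i) {
    exact_nb_test(a[i], b[i], libA, libB, phi = config$phi)
  }, numeric(1))
  res <- data.frame(feature_id = features,
                    countA = as.integer(a), countB = as.integer(b),
                    rpmA = unname(rpmA), rpmB = unname(rpmB),
                    M = unname(ma$M), A = unname(ma$A),
                    p = p, fdr = bh_fdr(p),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  call_significant(res, config)
}
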
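#' Cohen's kappa from a square cross-table
#'
#' Chance-corrected agreement: kappa = (p_o - p_e) / (1 - p_e) with
#' expected agreement from the marginal products. When both observed and
#' chance agreement are exactly 1 the statistic is defined as 1.
#'
#' @param cross_table square matrix or table of counts (raters in rows and
#'   columns, same category order).
#' @return kappa in \[-1, 1\].
#' @examples
#' cohen_kappa(matrix(c(45, 5, 5, 45), 2))  # 0.8
#' @export
cohen_kappa <- function(cross_table) {
  tab <- as.matrix(cross_table)
  if (nrow(tab) != ncol(tab)) stop("cross-table must be square")
  n <- sum(tab)
  if (n < 1) stop("cross-table is empty")
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < 1e-12) return(if (p_o >= 1 - 1e-12) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

#' Verbal strength-of-agreement label for a kappa value
#'
#' Landis-Koch conventions: <0 poor, 0-0.20 slight, 0.21-0.40 fair,
#' 0.41-0.60 moderate, 0.61-0.80 substantial, 0.81-1 almost perfect.
#'
#' @param kappa numeric vector.
#' @return character vector of labels.
#' @export
kappa_label <- function(kappa) {
  cut(kappa, breaks = c(-Inf, 0, 0.2, 0.4, 0.6, 0.8, Inf),
      labels = c("poor", "slight", "fair", "moderate", "substantial",
                 "almost perfect")) |> as.character()
}

check_pairs <- function(a, b, min_n = 1) {
  keep <- !is.na(a) & !is.na(b)
  if (sum(keep) < min_n) {
    stop("need at least ", min_n, " complete rating pair(s)")
  }
  list(a = a[keep], b = b[keep])
}

#' Kappa for continuous gradings agreeing within a tolerance
#'
#' Two variants of chance-corrected within-delta agreement for continuous
#' grades (e.g. VCDR "within 0.1"):
#' * `"binned"` (default): values are binned into delta-width bins aligned
#'   to the recording grid and Cohen's kappa is computed on the binned
#'   square table;
#' * `"collapse"`: observed agreement is the fraction of pairs with
#'   `|a - b| <= delta`; chance agreement is the probability of within-delta
#'   agreement under independent draws from the two empirical marginal
#'   distributions; kappa corrects one by the other.
#'
#' @param a,b paired gradings (same length).
#' @param delta positive tolerance.
#' @param method `"binned"` or `"collapse"`.
#' @return kappa.
#' @export
kappa_within_tolerance <- function(a, b, delta,
                                   method = c("binned", "collapse")) {
  method <- match.arg(method)
  if (delta <= 0) stop("delta must be positive")
  p <- check_pairs(a, b)
  if (method == "binned") {
    lo <- min(p$a, p$b)
    bins <- function(v) floor((v - lo) / delta + 1e-9)
    all_bins <- sort(unique(c(bins(p$a), bins(p$b))))
    ta <- factor(bins(p$a), levels = all_bins)
    tb <- factor(bins(p$b), levels = all_bins)
    cohen_kappa(table(ta, tb))
  } else {
    p_o <- mean(abs(p$a - p$b) <= delta + 1e-9)
    da <- table(p$a) / length(p$a)
    db <- table(p$b) / length(p$b)
    va <- as.numeric(names(da)); vb <- as.numeric(names(db))
    agree <- abs(outer(va, vb, `-`)) <= delta + 1e-9
    p_e <- sum(outer(as.numeric(da), as.numeric(db)) * agree)
    if (abs(1 - p_e) < 1e-12) return(if (p_o >= 1 - 1e-12) 1 else 0)
    (p_o - p_e) / (1 - p_e)
  }
}

#' Kappa after dichotomizing both raters at a cut point
#'
#' E.g. clinical VCDR classified as >= 0.6 versus < 0.6 by two observers.
#'
#' @param a,b paired gradings.
#' @param cut dichotomization point (`>= cut` vs `< cut`).
#' @return kappa.
#' @export
kappa_dichotomized <- function(a, b, cut) {
  p <- check_pairs(a, b)
  ta <- factor(p$a >= cut, levels = c(FALSE, TRUE))
  tb <- factor(p$b >= cut, levels = c(FALSE, TRUE))
  cohen_kappa(table(ta, tb))
}

#' Bland-Altman limits of agreement
#'
#' Bias is the mean paired difference `a - b`; the limits are
#' bias +/- 1.96 standard deviations of the differences, expected to
#' bracket about 95\% of differences for approximately normal differences.
#'
#' @param a,b paired continuous measurements.
#' @return list with `bias`, `lo_limit`, `hi_limit`, `sd`, `n`.
#' @export
bland_altman <- function(a, b) {
  p <- check_pairs(a, b, min_n = 2)
  d <- p$a - p$b
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, lo_limit = bias - 1.96 * s, hi_limit = bias + 1.96 * s,
       sd = s, n = length(d))
}

#' Percent of pairs agreeing within a tolerance
#'
#' @param a,b paired continuous measurements.
#' @param delta non-negative tolerance.
#' @return percent of pairs with `|a - b| <= delta`.
#' @export
proportion_within <- function(a, b, delta) {
  if (delta < 0) stop("delta must be non-negative")
  p <- check_pairs(a, b)
  100 * mean(abs(p$a - p$b) <= delta + 1e-9)
}
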
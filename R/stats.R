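#' Rank values in descending order with average ties
#'
#' Rank 1 is assigned to the largest value; tied values receive the average of
#' the ranks they span. This is the ranking used throughout the rank-product
#' tier, where per-pair log-ratios are converted to gene ranks.
#'
#' @param values Numeric vector, finite, non-empty.
#' @return Numeric vector of ranks (possibly fractional under ties).
#' @examples
#' rank_descending(c(3, 2, 1))   # 1 2 3
#' rank_descending(c(5, 5, 1))   # 1.5 1.5 3
#' @export
rank_descending <- function(values) {
  if (length(values) == 0L) stop("values must be non-empty")
  if (anyNA(values) || any(!is.finite(values))) stop("values must be finite (no NA/NaN)")
  rank(-values, ties.method = "average")
}

#' One-sided Fisher's exact test for enrichment
#'
#' Upper-tail hypergeometric probability of the in-both cell `a` of a 2x2
#' table given its margins: P(X >= a) where X ~ Hypergeometric. Used for every
#' enrichment claim in the pipeline (TF targets in a pathway, a query list in
#' a reference list). Degenerate margins (an empty query or empty reference)
#' return p = 1: no overlap is possible, hence no evidence, never an error.
#'
#' @param a,b,c,d Non-negative integer counts; `a` is the in-both cell, `b`
#'   completes the reference row, `c` completes the query column, `d` the rest
#'   of the universe.
#' @return One-sided p-value in (0, 1].
#' @export
fisher_greater <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0) || any(cells != floor(cells)))
    stop("cells must be non-negative integers")
  if (sum(cells) == 0) stop("empty table")
  if (a + b == 0 || a + c == 0) return(1)
  # draw (a+c) balls from an urn with (a+b) white and (c+d) black
  stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR adjustment: p_(i) * m / i, cumulative minimum from the
#' largest p downwards, capped at 1. Implemented directly so the test suite
#' can check it against an independent route.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * m / seq(m, 1)))
  adj[order(o)]
}

#' ROC AUC via the Mann-Whitney statistic
#'
#' AUC = P(score_pos > score_neg) + 0.5 P(tie), computed from rank sums.
#' Invariant under any strictly increasing transform of the scores.
#'
#' @param scores Numeric vector of classifier scores (larger = more positive).
#' @param labels Logical or character vector; `TRUE`/"positive"/"disease"
#'   marks positives.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.character(labels) %in% c("positive", "disease", "1", "TRUE")
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("need at least one positive and one negative label")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' One-sample t-test of a null distribution against an observed value
#'
#' Tests whether the mean of `null_values` lies below `observed`; returns the
#' one-sided lower-tail p-value. Used to compare the null AUC distribution of
#' random gene signatures against the AUC of the consensus signature.
#'
#' @param null_values Numeric vector (>= 3 values, nonzero variance).
#' @param observed Single numeric value.
#' @return One-sided p-value.
#' @export
one_sample_t <- function(null_values, observed) {
  n <- length(null_values)
  if (n < 3) stop("need at least 3 null values")
  s <- stats::sd(null_values)
  if (s == 0) stop("null values have zero variance")
  tstat <- (mean(null_values) - observed) / (s / sqrt(n))
  stats::pt(tstat, df = n - 1)
}
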
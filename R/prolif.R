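#' Chi-squared test of homogeneity for EdU proliferation counts
#'
#' Pearson chi-squared test on the groups x {EdU+, EdU-} contingency table,
#' asking whether all genotypes share one EdU-positive proportion.  Yates
#' continuity correction is applied for 2x2 tables only, never for larger
#' ones (the convention of `chisq.test`, which the downstream comparisons
#' assume).
#'
#' @param counts count table with columns `group`, `edu_pos`, `edu_neg`
#'   (see [read_edu_counts()]).
#' @return list: `statistic`, `df`, `p`, `n_groups`.
#' @export
chisq_homogeneity <- function(counts) {
  counts <- validate_edu_table(counts)
  m <- as.matrix(counts[c("edu_pos", "edu_neg")])
  rownames(m) <- counts$group
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate table: a zero row or column margin", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), n_groups = nrow(m))
}

#' Post-hoc pairwise chi-squared comparisons
#'
#' Every unordered pair of groups is tested as a 2x2 table (with continuity
#' correction); P values are Benjamini-Hochberg corrected across the pairs
#' of this table.  A degenerate pair (zero margin) is flagged with `NA`
#' P values; the remaining pairs are still reported.
#'
#' @param counts count table with columns `group`, `edu_pos`, `edu_neg`.
#' @return `data.frame`: `group1`, `group2`, `statistic`, `p_raw`, `p_adj`.
#' @export
posthoc_pairwise <- function(counts) {
  counts <- validate_edu_table(counts)
  pairs <- utils::combn(counts$group, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    sub <- counts[counts$group %in% pairs[, i], , drop = FALSE]
    res <- tryCatch(chisq_homogeneity(sub),
                    error = function(e) list(statistic = NA_real_, p = NA_real_))
    data.frame(group1 = pairs[1L, i], group2 = pairs[2L, i],
               statistic = res$statistic, p_raw = res$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_bh(out$p_raw)
  rownames(out) <- NULL
  out
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Boundary-safe at observed proportions of 0 and 100% (unlike the Wald
#' interval); always a strict subset of `[0, 1]` containing the point
#' estimate.  A Wald interval is available behind `method`.
#'
#' @param x number of successes (e.g. EdU-positive cells).
#' @param n total count, at least 1.
#' @param level confidence level, default 0.95.
#' @param method `"wilson"` (default) or `"wald"`.
#' @return named numeric `c(lo, hi)`.
#' @export
proportion_ci <- function(x, n, level = 0.95, method = c("wilson", "wald")) {
  method <- match.arg(method)
  if (n < 1 || x < 0 || x > n)
    stop_param("x,n", "need 0 <= x <= n and n >= 1")
  if (level <= 0 || level >= 1)
    stop_param("level", "must be in (0, 1)")
  p <- x / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "wald") {
    se <- sqrt(p * (1 - p) / n)
    return(c(lo = max(0, p - z * se), hi = min(1, p + z * se)))
  }
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # analytically lo = 0 when x = 0 and hi = 1 when x = n; pin the boundary
  # cases so floating point cannot push the point estimate outside
  lo <- if (x == 0) 0 else max(0, centre - half)
  hi <- if (x == n) 1 else min(1, centre + half)
  c(lo = lo, hi = hi)
}
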
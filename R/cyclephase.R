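#' Percentile ranks of a numeric vector
#'
#' Hazen definition: `(rank - 0.5) / N` with average ranks for ties.  With
#' this definition the median percentile rank of any distinct-valued vector
#' is exactly 0.5, which is the null anchor the phase-enrichment test
#' compares against.  The percent-rank variant `(rank - 1) / (N - 1)` is
#' available for compatibility with tools that use it.
#'
#' @param x numeric vector, length >= 1, no NA.
#' @param method `"hazen"` (default) or `"percent"`.
#' @return numeric vector of ranks in (0, 1) (`[0, 1]` for `"percent"`),
#'   order-preserving.
#' @export
percentile_rank <- function(x, method = c("hazen", "percent")) {
  method <- match.arg(method)
  if (length(x) == 0L)
    stop_param("x", "empty vector")
  if (any(!is.finite(x)))
    stop_param("x", "values must be finite")
  r <- rank(x, ties.method = "average")
  switch(method,
         hazen = (r - 0.5) / length(x),
         percent = if (length(x) == 1L) 0.5 else (r - 1) / (length(x) - 1))
}

# One-sample Wilcoxon signed-rank test of x against mu, two-sided.
# Zero differences are dropped (classical convention); the exact null
# distribution is used for n <= `exact_max` after zero removal when there are
# no ties among the absolute differences, otherwise the normal approximation
# with tie and continuity correction.
signed_rank_test <- function(x, mu = 0, exact_max = 25) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  if (n < 1L) return(list(p = 1, n_used = 0L, method = "degenerate"))
  use_exact <- n <= exact_max && !anyDuplicated(abs(d))
  ht <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  list(p = unname(ht$p.value), n_used = n,
       method = if (use_exact) "exact" else "normal")
}

#' Cell-cycle-phase percentile-rank enrichment
#'
#' Ranks every gene in the table by log2 fold change (WT/KO) using
#' [percentile_rank()], then, for each phase gene set, tests whether that
#' phase's ranks differ from the genome-wide median (0.5) with a two-sided
#' one-sample Wilcoxon signed-rank test; P values are Benjamini-Hochberg
#' corrected across the phases tested in this call.  A phase whose median
#' rank sits above 0.5 means the perturbed factor downregulates that phase's
#' program (WT/KO orientation), below 0.5 that it upregulates it.
#'
#' Phases with fewer than 2 usable member genes are flagged untestable
#' (P `NA`), never dropped silently.  Genes belonging to several phases are
#' tested in each phase independently.
#'
#' @param d DE table; ranks are computed over all genes with non-missing
#'   log2fc.
#' @param phases named list of gene-id vectors (one set per phase).
#' @param anchor null median; 0.5 unless ranks were transformed.
#' @param rank_method passed to [percentile_rank()].
#' @return `data.frame` with one row per phase: `phase`, `n_genes_tested`,
#'   `median_rank`, `q1`, `q3`, `p_raw`, `p_adj`, in canonical phase order
#'   (G1/S, S, G2, M, M/G1) when those labels are used, else input order.
#' @export
phase_enrichment <- function(d, phases, anchor = 0.5,
                             rank_method = c("hazen", "percent")) {
  rank_method <- match.arg(rank_method)
  d <- validate_de_table(d)
  stopifnot(is.list(phases), !is.null(names(phases)))
  usable <- !is.na(d$log2fc)
  if (!any(usable)) stop("no genes with usable log2fc", call. = FALSE)
  genes <- d$gene[usable]
  ranks <- stats::setNames(percentile_rank(d$log2fc[usable], rank_method), genes)

  canonical <- c("G1/S", "S", "G2", "M", "M/G1")
  ord <- if (all(names(phases) %in% canonical))
    names(phases)[order(match(names(phases), canonical))] else names(phases)
  if (!any(vapply(phases, function(g) any(g %in% genes), logical(1L))))
    stop("no phase set intersects the table's genes", call. = FALSE)

  rows <- lapply(ord, function(ph) {
    r <- ranks[intersect(phases[[ph]], genes)]
    n <- length(r)
    if (n < 2L) {
      return(data.frame(phase = ph, n_genes_tested = n,
                        median_rank = if (n) unname(r) else NA_real_,
                        q1 = NA_real_, q3 = NA_real_,
                        p_raw = NA_real_, p_adj = NA_real_,
                        stringsAsFactors = FALSE))
    }
    qs <- unname(stats::quantile(r, c(0.25, 0.5, 0.75), type = 7))
    data.frame(phase = ph, n_genes_tested = n,
               median_rank = qs[2L], q1 = qs[1L], q3 = qs[3L],
               p_raw = signed_rank_test(r, mu = anchor)$p,
               p_adj = NA_real_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_bh(out$p_raw)
  rownames(out) <- NULL
  out
}
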
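#' One-tailed hypergeometric gene-set overlap test
#'
#' Upper-tail probability of observing at least the seen intersection between
#' two gene sets drawn from a common universe: `P(X >= k)` where `X` is
#' hypergeometric with population `|universe|`, `|A|` successes and `|B|`
#' draws.  Computed through the survival function at `k - 1`
#' (`phyper(k - 1, ..., lower.tail = FALSE)`), which is the ">= k" tail
#' without the off-by-one the direct formulation invites.  Members outside
#' the universe are dropped (their count is reported).
#'
#' @param set_a,set_b character vectors of gene ids.
#' @param universe character vector; the population both sets are tested
#'   against.  For cross-dataset comparisons use the genes expressed in both
#'   merged datasets.
#' @return list of class `"overlap_test"`: `n_universe`, `n_a`, `n_b`,
#'   `n_overlap`, `expected`, `fold_enrichment`, `p` (upper tail), and
#'   `n_dropped_a`/`n_dropped_b` (members outside the universe).
#' @export
hypergeom_overlap <- function(set_a, set_b, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L)
    stop_param("universe", "empty universe")
  a0 <- unique(as.character(set_a)); b0 <- unique(as.character(set_b))
  a <- intersect(a0, universe); b <- intersect(b0, universe)
  dropped <- c(length(a0) - length(a), length(b0) - length(b))
  if (any(dropped > 0))
    message(sprintf("dropped %d/%d set members outside the universe",
                    dropped[1L], dropped[2L]))
  k <- length(intersect(a, b))
  nu <- length(universe)
  expected <- length(a) * length(b) / nu
  structure(list(
    n_universe = nu, n_a = length(a), n_b = length(b), n_overlap = k,
    expected = expected,
    fold_enrichment = if (expected > 0) k / expected else NA_real_,
    p = stats::phyper(k - 1, length(a), nu - length(a), length(b),
                      lower.tail = FALSE),
    n_dropped_a = dropped[1L], n_dropped_b = dropped[2L]),
    class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("Hypergeometric overlap: %d of %d x %d in universe %d (expected %.2f)\n",
              x$n_overlap, x$n_a, x$n_b, x$n_universe, x$expected))
  cat(sprintf("  fold enrichment %.3g, upper-tail P = %.4g\n",
              x$fold_enrichment, x$p))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Classical step-up false-discovery-rate correction.  Missing entries are
#' passed through as `NA` and excluded from the family size `m`.
#'
#' @param p numeric vector of P values in `[0, 1]` (NA allowed).
#' @return adjusted P values, same length and order as the input.
#' @export
adjust_bh <- function(p) {
  if (!is.numeric(p)) stop_param("p", "must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop_param("p", "entries must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Fraction of a target gene set carrying an annotation
#'
#' `|target intersect annotation| / |target|`, with both counts reported —
#' e.g. the fraction of genes upregulated by two factors that are also
#' direct targets of a third.
#'
#' @param target character vector (non-empty).
#' @param annotation character vector.
#' @return list: `fraction`, `n_target`, `n_annotated`.
#' @export
set_fraction <- function(target, annotation) {
  target <- unique(as.character(target))
  if (length(target) == 0L) stop_param("target", "empty target set")
  k <- length(intersect(target, unique(as.character(annotation))))
  list(fraction = k / length(target), n_target = length(target),
       n_annotated = k)
}
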
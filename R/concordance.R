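#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (tie-aware); pairs with any
#' missing value are dropped.
#'
#' @param x,y numeric vectors of equal length; at least 3 complete pairs.
#' @return Spearman rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop_param("x,y", "lengths differ")
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3L)
    stop("fewer than 3 complete pairs", call. = FALSE)
  stats::cor(x[ok], y[ok], method = "spearman")
}

# rho for a subset of pre-extracted complete columns (hot loop helper).
# A vector whose values are all tied has zero rank variance and an undefined
# rho; 0 (the centre of the permutation null) is used by convention so that
# rare all-tied bootstrap draws do not poison the null moments.
.rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) return(0)
  stats::cor(rx, ry)
}

#' Bootstrap-null concordance of two datasets' fold changes
#'
#' Computes the Spearman rho between the two datasets' log2 fold changes over
#' a selected gene set (typically the genes statistically dependent on the
#' predictor-dataset factor), then calibrates it against an empirical null:
#' `n_iter` gene sets of the same size are sampled (without replacement
#' within a draw) from all merged genes, a rho is computed for each, and the
#' observed rho is expressed as a Z-score against the null mean and SD.  The
#' one-sided upper-tail P is reported on the natural-log scale
#' (`pnorm(z, lower.tail = FALSE, log.p = TRUE)`), never exponentiated
#' internally, so it stays meaningful at |Z| well above 8.
#'
#' @param merged merged table from [merge_by_gene()].
#' @param selected character vector of gene ids (subset of `merged$gene`),
#'   at least 3.
#' @param n_iter number of null draws; at least 100.  100,000 gives a null
#'   mean/SD stable to well past 2 significant figures.
#' @param seed integer seed for the null draws.
#' @param labels length-2 dataset labels; defaults to the merged table's.
#' @return object of class `"concordance"`: `n_selected`, `rho`,
#'   `null_mean`, `null_sd`, `n_null_draws`, `z_score`, `log_p_one_sided`,
#'   `seed`.
#' @export
bootstrap_null_concordance <- function(merged, selected, n_iter = 100000,
                                       seed = 1, labels = NULL) {
  if (is.null(labels)) labels <- attr(merged, "labels")
  if (is.null(labels)) stop("dataset labels not found; pass `labels`",
                            call. = FALSE)
  if (n_iter < 100) stop_param("n_iter", "must be at least 100")
  ca <- merged_cols(merged, labels[1L]); cb <- merged_cols(merged, labels[2L])
  ok <- stats::complete.cases(ca$log2fc, cb$log2fc)
  genes <- merged$gene[ok]
  x <- ca$log2fc[ok]; y <- cb$log2fc[ok]
  selected <- unique(as.character(selected))
  if (!all(selected %in% genes))
    stop("`selected` contains genes absent from the merged table",
         call. = FALSE)
  k <- length(selected)
  if (k < 3L) stop("need at least 3 selected genes", call. = FALSE)
  idx <- match(selected, genes)
  rho_obs <- .rho(x[idx], y[idx])
  n <- length(genes)
  null_rhos <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      j <- sample.int(n, k)
      .rho(x[j], y[j])
    }, numeric(1L))
  })
  mu <- mean(null_rhos); sdev <- stats::sd(null_rhos)
  if (!is.finite(sdev) || sdev == 0)
    stop("degenerate null: all null draws give the same rho (is `selected` the whole universe?)",
         call. = FALSE)
  z <- (rho_obs - mu) / sdev
  structure(list(n_selected = k, rho = rho_obs, null_mean = mu,
                 null_sd = sdev, n_null_draws = as.integer(n_iter),
                 z_score = z,
                 log_p_one_sided = stats::pnorm(z, lower.tail = FALSE,
                                                log.p = TRUE),
                 seed = as.integer(seed)),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f over %d genes\n", x$rho, x$n_selected))
  cat(sprintf("  bootstrap null (%d draws): mean %.4f, sd %.4f\n",
              x$n_null_draws, x$null_mean, x$null_sd))
  cat(sprintf("  Z = %.2f, one-sided ln P = %.2f\n",
              x$z_score, x$log_p_one_sided))
  invisible(x)
}

#' Attenuation-slope linear model
#'
#' Ordinary least squares of one dataset's log2 fold changes on the other's
#' over a selected gene set:
#' `log2fc_response ~ beta0 + beta * log2fc_predictor`.  When the selected
#' set is the predictor factor's dependent genes, a slope of 1 means the
#' response perturbation reproduces the predictor factor's transcriptional
#' program in full; a slope in (0, 1) means partial retention (attenuation).
#' The 95% CI uses the t distribution with n - 2 df.
#'
#' @param merged merged table from [merge_by_gene()].
#' @param selected gene ids to fit over; at least 3 complete pairs.
#' @param response,predictor dataset labels in the merged table.
#' @param level confidence level for the slope CI.
#' @return object of class `"attenuation_fit"`: `beta0`, `beta`, `ci95`
#'   (lo, hi), `n`, `r_squared`, `response`, `predictor`, and the underlying
#'   `lm` fit as `$model`.
#' @export
attenuation_fit <- function(merged, selected, response, predictor,
                            level = 0.95) {
  cr <- merged_cols(merged, response); cp <- merged_cols(merged, predictor)
  selected <- unique(as.character(selected))
  idx <- match(selected, merged$gene)
  if (anyNA(idx))
    stop("`selected` contains genes absent from the merged table",
         call. = FALSE)
  df <- data.frame(y = cr$log2fc[idx], x = cp$log2fc[idx])
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < 3L) stop("fewer than 3 complete pairs", call. = FALSE)
  if (stats::var(df$x) == 0)
    stop("zero predictor variance: singular fit", call. = FALSE)
  fit <- stats::lm(y ~ x, data = df)
  # summary()/confint() warn on noiseless (zero-residual) fits; those are
  # legitimate inputs here (identity checks, planted noise-free data)
  ci <- suppressWarnings(stats::confint(fit, "x", level = level))
  structure(list(beta0 = unname(stats::coef(fit)[1L]),
                 beta = unname(stats::coef(fit)[2L]),
                 ci95 = c(lo = ci[1L], hi = ci[2L]),
                 n = nrow(df),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 response = response, predictor = predictor,
                 model = fit),
            class = "attenuation_fit")
}

#' @export
print.attenuation_fit <- function(x, ...) {
  cat(sprintf("Attenuation fit: log2fc[%s] ~ %.3f + %.3f * log2fc[%s]  (n = %d)\n",
              x$response, x$beta0, x$beta, x$predictor, x$n))
  cat(sprintf("  slope 95%% CI: %.3f-%.3f, R^2 = %.3f\n",
              x$ci95[["lo"]], x$ci95[["hi"]], x$r_squared))
  invisible(x)
}

#' @export
coef.attenuation_fit <- function(object, ...) {
  c(beta0 = object$beta0, beta = object$beta)
}

#' @export
predict.attenuation_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$model, ...))
  stats::predict(object$model, data.frame(x = newdata), ...)
}

#' @export
residuals.attenuation_fit <- function(object, ...) {
  stats::residuals(object$model, ...)
}

#' Paired comparison of two datasets' fold changes over a gene group
#'
#' Two-sided paired test on `log2fc_A - log2fc_B` over a gene group — used to
#' ask whether the two perturbations shift a small set of genes by
#' statistically similar amounts.  Paired Wilcoxon signed rank by default; a
#' paired t-test is available.
#'
#' @param merged merged table from [merge_by_gene()].
#' @param group gene ids; at least 5 complete pairs.
#' @param labels length-2 dataset labels; defaults to the merged table's.
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @return list: `n`, `median_a`, `median_b`, `statistic`, `p`,
#'   `all_zero` flag (TRUE when every difference is zero, in which case
#'   `p = 1`), `method`.
#' @export
paired_group_comparison <- function(merged, group, labels = NULL,
                                    method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  if (is.null(labels)) labels <- attr(merged, "labels")
  ca <- merged_cols(merged, labels[1L]); cb <- merged_cols(merged, labels[2L])
  idx <- match(unique(as.character(group)), merged$gene)
  idx <- idx[!is.na(idx)]
  a <- ca$log2fc[idx]; b <- cb$log2fc[idx]
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 5L) stop("fewer than 5 complete pairs", call. = FALSE)
  d <- a - b
  base <- list(n = length(a), median_a = stats::median(a),
               median_b = stats::median(b), method = method)
  if (all(d == 0))
    return(c(base, list(statistic = NA_real_, p = 1, all_zero = TRUE)))
  ht <- if (method == "wilcoxon") {
    nz <- d[d != 0]
    suppressWarnings(stats::wilcox.test(
      nz, mu = 0, alternative = "two.sided",
      exact = length(nz) <= 25 && !anyDuplicated(abs(nz)), correct = TRUE))
  } else {
    stats::t.test(d, mu = 0)
  }
  c(base, list(statistic = unname(ht$statistic), p = unname(ht$p.value),
               all_zero = FALSE))
}
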
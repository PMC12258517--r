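#' Full epistasis comparison of two perturbation transcriptomes
#'
#' Runs the complete downstream comparison of a response-dataset perturbation
#' (e.g. knockout of an upstream regulator) against a predictor-dataset
#' perturbation (e.g. knockout of its downstream effector): merge by gene
#' name, classify up-/down-regulated sets, phase-rank enrichment per dataset,
#' hypergeometric overlaps, bootstrap-null Spearman concordance on the
#' predictor-dependent genes, and the attenuation-slope linear model
#' `log2fc_response ~ beta0 + beta * log2fc_predictor`.
#'
#' The result is deterministic given the inputs and `seed`; all thresholds
#' are arguments, never hard-coded in the component operations.
#'
#' @param response DE table for the response dataset (its fold changes go on
#'   the regression's left-hand side).
#' @param predictor DE table for the predictor dataset; the "dependent genes"
#'   driving concordance and the slope are those with `padj < alpha` here,
#'   regardless of direction.
#' @param labels length-2 character vector naming response and predictor
#'   datasets.
#' @param phase_sets optional named list of cell-cycle-phase gene sets; when
#'   given, [phase_enrichment()] is run on each dataset.
#' @param regulator_set optional gene set of cell-cycle regulators; when
#'   given, its overlap with the shared and dataset-specific downregulated
#'   sets is tested.
#' @param alpha adjusted-P cutoff for regulated-set definitions and the
#'   dependent-gene selection.
#' @param lfc_threshold absolute log2 fold-change cutoff for regulated sets.
#' @param n_iter bootstrap-null draws for the concordance test.
#' @param seed integer seed (used only by the bootstrap null).
#' @param quiet suppress stage-boundary messages.
#' @return object of class `"epistasis"`; see [print.epistasis()],
#'   [summary.epistasis()], [coef.epistasis()], [plot.epistasis()].  Key
#'   components: `merged`, `regulated` (per-dataset up/down id vectors),
#'   `phase` (per-dataset enrichment tables), `overlaps` (data.frame, BH
#'   corrected within this call), `concordance`, `fit`, `provenance`.
#' @export
epistasis <- function(response, predictor, labels = c("response", "predictor"),
                      phase_sets = NULL, regulator_set = NULL,
                      alpha = 0.05, lfc_threshold = 0,
                      n_iter = 100000, seed = 1, quiet = FALSE) {
  response <- validate_de_table(response)
  predictor <- validate_de_table(predictor)
  say <- function(...) if (!quiet) message(sprintf(...))

  merged <- merge_by_gene(response, predictor, labels, quiet = quiet)
  universe <- merged$gene
  say("stage merge: %d genes in the shared universe", length(universe))

  # regulated sets, defined on the merged universe (both-expressed policy)
  sub <- function(d) d[d$gene %in% universe, , drop = FALSE]
  regulated <- list()
  for (i in 1:2) {
    d <- sub(if (i == 1) response else predictor)
    regulated[[labels[i]]] <- list(
      up = classify_regulated(d, "up", alpha, lfc_threshold),
      down = classify_regulated(d, "down", alpha, lfc_threshold))
  }
  say("stage classify: %s %d up / %d down; %s %d up / %d down",
      labels[1], length(regulated[[1]]$up), length(regulated[[1]]$down),
      labels[2], length(regulated[[2]]$up), length(regulated[[2]]$down))

  # per-dataset phase enrichment on the full (unmerged) tables
  phase <- NULL
  if (!is.null(phase_sets)) {
    phase <- stats::setNames(
      list(phase_enrichment(response, phase_sets),
           phase_enrichment(predictor, phase_sets)), labels)
    say("stage phase: %d phase sets tested per dataset", length(phase_sets))
  }

  # overlap battery, one BH family per call
  tests <- list(
    up_up = list(a = regulated[[1]]$up, b = regulated[[2]]$up),
    down_down = list(a = regulated[[1]]$down, b = regulated[[2]]$down))
  if (!is.null(regulator_set)) {
    d1 <- regulated[[1]]$down; d2 <- regulated[[2]]$down
    tests$down_shared_vs_regulators <- list(a = intersect(d1, d2),
                                            b = regulator_set)
    tests$down_only_1_vs_regulators <- list(a = setdiff(d1, d2),
                                            b = regulator_set)
    tests$down_only_2_vs_regulators <- list(a = setdiff(d2, d1),
                                            b = regulator_set)
  }
  overlaps <- do.call(rbind, lapply(names(tests), function(nm) {
    ot <- suppressMessages(hypergeom_overlap(tests[[nm]]$a, tests[[nm]]$b,
                                             universe))
    data.frame(comparison = nm, n_universe = ot$n_universe, n_a = ot$n_a,
               n_b = ot$n_b, n_overlap = ot$n_overlap,
               fold_enrichment = ot$fold_enrichment, p_raw = ot$p,
               stringsAsFactors = FALSE)
  }))
  overlaps$p_adj <- adjust_bh(overlaps$p_raw)
  say("stage overlap: %d hypergeometric tests", nrow(overlaps))

  # dependent genes: significant in the predictor dataset, any direction
  pp <- merged_cols(merged, labels[2])$padj
  selected <- universe[!is.na(pp) & pp < alpha]
  say("stage select: %d genes dependent on %s at alpha = %g",
      length(selected), labels[2], alpha)

  concord <- bootstrap_null_concordance(merged, selected, n_iter = n_iter,
                                        seed = seed)
  fit <- attenuation_fit(merged, selected, response = labels[1],
                         predictor = labels[2])
  say("stage fit: slope %.3f (95%% CI %.3f-%.3f)",
      fit$beta, fit$ci95[["lo"]], fit$ci95[["hi"]])

  config <- list(labels = labels, alpha = alpha,
                 lfc_threshold = lfc_threshold, n_iter = n_iter, seed = seed,
                 n_phase_sets = if (is.null(phase_sets)) 0L
                                else length(phase_sets),
                 has_regulator_set = !is.null(regulator_set))
  provenance <- list(
    package_version = as.character(utils::packageVersion("episeq")),
    config = config, config_hash = config_hash(config),
    n_genes = stats::setNames(list(nrow(response), nrow(predictor),
                                   length(universe), length(selected)),
                              c(labels, "merged", "selected")))

  structure(list(merged = merged, regulated = regulated, phase = phase,
                 overlaps = overlaps, selected = selected,
                 concordance = concord, fit = fit, provenance = provenance),
            class = "epistasis")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(config), collapse = ""), f)
  unname(tools::md5sum(f))
}

#' @export
print.epistasis <- function(x, ...) {
  lb <- x$provenance$config$labels
  cat(sprintf("Epistasis comparison: %s (response) vs %s (predictor)\n",
              lb[1], lb[2]))
  cat(sprintf("  %d merged genes, %d %s-dependent genes selected\n",
              nrow(x$merged), length(x$selected), lb[2]))
  cat(sprintf("  Spearman rho = %.3f, Z = %.2f (ln P = %.2f, %d null draws)\n",
              x$concordance$rho, x$concordance$z_score,
              x$concordance$log_p_one_sided, x$concordance$n_null_draws))
  cat(sprintf("  attenuation slope = %.3f (95%% CI %.3f-%.3f)\n",
              x$fit$beta, x$fit$ci95[["lo"]], x$fit$ci95[["hi"]]))
  invisible(x)
}

#' Summarise an epistasis comparison
#'
#' @param object an `"epistasis"` object.
#' @param ... unused.
#' @export
summary.epistasis <- function(object, ...) {
  print(object)
  cat("\nOverlap tests (BH within this battery):\n")
  print(object$overlaps, row.names = FALSE, digits = 4)
  if (!is.null(object$phase)) {
    for (nm in names(object$phase)) {
      cat(sprintf("\nPhase enrichment, %s:\n", nm))
      print(object$phase[[nm]], row.names = FALSE, digits = 4)
    }
  }
  invisible(object)
}

#' @export
coef.epistasis <- function(object, ...) coef(object$fit)

#' @export
residuals.epistasis <- function(object, ...) residuals(object$fit)

#' @export
predict.epistasis <- function(object, newdata = NULL, ...) {
  predict(object$fit, newdata = newdata, ...)
}

#' Scatter plot of the two datasets' fold changes with the fitted slope
#'
#' Selected (dependent) genes are drawn over the background; the attenuation
#' fit is the solid line, the identity the dashed one.  Points beyond `clip`
#' are displayed at the axis limit plus 0.1 (display only — statistics are
#' never clipped).
#'
#' @param x an `"epistasis"` object.
#' @param clip symmetric axis limit in log2 units; `NULL` for no clipping.
#' @param ... passed to `plot`.
#' @export
plot.epistasis <- function(x, clip = NULL, ...) {
  lb <- x$provenance$config$labels
  xs <- merged_cols(x$merged, lb[2])$log2fc
  ys <- merged_cols(x$merged, lb[1])$log2fc
  if (!is.null(clip)) {
    squash <- function(v) sign(v) * pmin(abs(v), clip + 0.1)
    xs <- squash(xs); ys <- squash(ys)
  }
  sel <- x$merged$gene %in% x$selected
  plot(xs, ys, col = "grey70", pch = 16, cex = 0.4,
       xlab = sprintf("log2 fold change, %s", lb[2]),
       ylab = sprintf("log2 fold change, %s", lb[1]), ...)
  graphics::points(xs[sel], ys[sel], col = "firebrick", pch = 16, cex = 0.5)
  graphics::abline(a = x$fit$beta0, b = x$fit$beta, lwd = 2)
  graphics::abline(a = 0, b = 1, lty = 2, col = "grey40")
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("slope = %.2f (%.2f-%.2f)", x$fit$beta,
                                    x$fit$ci95[["lo"]], x$fit$ci95[["hi"]]))
  invisible(x)
}

#' Serialise an epistasis report to JSON and TSV
#'
#' Writes `report.json` (all scalar results plus provenance) and TSV tables
#' for the overlap battery and any phase-enrichment results.  The JSON is
#' byte-identical across runs with identical inputs and seed.
#'
#' @param x an `"epistasis"` object.
#' @param dir output directory (created if absent).
#' @return the report path, invisibly.
#' @export
write_epistasis_report <- function(x, dir) {
  stopifnot(inherits(x, "epistasis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep <- list(
    provenance = x$provenance,
    concordance = x$concordance[c("n_selected", "rho", "null_mean", "null_sd",
                                  "n_null_draws", "z_score",
                                  "log_p_one_sided", "seed")],
    attenuation = list(beta0 = x$fit$beta0, beta = x$fit$beta,
                       ci95 = unname(x$fit$ci95), n = x$fit$n,
                       r_squared = x$fit$r_squared),
    overlaps = x$overlaps,
    n_regulated = lapply(x$regulated, function(r) lapply(r, length)))
  class(rep$provenance$n_genes) <- NULL
  path <- file.path(dir, "report.json")
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.table(x$overlaps, file.path(dir, "overlaps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(x$phase)) {
    for (nm in names(x$phase)) {
      utils::write.table(
        x$phase[[nm]],
        file.path(dir, sprintf("phase_%s.tsv", gsub("[^A-Za-z0-9]", "_", nm))),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}

#' Run a pair analysis from a YAML configuration file
#'
#' The configuration names the input files and thresholds; defaults mirror
#' the analysis defaults (`alpha` 0.05, `lfc_threshold` 0, `n_iter` 100000,
#' `seed` 1).  Recognised keys: `de_response`, `de_predictor` (TSV paths,
#' required), `labels` (length 2), `phase_sets`, `regulator_sets` (GMT/TSV
#' paths; for `regulator_sets` all sets in the file are unioned), `alpha`,
#' `lfc_threshold`, `n_iter`, `seed`, `outdir`.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param quiet suppress stage messages.
#' @return the `"epistasis"` object, invisibly; the report is written to
#'   `outdir` when given.
#' @export
run_pair_analysis <- function(config, quiet = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (k in c("de_response", "de_predictor"))
    if (is.null(cfg[[k]]))
      stop(sprintf("config key `%s` is required", k), call. = FALSE)
  defaults <- list(labels = c("response", "predictor"), alpha = 0.05,
                   lfc_threshold = 0, n_iter = 100000, seed = 1)
  cfg <- utils::modifyList(defaults, cfg)
  resp <- read_de_table(cfg$de_response, quiet = quiet)
  pred <- read_de_table(cfg$de_predictor, quiet = quiet)
  phase_sets <- if (!is.null(cfg$phase_sets)) read_gene_sets(cfg$phase_sets)
  regulator_set <- if (!is.null(cfg$regulator_sets))
    unique(unlist(read_gene_sets(cfg$regulator_sets), use.names = FALSE))
  res <- epistasis(resp, pred, labels = as.character(cfg$labels),
                   phase_sets = phase_sets, regulator_set = regulator_set,
                   alpha = cfg$alpha, lfc_threshold = cfg$lfc_threshold,
                   n_iter = cfg$n_iter, seed = cfg$seed, quiet = quiet)
  if (!is.null(cfg$outdir)) write_epistasis_report(res, cfg$outdir)
  invisible(res)
}

#' Simulation suite: slope recovery, CI coverage and test calibration
#'
#' For each attenuation coefficient in `f_values`, repeats the full
#' generate-classify-fit cycle `n_reps` times (noise-on-response-only mode,
#' so the OLS slope targets the planted coefficient) and reports the mean
#' fitted slope, its bias, and 95% CI coverage of the truth.  Alongside, a
#' null phase-enrichment rejection rate (planted shift 0) and the mean
#' concordance Z over random (non-dependent) selections estimate the type-I
#' behaviour of the two tests.
#'
#' @param f_values attenuation coefficients to recover.
#' @param n_reps simulation repeats per coefficient.
#' @param params_base baseline [sim_params()]; `attenuation_f` and `seed`
#'   are overridden per repeat.
#' @param n_iter_null bootstrap draws per repeat for the Z calibration
#'   (small by design; the Z needs only the null's first two moments).
#' @param phase_size genes per null phase set.
#' @param alpha significance level used throughout.
#' @param seed master seed; repeat r of coefficient i runs at substream
#'   `seed + (i * n_reps + r) * 48271 mod (2^31 - 1)`.
#' @param file optional TSV path for the result table.
#' @return `data.frame`, one row per `f_values` entry: `f`, `n_reps`,
#'   `slope_mean`, `slope_bias`, `ci_coverage`, `phase_type1`, `z_mean`,
#'   `z_sd`.
#' @export
run_recovery_suite <- function(f_values = c(0.34, 0.43, 1.0), n_reps = 200,
                               params_base = sim_params(), n_iter_null = 500,
                               phase_size = 50, alpha = 0.05, seed = 1,
                               file = NULL) {
  if (n_reps < 1) stop_param("n_reps", "must be at least 1")
  rows <- lapply(seq_along(f_values), function(i) {
    f <- f_values[i]
    cover <- logical(n_reps); slope <- numeric(n_reps)
    phase_rej <- numeric(n_reps); zs <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      s <- substream(seed, (i - 1L) * n_reps + r)
      p <- params_base
      p$attenuation_f <- f; p$seed <- s; p$predictor_noise <- FALSE
      sim <- simulate_perturbation_pair(p)
      merged <- merge_by_gene(sim$upstream, sim$downstream,
                              c("up", "down"), quiet = TRUE)
      dep <- merged$gene[!is.na(merged$padj_down) & merged$padj_down < alpha]
      fit <- attenuation_fit(merged, dep, "up", "down")
      slope[r] <- fit$beta
      cover[r] <- fit$ci95[["lo"]] <= f && f <= fit$ci95[["hi"]]
      # null phase sets on the upstream (noisy) table
      ps <- simulate_phase_sets(merged$gene, 5, phase_size, shift = 0,
                                seed = substream(s, 11L))
      pe <- phase_enrichment(sim$upstream, ps$sets)
      phase_rej[r] <- mean(pe$p_raw < alpha, na.rm = TRUE)
      # Z calibration on a random non-dependent selection
      rnd <- with_seed(substream(s, 12L), sample(merged$gene, phase_size))
      zs[r] <- bootstrap_null_concordance(merged, rnd, n_iter = n_iter_null,
                                          seed = substream(s, 13L))$z_score
    }
    data.frame(f = f, n_reps = n_reps, slope_mean = mean(slope),
               slope_bias = mean(slope) - f, ci_coverage = mean(cover),
               phase_type1 = mean(phase_rej), z_mean = mean(zs),
               z_sd = stats::sd(zs))
  })
  out <- do.call(rbind, rows)
  if (!is.null(file))
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
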
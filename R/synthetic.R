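#' Parameters for the paired-perturbation simulator
#'
#' Describes a pair of perturbation experiments sharing a regulon: a
#' "downstream" dataset in which the regulon genes respond with log2
#' fold-change effects drawn from `N(0, effect_sd^2)`, and an "upstream"
#' dataset that retains a fraction `attenuation_f` of those effects.  The
#' attenuation coefficient is the quantity the [attenuation_fit()] slope
#' estimates.
#'
#' By default measurement noise is added to the upstream (response) dataset
#' only, which makes the OLS slope an unbiased estimate of `attenuation_f`;
#' with `predictor_noise = TRUE` noise is added to both datasets, in which
#' case the OLS slope is attenuated below `attenuation_f` by the predictor's
#' reliability ratio (the estimand of plain OLS on noisy fold changes).
#'
#' @param n_genes number of genes in the universe.
#' @param regulon_fraction fraction of genes in the shared regulon, in (0,1);
#'   `regulon_fraction * n_genes` must be at least 1.
#' @param attenuation_f fraction of downstream activity retained upstream,
#'   in (0, 1].
#' @param effect_sd SD of regulon log2 fold-change effects (log2 units).
#' @param noise_sd per-dataset measurement noise SD on log2 fold changes.
#' @param n_reps_per_group pseudo-replicates per group used to convert
#'   effects to P values (z = log2fc / (noise_sd / sqrt(n))).
#' @param seed non-negative integer; identical parameters (including seed)
#'   yield byte-identical outputs.
#' @param predictor_noise logical; add noise to the downstream (predictor)
#'   dataset too (default `FALSE`).
#' @return validated list of class `"sim_params"`.
#' @export
sim_params <- function(n_genes = 2000, regulon_fraction = 0.25,
                       attenuation_f = 0.43, effect_sd = 1, noise_sd = 0.2,
                       n_reps_per_group = 3, seed = 1,
                       predictor_noise = FALSE) {
  chk_scalar <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
      stop_param(field, "must be a single non-missing number")
  }
  chk_scalar(n_genes, "n_genes")
  if (n_genes < 1 || n_genes != round(n_genes))
    stop_param("n_genes", "must be a positive integer")
  chk_scalar(regulon_fraction, "regulon_fraction")
  if (regulon_fraction <= 0 || regulon_fraction >= 1)
    stop_param("regulon_fraction", "must lie in (0, 1)")
  if (regulon_fraction * n_genes < 1)
    stop_param("regulon_fraction", "regulon_fraction * n_genes must be >= 1")
  chk_scalar(attenuation_f, "attenuation_f")
  if (attenuation_f <= 0 || attenuation_f > 1)
    stop_param("attenuation_f", "must lie in (0, 1]")
  chk_scalar(effect_sd, "effect_sd")
  if (effect_sd <= 0) stop_param("effect_sd", "must be strictly positive")
  chk_scalar(noise_sd, "noise_sd")
  if (noise_sd <= 0) stop_param("noise_sd", "must be strictly positive")
  chk_scalar(n_reps_per_group, "n_reps_per_group")
  if (n_reps_per_group < 1 || n_reps_per_group != round(n_reps_per_group))
    stop_param("n_reps_per_group", "must be a positive integer")
  chk_scalar(seed, "seed")
  if (seed < 0 || seed != round(seed))
    stop_param("seed", "must be a non-negative integer")
  if (!is.logical(predictor_noise) || length(predictor_noise) != 1L ||
      is.na(predictor_noise))
    stop_param("predictor_noise", "must be TRUE or FALSE")
  structure(list(n_genes = as.integer(n_genes),
                 regulon_fraction = regulon_fraction,
                 attenuation_f = attenuation_f, effect_sd = effect_sd,
                 noise_sd = noise_sd,
                 n_reps_per_group = as.integer(n_reps_per_group),
                 seed = as.integer(seed), predictor_noise = predictor_noise),
            class = "sim_params")
}

#' Simulate a pair of perturbation DE tables with a planted attenuation
#'
#' Gene universe `g000001 ... g<n>`; a random regulon of size
#' `round(regulon_fraction * n_genes)` receives effects
#' `beta_g ~ N(0, effect_sd^2)`.  Downstream log2 fold change is `beta_g`
#' (plus noise when `predictor_noise`), upstream is
#' `attenuation_f * beta_g` plus noise; non-regulon genes are pure noise
#' (exactly zero downstream in the default noise-on-response-only mode).
#' Adjusted P values come from a two-sided normal z-test
#' `z = log2fc / (noise_sd / sqrt(n_reps_per_group))` followed by the same
#' Benjamini-Hochberg operation the analysis path uses ([adjust_bh()]).
#'
#' The global seed fans out to independent substreams (regulon/effects,
#' downstream noise, upstream noise, base means) via a fixed counter scheme,
#' so adding a table never perturbs existing draws.
#'
#' @param params a [sim_params()] object.
#' @return list: `downstream` and `upstream` DE tables over the same gene
#'   universe, and `truth` (`regulon_genes`, `per_gene_effect` named by
#'   regulon gene, `attenuation_f`).
#' @export
simulate_perturbation_pair <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  genes <- sprintf("g%06d", seq_len(p$n_genes))
  m <- as.integer(round(p$regulon_fraction * p$n_genes))

  reg_idx <- with_seed(substream(p$seed, 1L), sample.int(p$n_genes, m))
  beta <- with_seed(substream(p$seed, 2L), stats::rnorm(m, 0, p$effect_sd))
  eff <- numeric(p$n_genes)
  eff[reg_idx] <- beta

  lfc_down <- eff
  if (p$predictor_noise)
    lfc_down <- lfc_down +
      with_seed(substream(p$seed, 3L), stats::rnorm(p$n_genes, 0, p$noise_sd))
  lfc_up <- p$attenuation_f * eff +
    with_seed(substream(p$seed, 4L), stats::rnorm(p$n_genes, 0, p$noise_sd))
  base_mean <- with_seed(substream(p$seed, 5L),
                         stats::rlnorm(p$n_genes, meanlog = 5, sdlog = 1.5))

  se <- p$noise_sd / sqrt(p$n_reps_per_group)
  padj_of <- function(lfc) {
    praw <- 2 * stats::pnorm(abs(lfc) / se, lower.tail = FALSE)
    adjust_bh(praw)
  }
  truth <- list(regulon_genes = genes[sort(reg_idx)],
                per_gene_effect = stats::setNames(eff[sort(reg_idx)],
                                                  genes[sort(reg_idx)]),
                attenuation_f = p$attenuation_f)
  list(downstream = de_table(genes, lfc_down, padj_of(lfc_down), base_mean),
       upstream = de_table(genes, lfc_up, padj_of(lfc_up), base_mean),
       truth = truth)
}

#' Simulate disjoint phase-labelled gene sets with planted rank shifts
#'
#' Draws `n_phases` disjoint gene sets of `genes_per_phase` each from the
#' universe and records a planted additive log2 fold-change shift per phase.
#' Apply the shifts to a companion DE table with [apply_phase_shifts()]; a
#' phase with shift 0 is a true null for [phase_enrichment()].
#'
#' @param universe character vector of gene ids.
#' @param n_phases number of phases; 5 gives the canonical labels
#'   G1/S, S, G2, M, M/G1.
#' @param genes_per_phase set size per phase.
#' @param shift numeric scalar or per-phase vector of planted log2fc shifts.
#' @param seed integer seed.
#' @return list: `sets` (named list of gene ids, pairwise disjoint) and
#'   `shifts` (named numeric, the planted truth).
#' @export
simulate_phase_sets <- function(universe, n_phases = 5, genes_per_phase = 50,
                                shift = 0, seed = 1) {
  universe <- unique(as.character(universe))
  need <- n_phases * genes_per_phase
  if (need > length(universe))
    stop_param("genes_per_phase",
               sprintf("%d x %d genes requested but universe has only %d",
                       n_phases, genes_per_phase, length(universe)))
  labels <- if (n_phases == 5L) c("G1/S", "S", "G2", "M", "M/G1")
            else paste0("phase", seq_len(n_phases))
  shifts <- stats::setNames(rep_len(shift, n_phases), labels)
  picked <- with_seed(substream(seed, 1L), sample(universe, need))
  sets <- split(picked, rep(labels, each = genes_per_phase))[labels]
  list(sets = sets, shifts = shifts)
}

#' Apply planted phase shifts to a DE table
#'
#' Adds each phase's shift to the log2 fold changes of that phase's member
#' genes.  P values are not recomputed: the shifted table is meant for the
#' rank-based phase statistic, which uses log2fc only.
#'
#' @param d DE table.
#' @param phase_sets named list of gene-id vectors.
#' @param shifts named numeric vector, one entry per phase set.
#' @return the shifted DE table.
#' @export
apply_phase_shifts <- function(d, phase_sets, shifts) {
  d <- validate_de_table(d)
  stopifnot(all(names(phase_sets) %in% names(shifts)))
  for (ph in names(phase_sets)) {
    idx <- d$gene %in% phase_sets[[ph]]
    d$log2fc[idx] <- d$log2fc[idx] + shifts[[ph]]
  }
  d
}

#' Simulate genotype-by-EdU proliferation counts
#'
#' Per-group EdU-positive counts are binomial(`n`, `p`); totals are
#' preserved exactly.
#'
#' @param p_by_group named numeric vector of true EdU-positive proportions
#'   in `[0, 1]`.
#' @param n_by_group named integer vector of cell totals (same names).
#' @param seed integer seed.
#' @return count `data.frame` with columns `group`, `edu_pos`, `edu_neg`.
#' @export
simulate_edu_counts <- function(p_by_group, n_by_group, seed = 1) {
  if (!identical(sort(names(p_by_group)), sort(names(n_by_group))))
    stop_param("p_by_group,n_by_group", "group names must match")
  if (any(p_by_group < 0 | p_by_group > 1))
    stop_param("p_by_group", "proportions must lie in [0, 1]")
  if (any(n_by_group < 1 | n_by_group != round(n_by_group)))
    stop_param("n_by_group", "totals must be positive integers")
  groups <- names(p_by_group)
  n <- as.integer(n_by_group[groups])
  pos <- with_seed(substream(seed, 1L),
                   stats::rbinom(length(groups), n, p_by_group[groups]))
  data.frame(group = groups, edu_pos = pos, edu_neg = n - pos,
             stringsAsFactors = FALSE, row.names = NULL)
}
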
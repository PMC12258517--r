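test_that("simulator parameters are validated field by field", {
  expect_error(sim_params(n_genes = 0), "n_genes")
  expect_error(sim_params(regulon_fraction = 0), "regulon_fraction")
  expect_error(sim_params(n_genes = 10, regulon_fraction = 0.01),
               "regulon_fraction")
  expect_error(sim_params(attenuation_f = 0), "attenuation_f")
  expect_error(sim_params(attenuation_f = 1.2), "attenuation_f")
  expect_error(sim_params(effect_sd = -1), "effect_sd")
  expect_error(sim_params(noise_sd = 0), "noise_sd")
  expect_error(sim_params(n_reps_per_group = 0.5), "n_reps_per_group")
  expect_error(sim_params(seed = -1), "seed")
})

test_that("identical parameters give byte-identical outputs; substreams are stable", {
  p <- sim_params(n_genes = 300, seed = 42)
  s1 <- simulate_perturbation_pair(p)
  s2 <- simulate_perturbation_pair(p)
  expect_identical(s1, s2)
  # the simulator leaves the caller's RNG stream untouched
  set.seed(1); before <- rnorm(3)
  set.seed(1); invisible(simulate_perturbation_pair(p)); after <- rnorm(3)
  expect_identical(before, after)
  # truth is keyed exactly by the regulon and lives inside the universe
  expect_named(s1$truth$per_gene_effect, s1$truth$regulon_genes)
  expect_true(all(s1$truth$regulon_genes %in% s1$downstream$gene))
  expect_equal(length(s1$truth$regulon_genes), round(0.25 * 300))
})

test_that("near-zero noise with f = 1 makes the two tables identical on the regulon", {
  p <- sim_params(n_genes = 200, attenuation_f = 1, noise_sd = 1e-9,
                  seed = 3)
  s <- simulate_perturbation_pair(p)
  reg <- match(s$truth$regulon_genes, s$downstream$gene)
  expect_equal(s$upstream$log2fc[reg], s$downstream$log2fc[reg],
               tolerance = 1e-6)
  expect_equal(s$downstream$log2fc[reg],
               unname(s$truth$per_gene_effect))
})

test_that("regulon concordance beats an equal-size random non-regulon set", {
  for (seed in 1:10) {
    p <- sim_params(n_genes = 400, attenuation_f = 1, effect_sd = 1,
                    noise_sd = 0.2, seed = seed, predictor_noise = TRUE)
    s <- simulate_perturbation_pair(p)
    reg <- s$truth$regulon_genes
    idx <- match(reg, s$downstream$gene)
    rho_reg <- spearman_rho(s$downstream$log2fc[idx], s$upstream$log2fc[idx])
    non <- setdiff(s$downstream$gene, reg)
    pick <- with_seed(seed, sample(non, length(reg)))
    jdx <- match(pick, s$downstream$gene)
    rho_non <- spearman_rho(s$downstream$log2fc[jdx], s$upstream$log2fc[jdx])
    expect_gte(rho_reg, rho_non)
  }
})

test_that("OLS on the truth regulon recovers the planted slope (coverage)", {
  hits <- vapply(1:200, function(seed) {
    p <- sim_params(n_genes = 2000, regulon_fraction = 0.25,
                    attenuation_f = 0.43, effect_sd = 1, noise_sd = 0.2,
                    seed = seed)
    s <- simulate_perturbation_pair(p)
    m <- merge_by_gene(s$upstream, s$downstream, c("up", "down"),
                       quiet = TRUE)
    fit <- attenuation_fit(m, s$truth$regulon_genes, "up", "down")
    fit$ci95[["lo"]] <= 0.43 && 0.43 <= fit$ci95[["hi"]]
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("attenuation effect on the fitted slope is monotone in expectation", {
  fs <- c(0.34, 0.43, 0.8, 1.0)
  mean_slopes <- vapply(fs, function(f) {
    mean(vapply(1:60, function(seed) {
      p <- sim_params(n_genes = 500, attenuation_f = f, seed = seed)
      s <- simulate_perturbation_pair(p)
      m <- merge_by_gene(s$upstream, s$downstream, c("up", "down"),
                         quiet = TRUE)
      attenuation_fit(m, s$truth$regulon_genes, "up", "down")$beta
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_slopes) > 0))
})

test_that("phase-set generation is disjoint, sized, and plants its shifts", {
  uni <- sprintf("g%06d", 1:500)
  ps <- simulate_phase_sets(uni, 5, 40, shift = c(2, 0, 0, 0, -1), seed = 6)
  expect_named(ps$sets, c("G1/S", "S", "G2", "M", "M/G1"))
  expect_true(all(lengths(ps$sets) == 40))
  for (i in 1:4) for (j in (i + 1):5)
    expect_length(intersect(ps$sets[[i]], ps$sets[[j]]), 0L)
  expect_error(simulate_phase_sets(uni[1:100], 5, 40), "universe has only")

  # a large planted positive shift pushes that phase's median rank up
  d <- de_table(uni, rnorm(500), 0.5)
  d2 <- apply_phase_shifts(d, ps$sets, ps$shifts)
  res <- phase_enrichment(d2, ps$sets)
  expect_gt(res$median_rank[res$phase == "G1/S"], 0.5)
  expect_lt(res$median_rank[res$phase == "M/G1"], 0.5)
})

test_that("EdU count simulation respects degenerate and central proportions", {
  tab0 <- simulate_edu_counts(c(WT = 0, KO = 1), c(WT = 40, KO = 25), seed = 2)
  expect_equal(tab0$edu_pos[tab0$group == "WT"], 0)
  expect_equal(tab0$edu_pos[tab0$group == "KO"], 25)
  expect_equal(tab0$edu_pos + tab0$edu_neg, c(40, 25))

  # p = 0.5, n = 10000: observed proportion within 0.02 (binomial tail bound
  # puts failures at ~6e-5 per seed)
  props <- vapply(1:50, function(s) {
    t1 <- simulate_edu_counts(c(g = 0.5), c(g = 10000), seed = s)
    t1$edu_pos / 10000
  }, numeric(1))
  expect_true(all(abs(props - 0.5) <= 0.02))

  expect_error(simulate_edu_counts(c(a = 1.5, b = 0.5), c(a = 10, b = 10)),
               "p_by_group")
  expect_error(simulate_edu_counts(c(a = 0.5), c(b = 10)), "names")
})
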
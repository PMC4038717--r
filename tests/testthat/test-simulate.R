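# synthetic_data: generator structure, determinism, statistical calibration

test_that("same seed gives bit-identical panel, truth and phenotypes", {
  cfg <- tiny_sim()
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$panel, b$panel)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)
  expect_identical(a$phenotypes$means, b$phenotypes$means)
  # a different seed changes the genotypes
  c_ <- simulate_panel(simulation_config(
    n_strains = 16L, n_chromosomes = 2L, snps_per_chromosome = 120L,
    n_genes = 12L, seed = 999L))
  expect_false(identical(a$panel$geno, c_$panel$geno))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_dataset(tiny_sim()))
  expect_identical(.Random.seed, before)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(simulation_config(causal_effect_variance_fraction = 1.5),
               "variance_fraction")
  expect_error(simulation_config(trait_correlation = 1), "correlation")
  expect_error(simulation_config(missing_rate = 1), "missing_rate")
  expect_error(simulation_config(causal_gene_index = 101, n_genes = 100),
               "causal_gene_index")
  expect_error(simulation_config(n_strains = 1), "strains")
})

test_that("one ancestral haplotype makes strains identical: nothing to map", {
  cfg <- simulation_config(n_strains = 10L, n_chromosomes = 1L,
                           snps_per_chromosome = 60L, n_genes = 6L,
                           n_ancestral_haplotypes = 1L, missing_rate = 0,
                           causal_gene_index = NA, seed = 5L)
  sim <- simulate_panel(cfg)
  b <- enumerate_blocks(sim$panel, hbcgm_config(min_group_size = 1L))
  expect_identical(nrow(b$blocks), 0L)
})

test_that("region lengths are geometric with the configured mean", {
  set.seed(77)
  lens <- hbcgm:::.draw_region_lengths(10000L, 10L)
  expect_lt(abs(mean(lens) - 10) / 10, 0.05)
  expect_true(all(lens >= 1L))
})

test_that("the causal block lies inside the causal gene's interval", {
  for (seed in c(1L, 9L, 33L)) {
    sim <- simulate_panel(simulation_config(seed = seed))
    tr <- sim$truth
    g <- sim$annotation[sim$annotation$gene == tr$causal_gene, ]
    expect_identical(g$chrom, tr$causal_chrom)
    expect_gte(tr$causal_start_pos, g$start)
    expect_lte(tr$causal_end_pos, g$end)
    # all strains share an ancestral haplotype label at the causal block
    expect_identical(sort(names(tr$causal_labels)), sort(sim$panel$strains))
  }
})

test_that("genotypes are constant per strain within the causal region", {
  sim <- simulate_panel(simulation_config(seed = 3L, missing_rate = 0))
  tr <- sim$truth
  rows <- tr$causal_start_idx:tr$causal_end_idx
  g <- sim$panel$geno[rows, , drop = FALSE]
  lab <- tr$causal_labels[sim$panel$strains]
  for (l in unique(lab)) {
    cols <- g[, lab == l, drop = FALSE]
    expect_true(all(cols == cols[, 1L]))
  }
})

test_that("variance fraction 1 with zero noise makes means constant in-group", {
  cfg <- simulation_config(n_strains = 18L, n_chromosomes = 1L,
                           snps_per_chromosome = 100L, n_genes = 10L,
                           causal_gene_index = 4L,
                           causal_effect_variance_fraction = 1,
                           replicate_noise_sd = 0, missing_rate = 0,
                           n_traits = 2L, seed = 8L)
  sim <- simulate_dataset(cfg)
  lab <- sim$truth$causal_labels[colnames(sim$phenotypes$means)]
  for (tr in rownames(sim$phenotypes$means)) {
    v <- sim$phenotypes$means[tr, ]
    expect_true(all(abs(ave(v, lab) - v) < 1e-12))
  }
})

test_that("the strain-level variance decomposition matches the request", {
  cfg <- simulation_config(n_strains = 400L, n_chromosomes = 1L,
                           snps_per_chromosome = 60L, n_genes = 6L,
                           causal_gene_index = 3L,
                           causal_effect_variance_fraction = 0.7,
                           n_traits = 2L, missing_rate = 0, seed = 44L)
  sim <- simulate_dataset(cfg)
  gv <- sim$truth$genetic_values
  lab <- sim$truth$causal_labels[colnames(gv)]
  for (tr in rownames(gv)) {
    a <- anova_oracle(lab, gv[tr, ])
    expect_equal(a$eta, 0.7, tolerance = 1e-10)   # exact by construction
  }
})

test_that("cross-trait correlation of genetic values matches the request", {
  # null genome: with a causal block the k (2-4) group effects cannot carry
  # a meaningful sample correlation, so the target applies to the
  # strain-level latent values (see the methods vignette)
  cfg <- simulation_config(n_strains = 1000L, n_chromosomes = 1L,
                           snps_per_chromosome = 40L, n_genes = 4L,
                           causal_gene_index = NA,
                           n_traits = 2L, trait_correlation = 0.9,
                           missing_rate = 0, seed = 55L)
  sim <- simulate_dataset(cfg)
  gv <- sim$truth$genetic_values
  expect_lt(abs(cor(gv[1L, ], gv[2L, ]) - 0.9), 0.05)
})

test_that("replicate bookkeeping: means, SEM and n agree with raw values", {
  sim <- simulate_dataset(tiny_sim())
  pt <- sim$phenotypes
  expect_true(all(pt$n == 4L))
  tr <- traits(pt)[2L]
  st <- colnames(pt$means)[3L]
  v <- pt$replicates[[tr]][[st]]
  expect_identical(length(v), 4L)
  expect_equal(pt$means[tr, st], mean(v))
  expect_equal(pt$sem[tr, st], sd(v) / 2)
})

test_that("null calibration: with no causal effect the causal gene wins at chance", {
  n_genes <- 20L
  wins <- vapply(1:200, function(seed) {
    cfg <- simulation_config(
      n_strains = 20L, n_chromosomes = 1L, snps_per_chromosome = 200L,
      n_genes = n_genes, causal_gene_index = 10L,
      causal_effect_variance_fraction = 0, n_traits = 1L,
      mean_block_length_snps = 8L, missing_rate = 0, seed = seed)
    sim <- simulate_dataset(cfg)
    rec <- map_trait(sim$panel, sim$annotation, sim$phenotypes,
                     "mech_oih")
    gs <- gene_summary(rec)
    nrow(gs) > 0L && gs$gene[1L] == sim$truth$causal_gene
  }, TRUE)
  ci <- binom.test(sum(wins), 200, p = 1 / n_genes)
  expect_gt(ci$p.value, 0.001)   # consistent with the 1/n_genes chance rate
})
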
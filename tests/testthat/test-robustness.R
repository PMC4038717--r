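# robustness: subset draws, censored scoring, end-to-end resampling

test_that("default draws give distinct subsets of size n-6 .. n-3", {
  strains <- sprintf("s%02d", 1:23)
  subs <- draw_unique_subsets(strains, resampling_config(seed = 2L))
  expect_identical(length(subs), 100L)
  sizes <- lengths(subs)
  expect_true(all(sizes %in% 17:20))
  keys <- vapply(subs, function(s) paste(sort(s), collapse = "|"), "")
  expect_identical(anyDuplicated(keys), 0L)
  # retained subsets preserve panel order
  expect_true(all(vapply(subs, function(s)
    identical(s, strains[strains %in% s]), TRUE)))
})

test_that("exhaustive leave-one-out is drawn exactly; impossible asks fail", {
  strains <- letters[1:5]
  cfg <- resampling_config(n_iterations = 5L, exclusion_sizes = 1L,
                           seed = 1L)
  subs <- draw_unique_subsets(strains, cfg)
  expect_identical(length(subs), 5L)
  expect_setequal(vapply(subs, paste, "", collapse = ""),
                  c("bcde", "acde", "abde", "abce", "abcd"))
  expect_error(
    draw_unique_subsets(strains,
                        resampling_config(n_iterations = 6L,
                                          exclusion_sizes = 1L)),
    "only 5 distinct subsets")
  expect_error(
    draw_unique_subsets(letters[1:4],
                        resampling_config(exclusion_sizes = 4L)),
    "smaller than")
})

test_that("subset draws depend only on the seed", {
  strains <- sprintf("s%02d", 1:23)
  a <- draw_unique_subsets(strains, resampling_config(seed = 7L))
  b <- draw_unique_subsets(strains, resampling_config(seed = 7L))
  expect_identical(a, b)
  c_ <- draw_unique_subsets(strains, resampling_config(seed = 8L))
  expect_false(identical(a, c_))
})

test_that("robustness_score censors at the cutoff", {
  expect_identical(robustness_score(rep(NA_real_, 100), 0.01), 200)
  expect_equal(robustness_score(rep(1e-4, 100), 0.01), 400)
  expect_equal(robustness_score(c(1e-6, 0.5, 1e-3), 0.01), 11)
  expect_equal(robustness_score(c(0.01, 0.02), 0.01), 4)  # at-cutoff censors
  expect_equal(robustness_score(numeric(0), 0.01), 0)
})

test_that("score is monotone in every p and insensitive above the cutoff", {
  set.seed(20)
  for (i in 1:25) {
    p <- runif(30, 0, 0.2)
    s0 <- robustness_score(p, 0.01)
    j <- sample(30, 1)
    p2 <- p
    p2[j] <- p[j] * runif(1)          # decrease one p
    expect_gte(robustness_score(p2, 0.01), s0)
    p3 <- p
    p3[p3 >= 0.01] <- runif(sum(p3 >= 0.01), 0.011, 1)  # shuffle censored
    expect_equal(robustness_score(p3, 0.01), s0)
  }
})

test_that("every tabulated gene scores at least n_hits times -log10 cutoff", {
  sim <- simulate_dataset(tiny_sim())
  cfg <- resampling_config(n_iterations = 25L, seed = 4L,
                           exclusion_sizes = 2:3)
  tab <- run_robustness(sim$panel, sim$annotation, sim$phenotypes,
                        "mech_oih", cfg)
  expect_true(all(tab$n_hits >= 1L))
  expect_true(all(tab$score >= tab$n_hits * 2 - 1e-9))
  expect_true(all(tab$score >= cfg$n_iterations * 2 - 1e-9))
  expect_identical(tab$rank, seq_len(nrow(tab)))
  expect_false(is.unsorted(-tab$score))
})

test_that("run_robustness is reproducible and finds a strong causal gene", {
  sim <- simulate_dataset(tiny_sim(seed = 31L, h = 0.9))
  cfg <- resampling_config(n_iterations = 40L, exclusion_sizes = 2:4,
                           seed = 9L)
  t1 <- run_robustness(sim$panel, sim$annotation, sim$phenotypes,
                       "mech_oih", cfg)
  t2 <- run_robustness(sim$panel, sim$annotation, sim$phenotypes,
                       "mech_oih", cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(t1$gene[1L], sim$truth$causal_gene)
})

test_that("per-iteration gene p-values agree with a direct map_trait run", {
  sim <- simulate_dataset(tiny_sim(seed = 12L))
  mcfg <- hbcgm_config()
  ctx <- hbcgm:::.mapping_context(sim$panel, sim$annotation,
                                  sim$phenotypes, mcfg)
  sub <- ctx$common[-c(2L, 5L, 9L)]
  fast <- hbcgm:::.context_gene_pvalues(ctx, "tf_oih", sub)
  rec <- map_trait(subset_strains(sim$panel, sub), sim$annotation,
                   sim$phenotypes, "tf_oih", mcfg)
  gs <- gene_summary(rec)
  for (g in gs$gene) expect_identical(fast[[g]], gs$p_value[gs$gene == g])
  expect_true(all(is.na(fast[setdiff(names(fast), gs$gene)])))
})

test_that("cutoff_sensitivity reports rank agreement on shared draws", {
  sim <- simulate_dataset(tiny_sim(seed = 31L, h = 0.9))
  cfg <- resampling_config(n_iterations = 30L, exclusion_sizes = 2:4,
                           seed = 9L)
  cs <- cutoff_sensitivity(sim$panel, sim$annotation, sim$phenotypes,
                           "mech_oih", cfg, alternate_cutoff = 0.01,
                           k = 5L)
  # identical cutoffs: trivially full agreement
  expect_identical(cs$n_agree, cs$k_effective)
  expect_identical(cs$agreement, 1)
  # a pure-noise panel still produces a report
  simn <- simulate_dataset(
    simulation_config(n_strains = 14L, n_chromosomes = 1L,
                      snps_per_chromosome = 80L, n_genes = 8L,
                      causal_effect_variance_fraction = 0, n_traits = 1L,
                      seed = 2L))
  csn <- cutoff_sensitivity(simn$panel, simn$annotation, simn$phenotypes,
                            "mech_oih",
                            resampling_config(n_iterations = 10L,
                                              exclusion_sizes = 2L,
                                              seed = 3L),
                            alternate_cutoff = 0.001, k = 5L)
  expect_true(is.numeric(csn$n_agree))
  expect_error(
    cutoff_sensitivity(simn$panel, simn$annotation, simn$phenotypes,
                       "mech_oih", alternate_cutoff = 2),
    "alternate_cutoff")
})
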
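# association: one-way ANOVA kernel, gene assignment, whole-genome mapping

test_that("perfect separation reports eta 1 and the p floor, never zero", {
  res <- block_association(c(0L, 0L, 1L, 1L), c(1, 1, 3, 3))
  expect_identical(res$genetic_effect, 1)
  expect_identical(res$p_value, 1e-300)
  expect_identical(res$f_statistic, Inf)
})

test_that("identical group means give F = 0, eta = 0, p = 1", {
  res <- block_association(c(0L, 0L, 1L, 1L), c(1, 2, 1, 2))
  expect_identical(res$f_statistic, 0)
  expect_identical(res$genetic_effect, 0)
  expect_identical(res$p_value, 1)
})

test_that("guards: degenerate data, too few groups, small groups", {
  expect_error(block_association(c(0L, 0L, 1L, 1L), c(2, 2, 2, 2)),
               "identical")
  expect_error(block_association(c(0L, 0L, 0L, 0L), c(1, 2, 3, 4)),
               "2 groups")
  expect_error(block_association(c(0L, 1L, 1L, 1L), c(1, 2, 3, 4)),
               "at least 2 strains")
})

test_that("ANOVA matches the textbook lm/anova oracle to 1e-10", {
  set.seed(71)
  for (i in 1:60) {
    n <- sample(8:23, 1)
    k <- sample(2:4, 1)
    lab <- sample(rep(seq_len(k) - 1L, length.out = n))
    y <- rnorm(n, mean = lab * runif(1, 0, 2))
    res <- block_association(lab, y, min_group_size = 1L)
    want <- anova_oracle(lab, y)
    expect_equal(res$f_statistic, want$f, tolerance = 1e-10)
    expect_equal(res$p_value, want$p, tolerance = 1e-10)
    expect_equal(res$genetic_effect, want$eta, tolerance = 1e-10)
  }
})

test_that("named partitions align to named trait values", {
  lab <- c(s1 = 0L, s2 = 0L, s3 = 1L, s4 = 1L)
  y <- c(s4 = 3, s3 = 3, s2 = 1, s1 = 1)   # shuffled names
  res <- block_association(lab, y)
  expect_identical(res$genetic_effect, 1)
})

test_that("blocks are assigned to all overlapping genes, intronic included", {
  p <- random_panel(6, 10, seed = 3)   # positions 10..100
  ann <- gene_annotation(data.frame(
    gene = c("big", "nested", "far"),
    chrom = c("chr1", "chr1", "chr1"),
    start = c(1L, 35L, 5000L), end = c(1090000L, 55L, 6000L)))
  b <- enumerate_blocks(p, hbcgm_config(min_group_size = 2L))
  genes <- map_blocks_to_genes(b, ann)
  spans <- b$blocks
  for (i in seq_along(genes)) {
    want <- character(0)
    if (spans$start_pos[i] <= 1090000) want <- c(want, "big")
    if (spans$start_pos[i] <= 55 && spans$end_pos[i] >= 35)
      want <- c(want, "nested")
    expect_identical(genes[[i]], sort(want))
  }
  # flank pulls in a gene 10 kb away
  ann2 <- gene_annotation(data.frame(gene = "g", chrom = "chr1",
                                     start = 10050L, end = 10100L))
  g0 <- map_blocks_to_genes(b, ann2, flank = 0L)
  g1 <- map_blocks_to_genes(b, ann2, flank = 10000L)
  expect_true(all(lengths(g0) == 0L))
  expect_identical(lengths(g1), as.integer(spans$end_pos >= 50L))
})

test_that("map_trait is deterministic and shares p across equal partitions", {
  sim <- simulate_dataset(tiny_sim())
  rec <- map_trait(sim$panel, sim$annotation, sim$phenotypes, "mech_oih")
  rec2 <- map_trait(sim$panel, sim$annotation, sim$phenotypes, "mech_oih")
  expect_identical(as.data.frame(rec), as.data.frame(rec2))
  expect_false(is.unsorted(rec$p_value))
  # identical partition key => bit-identical statistics
  sp <- split(seq_len(nrow(rec)), rec$partition_key)
  for (ix in sp[lengths(sp) > 1L][1:min(10, sum(lengths(sp) > 1L))]) {
    expect_identical(length(unique(rec$p_value[ix])), 1L)
    expect_identical(length(unique(rec$f_statistic[ix])), 1L)
    expect_identical(length(unique(rec$genetic_effect[ix])), 1L)
  }
})

test_that("a duplicated trait column maps identically", {
  sim <- simulate_dataset(tiny_sim())
  m <- sim$phenotypes$means
  m2 <- rbind(m, copy = m["mech_oih", ])
  pt2 <- phenotype_table(m2)
  r1 <- map_trait(sim$panel, sim$annotation, pt2, "mech_oih")
  r2 <- map_trait(sim$panel, sim$annotation, pt2, "copy")
  r2$trait <- "mech_oih"
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("map_trait recovers a strong causal gene at the top", {
  sim <- simulate_dataset(tiny_sim(seed = 21L, h = 0.9))
  rec <- map_trait(sim$panel, sim$annotation, sim$phenotypes, "mech_oih")
  gs <- gene_summary(rec)
  expect_true(match(sim$truth$causal_gene, gs$gene) <= 3L)
})

test_that("gene_summary keeps the minimum-p record per gene", {
  sim <- simulate_dataset(tiny_sim())
  rec <- map_trait(sim$panel, sim$annotation, sim$phenotypes, "tf_oih")
  gs <- gene_summary(rec)
  expect_false(is.unsorted(gs$p_value))
  expect_identical(gs$rank, seq_len(nrow(gs)))
  long <- rec[rec$genes != "", ]
  for (g in gs$gene[1:min(5, nrow(gs))]) {
    hits <- vapply(strsplit(long$genes, ","), function(x) g %in% x, TRUE)
    expect_identical(gs$p_value[gs$gene == g], min(long$p_value[hits]))
  }
  # intergenic blocks excluded unless requested
  expect_false("(intergenic)" %in% gs$gene)
})

test_that("genes sharing one partition share one p in the summary", {
  # one informative SNP inside each of 3 tiny genes, identical columns
  geno <- matrix(rep(c(0L, 0L, 0L, 1L, 1L, 1L), 3), nrow = 3, byrow = TRUE)
  p <- strain_panel(sprintf("s%d", 1:6),
                    data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                               ref = "A", alt = "C"), geno)
  ann <- gene_annotation(data.frame(
    gene = c("gA", "gB", "gC"), chrom = "chr1",
    start = c(90L, 190L, 290L), end = c(110L, 210L, 310L)))
  pt <- phenotype_table(matrix(c(1, 1.2, 0.9, 3, 3.1, 2.9), nrow = 1,
                               dimnames = list("t", sprintf("s%d", 1:6))))
  rec <- map_trait(p, ann, pt, "t",
                   hbcgm_config(window_sizes = 1L, min_group_size = 3L,
                                min_strains = 2L))
  gs <- gene_summary(rec)
  expect_identical(nrow(gs), 3L)
  expect_identical(length(unique(gs$p_value)), 1L)
})

test_that("removing a strain leaves blocks where it was missing unchanged", {
  p <- random_panel(8, 40, missing_rate = 0.2, seed = 8)
  set.seed(1)
  y <- rnorm(8)
  names(y) <- p$strains
  pt <- phenotype_table(matrix(y, 1, dimnames = list("t", p$strains)))
  cfg <- hbcgm_config(min_group_size = 2L, min_nonmissing_frac = 0,
                      min_strains = 2L)
  ann <- gene_annotation(data.frame(gene = "g", chrom = "chr1",
                                    start = 1L, end = 10000L))
  drop <- "s03"
  rec1 <- map_trait(p, ann, pt, "t", cfg)
  p2 <- subset_strains(p, setdiff(p$strains, drop))
  rec2 <- map_trait(p2, ann, pt, "t", cfg)
  # blocks in which s03 carried no label must be identical in both runs
  miss <- vapply(seq_len(nrow(rec1)), function(i) {
    b <- rec1[i, ]
    anyNA(p$geno[b$start_idx:b$end_idx, drop])
  }, TRUE)
  k1 <- paste(rec1$chrom, rec1$start_idx, rec1$window)[miss]
  k2 <- paste(rec2$chrom, rec2$start_idx, rec2$window)
  m <- match(k1, k2)
  expect_false(anyNA(m))
  expect_identical(rec1$p_value[miss], rec2$p_value[m])
  expect_identical(rec1$partition_key[miss], rec2$partition_key[m])
})
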
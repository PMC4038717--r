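# blocks: window enumeration, partition canonicalization, de-duplication

test_that("monomorphic panels yield no testable blocks", {
  geno <- matrix(0L, 10, 6)
  p <- strain_panel(sprintf("s%d", 1:6),
                    data.frame(chrom = "chr1", pos = 1:10 * 10L,
                               ref = "A", alt = "C"),
                    geno)
  b <- enumerate_blocks(p, hbcgm_config(min_group_size = 1L))
  expect_identical(nrow(b$blocks), 0L)
})

test_that("a single informative SNP induces the expected partition", {
  geno <- matrix(c(0L, 0L, 1L, 1L), 1, 4)
  p <- strain_panel(c("A", "B", "C", "D"),
                    data.frame(chrom = "chr1", pos = 50L,
                               ref = "A", alt = "C"),
                    geno)
  b <- enumerate_blocks(p, hbcgm_config(window_sizes = 1L,
                                        min_group_size = 2L))
  expect_identical(nrow(b$blocks), 1L)
  expect_identical(unname(block_labels(b, 1L)), c(0L, 0L, 1L, 1L))
  expect_identical(b$blocks$n_groups, 2L)
})

test_that("enumeration matches exhaustive brute force on random panels", {
  for (seed in 1:6) {
    p <- random_panel(sample(6:12, 1), sample(30:60, 1),
                      n_chrom = sample(1:2, 1),
                      missing_rate = sample(c(0, 0.1), 1), seed = seed)
    cfg <- hbcgm_config(min_group_size = 2L, max_groups = 4L,
                        min_nonmissing_frac = 0.5)
    got <- enumerate_blocks(p, cfg)
    want <- brute_force_blocks(p, cfg$window_sizes, cfg$min_group_size,
                               cfg$max_groups, cfg$min_nonmissing_frac)
    key <- function(s, e, w) paste(s, e, w)
    got_keys <- key(got$blocks$start_idx, got$blocks$end_idx,
                    got$blocks$window)
    want_keys <- vapply(want, function(b)
      key(b$start_idx, b$end_idx, b$window), "")
    expect_setequal(got_keys, want_keys)
    # canonical labels agree block by block
    m <- match(want_keys, got_keys)
    for (i in seq_along(want)) {
      expect_identical(unname(block_labels(got, m[i])), want[[i]]$labels)
    }
  }
})

test_that("window-1 block count equals SNPs passing the group filters", {
  p <- random_panel(10, 50, seed = 9)
  cfg <- hbcgm_config(window_sizes = 1L, min_group_size = 3L)
  b <- enumerate_blocks(p, cfg)
  pass <- sum(apply(p$geno, 1L, function(g) {
    tab <- table(g)
    length(tab) == 2L && all(tab >= 3L)
  }))
  expect_identical(nrow(b$blocks), pass)
})

test_that("partition keys are invariant to strain column order", {
  p <- random_panel(8, 40, missing_rate = 0.05, seed = 5)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  p2 <- strain_panel(p$strains[perm], p$variants,
                     p$geno[, perm, drop = FALSE])
  cfg <- hbcgm_config(min_group_size = 2L)
  b1 <- enumerate_blocks(p, cfg)
  b2 <- enumerate_blocks(p2, cfg)
  ord1 <- order(b1$blocks$window, b1$blocks$start_idx)
  ord2 <- order(b2$blocks$window, b2$blocks$start_idx)
  expect_identical(b1$blocks$start_idx[ord1], b2$blocks$start_idx[ord2])
  expect_identical(b1$blocks$partition_key[ord1],
                   b2$blocks$partition_key[ord2])
})

test_that("dedupe_partitions conserves blocks and shares identical windows", {
  # two adjacent identical SNPs: all windows over them share one partition
  geno <- rbind(c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L))
  p <- strain_panel(c("A", "B", "C", "D"),
                    data.frame(chrom = "chr1", pos = c(10L, 20L),
                               ref = "A", alt = "C"),
                    geno)
  b <- enumerate_blocks(p, hbcgm_config(window_sizes = c(1L, 2L),
                                        min_group_size = 2L))
  groups <- dedupe_partitions(b)
  expect_identical(length(groups), 1L)
  expect_identical(sum(lengths(groups)), nrow(b$blocks))

  # random panel: conservation of members
  p2 <- random_panel(8, 30, seed = 2)
  b2 <- enumerate_blocks(p2, hbcgm_config(min_group_size = 2L))
  g2 <- dedupe_partitions(b2)
  expect_identical(sum(lengths(g2)), nrow(b2$blocks))
  expect_identical(sort(unique(names(g2))),
                   sort(unique(b2$blocks$partition_key)))
})

test_that("partition_by_snps groups strains by joint allele pattern", {
  geno <- rbind(c(0L, 0L, 0L, 1L, 1L, 1L, 0L),
                c(0L, 1L, 1L, 0L, 0L, 0L, 1L))
  p <- strain_panel(sprintf("s%d", 1:7),
                    data.frame(chrom = "chr18", pos = c(100L, 200L),
                               ref = "A", alt = "C"),
                    geno)
  pheno <- c(s1 = 0.8, s2 = 0.9, s3 = 0.7, s4 = 0.2, s5 = 0.3, s6 = 0.1,
             s7 = 0.95)
  res <- partition_by_snps(p, data.frame(chrom = "chr18",
                                         pos = c(100L, 200L)), pheno)
  # patterns present: (0,0), (0,1), (1,0) -> exactly 3 groups
  expect_identical(nrow(res$groups), 3L)
  expect_identical(res$strains$class[res$strains$strain == "s4"], "low")
  expect_identical(res$strains$class[res$strains$strain == "s1"], "high")
  # group of the A713V-like pattern is uniformly low
  g10 <- res$strains$group[res$strains$pattern == "1/0"][1L]
  expect_true(all(res$strains$class[res$strains$group == g10] == "low"))
  expect_error(
    partition_by_snps(p, data.frame(chrom = "chr18", pos = 999L), pheno),
    "not found")
})

test_that("single-SNP selectors with one allele give one group; thresholds classify", {
  geno <- matrix(0L, 1, 4)
  p <- strain_panel(c("A", "B", "C", "D"),
                    data.frame(chrom = "chr1", pos = 10L,
                               ref = "A", alt = "C"), geno)
  pheno <- c(A = 0.1, B = 0.2, C = 0.3, D = 0.4)
  res <- partition_by_snps(p, data.frame(chrom = "chr1", pos = 10L), pheno)
  expect_identical(nrow(res$groups), 1L)
  expect_true(all(res$strains$class == "low"))
})
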
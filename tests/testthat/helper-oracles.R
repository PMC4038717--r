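# Shared fixtures and independent oracles. Everything is built in code;
# oracles deliberately avoid the package's own code paths.

# small random panel; codes 0/1 with optional missingness
random_panel <- function(n_strains, n_snps, n_chrom = 1L,
                         missing_rate = 0, seed = 1L) {
  set.seed(seed)
  strains <- sprintf("s%02d", seq_len(n_strains))
  per <- ceiling(n_snps / n_chrom)
  chrom <- rep(paste0("chr", seq_len(n_chrom)), each = per)[seq_len(n_snps)]
  pos <- unlist(lapply(split(seq_len(n_snps), chrom)[unique(chrom)],
                       function(ix) seq_along(ix) * 10L), use.names = FALSE)
  geno <- matrix(sample(0:1, n_snps * n_strains, replace = TRUE),
                 n_snps, n_strains)
  if (missing_rate > 0)
    geno[runif(length(geno)) < missing_rate] <- NA_integer_
  strain_panel(strains,
               data.frame(chrom = chrom, pos = pos, ref = "A", alt = "C"),
               geno)
}

# exhaustive brute-force block enumeration, independent of the compiled path
brute_force_blocks <- function(panel, window_sizes = c(1L, 2L, 3L),
                               min_group_size = 3L, max_groups = 4L,
                               min_nonmissing_frac = 0.5) {
  S <- length(panel$strains)
  out <- list()
  for (w in window_sizes) {
    for (ch in unique(panel$variants$chrom)) {
      idx <- which(panel$variants$chrom == ch)
      if (length(idx) < w) next
      for (s in seq_len(length(idx) - w + 1L)) {
        rows <- idx[s:(s + w - 1L)]
        g <- panel$geno[rows, , drop = FALSE]
        hap <- apply(g, 2L, function(col)
          if (anyNA(col)) NA_character_ else paste(col, collapse = ""))
        nonmiss <- sum(!is.na(hap))
        if (nonmiss < min_nonmissing_frac * S - 1e-9) next
        tab <- table(hap[!is.na(hap)])
        if (length(tab) < 2L || length(tab) > max_groups ||
            any(tab < min_group_size)) next
        lab <- match(hap, unique(hap[!is.na(hap)])) - 1L
        out[[length(out) + 1L]] <- list(
          start_idx = rows[1L], end_idx = rows[w], window = w,
          labels = unname(lab))
      }
    }
  }
  out
}

# textbook one-way ANOVA via lm/anova (the independent statistics oracle)
anova_oracle <- function(labels, y) {
  keep <- !is.na(labels) & !is.na(y)
  d <- data.frame(g = factor(labels[keep]), y = y[keep])
  a <- stats::anova(stats::lm(y ~ g, data = d))
  ss <- a[["Sum Sq"]]
  list(f = a[["F value"]][1L], p = a[["Pr(>F)"]][1L],
       eta = ss[1L] / sum(ss))
}

# hand-rolled BH step-up, written differently from the package's version
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    v <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- v
    prev <- v
  }
  pmin(adj, 1)
}

# a tiny deterministic simulated dataset for pipeline tests
tiny_sim <- function(seed = 11L, h = 0.8) {
  simulation_config(
    n_strains = 16L, n_chromosomes = 2L, snps_per_chromosome = 120L,
    n_genes = 12L, causal_gene_index = 5L,
    causal_effect_variance_fraction = h, n_traits = 3L,
    mean_block_length_snps = 8L, replicates_per_strain = 4L,
    replicate_noise_sd = 0.5, missing_rate = 0.01, seed = seed)
}
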
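# Synthetic strain-panel generator. The genome is a sequence of ancestral
# haplotype regions: within a region every strain carries one of a small
# number of ancestral allele strings (so nearby SNPs are perfectly correlated
# within a region and independent across regions). One region, embedded
# inside a designated gene, drives the simulated traits.

# run expr with a private RNG stream; the caller's .Random.seed is restored
.with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Defaults emulate the stated world of the package's motivating use case: a
#' 23-strain inbred panel, 8 replicate animals per strain, five
#' cross-correlated traits, and one causal haplotype block explaining a
#' large fraction of the strain-level variance of every trait.
#'
#' @param n_strains number of inbred strains.
#' @param n_chromosomes number of chromosomes.
#' @param snps_per_chromosome SNPs per chromosome.
#' @param n_ancestral_haplotypes distinct ancestral allele strings per
#'   region (capped at \code{2^length} for very short regions).
#' @param mean_block_length_snps mean region length; lengths are geometric.
#' @param n_genes genes tiled over the genome (non-overlapping).
#' @param causal_gene_index 1-based index of the causal gene; NULL (default)
#'   picks the middle gene, NA produces a purely null genome.
#' @param causal_effect_variance_fraction fraction of strain-level trait
#'   variance explained by the causal block's haplotype grouping, in [0,1].
#' @param n_traits number of traits.
#' @param trait_correlation cross-trait correlation of strain-level genetic
#'   values, in (-1,1).
#' @param replicates_per_strain animals per strain per trait.
#' @param replicate_noise_sd per-animal Gaussian noise SD (strain-level
#'   genetic values have unit variance, so this is a relative scale).
#' @param missing_rate independent missing-call probability per genotype.
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_strains = 23L,
                              n_chromosomes = 5L,
                              snps_per_chromosome = 1000L,
                              n_ancestral_haplotypes = 3L,
                              mean_block_length_snps = 10L,
                              n_genes = 100L,
                              causal_gene_index = NULL,
                              causal_effect_variance_fraction = 0.7,
                              n_traits = 5L,
                              trait_correlation = 0.5,
                              replicates_per_strain = 8L,
                              replicate_noise_sd = 1,
                              missing_rate = 0.02,
                              seed = 1L) {
  cfg <- list(n_strains = as.integer(n_strains),
              n_chromosomes = as.integer(n_chromosomes),
              snps_per_chromosome = as.integer(snps_per_chromosome),
              n_ancestral_haplotypes = as.integer(n_ancestral_haplotypes),
              mean_block_length_snps = as.integer(mean_block_length_snps),
              n_genes = as.integer(n_genes),
              causal_gene_index = if (is.null(causal_gene_index))
                                    as.integer(ceiling(n_genes / 2))
                                  else if (is.na(causal_gene_index))
                                    NA_integer_
                                  else as.integer(causal_gene_index),
              causal_effect_variance_fraction =
                as.numeric(causal_effect_variance_fraction),
              n_traits = as.integer(n_traits),
              trait_correlation = as.numeric(trait_correlation),
              replicates_per_strain = as.integer(replicates_per_strain),
              replicate_noise_sd = as.numeric(replicate_noise_sd),
              missing_rate = as.numeric(missing_rate),
              seed = as.integer(seed))
  with(cfg, {
    if (n_strains < 2L) stop("need >= 2 strains", call. = FALSE)
    if (n_chromosomes < 1L || snps_per_chromosome < 1L || n_genes < 1L ||
        n_traits < 1L || replicates_per_strain < 1L ||
        mean_block_length_snps < 1L || n_ancestral_haplotypes < 1L)
      stop("all counts must be positive", call. = FALSE)
    if (!is.na(causal_gene_index) &&
        (causal_gene_index < 1L || causal_gene_index > n_genes))
      stop("causal_gene_index must be in 1..n_genes", call. = FALSE)
    if (causal_effect_variance_fraction < 0 ||
        causal_effect_variance_fraction > 1)
      stop("causal_effect_variance_fraction must be in [0, 1]",
           call. = FALSE)
    if (abs(trait_correlation) >= 1)
      stop("trait_correlation must be in (-1, 1)", call. = FALSE)
    if (missing_rate < 0 || missing_rate >= 1)
      stop("missing_rate must be in [0, 1)", call. = FALSE)
    if (replicate_noise_sd < 0)
      stop("replicate_noise_sd must be >= 0", call. = FALSE)
    if (n_genes > n_chromosomes * snps_per_chromosome)
      stop("more genes than SNPs", call. = FALSE)
  })
  structure(cfg, class = "simulation_config")
}

# geometric region lengths with the configured mean (support 1, 2, ...)
.draw_region_lengths <- function(n, mean_len) {
  if (mean_len <= 1) rep(1L, n)
  else stats::rgeom(n, 1 / mean_len) + 1L
}

# tile `total` SNPs with geometric regions; returns region lengths
.tile_lengths <- function(total, mean_len) {
  if (total == 0L) return(integer(0))
  lens <- integer(0)
  while (sum(lens) < total) {
    lens <- c(lens, .draw_region_lengths(max(16L, ceiling(total / mean_len)),
                                         mean_len))
  }
  cum <- cumsum(lens)
  k <- which(cum >= total)[1L]
  lens <- lens[seq_len(k)]
  lens[k] <- lens[k] - (cum[k] - total)
  lens[lens > 0L]
}

# distinct ancestral allele strings: len x k matrix of 0/1
.draw_ancestral <- function(len, k) {
  k <- min(k, 2^min(len, 30))
  H <- matrix(stats::rbinom(len * k, 1L, 0.5), nrow = len)
  if (k > 1L) {
    repeat {
      key <- apply(H, 2L, paste, collapse = "")
      dup <- duplicated(key)
      if (!any(dup)) break
      H[, dup] <- stats::rbinom(len * sum(dup), 1L, 0.5)
    }
  }
  H
}

#' Simulate a strain genotype panel with an embedded causal block
#'
#' Generates block-structured genotypes for \code{n_strains} strains, a
#' tiling gene annotation, and the ground truth needed to validate mapping.
#' When a causal gene is configured, one ancestral-haplotype region is
#' placed entirely inside that gene (so the causal signal is attributable to
#' exactly one gene); all other regions are independent.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with elements \code{panel} (\code{strain_panel}),
#'   \code{annotation} (\code{gene_annotation}) and \code{truth} (class
#'   \code{simulation_truth}: causal gene/block coordinates and the
#'   per-strain haplotype label at the causal block).
#' @export
simulate_panel <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed, .simulate_panel_impl(config))
}

.simulate_panel_impl <- function(config) {
  nS <- config$n_strains
  nC <- config$n_chromosomes
  nV <- config$snps_per_chromosome
  spacing <- 1000L
  strains <- sprintf("strain%02d", seq_len(nS))
  chroms <- paste0("chr", seq_len(nC))

  # tile genes over chromosomes (near-even split, remainder to the first)
  genes_per_chrom <- rep(config$n_genes %/% nC, nC)
  extra <- config$n_genes %% nC
  if (extra) genes_per_chrom[seq_len(extra)] <- genes_per_chrom[seq_len(extra)] + 1L
  gene_rows <- list()
  gid <- 0L
  gene_span <- list()  # per gene: chrom index + SNP index range (local)
  for (c_i in seq_len(nC)) {
    gpc <- genes_per_chrom[c_i]
    if (gpc == 0L) next
    bnd <- floor(seq(0L, nV, length.out = gpc + 1L))
    for (g in seq_len(gpc)) {
      gid <- gid + 1L
      a <- bnd[g] + 1L
      b <- bnd[g + 1L]
      gene_rows[[gid]] <- data.frame(
        gene = sprintf("gene%03d", gid), chrom = chroms[c_i],
        start = (a - 1L) * spacing + 1L, end = b * spacing,
        stringsAsFactors = FALSE)
      gene_span[[gid]] <- list(chrom = c_i, a = a, b = b)
    }
  }
  annotation <- gene_annotation(do.call(rbind, gene_rows))

  causal <- config$causal_gene_index
  causal_chrom <- if (is.na(causal)) NA_integer_ else gene_span[[causal]]$chrom

  geno <- matrix(NA_integer_, nrow = nC * nV, ncol = nS)
  causal_labels <- NULL
  causal_range <- NULL
  for (c_i in seq_len(nC)) {
    if (!is.na(causal) && c_i == causal_chrom) {
      a <- gene_span[[causal]]$a
      b <- gene_span[[causal]]$b
      len_c <- min(.draw_region_lengths(1L, config$mean_block_length_snps),
                   b - a + 1L)
      cstart <- a + (b - a + 1L - len_c) %/% 2L
      cend <- cstart + len_c - 1L
      lens <- c(.tile_lengths(cstart - 1L, config$mean_block_length_snps),
                len_c,
                .tile_lengths(nV - cend, config$mean_block_length_snps))
      causal_region_idx <- sum(cumsum(lens) < cstart) + 1L
    } else {
      lens <- .tile_lengths(nV, config$mean_block_length_snps)
      causal_region_idx <- NA_integer_
    }
    offs <- cumsum(c(0L, lens))
    for (r in seq_along(lens)) {
      len <- lens[r]
      H <- .draw_ancestral(len, config$n_ancestral_haplotypes)
      assign_ <- sample.int(ncol(H), nS, replace = TRUE)
      rows <- (c_i - 1L) * nV + offs[r] + seq_len(len)
      geno[rows, ] <- H[, assign_, drop = FALSE]
      if (!is.na(causal_region_idx) && r == causal_region_idx) {
        causal_labels <- match(assign_, unique(assign_)) - 1L
        names(causal_labels) <- strains
        causal_range <- c(min(rows), max(rows))
      }
    }
  }

  if (config$missing_rate > 0) {
    mask <- stats::runif(length(geno)) < config$missing_rate
    geno[mask] <- NA_integer_
  }

  pos_local <- seq_len(nV) * spacing
  variants <- data.frame(
    chrom = rep(chroms, each = nV),
    pos = rep(pos_local, nC),
    ref = "A", alt = "G", stringsAsFactors = FALSE)
  panel <- strain_panel(strains, variants, geno)

  truth <- structure(list(
    causal_gene = if (is.na(causal)) NA_character_
                  else annotation$gene[causal],
    causal_chrom = if (is.na(causal)) NA_character_ else chroms[causal_chrom],
    causal_start_idx = if (is.null(causal_range)) NA_integer_
                       else causal_range[1L],
    causal_end_idx = if (is.null(causal_range)) NA_integer_
                     else causal_range[2L],
    causal_start_pos = if (is.null(causal_range)) NA_integer_
                       else panel$variants$pos[causal_range[1L]],
    causal_end_pos = if (is.null(causal_range)) NA_integer_
                     else panel$variants$pos[causal_range[2L]],
    causal_labels = causal_labels,
    genetic_values = NULL), class = "simulation_truth")
  list(panel = panel, annotation = annotation, truth = truth)
}

#' Simulate correlated multi-trait phenotypes on a panel
#'
#' Strain-level value for each trait = causal-block group effect (scaled so
#' the configured fraction of unit strain-level variance is attributable to
#' the causal grouping) + correlated residual. Both components share the
#' configured equicorrelation across traits, so strain-level genetic values
#' of any trait pair correlate at \code{trait_correlation}. Per-animal
#' replicates add independent Gaussian noise; per-cell means, SEM and n are
#' populated from the replicates.
#'
#' @param panel a \code{strain_panel} from \code{\link{simulate_panel}}.
#' @param truth the matching \code{simulation_truth}.
#' @param config the matching \code{\link{simulation_config}}.
#' @return a \code{phenotype_table}; the matrix of strain-level genetic
#'   values (traits x strains, before replicate noise) is attached as
#'   attribute \code{"genetic_values"}.
#' @export
simulate_phenotypes <- function(panel, truth, config) {
  stopifnot(inherits(panel, "strain_panel"),
            inherits(truth, "simulation_truth"),
            inherits(config, "simulation_config"))
  # distinct stream from the genotype stream, still a pure function of seed
  seed2 <- (config$seed + 77003L) %% .Machine$integer.max
  .with_seed(seed2, .simulate_phenotypes_impl(panel, truth, config))
}

.trait_names <- function(n) {
  base <- c("mech_oih", "tf_oih", "therm_oih", "tolerance", "dependence")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("trait%02d", seq.int(length(base) + 1L, n)))
}

.simulate_phenotypes_impl <- function(panel, truth, config) {
  nS <- length(panel$strains)
  nT <- config$n_traits
  h <- config$causal_effect_variance_fraction
  rho <- config$trait_correlation
  Sigma <- matrix(rho, nT, nT); diag(Sigma) <- 1
  Ch <- chol(Sigma)
  rmvn <- function(n) matrix(stats::rnorm(n * nT), n, nT) %*% Ch

  # The variance fraction is enforced exactly in-sample, per trait: the
  # causal component (constant within haplotype group) is standardized
  # across strains, the residual is orthogonalized against the grouping
  # (group means removed) and standardized, and the two are mixed with
  # weights sqrt(h), sqrt(1-h). A one-way ANOVA of the strain-level values
  # on the causal grouping then yields eta-squared = h exactly.
  std <- function(v) {
    v <- v - mean(v)
    s <- stats::sd(v)
    if (s > 0) v / s else v
  }
  if (!is.na(truth$causal_gene) && h > 0) {
    lab <- truth$causal_labels[panel$strains]
    k <- length(unique(lab))
    E <- rmvn(k)                       # per-group, per-trait effects
    causal_part <- apply(E[lab + 1L, , drop = FALSE], 2L, std)
    resid <- rmvn(nS)
    resid <- apply(resid, 2L, function(v) {
      std(v - stats::ave(v, lab))      # no between-group leakage
    })
  } else {
    causal_part <- matrix(0, nS, nT)
    h <- 0
    resid <- apply(rmvn(nS), 2L, std)
  }
  X <- sqrt(h) * causal_part + sqrt(1 - h) * resid   # strains x traits
  genetic <- t(X)
  dimnames(genetic) <- list(.trait_names(nT), panel$strains)

  reps <- config$replicates_per_strain
  replicates <- stats::setNames(vector("list", nT), rownames(genetic))
  means <- sem <- matrix(NA_real_, nT, nS, dimnames = dimnames(genetic))
  nmat <- matrix(reps, nT, nS, dimnames = dimnames(genetic))
  for (t_i in seq_len(nT)) {
    replicates[[t_i]] <- stats::setNames(vector("list", nS), panel$strains)
    for (s_i in seq_len(nS)) {
      v <- genetic[t_i, s_i] +
        stats::rnorm(reps, 0, config$replicate_noise_sd)
      replicates[[t_i]][[s_i]] <- v
      means[t_i, s_i] <- mean(v)
      sem[t_i, s_i] <- if (reps > 1L) stats::sd(v) / sqrt(reps) else 0
    }
  }
  pt <- phenotype_table(means, n = nmat, sem = sem, replicates = replicates)
  attr(pt, "genetic_values") <- genetic
  pt
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: panel + annotation + truth + phenotypes, with the
#' truth's per-trait strain-level genetic values filled in.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with \code{panel}, \code{annotation}, \code{truth},
#'   \code{phenotypes}.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  sim <- simulate_panel(config)
  pheno <- simulate_phenotypes(sim$panel, sim$truth, config)
  sim$truth$genetic_values <- attr(pheno, "genetic_values")
  sim$phenotypes <- pheno
  sim
}

#' Simulate a morphine dose-response curve
#'
#' Percent maximal possible effect follows a variable-slope sigmoid rising
#' from 0 to 100, \code{100 / (1 + (ed50/dose)^hill)}, with additive
#' Gaussian noise clipped to [0, 100]. Dose 0 is the floor (0%MPE).
#'
#' @param ed50 dose producing 50% of maximal effect (mg/kg), > 0.
#' @param hill_slope Hill slope (dimensionless, > 0 for a rising curve).
#' @param doses doses in mg/kg (default: the cumulative-dosing ladder
#'   0, 1, 2, 4, 8, 16, 32).
#' @param noise_sd additive noise SD in %MPE units.
#' @param seed integer seed (ignored when \code{noise_sd = 0}).
#' @return data.frame with columns \code{dose}, \code{mpe}.
#' @export
simulate_dose_response <- function(ed50, hill_slope,
                                   doses = c(0, 1, 2, 4, 8, 16, 32),
                                   noise_sd = 0, seed = 1L) {
  if (ed50 <= 0) stop("ed50 must be > 0", call. = FALSE)
  if (any(doses < 0)) stop("doses must be >= 0", call. = FALSE)
  mpe <- ifelse(doses == 0, 0, 100 / (1 + (ed50 / doses)^hill_slope))
  if (noise_sd > 0) {
    mpe <- .with_seed(seed, mpe + stats::rnorm(length(doses), 0, noise_sd))
    mpe <- pmin(pmax(mpe, 0), 100)
  }
  data.frame(dose = doses, mpe = mpe)
}
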
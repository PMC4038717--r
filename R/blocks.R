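# Haplotype block enumeration: sliding windows of consecutive SNPs, strains
# grouped by exact allele string. The compiled kernel does the heavy lifting;
# this file owns the user-facing objects and the partition-key canonicalization.

#' Mapping/analysis configuration
#'
#' Bundles the tunable parameters of block enumeration and association
#' testing. Defaults target a ~23-strain panel: windows of 1-3 SNPs,
#' haplotype groups of at least 3 strains, at most 4 groups.
#'
#' @param window_sizes integer vector of sliding-window widths (SNPs).
#' @param min_group_size smallest admissible haplotype group; windows
#'   producing any smaller group are discarded.
#' @param max_groups largest admissible number of haplotype groups.
#' @param min_nonmissing_frac minimum fraction of strains that must be fully
#'   genotyped in a window for it to be testable.
#' @param flank basepairs added to both sides of gene intervals when
#'   assigning blocks to genes.
#' @param p_floor smallest reported p-value (keeps -log10 finite).
#' @param effect_measure \code{"eta2"} (between-group / total sum of squares)
#'   or \code{"range"} (max group-mean difference over the phenotype range).
#' @param min_strains warn when fewer strains than this enter the mapping.
#' @return a list of class \code{hbcgm_config}.
#' @export
hbcgm_config <- function(window_sizes = c(1L, 2L, 3L),
                         min_group_size = 3L,
                         max_groups = 4L,
                         min_nonmissing_frac = 0.5,
                         flank = 0L,
                         p_floor = 1e-300,
                         effect_measure = c("eta2", "range"),
                         min_strains = 10L) {
  effect_measure <- match.arg(effect_measure)
  window_sizes <- sort(unique(as.integer(window_sizes)))
  if (length(window_sizes) == 0L || any(window_sizes < 1L))
    stop("window sizes must be positive integers", call. = FALSE)
  if (min_group_size < 1L) stop("min_group_size must be >= 1", call. = FALSE)
  if (max_groups < 2L) stop("max_groups must be >= 2", call. = FALSE)
  if (min_nonmissing_frac < 0 || min_nonmissing_frac > 1)
    stop("min_nonmissing_frac must be in [0, 1]", call. = FALSE)
  structure(list(window_sizes = window_sizes,
                 min_group_size = as.integer(min_group_size),
                 max_groups = as.integer(max_groups),
                 min_nonmissing_frac = min_nonmissing_frac,
                 flank = as.integer(flank),
                 p_floor = p_floor,
                 effect_measure = effect_measure,
                 min_strains = as.integer(min_strains)),
            class = "hbcgm_config")
}

# integer chromosome codes in order of first appearance
.chrom_codes <- function(variants) {
  match(variants$chrom, unique(variants$chrom))
}

# Canonical partition key, invariant to strain column order: strains sorted
# by name, missing strains dropped, groups relabelled by first occurrence in
# sorted order. Same induced partition <=> same key.
.partition_key <- function(labels, strains) {
  ord <- order(strains)
  l <- labels[ord]
  s <- strains[ord]
  keep <- !is.na(l)
  l <- l[keep]
  s <- s[keep]
  l <- match(l, unique(l)) - 1L
  paste(s, l, sep = "=", collapse = "|")
}

#' Enumerate haplotype blocks over a strain panel
#'
#' Slides windows of each configured size along every chromosome, groups
#' strains by their exact allele string in the window and keeps windows whose
#' induced partition passes the group-count/group-size/missingness filters.
#' Strains with any missing call in a window carry no label there.
#'
#' @param panel a \code{strain_panel}.
#' @param config an \code{\link{hbcgm_config}} (window sizes and filters).
#' @return An object of class \code{haplotype_blocks}: a list with
#'   \describe{
#'     \item{blocks}{data.frame, one row per retained window: \code{chrom},
#'       \code{start_idx}/\code{end_idx} (variant indices), \code{start_pos}/
#'       \code{end_pos} (bp), \code{window}, \code{n_groups}, \code{part_id},
#'       \code{partition_key}.}
#'     \item{partitions}{integer matrix, one row per distinct partition,
#'       one column per strain; canonical group labels 0,1,..., \code{NA}
#'       for unlabelled strains.}
#'     \item{strains}{strain identifiers (column order of
#'       \code{partitions}).}
#'   }
#' @export
enumerate_blocks <- function(panel, config = hbcgm_config()) {
  stopifnot(inherits(panel, "strain_panel"))
  stopifnot(inherits(config, "hbcgm_config"))
  cc <- .chrom_codes(panel$variants)
  res <- .enumerate_blocks_cpp(panel$geno, cc, config$window_sizes,
                               config$min_group_size, config$max_groups,
                               config$min_nonmissing_frac)
  parts <- res$partitions
  colnames(parts) <- panel$strains
  keys <- if (nrow(parts)) {
    vapply(seq_len(nrow(parts)),
           function(u) .partition_key(parts[u, ], panel$strains), "")
  } else character(0)
  ch <- panel$variants$chrom
  pos <- panel$variants$pos
  n_groups <- if (nrow(parts)) {
    apply(parts, 1L, function(r) length(unique(r[!is.na(r)])))
  } else integer(0)
  blocks <- data.frame(
    chrom = ch[res$start],
    start_idx = res$start, end_idx = res$end,
    start_pos = pos[res$start], end_pos = pos[res$end],
    window = res$window,
    n_groups = n_groups[res$part_id],
    part_id = res$part_id,
    partition_key = keys[res$part_id],
    widx = res$widx,
    stringsAsFactors = FALSE)
  structure(list(blocks = blocks, partitions = parts,
                 strains = panel$strains, config = config,
                 n_windows = res$n_windows),
            class = "haplotype_blocks")
}

#' @export
print.haplotype_blocks <- function(x, ...) {
  cat(sprintf(
    "<haplotype_blocks> %d blocks (%d distinct partitions) over %d strains\n",
    nrow(x$blocks), nrow(x$partitions), length(x$strains)))
  invisible(x)
}

#' Strain group labels for one block
#' @param blocks a \code{haplotype_blocks} object.
#' @param i block row index.
#' @return named integer vector of canonical group labels (NA = unlabelled).
#' @export
block_labels <- function(blocks, i) {
  stopifnot(inherits(blocks, "haplotype_blocks"))
  labs <- blocks$partitions[blocks$blocks$part_id[i], ]
  names(labs) <- blocks$strains
  labs
}

#' Group blocks by the strain partition they induce
#'
#' Blocks inducing the same partition share their association test and its
#' p-value, so the test is run once per distinct partition.
#'
#' @param blocks a \code{haplotype_blocks} object.
#' @return named list mapping \code{partition_key} to the integer indices of
#'   member block rows. The total member count equals the block count.
#' @export
dedupe_partitions <- function(blocks) {
  stopifnot(inherits(blocks, "haplotype_blocks"))
  if (nrow(blocks$blocks) == 0L) return(structure(list(), names = character(0)))
  split(seq_len(nrow(blocks$blocks)), blocks$blocks$partition_key)
}

#' Partition strains by their alleles at selected SNPs
#'
#' Groups strains by the joint allele pattern at a handful of named SNPs
#' (e.g. amino-acid-changing variants within a candidate gene) and classifies
#' each strain's phenotype value against a threshold. Strains with a missing
#' call at any selected SNP form their own \code{NA}-pattern group.
#'
#' @param panel a \code{strain_panel}.
#' @param snp_selectors data.frame with columns \code{chrom}, \code{pos}.
#' @param phenotype named numeric vector of per-strain values (e.g.
#'   fraction-of-baseline thresholds).
#' @param threshold low/high classification boundary (default 0.5; values
#'   strictly below are "low").
#' @return list with \code{strains} (data.frame: strain, pattern, group,
#'   value, class) and \code{groups} (data.frame: group, pattern, n,
#'   mean_value, class counts).
#' @export
partition_by_snps <- function(panel, snp_selectors, phenotype,
                              threshold = 0.5) {
  stopifnot(inherits(panel, "strain_panel"))
  snp_selectors <- as.data.frame(snp_selectors)
  idx <- mapply(function(ch, po) {
    i <- which(panel$variants$chrom == ch & panel$variants$pos == po)
    if (length(i) != 1L)
      stop(sprintf("SNP %s:%d not found in panel", ch, as.integer(po)),
           call. = FALSE)
    i
  }, snp_selectors$chrom, snp_selectors$pos)
  g <- panel$geno[idx, , drop = FALSE]
  pattern <- apply(g, 2L, function(col) paste(ifelse(is.na(col), ".", col),
                                              collapse = "/"))
  group <- match(pattern, unique(pattern))
  value <- phenotype[panel$strains]
  cls <- ifelse(is.na(value), NA_character_,
                ifelse(value < threshold, "low", "high"))
  per_strain <- data.frame(strain = panel$strains, pattern = pattern,
                           group = group, value = unname(value),
                           class = cls, stringsAsFactors = FALSE,
                           row.names = NULL)
  gs <- split(per_strain, per_strain$group)
  groups <- do.call(rbind, lapply(gs, function(d) data.frame(
    group = d$group[1L], pattern = d$pattern[1L], n = nrow(d),
    mean_value = mean(d$value, na.rm = TRUE),
    n_low = sum(d$class == "low", na.rm = TRUE),
    n_high = sum(d$class == "high", na.rm = TRUE),
    stringsAsFactors = FALSE)))
  rownames(groups) <- NULL
  list(strains = per_strain, groups = groups)
}
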
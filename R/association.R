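# Association engine: one-way fixed-effects ANOVA of strain means grouped by
# haplotype label, vectorized across the distinct partitions of a panel.

# Vectorized one-way ANOVA over partitions (compiled kernel).
# L: U x S integer label matrix (0..G-1, NA = excluded strain);
# y: numeric length S, one value per strain (no NAs).
# Returns data.frame with f, p, eta, effect_range, k, n, degenerate.
.anova_partitions <- function(L, y, p_floor = 1e-300) {
  U <- nrow(L)
  if (U == 0L)
    return(data.frame(f = numeric(0), p = numeric(0), eta = numeric(0),
                      effect_range = numeric(0), k = integer(0),
                      n = integer(0), degenerate = logical(0)))
  stopifnot(length(y) == ncol(L), !anyNA(y))
  res <- .anova_partitions_cpp(L, as.numeric(y), p_floor)
  yrange <- diff(range(y))
  effect_range <- if (yrange > 0)
    pmin(pmax(res$mean_range / yrange, 0), 1) else rep(NA_real_, U)
  data.frame(f = res$f, p = res$p, eta = res$eta,
             effect_range = effect_range, k = res$k, n = res$n,
             degenerate = res$degenerate)
}

#' Test one strain partition against a trait
#'
#' One-way fixed-effects analysis of variance of per-strain trait means
#' grouped by haplotype label. The genetic effect is eta-squared: the
#' between-group sum of squares over the total sum of squares, i.e. the
#' fraction of inter-strain variance attributable to the partition.
#'
#' @param partition integer/factor vector of group labels, one per strain
#'   (NA = strain excluded). Named vectors are matched to
#'   \code{trait_values} by name.
#' @param trait_values numeric per-strain trait means (NA allowed; such
#'   strains are excluded).
#' @param min_group_size groups smaller than this (after exclusions) raise
#'   an error (default 2: the F-test needs within-group replication unless
#'   separation is perfect).
#' @param p_floor smallest reported p-value; perfect separation (zero
#'   within-group variance with unequal means) reports this floor, never 0.
#' @return list with \code{f_statistic}, \code{p_value},
#'   \code{genetic_effect}, \code{n_strains_tested}, \code{n_groups},
#'   \code{degenerate}.
#' @examples
#' block_association(c(0, 0, 1, 1), c(1, 1, 3, 3))   # perfect separation
#' @export
block_association <- function(partition, trait_values, min_group_size = 2L,
                              p_floor = 1e-300) {
  if (!is.null(names(partition)) && !is.null(names(trait_values)))
    trait_values <- trait_values[names(partition)]
  if (length(partition) != length(trait_values))
    stop("partition and trait_values lengths differ", call. = FALSE)
  lab <- as.integer(as.factor(partition))
  keep <- !is.na(lab) & !is.na(trait_values)
  lab <- lab[keep]
  y <- as.numeric(trait_values[keep])
  if (length(unique(lab)) < 2L)
    stop("need at least 2 groups with phenotype values", call. = FALSE)
  sizes <- table(lab)
  if (any(sizes < min_group_size))
    stop("every group must have at least ", min_group_size, " strains",
         call. = FALSE)
  L <- matrix(match(lab, unique(lab)) - 1L, nrow = 1L)
  res <- .anova_partitions(L, y, p_floor = p_floor)
  if (res$degenerate[1L])
    stop("all trait values identical; association undefined", call. = FALSE)
  list(f_statistic = res$f[1L], p_value = res$p[1L],
       genetic_effect = res$eta[1L], n_strains_tested = res$n[1L],
       n_groups = res$k[1L], degenerate = FALSE)
}

# ---- genomic spans of all candidate windows (independent of strain subset) --

# Enumerates window spans in exactly the order of the compiled kernel:
# by window size, then chromosome run, then start index.
.window_spans <- function(panel, window_sizes) {
  cc <- .chrom_codes(panel$variants)
  pos <- panel$variants$pos
  ch <- panel$variants$chrom
  runs <- rle(cc)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  out <- vector("list", length(window_sizes) * length(run_start))
  j <- 0L
  for (w in window_sizes) {
    for (r in seq_along(run_start)) {
      j <- j + 1L
      if (run_end[r] - run_start[r] + 1L < w) next
      starts <- run_start[r]:(run_end[r] - w + 1L)
      out[[j]] <- data.frame(chrom = ch[starts], start_pos = pos[starts],
                             end_pos = pos[starts + w - 1L],
                             stringsAsFactors = FALSE)
    }
  }
  spans <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(spans))
    spans <- data.frame(chrom = character(0), start_pos = integer(0),
                        end_pos = integer(0))
  spans$widx <- seq_len(nrow(spans))
  spans
}

# gene -> integer vector of window indices whose span overlaps the gene
.gene_window_index <- function(spans, annotation, flank = 0L) {
  gr_w <- GenomicRanges::GRanges(
    spans$chrom, IRanges::IRanges(spans$start_pos, spans$end_pos))
  gr_g <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(pmax(1L, annotation$start - flank),
                     annotation$end + flank))
  hits <- GenomicRanges::findOverlaps(gr_g, gr_w)
  idx <- split(S4Vectors::subjectHits(hits),
               factor(S4Vectors::queryHits(hits),
                      levels = seq_len(nrow(annotation))))
  names(idx) <- annotation$gene
  lapply(idx, as.integer)
}

#' Assign haplotype blocks to overlapping genes
#'
#' A block is assigned to every gene whose (optionally flanked) interval
#' overlaps the block's genomic span, first to last SNP position. Gene
#' intervals are full gene bodies, so intronic blocks are assigned.
#'
#' @param blocks a \code{haplotype_blocks} object.
#' @param annotation a \code{gene_annotation}.
#' @param flank basepairs added to both sides of each gene interval.
#' @return list of character vectors, one per block (possibly empty).
#' @export
map_blocks_to_genes <- function(blocks, annotation, flank = 0L) {
  stopifnot(inherits(blocks, "haplotype_blocks"),
            inherits(annotation, "gene_annotation"))
  b <- blocks$blocks
  if (nrow(b) == 0L) return(list())
  gr_b <- GenomicRanges::GRanges(
    b$chrom, IRanges::IRanges(b$start_pos, b$end_pos))
  gr_g <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(pmax(1L, annotation$start - flank),
                     annotation$end + flank))
  hits <- GenomicRanges::findOverlaps(gr_b, gr_g)
  out <- rep(list(character(0)), nrow(b))
  if (length(hits)) {
    sp <- split(annotation$gene[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    out[as.integer(names(sp))] <- lapply(sp, function(g) sort(unique(g)))
  }
  out
}

# ---- mapping context: reusable precomputation for resampling loops ---------

.mapping_context <- function(panel, annotation, phenotypes, config) {
  stopifnot(inherits(panel, "strain_panel"),
            inherits(annotation, "gene_annotation"),
            inherits(phenotypes, "phenotype_table"))
  common <- intersect(panel$strains, colnames(phenotypes$means))
  if (length(common) < 2L)
    stop("panel and phenotype table share fewer than 2 strains",
         call. = FALSE)
  spans <- .window_spans(panel, config$window_sizes)
  list(panel = panel, annotation = annotation, phenotypes = phenotypes,
       config = config, common = common,
       chrom_codes = .chrom_codes(panel$variants),
       spans = spans,
       gene_widx = .gene_window_index(spans, annotation, config$flank))
}

# Per-gene best (minimum) p-value for one trait on one strain subset.
# Returns named numeric vector over all annotation genes (NA = gene has no
# testable block in this subset).
.context_gene_pvalues <- function(ctx, trait, strains = ctx$common) {
  cfg <- ctx$config
  y <- ctx$phenotypes$means[trait, strains]
  geno <- ctx$panel$geno[, strains, drop = FALSE]
  res <- .enumerate_blocks_cpp(geno, ctx$chrom_codes, cfg$window_sizes,
                               cfg$min_group_size, cfg$max_groups,
                               cfg$min_nonmissing_frac)
  genes <- names(ctx$gene_widx)
  p_win <- rep(NA_real_, res$n_windows)
  if (length(res$start)) {
    an <- .anova_partitions(res$partitions, as.numeric(y),
                            p_floor = cfg$p_floor)
    pb <- an$p[res$part_id]
    pb[an$degenerate[res$part_id]] <- NA_real_
    p_win[res$widx] <- pb
  }
  vapply(ctx$gene_widx, function(ix) {
    v <- p_win[ix]
    v <- v[!is.na(v)]
    if (length(v)) min(v) else NA_real_
  }, numeric(1), USE.NAMES = TRUE)
}

#' Map one trait genome-wide
#'
#' The whole-genome engine: enumerate haplotype blocks, run the association
#' test once per distinct strain partition, broadcast the shared result to
#' every member block, annotate overlapping genes, and sort.
#'
#' @param panel a \code{strain_panel}.
#' @param annotation a \code{gene_annotation}.
#' @param phenotypes a \code{phenotype_table}.
#' @param trait trait name to map.
#' @param config an \code{\link{hbcgm_config}}.
#' @return data.frame of class \code{association_records}, one row per
#'   retained block, sorted by ascending p-value with deterministic
#'   tie-breaks (genetic effect descending, then chromosome/position, then
#'   gene label). Columns: trait, chrom, start_pos, end_pos, start_idx,
#'   end_idx, window, n_groups, partition_key, f_statistic, p_value,
#'   genetic_effect, n_strains_tested, genes (comma-separated, "" if
#'   intergenic).
#' @export
map_trait <- function(panel, annotation, phenotypes, trait,
                      config = hbcgm_config()) {
  ctx <- .mapping_context(panel, annotation, phenotypes, config)
  if (!trait %in% rownames(phenotypes$means))
    stop("unknown trait: ", trait, call. = FALSE)
  strains <- ctx$common
  if (length(strains) < config$min_strains)
    warning(sprintf(
      "only %d strains shared by panel and phenotypes (recommended >= %d)",
      length(strains), config$min_strains))
  y <- phenotypes$means[trait, strains]
  sub <- subset_strains(panel, strains)
  blocks <- enumerate_blocks(sub, config)
  b <- blocks$blocks
  if (nrow(b) == 0L) {
    warning("no testable blocks for trait ", trait)
    return(.empty_records(trait))
  }
  an <- .anova_partitions(blocks$partitions, as.numeric(y),
                          p_floor = config$p_floor)
  ndeg <- sum(an$degenerate)
  if (ndeg)
    message(sprintf("%d degenerate partition(s) skipped for trait %s",
                    ndeg, trait))
  keep <- !an$degenerate[b$part_id]
  b <- b[keep, , drop = FALSE]
  if (nrow(b) == 0L) return(.empty_records(trait))
  pid <- b$part_id
  eff <- if (config$effect_measure == "eta2") an$eta else an$effect_range
  genes <- map_blocks_to_genes(
    structure(list(blocks = b, partitions = blocks$partitions,
                   strains = blocks$strains), class = "haplotype_blocks"),
    annotation, config$flank)
  gene_label <- vapply(genes, paste, "", collapse = ",")
  rec <- data.frame(
    trait = trait, chrom = b$chrom,
    start_pos = b$start_pos, end_pos = b$end_pos,
    start_idx = b$start_idx, end_idx = b$end_idx,
    window = b$window, n_groups = b$n_groups,
    partition_key = b$partition_key,
    part_id = b$part_id,
    f_statistic = an$f[pid], p_value = an$p[pid],
    genetic_effect = eff[pid], n_strains_tested = an$n[pid],
    genes = gene_label, stringsAsFactors = FALSE)
  ord <- order(rec$p_value, -rec$genetic_effect,
               match(rec$chrom, unique(panel$variants$chrom)),
               rec$start_pos, rec$genes, method = "radix")
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "strains") <- strains
  attr(rec, "partitions") <- blocks$partitions
  class(rec) <- c("association_records", "data.frame")
  rec
}

.empty_records <- function(trait) {
  rec <- data.frame(trait = character(0), chrom = character(0),
                    start_pos = integer(0), end_pos = integer(0),
                    start_idx = integer(0), end_idx = integer(0),
                    window = integer(0), n_groups = integer(0),
                    partition_key = character(0), part_id = integer(0),
                    f_statistic = numeric(0),
                    p_value = numeric(0), genetic_effect = numeric(0),
                    n_strains_tested = integer(0), genes = character(0),
                    stringsAsFactors = FALSE)
  class(rec) <- c("association_records", "data.frame")
  rec
}

#' Best association per gene
#'
#' Collapses block-level association records to one row per gene (the
#' minimum-p block among blocks overlapping the gene) and ranks genes by
#' ascending p. Intergenic blocks (no overlapping gene) are excluded from
#' the ranking; set \code{include_intergenic = TRUE} to append their best
#' record under the sentinel label \code{"(intergenic)"} with rank NA.
#'
#' @param records an \code{association_records} data.frame from
#'   \code{\link{map_trait}}.
#' @param include_intergenic append the best intergenic record?
#' @return data.frame: gene, p_value, f_statistic, genetic_effect, chrom,
#'   start_pos, end_pos, window, partition_key, rank.
#' @export
gene_summary <- function(records, include_intergenic = FALSE) {
  stopifnot(inherits(records, "association_records"))
  if (nrow(records) == 0L) {
    out <- records[, c("chrom", "start_pos", "end_pos", "window",
                       "partition_key", "f_statistic", "p_value",
                       "genetic_effect")]
    out$gene <- character(0)
    out$rank <- integer(0)
    out <- out[, c("gene", "p_value", "f_statistic", "genetic_effect",
                   "chrom", "start_pos", "end_pos", "window",
                   "partition_key", "rank")]
    class(out) <- "data.frame"
    return(out)
  }
  gl <- strsplit(records$genes, ",", fixed = TRUE)
  nper <- lengths(gl)
  has <- nper > 0L
  long <- records[rep(seq_len(nrow(records)), nper), , drop = FALSE]
  long$gene <- unlist(gl)
  if (include_intergenic && any(!has)) {
    inter <- records[!has, , drop = FALSE]
    inter$gene <- "(intergenic)"
    inter <- inter[1L, , drop = FALSE]  # records are p-sorted: best first
    long <- rbind(long, inter)
  }
  # records are already sorted with full tie-breaks; the first row per gene
  # is its best record
  first <- !duplicated(long$gene)
  out <- long[first, c("gene", "p_value", "f_statistic", "genetic_effect",
                       "chrom", "start_pos", "end_pos", "window",
                       "partition_key"), drop = FALSE]
  ord <- order(out$gene != "(intergenic)", decreasing = TRUE)
  out <- out[ord, , drop = FALSE]
  genic <- out$gene != "(intergenic)"
  out$rank <- NA_integer_
  out$rank[genic] <- seq_len(sum(genic))
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}
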
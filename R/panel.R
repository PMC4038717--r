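#' Construct a strain genotype panel
#'
#' The central container of the package: an ordered set of inbred strains
#' genotyped at biallelic SNPs. Because inbred strains are homozygous, each
#' strain carries a single allele code per variant: \code{0} (reference),
#' \code{1} (alternate) or \code{NA} (missing / no-call).
#'
#' @param strains character vector of unique strain identifiers.
#' @param variants data.frame with columns \code{chrom} (character),
#'   \code{pos} (1-based integer position), \code{ref} and \code{alt}
#'   (single bases). Within each chromosome positions must be strictly
#'   increasing.
#' @param geno integer matrix of allele codes, \code{nrow(variants)} rows by
#'   \code{length(strains)} columns, values in \code{c(0L, 1L, NA)}.
#' @return An object of class \code{strain_panel} with elements
#'   \code{strains}, \code{variants}, \code{geno}.
#' @examples
#' p <- strain_panel(
#'   strains  = c("A", "B", "C"),
#'   variants = data.frame(chrom = "chr1", pos = c(100L, 200L),
#'                         ref = "A", alt = "G"),
#'   geno     = matrix(c(0L, 1L, 1L, 0L, 0L, 1L), nrow = 2, byrow = TRUE)
#' )
#' p
#' @export
strain_panel <- function(strains, variants, geno) {
  strains <- as.character(strains)
  if (length(strains) < 2L)
    stop("a strain panel needs at least 2 strains", call. = FALSE)
  if (anyDuplicated(strains))
    stop("strain identifiers must be unique", call. = FALSE)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(variants)))
    stop("variants must have columns chrom, pos, ref, alt", call. = FALSE)
  variants <- variants[, req]
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(variants) || ncol(geno) != length(strains))
    stop("geno must be nrow(variants) x length(strains)", call. = FALSE)
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop("allele codes must be 0, 1 or NA", call. = FALSE)
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0L))
      stop("positions must be strictly increasing within chromosome ", ch,
           call. = FALSE)
  }
  if (any(nchar(variants$ref) != 1L) || any(nchar(variants$alt) != 1L))
    stop("only biallelic SNVs are allowed (single-base ref/alt)",
         call. = FALSE)
  # canonical ordering: chromosomes contiguous (in order of first
  # appearance), positions increasing within each
  ord <- order(match(variants$chrom, unique(variants$chrom)),
               method = "radix")
  if (is.unsorted(ord)) {
    variants <- variants[ord, , drop = FALSE]
    geno <- geno[ord, , drop = FALSE]
  }
  dimnames(geno) <- list(NULL, strains)
  rownames(variants) <- NULL
  structure(list(strains = strains, variants = variants, geno = geno),
            class = "strain_panel")
}

#' @export
print.strain_panel <- function(x, ...) {
  cat(sprintf("<strain_panel> %d strains x %d SNPs on %d chromosome(s)\n",
              length(x$strains), nrow(x$variants),
              length(unique(x$variants$chrom))))
  nmiss <- sum(is.na(x$geno))
  if (nmiss)
    cat(sprintf("  missing calls: %d (%.2f%%)\n", nmiss,
                100 * nmiss / length(x$geno)))
  invisible(x)
}

#' Restrict a panel to a subset of strains
#'
#' Variants are untouched; only genotype columns are dropped. Used by the
#' robustness resampling machinery.
#'
#' @param panel a \code{strain_panel}.
#' @param strains character vector of strains to keep (order respected).
#' @return a \code{strain_panel} over the requested strains.
#' @export
subset_strains <- function(panel, strains) {
  stopifnot(inherits(panel, "strain_panel"))
  missing_ <- setdiff(strains, panel$strains)
  if (length(missing_))
    stop("strains not in panel: ", paste(missing_, collapse = ", "),
         call. = FALSE)
  strain_panel(strains, panel$variants,
               panel$geno[, strains, drop = FALSE])
}

#' Construct a gene annotation table
#'
#' @param genes data.frame with columns \code{gene}, \code{chrom},
#'   \code{start}, \code{end}; coordinates are 1-based inclusive. Overlapping
#'   genes are retained as-is (never merged); a gene may span megabases.
#' @return object of class \code{gene_annotation} (a validated data.frame).
#' @export
gene_annotation <- function(genes) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  req <- c("gene", "chrom", "start", "end")
  if (!all(req %in% names(genes)))
    stop("annotation needs columns gene, chrom, start, end", call. = FALSE)
  genes <- genes[, req]
  genes$gene <- as.character(genes$gene)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (anyDuplicated(genes$gene))
    stop("gene names must be unique", call. = FALSE)
  if (any(genes$start > genes$end))
    stop("gene intervals must satisfy start <= end", call. = FALSE)
  if (any(genes$start < 1L))
    stop("1-based coordinates: start must be >= 1", call. = FALSE)
  rownames(genes) <- NULL
  class(genes) <- c("gene_annotation", "data.frame")
  genes
}

#' Construct a phenotype table
#'
#' Holds trait-by-strain means (the response variables of the mapping),
#' optionally with per-cell replicate counts, standard errors and raw
#' per-animal values.
#'
#' @param means numeric matrix, traits in rows, strains in columns, with
#'   dimnames. All stored means must be finite.
#' @param n optional integer matrix of per-cell replicate counts (same shape).
#' @param sem optional numeric matrix of per-cell standard errors.
#' @param replicates optional named list: \code{replicates[[trait]][[strain]]}
#'   is the vector of per-animal values. When present, replicate means must
#'   agree with \code{means} to within \code{tol}.
#' @param tol tolerance for the replicate-mean consistency check.
#' @return object of class \code{phenotype_table}.
#' @export
phenotype_table <- function(means, n = NULL, sem = NULL, replicates = NULL,
                            tol = 1e-8) {
  means <- as.matrix(means)
  if (is.null(rownames(means)) || is.null(colnames(means)))
    stop("means must have trait rownames and strain colnames", call. = FALSE)
  if (anyDuplicated(rownames(means)) || anyDuplicated(colnames(means)))
    stop("trait and strain names must be unique", call. = FALSE)
  if (any(!is.finite(means)))
    stop("all trait means must be finite", call. = FALSE)
  chk_shape <- function(m, what) {
    if (!is.null(m)) {
      m <- as.matrix(m)
      if (!identical(dim(m), dim(means)))
        stop(what, " must match the shape of means", call. = FALSE)
      dimnames(m) <- dimnames(means)
    }
    m
  }
  n <- chk_shape(n, "n")
  sem <- chk_shape(sem, "sem")
  if (!is.null(replicates)) {
    for (tr in names(replicates)) {
      if (!tr %in% rownames(means))
        stop("replicates for unknown trait ", tr, call. = FALSE)
      for (st in names(replicates[[tr]])) {
        v <- replicates[[tr]][[st]]
        if (abs(mean(v) - means[tr, st]) > tol)
          stop(sprintf("replicate mean mismatch for (%s, %s)", tr, st),
               call. = FALSE)
      }
    }
  }
  structure(list(means = means, n = n, sem = sem, replicates = replicates),
            class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("<phenotype_table> %d trait(s) x %d strain(s)\n",
              nrow(x$means), ncol(x$means)))
  cat("  traits:", paste(rownames(x$means), collapse = ", "), "\n")
  invisible(x)
}

#' Trait names of a phenotype table
#' @param table a \code{phenotype_table}.
#' @return character vector of trait names.
#' @export
traits <- function(table) {
  stopifnot(inherits(table, "phenotype_table"))
  rownames(table$means)
}

#' Strain means for one trait
#' @param table a \code{phenotype_table}.
#' @param trait trait name.
#' @return named numeric vector of per-strain means.
#' @export
trait_values <- function(table, trait) {
  stopifnot(inherits(table, "phenotype_table"))
  if (!trait %in% rownames(table$means))
    stop("unknown trait: ", trait, call. = FALSE)
  table$means[trait, ]
}
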
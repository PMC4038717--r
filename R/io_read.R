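# Readers: multi-sample VCF / TSV genotype matrices, BED / GFF3 gene
# annotations, wide or long phenotype CSVs. Everything is validated into the
# package's domain types at the boundary; internal coordinates are 1-based
# inclusive throughout.

#' Read a multi-strain genotype panel
#'
#' VCF input expects one sample column per inbred strain with homozygous
#' diploid (or haploid) genotype calls; \code{0/0} maps to allele code 0,
#' \code{1/1} to 1, missing to NA. Multi-allelic sites and indels are
#' skipped with a reported count. Residual heterozygous calls are handled
#' per \code{het_action}: set to missing (default, with a warning), drop the
#' variant, or error.
#'
#' The TSV dialect is a plain variant-by-strain matrix: header row, columns
#' \code{chrom}, \code{pos}, \code{ref}, \code{alt}, then one column per
#' strain with codes 0/1/NA.
#'
#' @param path input file.
#' @param format \code{"auto"} (by extension), \code{"vcf"} or
#'   \code{"tsv"}.
#' @param het_action one of \code{"set-missing"}, \code{"drop-variant"},
#'   \code{"error"}.
#' @return a \code{strain_panel}; the number of skipped non-SNV records is
#'   attached as attribute \code{"n_skipped"}.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           het_action = c("set-missing", "drop-variant",
                                          "error")) {
  format <- match.arg(format)
  het_action <- match.arg(het_action)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  if (format == "vcf") .read_genotypes_vcf(path, het_action)
  else .read_genotypes_tsv(path, het_action)
}

.apply_het_action <- function(geno, het, het_action) {
  n_het <- sum(het)
  if (n_het == 0L) return(list(geno = geno, drop = logical(nrow(geno))))
  if (het_action == "error")
    stop(n_het, " heterozygous call(s) in inbred panel", call. = FALSE)
  if (het_action == "set-missing") {
    warning(n_het, " heterozygous call(s) set to missing")
    geno[het] <- NA_integer_
    return(list(geno = geno, drop = logical(nrow(geno))))
  }
  drop <- rowSums(het) > 0L
  warning(sum(drop), " variant(s) with heterozygous calls dropped")
  list(geno = geno, drop = drop)
}

.read_genotypes_vcf <- function(path, het_action) {
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path, genome = "unknown"),
    error = function(e) stop("failed to parse VCF ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  snv <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snv)
  if (n_skipped)
    message(n_skipped, " non-biallelic-SNV record(s) skipped")
  if (!any(snv)) stop("no usable biallelic SNVs in ", path, call. = FALSE)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  gt <- gt[snv, , drop = FALSE]
  code <- matrix(NA_integer_, nrow(gt), ncol(gt),
                 dimnames = dimnames(gt))
  code[gt %in% c("0/0", "0|0", "0")] <- 0L
  code[gt %in% c("1/1", "1|1", "1")] <- 1L
  het <- gt %in% c("0/1", "1/0", "0|1", "1|0")
  dim(het) <- dim(gt)
  res <- .apply_het_action(code, het, het_action)
  keep <- !res$drop
  variants <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[snv][keep],
    pos = GenomicRanges::start(rr)[snv][keep],
    ref = ref[snv][keep], alt = alt1[snv][keep],
    stringsAsFactors = FALSE)
  if (nrow(variants) == 0L)
    stop("no usable variants remain in ", path, call. = FALSE)
  panel <- strain_panel(colnames(gt), variants,
                        res$geno[keep, , drop = FALSE])
  attr(panel, "n_skipped") <- n_skipped
  panel
}

.read_genotypes_tsv <- function(path, het_action) {
  d <- tryCatch(
    data.table::fread(path, sep = "\t", header = TRUE,
                      colClasses = list(character = c("chrom", "ref", "alt")),
                      data.table = FALSE, na.strings = c("NA", ".")),
    error = function(e) stop("failed to parse TSV ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(d)))
    stop("genotype TSV needs header columns chrom, pos, ref, alt",
         call. = FALSE)
  strains <- setdiff(names(d), req)
  if (length(strains) < 2L)
    stop("genotype TSV needs at least 2 strain columns", call. = FALSE)
  geno <- as.matrix(d[, strains, drop = FALSE])
  storage.mode(geno) <- "integer"
  snv <- nchar(d$ref) == 1L & nchar(d$alt) == 1L
  n_skipped <- sum(!snv)
  if (n_skipped) message(n_skipped, " non-SNV record(s) skipped")
  if (!any(snv)) stop("no usable biallelic SNVs in ", path, call. = FALSE)
  panel <- strain_panel(strains, d[snv, req], geno[snv, , drop = FALSE])
  attr(panel, "n_skipped") <- n_skipped
  panel
}

#' Read a gene annotation
#'
#' BED intervals (0-based half-open) are converted to the 1-based inclusive
#' internal convention; GFF3 rows are restricted to a feature type (default
#' \code{"gene"}) and used as-is. Overlapping genes are retained, never
#' merged.
#'
#' @param path input file.
#' @param format \code{"auto"} (by extension), \code{"bed"} or
#'   \code{"gff3"}.
#' @param feature_type GFF3 feature type to keep.
#' @return a \code{gene_annotation}.
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gff3"),
                            feature_type = "gene") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed"
              else "gff3"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3"),
    error = function(e) stop("failed to parse ", format, " ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (format == "gff3") {
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == feature_type]
    md <- S4Vectors::mcols(gr)
    nm <- if ("Name" %in% names(md) && !all(is.na(md$Name))) md$Name
          else if ("ID" %in% names(md)) md$ID
          else as.character(seq_along(gr))
    nm <- as.character(nm)
  } else {
    nm <- if (!is.null(gr$name)) as.character(gr$name)
          else as.character(seq_along(gr))
  }
  if (length(gr) == 0L)
    stop("no ", if (format == "gff3") feature_type else "interval",
         " records in ", path, call. = FALSE)
  gene_annotation(data.frame(
    gene = nm,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),   # rtracklayer already 1-based
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE))
}

#' Read a phenotype table
#'
#' Wide format: a \code{strain} column plus one numeric column per trait
#' (strain means). Long format (detected by its column set): columns
#' \code{strain}, \code{trait}, \code{animal}, \code{value}; per-animal
#' values are aggregated to strain means with n and SEM retained.
#'
#' @param path CSV file.
#' @return a \code{phenotype_table}.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- tryCatch(
    data.table::fread(path, header = TRUE, data.table = FALSE,
                      colClasses = "character", na.strings = "NA"),
    error = function(e) stop("failed to parse CSV ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  cn <- tolower(names(d))
  if (all(c("strain", "trait", "animal", "value") %in% cn)) {
    names(d) <- cn
    key <- paste(d$strain, d$trait, d$animal, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1L]
      stop("duplicate (strain, trait, animal) record: ",
           gsub("\r", "/", dup), call. = FALSE)
    }
    v <- .parse_numeric(d$value, path)
    traits_ <- unique(d$trait)
    strains_ <- unique(d$strain)
    mk <- function(f) {
      m <- matrix(NA_real_, length(traits_), length(strains_),
                  dimnames = list(traits_, strains_))
      agg <- tapply(v, list(factor(d$trait, traits_),
                            factor(d$strain, strains_)), f)
      m[] <- agg
      m
    }
    means <- mk(mean)
    nmat <- mk(length)
    storage.mode(nmat) <- "integer"
    sem <- mk(function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x))
                          else 0)
    replicates <- lapply(stats::setNames(traits_, traits_), function(tr) {
      rows <- d$trait == tr
      split(v[rows], factor(d$strain[rows], strains_))
    })
    if (any(!is.finite(means)))
      stop("every (trait, strain) cell needs at least one value",
           call. = FALSE)
    phenotype_table(means, n = nmat, sem = sem, replicates = replicates)
  } else {
    sc <- which(cn == "strain")
    if (length(sc) != 1L) sc <- 1L
    strains_ <- d[[sc]]
    traits_ <- names(d)[-sc]
    if (length(traits_) < 1L)
      stop("phenotype CSV needs at least one trait column", call. = FALSE)
    vals <- vapply(traits_, function(tr) .parse_numeric(d[[tr]], path),
                   numeric(nrow(d)))
    means <- t(matrix(vals, nrow(d), length(traits_),
                      dimnames = list(strains_, traits_)))
    phenotype_table(means)
  }
}

.parse_numeric <- function(x, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) & !is.na(x) & x != ""
  if (any(bad))
    stop("non-numeric phenotype value in ", path, ": '", x[bad][1L], "'",
         call. = FALSE)
  v
}
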
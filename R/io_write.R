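# Writers. Coordinate conversions (1-based inclusive internal -> BED
# half-open) happen only here, mirroring the readers.

# doubles formatted so that as.numeric() round-trips exactly
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a genotype panel
#'
#' \code{"tsv"} emits the package's matrix dialect (header: chrom, pos, ref,
#' alt, one column per strain; codes 0/1/NA). \code{"vcf"} emits a minimal
#' VCFv4.2 with homozygous diploid GT calls (\code{0/0}, \code{1/1},
#' \code{./.}), one sample column per strain.
#'
#' @param panel a \code{strain_panel}.
#' @param path output file.
#' @param format \code{"tsv"} or \code{"vcf"}.
#' @return invisibly, \code{path}.
#' @export
write_genotypes <- function(panel, path, format = c("tsv", "vcf")) {
  stopifnot(inherits(panel, "strain_panel"))
  format <- match.arg(format)
  if (format == "tsv") {
    d <- cbind(panel$variants, as.data.frame(panel$geno))
    data.table::fwrite(d, path, sep = "\t", na = "NA", quote = FALSE)
  } else {
    gt <- matrix("./.", nrow(panel$geno), ncol(panel$geno))
    gt[!is.na(panel$geno) & panel$geno == 0L] <- "0/0"
    gt[!is.na(panel$geno) & panel$geno == 1L] <- "1/1"
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=hbcgm",
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      paste0("##contig=<ID=", unique(panel$variants$chrom), ">"),
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", panel$strains), collapse = "\t"))
    body <- do.call(paste, c(list(
      panel$variants$chrom, panel$variants$pos, ".",
      panel$variants$ref, panel$variants$alt, ".", "PASS", ".", "GT"),
      lapply(seq_along(panel$strains), function(s) gt[, s]),
      sep = "\t"))
    writeLines(c(header, body), path)
  }
  invisible(path)
}

#' Write a gene annotation
#'
#' BED output converts the internal 1-based inclusive intervals to 0-based
#' half-open; GFF3 output keeps 1-based inclusive coordinates with feature
#' type \code{gene}.
#'
#' @param annotation a \code{gene_annotation}.
#' @param path output file.
#' @param format \code{"bed"} or \code{"gff3"}.
#' @return invisibly, \code{path}.
#' @export
write_annotation <- function(annotation, path, format = c("bed", "gff3")) {
  stopifnot(inherits(annotation, "gene_annotation"))
  format <- match.arg(format)
  if (format == "bed") {
    lines <- paste(annotation$chrom, annotation$start - 1L, annotation$end,
                   annotation$gene, sep = "\t")
    writeLines(lines, path)
  } else {
    lines <- c("##gff-version 3",
               paste(annotation$chrom, "hbcgm", "gene", annotation$start,
                     annotation$end, ".", ".", ".",
                     paste0("ID=", annotation$gene, ";Name=",
                            annotation$gene),
                     sep = "\t"))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Write a phenotype table
#'
#' \code{"wide"}: one row per strain, one column per trait (strain means).
#' \code{"long"}: per-animal rows (strain, trait, animal, value); requires
#' replicates. Numeric values are written so they round-trip exactly.
#'
#' @param table a \code{phenotype_table}.
#' @param path output CSV.
#' @param format \code{"wide"} or \code{"long"}.
#' @return invisibly, \code{path}.
#' @export
write_phenotypes <- function(table, path, format = c("wide", "long")) {
  stopifnot(inherits(table, "phenotype_table"))
  format <- match.arg(format)
  if (format == "wide") {
    d <- data.frame(strain = colnames(table$means), stringsAsFactors = FALSE)
    for (tr in rownames(table$means)) d[[tr]] <- .fmt_num(table$means[tr, ])
    data.table::fwrite(d, path, sep = ",", quote = FALSE)
  } else {
    if (is.null(table$replicates))
      stop("long format requires per-animal replicates", call. = FALSE)
    rows <- list()
    i <- 0L
    for (tr in names(table$replicates)) {
      for (st in names(table$replicates[[tr]])) {
        v <- table$replicates[[tr]][[st]]
        i <- i + 1L
        rows[[i]] <- data.frame(strain = st, trait = tr,
                                animal = seq_along(v),
                                value = .fmt_num(v),
                                stringsAsFactors = FALSE)
      }
    }
    data.table::fwrite(do.call(rbind, rows), path, sep = ",", quote = FALSE)
  }
  invisible(path)
}

#' Write a ranked gene table or association records as TSV
#'
#' Column order is stable and row order deterministic: gene score tables by
#' rank (ties already broken by gene name), association records by ascending
#' p-value with the mapping tie-breaks. For association records the
#' per-strain haplotype codes of each block are appended as one column per
#' strain when the partition labels are available. An empty table yields a
#' header-only file.
#'
#' @param table a \code{gene_score_table}, \code{association_records}, or
#'   plain data.frame (written as-is).
#' @param path output TSV.
#' @return invisibly, \code{path}.
#' @export
write_gene_table <- function(table, path) {
  if (inherits(table, "gene_score_table")) {
    d <- as.data.frame(table)
    d <- d[order(d$rank, d$gene), , drop = FALSE]
    front <- intersect(c("gene", "score", "n_hits", "rank"), names(d))
    d <- d[, c(front, setdiff(names(d), front)), drop = FALSE]
  } else if (inherits(table, "association_records")) {
    d <- as.data.frame(table)
    parts <- attr(table, "partitions")
    cols <- c("trait", "genes", "p_value", "f_statistic", "genetic_effect",
              "chrom", "start_pos", "end_pos", "window", "n_groups",
              "n_strains_tested", "partition_key")
    d <- d[, c(cols, setdiff(names(d), cols)), drop = FALSE]
    if (!is.null(parts) && !is.null(d$part_id) && nrow(d) > 0L) {
      lab <- parts[d$part_id, , drop = FALSE]
      colnames(lab) <- paste0("hap_", colnames(parts))
      d <- cbind(d[, setdiff(names(d), "part_id"), drop = FALSE],
                 as.data.frame(lab))
    } else {
      d$part_id <- NULL
    }
  } else {
    d <- as.data.frame(table)
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch({
    data.table::fwrite(d, path, sep = "\t", na = "NA", quote = FALSE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}
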
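# Cross-trait gene prioritization: map every trait, count sub-cutoff
# associations per gene and score with the same censored -log10 p sum used
# by the robustness analysis, the index now running over traits.

#' Integrate mapping results across related traits
#'
#' Runs the whole-genome mapping once per trait, takes each gene's best
#' p-value per trait, counts traits with \code{p < p_cutoff} (\code{n_hits})
#' and scores each gene with the censored sum
#' \code{sum over traits of -log10(p~)} where p-values at or above the
#' cutoff (or missing) are censored to the cutoff. Genes are ranked by
#' descending score. By default only genes tabulated at \code{p < p_cutoff}
#' in at least one trait appear.
#'
#' @param panel a \code{strain_panel}.
#' @param annotation a \code{gene_annotation}.
#' @param phenotypes a \code{phenotype_table}.
#' @param traits traits to integrate (default: all traits in the table).
#' @param p_cutoff tabulation/censoring cutoff.
#' @param map_config an \code{\link{hbcgm_config}}.
#' @param include_all_genes keep genes never reaching the cutoff.
#' @return a \code{gene_score_table} data.frame: gene, score, n_hits, rank,
#'   plus one \code{p_<trait>} column per trait with the gene's best p-value
#'   for that trait (NA = no testable block).
#' @export
integrate_traits <- function(panel, annotation, phenotypes,
                             traits = NULL, p_cutoff = 0.01,
                             map_config = hbcgm_config(),
                             include_all_genes = FALSE) {
  stopifnot(inherits(phenotypes, "phenotype_table"))
  if (is.null(traits)) traits <- rownames(phenotypes$means)
  missing_ <- setdiff(traits, rownames(phenotypes$means))
  if (length(missing_))
    stop("unknown trait(s): ", paste(missing_, collapse = ", "),
         call. = FALSE)
  if (p_cutoff <= 0 || p_cutoff >= 1)
    stop("p_cutoff must be in (0, 1)", call. = FALSE)
  ctx <- .mapping_context(panel, annotation, phenotypes, map_config)
  P <- vapply(traits, function(tr) .context_gene_pvalues(ctx, tr),
              numeric(length(ctx$gene_widx)))
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L,
                                   dimnames = list(names(ctx$gene_widx),
                                                   traits))
  out <- .score_pmatrix(P, p_cutoff, include_all_genes)
  pcols <- as.data.frame(P[out$gene, , drop = FALSE])
  names(pcols) <- paste0("p_", traits)
  out <- cbind(out, pcols)
  rownames(out) <- NULL
  class(out) <- c("gene_score_table", "data.frame")
  attr(out, "traits") <- traits
  attr(out, "p_cutoff") <- p_cutoff
  out
}

#' Overlap of two top-k gene rankings
#'
#' Genes appearing in the top \code{k} of both a robustness table and an
#' integration table, reported with both ranks.
#'
#' @param robust_table,integrated_table ranked \code{gene_score_table}s.
#' @param k ranking depth (default 15).
#' @return data.frame: gene, rank_robust, rank_integrated, sorted by
#'   rank_robust.
#' @export
overlap_report <- function(robust_table, integrated_table, k = 15L) {
  stopifnot(inherits(robust_table, "gene_score_table"),
            inherits(integrated_table, "gene_score_table"))
  t1 <- robust_table[robust_table$rank <= k, c("gene", "rank")]
  t2 <- integrated_table[integrated_table$rank <= k, c("gene", "rank")]
  common <- intersect(t1$gene, t2$gene)
  out <- data.frame(gene = common,
                    rank_robust = t1$rank[match(common, t1$gene)],
                    rank_integrated = t2$rank[match(common, t2$gene)],
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank_robust), , drop = FALSE]
  rownames(out) <- NULL
  out
}
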
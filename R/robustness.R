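# Strain-resampling robustness analysis: re-map the trait on many random
# strain subsets and aggregate each gene's per-iteration best p-value into a
# censored sum of -log10 p.

#' Resampling configuration
#'
#' @param n_iterations number of distinct strain subsets to analyze.
#' @param exclusion_sizes candidate numbers of strains to exclude; one is
#'   drawn uniformly per iteration.
#' @param p_cutoff significance cutoff for tabulating a gene in an
#'   iteration; p-values at or above it are censored to the cutoff in the
#'   score.
#' @param seed integer seed driving both the exclusion-size draw and the
#'   strain draw (one stream, so runs replay exactly).
#' @param max_redraws how many duplicate subsets may be discarded before
#'   giving up.
#' @return list of class \code{resampling_config}.
#' @export
resampling_config <- function(n_iterations = 100L,
                              exclusion_sizes = c(3L, 4L, 5L, 6L),
                              p_cutoff = 0.01,
                              seed = 1L,
                              max_redraws = 10000L) {
  exclusion_sizes <- sort(unique(as.integer(exclusion_sizes)))
  if (any(exclusion_sizes < 1L))
    stop("exclusion sizes must be positive", call. = FALSE)
  if (p_cutoff <= 0 || p_cutoff >= 1)
    stop("p_cutoff must be in (0, 1)", call. = FALSE)
  if (n_iterations < 1L) stop("n_iterations must be >= 1", call. = FALSE)
  structure(list(n_iterations = as.integer(n_iterations),
                 exclusion_sizes = exclusion_sizes,
                 p_cutoff = as.numeric(p_cutoff),
                 seed = as.integer(seed),
                 max_redraws = as.integer(max_redraws)),
            class = "resampling_config")
}

#' Draw distinct retained-strain subsets
#'
#' Each iteration draws an exclusion size uniformly from
#' \code{exclusion_sizes}, then excludes that many strains uniformly without
#' replacement. A subset identical to an earlier one is discarded and
#' redrawn. Draws depend only on the seed, never on phenotype values, so two
#' traits scored with the same seed see identical subsets.
#'
#' @param strains character vector of available strains.
#' @param config a \code{\link{resampling_config}}.
#' @return list of \code{n_iterations} pairwise-distinct character vectors
#'   of retained strains (panel order preserved).
#' @export
draw_unique_subsets <- function(strains, config = resampling_config()) {
  stopifnot(inherits(config, "resampling_config"))
  n <- length(strains)
  if (any(config$exclusion_sizes >= n))
    stop("exclusion sizes must be smaller than the number of strains",
         call. = FALSE)
  bound <- sum(choose(n, config$exclusion_sizes))
  if (config$n_iterations > bound)
    stop(sprintf(
      "impossible request: only %d distinct subsets exist for %d strains with exclusion sizes {%s}, but %d iterations were requested",
      bound, n, paste(config$exclusion_sizes, collapse = ","),
      config$n_iterations), call. = FALSE)
  .with_seed(config$seed, {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    out <- vector("list", config$n_iterations)
    got <- 0L
    redraws <- 0L
    while (got < config$n_iterations) {
      k <- if (length(config$exclusion_sizes) == 1L) config$exclusion_sizes
           else sample(config$exclusion_sizes, 1L)
      excl <- sample(strains, k)
      retained <- setdiff(strains, excl)
      key <- paste(sort(retained), collapse = "|")
      if (exists(key, envir = seen, inherits = FALSE)) {
        redraws <- redraws + 1L
        if (redraws > config$max_redraws)
          stop(sprintf(
            "exceeded max_redraws (%d) while seeking %d distinct subsets out of the %.0f possible",
            config$max_redraws, config$n_iterations, bound), call. = FALSE)
        next
      }
      assign(key, TRUE, envir = seen)
      got <- got + 1L
      out[[got]] <- retained
    }
    out
  })
}

#' Censored -log10 p robustness score
#'
#' \code{sum(-log10(p~))} where \code{p~ = p} when \code{p < p_cutoff} and
#' \code{p~ = p_cutoff} otherwise (including missing entries: a gene with no
#' sub-cutoff block in an iteration is censored at the cutoff). Larger
#' scores indicate stronger, more robust association.
#'
#' @param p_values per-iteration best p-values for one gene (NA = censored).
#' @param p_cutoff censoring cutoff.
#' @return the score (scalar).
#' @examples
#' robustness_score(rep(NA, 100), 0.01)       # fully censored: 200
#' robustness_score(rep(1e-4, 100), 0.01)     # 400
#' @export
robustness_score <- function(p_values, p_cutoff = 0.01) {
  p <- as.numeric(p_values)
  p <- ifelse(!is.na(p) & p < p_cutoff, p, p_cutoff)
  sum(-log10(p))
}

# rank a gene score data.frame: score descending, ties by gene name
.rank_scores <- function(df) {
  ord <- order(-df$score, df$gene, method = "radix")
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  class(df) <- c("gene_score_table", "data.frame")
  df
}

# genes x iterations matrix of per-iteration best p-values
.robustness_pmatrix <- function(panel, annotation, phenotypes, trait,
                                config, map_config) {
  ctx <- .mapping_context(panel, annotation, phenotypes, map_config)
  if (!trait %in% rownames(phenotypes$means))
    stop("unknown trait: ", trait, call. = FALSE)
  subsets <- draw_unique_subsets(ctx$common, config)
  P <- vapply(subsets,
              function(s) .context_gene_pvalues(ctx, trait, strains = s),
              numeric(length(ctx$gene_widx)))
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L,
                                   dimnames = list(names(ctx$gene_widx)))
  P
}

.score_pmatrix <- function(P, p_cutoff, include_fully_censored) {
  hits <- !is.na(P) & P < p_cutoff
  n_hits <- as.integer(rowSums(hits))
  score <- apply(P, 1L, robustness_score, p_cutoff = p_cutoff)
  df <- data.frame(gene = rownames(P), score = score, n_hits = n_hits,
                   stringsAsFactors = FALSE, row.names = NULL)
  if (!include_fully_censored) df <- df[df$n_hits > 0L, , drop = FALSE]
  .rank_scores(df)
}

#' Strain-resampling robustness analysis
#'
#' Re-runs the whole-genome mapping on \code{n_iterations} distinct random
#' strain subsets, takes each gene's best p-value per iteration, and scores
#' every gene that reaches \code{p < p_cutoff} in at least one iteration
#' with the censored \code{-log10} sum of \code{\link{robustness_score}}.
#' Genes are ranked by descending score (ties by name).
#'
#' @param panel a \code{strain_panel}.
#' @param annotation a \code{gene_annotation}.
#' @param phenotypes a \code{phenotype_table}.
#' @param trait trait to map.
#' @param config a \code{\link{resampling_config}}.
#' @param map_config an \code{\link{hbcgm_config}}.
#' @param include_fully_censored also score genes never reaching the cutoff
#'   (they all score \code{n_iterations * -log10(p_cutoff)}).
#' @return a \code{gene_score_table} data.frame: gene, score, n_hits, rank.
#' @export
run_robustness <- function(panel, annotation, phenotypes, trait,
                           config = resampling_config(),
                           map_config = hbcgm_config(),
                           include_fully_censored = FALSE) {
  P <- .robustness_pmatrix(panel, annotation, phenotypes, trait,
                           config, map_config)
  out <- .score_pmatrix(P, config$p_cutoff, include_fully_censored)
  attr(out, "trait") <- trait
  attr(out, "config") <- config
  out
}

#' Sensitivity of robustness rankings to the censoring cutoff
#'
#' Scores the same subset draws at two cutoffs and reports how many of the
#' top-k ranked genes keep their rank position.
#'
#' @inheritParams run_robustness
#' @param alternate_cutoff second cutoff to score at.
#' @param k depth of the ranking comparison (default 50).
#' @return list with \code{k_effective}, \code{n_agree},
#'   \code{agreement}, \code{top_primary}, \code{top_alternate}, and the two
#'   full score tables.
#' @export
cutoff_sensitivity <- function(panel, annotation, phenotypes, trait,
                               config = resampling_config(),
                               alternate_cutoff = 0.001,
                               k = 50L,
                               map_config = hbcgm_config()) {
  if (alternate_cutoff <= 0 || alternate_cutoff >= 1)
    stop("alternate_cutoff must be in (0, 1)", call. = FALSE)
  P <- .robustness_pmatrix(panel, annotation, phenotypes, trait,
                           config, map_config)
  t1 <- .score_pmatrix(P, config$p_cutoff, FALSE)
  t2 <- .score_pmatrix(P, alternate_cutoff, FALSE)
  k_eff <- min(k, nrow(t1), nrow(t2))
  top1 <- t1$gene[seq_len(k_eff)]
  top2 <- t2$gene[seq_len(k_eff)]
  n_agree <- sum(top1 == top2)
  list(k_effective = k_eff, n_agree = n_agree,
       agreement = if (k_eff) n_agree / k_eff else NA_real_,
       top_primary = top1, top_alternate = top2,
       table_primary = t1, table_alternate = t2)
}
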
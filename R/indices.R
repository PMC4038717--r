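# Behavioral phenotype indices consumed by the mapping: hyperalgesia
# fractions, percent decrease, %MPE, and the tolerance ED50 shift.

#' Fraction of baseline nociceptive threshold
#'
#' Post-treatment threshold divided by baseline. Opioid-induced hyperalgesia
#' corresponds to values below 1.
#'
#' @param baseline baseline threshold (g or s), must be > 0.
#' @param post post-treatment threshold, same units.
#' @return dimensionless fraction post/baseline (vectorized).
#' @export
fraction_of_baseline <- function(baseline, post) {
  if (any(baseline <= 0))
    stop("baseline threshold must be > 0", call. = FALSE)
  post / baseline
}

#' Percent decrease from baseline threshold
#'
#' \code{100 * (baseline - post) / baseline}; identically
#' \code{100 * (1 - fraction_of_baseline(baseline, post))}. Negative values
#' (post above baseline, i.e. hypoalgesia) are allowed.
#'
#' @inheritParams fraction_of_baseline
#' @return percent decrease (vectorized).
#' @export
percent_decrease <- function(baseline, post) {
  100 * (1 - fraction_of_baseline(baseline, post))
}

#' Percent maximal possible effect
#'
#' Normalizes a response latency between its pre-drug baseline and the assay
#' cutoff: \code{100 * (latency - baseline) / (cutoff - baseline)}.
#'
#' @param latency observed withdrawal latency (s).
#' @param baseline pre-drug latency (s).
#' @param cutoff assay cutoff latency (s), must exceed baseline.
#' @param clip clip the result to [0, 100] (default TRUE).
#' @return percent of maximal possible effect (vectorized).
#' @export
percent_mpe <- function(latency, baseline, cutoff, clip = TRUE) {
  if (any(cutoff <= baseline))
    stop("cutoff latency must exceed baseline", call. = FALSE)
  mpe <- 100 * (latency - baseline) / (cutoff - baseline)
  if (clip) mpe <- pmin(pmax(mpe, 0), 100)
  mpe
}

#' Morphine tolerance index (ED50 fold-shift)
#'
#' Ratio of the post-treatment to pre-treatment ED50 from two dose-response
#' fits; values above 1 indicate analgesic tolerance.
#'
#' @param fit_pre,fit_post converged \code{\link{fit_dose_response}} objects.
#' @return dimensionless ED50 ratio.
#' @export
tolerance_index <- function(fit_pre, fit_post) {
  stopifnot(inherits(fit_pre, "dose_response_fit"),
            inherits(fit_post, "dose_response_fit"))
  if (!fit_pre$converged || !fit_post$converged)
    stop("tolerance index requires two converged dose-response fits",
         call. = FALSE)
  fit_post$ed50 / fit_pre$ed50
}
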
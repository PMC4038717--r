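# Trait-correlation table: pairwise Pearson r on strain means with two-sided
# t-test p-values and Benjamini-Hochberg adjustment across the unique pairs.

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up adjusted p-values: \code{p_(i) * m / i}, running minimum
#' from the largest rank down, capped at 1, returned in input order. Never
#' decreases any p-value.
#'
#' @param p_values numeric vector of p-values in [0, 1] (NA passed through).
#' @return adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  p <- as.numeric(p_values)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must be in [0, 1]", call. = FALSE)
  res <- rep(NA_real_, length(p))
  x <- p[ok]
  m <- length(x)
  if (m) {
    o <- order(x, decreasing = TRUE)         # largest first
    adj <- pmin(1, cummin(x[o] * m / seq.int(m, 1L)))
    tmp <- numeric(m)
    tmp[o] <- adj
    res[ok] <- pmax(tmp, x)   # never below the raw p, even by rounding
  }
  res
}

# Pearson r and two-sided p via the t transform, written out longhand so the
# package's own arithmetic can be checked against stats::cor.test.
.pearson <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  dx <- x - mx; dy <- y - my
  sxx <- sum(dx * dx); syy <- sum(dy * dy)
  if (sxx == 0 || syy == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- min(max(r, -1), 1)
  if (abs(r) == 1) return(list(r = r, p = 0, n = n))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(r = r, p = p, n = n)
}

#' Pairwise Pearson correlations between traits
#'
#' Correlates every unique trait pair over the strains common to the pair
#' (strain means), computes two-sided p-values from the t transform and
#' adjusts them with \code{\link{benjamini_hochberg}} across the unique
#' off-diagonal pairs. Zero-variance traits yield NA for their pairs.
#'
#' @param table a \code{phenotype_table}.
#' @param min_strains minimum common strains per pair (default 3).
#' @return object of class \code{correlation_table}: list with
#'   \code{pairs} (data.frame: trait1, trait2, n, r, p_raw, p_adjusted,
#'   significant flags at raw/adjusted 0.05) and symmetric matrices
#'   \code{r}, \code{p_raw}, \code{p_adjusted} with unit/NA diagonals.
#' @export
trait_correlations <- function(table, min_strains = 3L) {
  stopifnot(inherits(table, "phenotype_table"))
  M <- table$means
  tn <- rownames(M)
  nt <- length(tn)
  if (nt < 2L) stop("need at least 2 traits", call. = FALSE)
  combs <- utils::combn(nt, 2L)
  pr <- apply(combs, 2L, function(ij) {
    x <- M[ij[1L], ]; y <- M[ij[2L], ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_strains)
      stop(sprintf("traits %s and %s share fewer than %d strains",
                   tn[ij[1L]], tn[ij[2L]], min_strains), call. = FALSE)
    .pearson(x[ok], y[ok])
  })
  pairs <- data.frame(
    trait1 = tn[combs[1L, ]], trait2 = tn[combs[2L, ]],
    n = vapply(pr, `[[`, 0L, "n"),
    r = vapply(pr, `[[`, 0, "r"),
    p_raw = vapply(pr, `[[`, 0, "p"),
    stringsAsFactors = FALSE)
  pairs$p_adjusted <- benjamini_hochberg(pairs$p_raw)
  pairs$sig_raw <- !is.na(pairs$p_raw) & pairs$p_raw < 0.05
  pairs$sig_adjusted <- !is.na(pairs$p_adjusted) & pairs$p_adjusted < 0.05
  mk <- function(v, diag_val) {
    m <- matrix(NA_real_, nt, nt, dimnames = list(tn, tn))
    for (j in seq_len(ncol(combs))) {
      m[combs[1L, j], combs[2L, j]] <- v[j]
      m[combs[2L, j], combs[1L, j]] <- v[j]
    }
    diag(m) <- diag_val
    m
  }
  structure(list(pairs = pairs,
                 r = mk(pairs$r, 1),
                 p_raw = mk(pairs$p_raw, NA_real_),
                 p_adjusted = mk(pairs$p_adjusted, NA_real_)),
            class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, ...) {
  cat("<correlation_table>\n")
  print(round(x$r, 2))
  invisible(x)
}
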
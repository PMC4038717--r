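# Nelder-Mead with one restart. NM can exit with code 10 (simplex
# degeneracy) when the start already sits at the optimum (noiseless data);
# the fit is accepted when a restart cannot improve the objective.
.optim2 <- function(start, fn, maxit = 5000) {
  ctl <- list(reltol = 1e-14, maxit = maxit)
  o1 <- stats::optim(start, fn, method = "Nelder-Mead", control = ctl)
  o2 <- stats::optim(o1$par, fn, method = "Nelder-Mead", control = ctl)
  best <- if (o2$value <= o1$value) o2 else o1
  converged <- o2$convergence == 0L ||
    abs(o2$value - o1$value) <= 1e-10 * (1 + abs(o1$value))
  list(par = best$par, value = best$value, converged = converged,
       message = if (converged) "OK"
                 else paste("optim convergence code", o2$convergence))
}

#' Fit a variable-slope sigmoid dose-response curve
#'
#' Least-squares fit of
#' \code{response = bottom + (top - bottom) / (1 + (ed50/dose)^hill)}
#' on the positive doses (dose 0 acts as the floor anchor when the bottom is
#' fixed). By default the bottom and top are fixed at 0 and 100 %MPE and
#' only ED50 and the Hill slope are free ("variable slope"); set
#' \code{fix_asymptotes = FALSE} for the 4-parameter fit.
#'
#' Optimization is over (log ED50, log hill), seeded from a logit-linear
#' regression, refined by Nelder-Mead at tight tolerance. Non-convergence or
#' degenerate data (no response variation) is flagged, never silently
#' returned as a fit.
#'
#' @param doses doses in mg/kg (>= 0); at least 4 distinct positive doses.
#' @param responses responses (%MPE) matching \code{doses}.
#' @param bottom,top fixed asymptotes used when \code{fix_asymptotes}.
#' @param fix_asymptotes keep bottom/top fixed (default TRUE).
#' @return object of class \code{dose_response_fit}: list with \code{ed50},
#'   \code{hill_slope}, \code{bottom}, \code{top}, \code{converged},
#'   \code{residual_sse}, \code{message}.
#' @examples
#' d <- simulate_dose_response(ed50 = 4, hill_slope = 1)
#' fit_dose_response(d$dose, d$mpe)
#' @export
fit_dose_response <- function(doses, responses, bottom = 0, top = 100,
                              fix_asymptotes = TRUE) {
  stopifnot(length(doses) == length(responses))
  if (any(doses < 0)) stop("doses must be >= 0", call. = FALSE)
  pos <- doses > 0
  d <- doses[pos]
  r <- responses[pos]
  fail <- function(msg) structure(
    list(ed50 = NA_real_, hill_slope = NA_real_, bottom = bottom, top = top,
         converged = FALSE, residual_sse = NA_real_, message = msg),
    class = "dose_response_fit")
  if (length(unique(d)) < 4L)
    return(fail("need at least 4 distinct positive doses"))
  if (stats::sd(r) == 0)
    return(fail("degenerate data: all responses equal"))

  if (fix_asymptotes) {
    # logit-linear start: logit((r - bottom)/(top - bottom)) ~ hill * log(d)
    fr <- pmin(pmax((r - bottom) / (top - bottom), 1e-4), 1 - 1e-4)
    lf <- stats::qlogis(fr)
    ld <- log(d)
    sl <- unname(stats::coef(stats::lm(lf ~ ld)))
    hill0 <- max(sl[2L], 1e-2)
    led0 <- -sl[1L] / max(sl[2L], 1e-6)
    sse <- function(par) {
      pred <- bottom + (top - bottom) / (1 + exp(exp(par[2L]) *
                                                   (par[1L] - log(d))))
      sum((r - pred)^2)
    }
    opt <- .optim2(c(led0, log(hill0)), sse)
    ed50 <- exp(opt$par[1L])
    hill <- exp(opt$par[2L])
    out <- structure(
      list(ed50 = ed50, hill_slope = hill, bottom = bottom, top = top,
           converged = opt$converged, residual_sse = opt$value,
           message = opt$message),
      class = "dose_response_fit")
  } else {
    sse4 <- function(par) {
      b <- par[3L]; t_ <- par[4L]
      pred <- b + (t_ - b) / (1 + exp(exp(par[2L]) * (par[1L] - log(d))))
      sum((r - pred)^2)
    }
    start <- c(log(stats::median(d)), 0, min(r), max(r))
    opt <- .optim2(start, sse4, maxit = 10000)
    out <- structure(
      list(ed50 = exp(opt$par[1L]), hill_slope = exp(opt$par[2L]),
           bottom = opt$par[3L], top = opt$par[4L],
           converged = opt$converged, residual_sse = opt$value,
           message = opt$message),
      class = "dose_response_fit")
  }
  if (out$converged && (!is.finite(out$ed50) || out$ed50 <= 0))
    return(fail("fit did not yield a positive ED50"))
  out
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf(
      "<dose_response_fit> ED50 = %.4g, hill = %.4g, [%.4g, %.4g], SSE = %.4g\n",
      x$ed50, x$hill_slope, x$bottom, x$top, x$residual_sse))
  else
    cat("<dose_response_fit> NOT converged:", x$message, "\n")
  invisible(x)
}
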
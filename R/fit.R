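#' Fit a four-parameter log-logistic melting curve
#'
#' Least-squares fit of the LL4 model (see [ll4_response()]) to one
#' fold-change series over the temperature gradient, by Levenberg-Marquardt
#' (via `minpack.lm::nlsLM`). The fit is deterministic: the starting values
#' follow a fixed rule (lower = min(response), upper = max(response),
#' slope = +10, inflection = temperature of the point nearest mid-range),
#' with two fallback restarts perturbing the starting slope by -50% and
#' +50% if the first attempt fails. No randomness is involved.
#'
#' A flat series (response range below `flat_tol`) cannot identify the four
#' parameters and is returned as a non-converged sentinel with the constant
#' value in both plateaus rather than an error, so that callers can flag
#' the protein instead of aborting a proteome-wide run.
#'
#' @param temperatures numeric vector of temperatures (degrees C),
#'   strictly positive.
#' @param responses numeric vector of fold-changes, same length; at least 5
#'   finite values are required to fit 4 parameters with a residual.
#' @param max_fev maximum number of function evaluations per attempt.
#' @param flat_tol response range below which the series is declared flat.
#' @return an [ll4_params()] object with `rss` and `converged` set, plus a
#'   `fitted` attribute carrying the fitted values on `temperatures` and a
#'   `diagnostics` attribute (character) describing failures, if any.
#' @examples
#' tt <- seq(37, 64, by = 3)
#' y <- ll4_response(ll4_params(12, 0.05, 1, 51), tt)
#' fit_ll4(tt, y)
#' @export
fit_ll4 <- function(temperatures, responses, max_fev = 2000,
                    flat_tol = 1e-8) {
  if (length(temperatures) != length(responses)) {
    stop("`temperatures` and `responses` must have equal length",
         call. = FALSE)
  }
  ok <- is.finite(temperatures) & is.finite(responses)
  tt <- temperatures[ok]
  yy <- responses[ok]
  if (length(yy) < 5) {
    stop("need at least 5 finite points to fit the 4-parameter model",
         call. = FALSE)
  }
  if (any(tt <= 0)) stop("temperatures must be > 0", call. = FALSE)

  if (diff(range(yy)) < flat_tol) {
    out <- ll4_params(slope = NA_real_, lower = yy[1], upper = yy[1],
                      inflection = NA_real_, rss = sum((yy - mean(yy))^2),
                      converged = FALSE)
    attr(out, "fitted") <- rep(mean(yy), length(temperatures))
    attr(out, "diagnostics") <- "flat series: parameters not identifiable"
    return(out)
  }

  mid <- (min(yy) + max(yy)) / 2
  e0 <- tt[which.min(abs(yy - mid))]
  start0 <- list(slope = 10, lower = min(yy), upper = max(yy),
                 inflection = e0)
  slope_factors <- c(1, 0.5, 1.5)  # initial try + two fallback restarts
  diagnostics <- character(0)

  for (f in slope_factors) {
    start <- start0
    start$slope <- start0$slope * f
    fit <- tryCatch(
      minpack.lm::nlsLM(
        yy ~ lower + (upper - lower) /
          (1 + exp(slope * (log(tt) - log(inflection)))),
        start = start,
        lower = c(slope = -Inf, lower = -Inf, upper = -Inf,
                  inflection = 1e-3),
        control = minpack.lm::nls.lm.control(
          maxiter = 1024, maxfev = max_fev, ftol = 1e-10, ptol = 1e-10)
      ),
      error = function(e) conditionMessage(e),
      warning = function(w) conditionMessage(w)
    )
    if (inherits(fit, "nls")) {
      cf <- stats::coef(fit)
      out <- ll4_params(slope = cf[["slope"]], lower = cf[["lower"]],
                        upper = cf[["upper"]],
                        inflection = cf[["inflection"]],
                        rss = sum(stats::resid(fit)^2), converged = TRUE)
      attr(out, "fitted") <- ll4_response(out, temperatures)
      if (length(diagnostics)) attr(out, "diagnostics") <- diagnostics
      return(out)
    }
    diagnostics <- c(diagnostics,
                     sprintf("start slope %.1f: %s", start$slope, fit))
  }

  out <- ll4_params(slope = NA_real_, lower = NA_real_, upper = NA_real_,
                    inflection = NA_real_, rss = NA_real_, converged = FALSE)
  attr(out, "fitted") <- rep(NA_real_, length(temperatures))
  attr(out, "diagnostics") <- diagnostics
  out
}

#' Fit melting curves for every protein and sample of a dataset
#'
#' Runs [fit_ll4()] on each complete (protein, sample) series and solves
#' the melting point at `tm_level` via [melting_point()]. Incomplete series
#' (any missing value) are reported with `fitted = FALSE` and skipped.
#'
#' @param dataset a [melt_dataset()].
#' @param proteins optional character vector restricting fitting to these
#'   protein IDs (default: all).
#' @param tm_level fold-change level defining the melting point.
#' @return data frame with one row per (protein, sample): LL4 parameters,
#'   `rss`, `converged`, `fitted` (whether a fit was attempted), `tm`,
#'   `tm_defined`, `tm_reason`.
#' @export
fit_melt_curves <- function(dataset, proteins = NULL, tm_level = 0.5) {
  stopifnot(inherits(dataset, "melt_dataset"))
  ids <- if (is.null(proteins)) dataset$protein_ids else proteins
  if (!all(ids %in% dataset$protein_ids)) {
    stop("unknown protein IDs requested", call. = FALSE)
  }
  samples <- dataset$samples$sample_id
  n <- length(ids) * length(samples)
  res <- data.frame(
    protein_id = rep(ids, each = length(samples)),
    sample_id = rep(samples, times = length(ids)),
    slope = NA_real_, lower = NA_real_, upper = NA_real_,
    inflection = NA_real_, rss = NA_real_,
    converged = FALSE, fitted = FALSE,
    tm = NA_real_, tm_defined = FALSE, tm_reason = "not fitted",
    stringsAsFactors = FALSE
  )
  row <- 0L
  for (p in ids) {
    for (s in samples) {
      row <- row + 1L
      y <- dataset$values[p, s, ]
      if (anyNA(y)) {
        res$tm_reason[row] <- "incomplete series"
        next
      }
      fp <- fit_ll4(dataset$temperatures, y)
      res$fitted[row] <- TRUE
      res$slope[row] <- fp$slope
      res$lower[row] <- fp$lower
      res$upper[row] <- fp$upper
      res$inflection[row] <- fp$inflection
      res$rss[row] <- fp$rss
      res$converged[row] <- fp$converged
      mp <- melting_point(fp, level = tm_level)
      res$tm[row] <- mp$tm
      res$tm_defined[row] <- mp$defined
      res$tm_reason[row] <- mp$reason
    }
  }
  stopifnot(row == n)
  res
}
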
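#' Median fold-change profile of one run
#'
#' For one sample (= one run: condition x replicate), the per-temperature
#' median fold-change over all proteins complete in that run. This profile
#' represents the overall melting trend of the whole proteome in that run
#' and is the input to the normalization fit.
#'
#' @param dataset a [melt_dataset()].
#' @param sample_id one of `dataset$samples$sample_id`.
#' @return numeric vector, one median per temperature.
#' @export
compute_median_profile <- function(dataset, sample_id) {
  stopifnot(inherits(dataset, "melt_dataset"))
  if (!sample_id %in% dataset$samples$sample_id) {
    stop(sprintf("unknown sample: %s", sample_id), call. = FALSE)
  }
  v <- dataset$values[, sample_id, , drop = TRUE]
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  complete <- !apply(is.na(v), 1, any)
  if (!any(complete)) {
    stop(sprintf("no complete proteins in run %s", sample_id),
         call. = FALSE)
  }
  apply(v[complete, , drop = FALSE], 2, stats::median)
}

#' Fit the proteome melting trend to a sigmoid
#'
#' Fits the per-run median profile with the same four-parameter
#' log-logistic model used for individual proteins ([fit_ll4()]),
#' unconstrained. A flat (degenerate) profile raises an error rather than
#' silently passing through; [normalize_dataset()] exposes an
#' identity-normalization fallback for that case.
#'
#' @param temperatures temperature grid (degrees C).
#' @param median_profile per-temperature median fold-changes.
#' @return list with `params` ([ll4_params()]) and `fitted_profile`
#'   (fitted values on the grid).
#' @export
fit_median_sigmoid <- function(temperatures, median_profile) {
  if (any(!is.finite(median_profile))) {
    stop("median profile must be finite", call. = FALSE)
  }
  fit <- fit_ll4(temperatures, median_profile)
  if (!fit$converged) {
    diag <- attr(fit, "diagnostics")
    stop(paste0("median-profile sigmoid fit failed: ",
                paste(diag, collapse = "; ")), call. = FALSE)
  }
  list(params = fit, fitted_profile = attr(fit, "fitted"))
}

#' Normalization factors of one run
#'
#' Combines the observed and fitted median profiles into the run's
#' normalization vector: the fitting factor re-shapes each temperature
#' channel onto the fitted melting trend
#' (`fitting_factor[j] = fitted[j] / observed[j]`), and the scaling factor
#' anchors the fitted trend at 1.0 at the lowest temperature
#' (`scaling_factor = 1 / fitted[lowest]`), correcting baseline
#' differences between runs. The applied per-channel factor is their
#' product.
#'
#' @param median_profile observed per-temperature medians (strictly
#'   positive).
#' @param fitted_profile fitted medians from [fit_median_sigmoid()]
#'   (strictly positive).
#' @param run optional run identifier carried in the result.
#' @return an object of class `normalization_factors` with fields
#'   `run`, `median_profile`, `fitted_profile`, `fitting_factor`,
#'   `scaling_factor`, `normalization_factor`.
#' @export
compute_normalization_factors <- function(median_profile, fitted_profile,
                                          run = NULL) {
  if (length(median_profile) != length(fitted_profile)) {
    stop("profiles must have equal length", call. = FALSE)
  }
  if (any(median_profile <= 0) || any(!is.finite(median_profile))) {
    stop("observed medians must be finite and > 0", call. = FALSE)
  }
  if (any(fitted_profile <= 0) || any(!is.finite(fitted_profile))) {
    stop("fitted medians must be finite and > 0", call. = FALSE)
  }
  fitting_factor <- fitted_profile / median_profile
  scaling_factor <- 1 / fitted_profile[1]
  structure(
    list(run = run,
         median_profile = median_profile,
         fitted_profile = fitted_profile,
         fitting_factor = fitting_factor,
         scaling_factor = scaling_factor,
         normalization_factor = scaling_factor * fitting_factor),
    class = "normalization_factors"
  )
}

#' @export
print.normalization_factors <- function(x, ...) {
  cat(sprintf("normalization factors%s: scaling %.4f, per-channel %s\n",
              if (is.null(x$run)) "" else paste0(" [", x$run, "]"),
              x$scaling_factor,
              paste(sprintf("%.3f", x$normalization_factor),
                    collapse = " ")))
  invisible(x)
}

#' Apply per-run normalization factors to a dataset
#'
#' Multiplies each value by its run's per-temperature normalization
#' factor; missing values stay missing. Factors are per-run-per-temperature
#' scalars, so protein rank order within any one channel is preserved.
#'
#' @param dataset a [melt_dataset()].
#' @param factors named list of [compute_normalization_factors()] results,
#'   one per sample ID.
#' @return the normalized [melt_dataset()]; provenance records the factors.
#' @export
apply_normalization <- function(dataset, factors) {
  stopifnot(inherits(dataset, "melt_dataset"))
  missing_runs <- setdiff(dataset$samples$sample_id, names(factors))
  if (length(missing_runs)) {
    stop(sprintf("no normalization factors for run: %s",
                 missing_runs[1]), call. = FALSE)
  }
  values <- dataset$values
  for (sid in dataset$samples$sample_id) {
    nf <- factors[[sid]]$normalization_factor
    if (length(nf) != length(dataset$temperatures)) {
      stop("factor vector length must match the temperature grid",
           call. = FALSE)
    }
    values[, sid, ] <- sweep(values[, sid, , drop = FALSE], 3, nf, `*`)
  }
  prov <- dataset$provenance
  prov$normalization <- lapply(factors, function(f) {
    list(scaling_factor = f$scaling_factor,
         normalization_factor = f$normalization_factor)
  })
  melt_dataset(values, dataset$temperatures, dataset$samples,
               dataset$protein_ids, provenance = prov)
}

#' Normalize every run of a dataset
#'
#' Convenience wrapper: per run, compute the median profile, fit the
#' sigmoidal melting trend, derive the normalization factors, and apply
#' them.
#'
#' @param dataset a [melt_dataset()].
#' @param fallback_identity if `TRUE`, a run whose median-profile fit fails
#'   (e.g. a flat profile) is left unchanged (identity factors) with a
#'   warning instead of erroring.
#' @return list with `dataset` (normalized) and `factors` (named list per
#'   run).
#' @export
normalize_dataset <- function(dataset, fallback_identity = FALSE) {
  stopifnot(inherits(dataset, "melt_dataset"))
  factors <- list()
  for (sid in dataset$samples$sample_id) {
    profile <- compute_median_profile(dataset, sid)
    fit <- tryCatch(fit_median_sigmoid(dataset$temperatures, profile),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      if (!fallback_identity) stop(fit)
      warning(sprintf(
        "run %s: %s; falling back to identity normalization",
        sid, conditionMessage(fit)), call. = FALSE)
      m <- length(dataset$temperatures)
      factors[[sid]] <- structure(
        list(run = sid, median_profile = profile,
             fitted_profile = profile,
             fitting_factor = rep(1, m), scaling_factor = 1,
             normalization_factor = rep(1, m)),
        class = "normalization_factors")
    } else {
      factors[[sid]] <- compute_normalization_factors(
        profile, fit$fitted_profile, run = sid)
    }
  }
  list(dataset = apply_normalization(dataset, factors),
       factors = factors)
}
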
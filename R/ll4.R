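#' Four-parameter log-logistic melting model
#'
#' Evaluates the four-parameter log-logistic (LL4) response
#' \deqn{f(T) = c + \frac{d - c}{1 + \exp\{b(\ln T - \ln e)\}}}
#' where `c` is the lower plateau, `d` the upper plateau, `b` the slope and
#' `e` the inflection temperature. With `b > 0` the curve decreases with
#' temperature, the convention for melting (soluble-fraction) curves: the
#' fold-change starts near 1 at the lowest temperature and decays to the
#' bottom plateau as the protein denatures and precipitates.
#'
#' @param params an [ll4_params()] object (or any list with elements
#'   `slope`, `lower`, `upper`, `inflection`).
#' @param temperature numeric vector of temperatures in degrees Celsius;
#'   must be strictly positive (the model acts on `ln T`).
#' @return numeric vector of fold-change responses, one per temperature.
#' @examples
#' p <- ll4_params(slope = 10, lower = 0.05, upper = 1, inflection = 50)
#' ll4_response(p, c(37, 50, 64))
#' @seealso [melting_point()], [fit_ll4()]
#' @export
ll4_response <- function(params, temperature) {
  if (!is.numeric(temperature) || any(!is.finite(temperature))) {
    stop("`temperature` must be finite numeric", call. = FALSE)
  }
  if (any(temperature <= 0)) {
    stop("`temperature` must be strictly positive (model is in ln T)",
         call. = FALSE)
  }
  b <- params$slope
  c_ <- params$lower
  d <- params$upper
  e <- params$inflection
  if (is.null(b) || is.null(c_) || is.null(d) || is.null(e)) {
    stop("`params` must carry slope, lower, upper and inflection",
         call. = FALSE)
  }
  c_ + (d - c_) / (1 + exp(b * (log(temperature) - log(e))))
}

#' Construct an LL4 parameter set
#'
#' @param slope dimensionless slope `b`; positive for curves that decrease
#'   with temperature.
#' @param lower bottom fold-change plateau `c`.
#' @param upper top fold-change plateau `d`.
#' @param inflection inflection temperature `e` in degrees Celsius; must be
#'   positive.
#' @param rss residual sum of squares of the fit that produced these
#'   parameters (0 for exact/constructed parameters).
#' @param converged logical; whether the producing fit converged.
#' @return an object of class `ll4_params`.
#' @export
ll4_params <- function(slope, lower, upper, inflection, rss = 0,
                       converged = TRUE) {
  if (is.finite(inflection) && inflection <= 0) {
    stop("`inflection` must be > 0", call. = FALSE)
  }
  if (is.finite(rss) && rss < 0) stop("`rss` must be >= 0", call. = FALSE)
  structure(
    list(slope = slope, lower = lower, upper = upper,
         inflection = inflection, rss = rss, converged = isTRUE(converged)),
    class = "ll4_params"
  )
}

#' @export
print.ll4_params <- function(x, ...) {
  cat(sprintf(
    "LL4: slope=%.4g lower=%.4g upper=%.4g inflection=%.4g C (rss=%.3g, %s)\n",
    x$slope, x$lower, x$upper, x$inflection, x$rss,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Melting point of an LL4 curve at a fold-change level
#'
#' Solves `ll4_response(params, T) = level` in closed form. Rearranging the
#' LL4 model gives
#' \deqn{T_m = e \left(\frac{d - \mathrm{level}}{\mathrm{level} - c}\right)^{1/b}}
#' which exists whenever the level lies strictly between the two plateaus.
#' The default level of 0.5 defines the melting point as the temperature at
#' which half of the protein remains soluble relative to the lowest
#' temperature, the convention used for thermal-shift (delta Tm) analysis.
#'
#' @param params an [ll4_params()] object; must be converged.
#' @param level fold-change level at which the melting point is read
#'   (default 0.5).
#' @return an object of class `melting_point`: list with `tm` (degrees C, or
#'   `NA` when undefined), `level`, `defined` flag and `reason` (empty when
#'   defined).
#' @examples
#' melting_point(ll4_params(1, 0.2, 1.0, 45))$tm  # 45 * (0.5/0.3) = 75
#' @export
melting_point <- function(params, level = 0.5) {
  undefined <- function(reason) {
    structure(list(tm = NA_real_, level = level, defined = FALSE,
                   reason = reason), class = "melting_point")
  }
  if (!isTRUE(params$converged)) return(undefined("fit not converged"))
  c_ <- params$lower
  d <- params$upper
  b <- params$slope
  e <- params$inflection
  if (!all(is.finite(c(b, c_, d, e)))) return(undefined("non-finite parameters"))
  if (c_ >= level) return(undefined("lower plateau at or above level"))
  if (d <= level) return(undefined("upper plateau at or below level"))
  if (b == 0) return(undefined("zero slope (flat curve)"))
  tm <- e * ((d - level) / (level - c_))^(1 / b)
  if (!is.finite(tm) || tm <= 0) return(undefined("no positive crossing"))
  structure(list(tm = tm, level = level, defined = TRUE, reason = ""),
            class = "melting_point")
}

#' @export
print.melting_point <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("Tm = %.3f C at level %.2f\n", x$tm, x$level))
  } else {
    cat(sprintf("Tm undefined at level %.2f: %s\n", x$level, x$reason))
  }
  invisible(x)
}
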
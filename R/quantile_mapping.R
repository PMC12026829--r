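# Empirical quantile mapping.
#
# The correction h(x) = CDF_y^-1(CDF_x(x)) is estimated non-parametrically:
# matching empirical quantiles of the modeled sample (the GBLUP training
# predictions, x) and the reference sample (the training observed values, y)
# at equally spaced probability points, with monotone piecewise-linear
# interpolation between the knot pairs. Applying h to the model output makes
# its distribution match the reference over the calibration range.

#' Build an empirical quantile-mapping transfer function
#'
#' @param observed_train Reference sample (training observed values).
#' @param predicted_train Modeled sample (training predictions); same length.
#' @param n_knots Number of quantile knots (>= 2); default
#'   `min(100, length(observed_train))`. Quantiles use type-7 interpolation
#'   at probabilities `seq(0, 1, length.out = n_knots)`.
#' @param extrapolation_policy How to map values beyond the knot range:
#'   `"constant_offset"` (default) adds the boundary offset
#'   `y_knot - x_knot`; `"clamp"` returns the boundary y knot.
#' @return An object of class `qm_transfer` with sorted `x_quantiles`,
#'   `y_quantiles`, `n_knots` and the policy.
#' @examples
#' tf <- build_transfer(rnorm(200, 2), rnorm(200), n_knots = 20)
#' apply_transfer(tf, c(-1, 0, 1))
#' @export
build_transfer <- function(observed_train, predicted_train,
                           n_knots = NULL,
                           extrapolation_policy = c("constant_offset",
                                                    "clamp")) {
  extrapolation_policy <- match.arg(extrapolation_policy)
  if (length(observed_train) != length(predicted_train)) {
    stop("observed and predicted calibration samples differ in length",
         call. = FALSE)
  }
  if (length(observed_train) < 2L) {
    stop("need at least 2 calibration pairs", call. = FALSE)
  }
  if (anyNA(observed_train) || anyNA(predicted_train) ||
      any(!is.finite(observed_train)) || any(!is.finite(predicted_train))) {
    stop("calibration samples must be finite", call. = FALSE)
  }
  if (is.null(n_knots)) n_knots <- min(100L, length(observed_train))
  n_knots <- as.integer(n_knots)
  if (n_knots < 2L) stop("`n_knots` must be >= 2", call. = FALSE)

  probs <- seq(0, 1, length.out = n_knots)
  structure(
    list(x_quantiles = unname(stats::quantile(predicted_train, probs,
                                              type = 7)),
         y_quantiles = unname(stats::quantile(observed_train, probs,
                                              type = 7)),
         n_knots = n_knots,
         extrapolation_policy = extrapolation_policy),
    class = "qm_transfer"
  )
}

#' Apply a quantile-mapping transfer function
#'
#' Values inside the knot range are mapped by monotone piecewise-linear
#' interpolation between knot pairs (tied x knots are collapsed to the mean
#' of their y knots); values outside are handled by the transfer's
#' extrapolation policy.
#'
#' @param tf A [build_transfer()] result.
#' @param predicted_test Numeric vector to map (may be empty).
#' @return Mapped numeric vector, same length and names.
#' @export
apply_transfer <- function(tf, predicted_test) {
  stopifnot(inherits(tf, "qm_transfer"))
  if (length(predicted_test) == 0L) return(predicted_test[0])
  xk <- tf$x_quantiles
  yk <- tf$y_quantiles
  if (any(duplicated(xk))) {
    agg <- tapply(yk, xk, mean)
    xk <- as.numeric(names(agg))
    yk <- unname(agg)
  }
  out <- if (length(xk) == 1L) {
    # Fully degenerate modeled sample: constant offset everywhere.
    predicted_test + (yk[1] - xk[1])
  } else {
    stats::approx(xk, yk, xout = predicted_test, rule = 2)$y
  }
  lo <- predicted_test < xk[1]
  hi <- predicted_test > xk[length(xk)]
  if (tf$extrapolation_policy == "constant_offset") {
    out[lo] <- predicted_test[lo] + (yk[1] - xk[1])
    out[hi] <- predicted_test[hi] + (yk[length(yk)] - xk[length(xk)])
  } # "clamp" is what rule = 2 already did
  names(out) <- names(predicted_test)
  out
}

#' @export
print.qm_transfer <- function(x, ...) {
  cat(sprintf("Quantile-mapping transfer: %d knots, policy = %s\n",
              x$n_knots, x$extrapolation_policy))
  cat(sprintf("x range [%.4f, %.4f] -> y range [%.4f, %.4f]\n",
              min(x$x_quantiles), max(x$x_quantiles),
              min(x$y_quantiles), max(x$y_quantiles)))
  invisible(x)
}
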
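#' Inverse-variance-weighted slope (minPPV estimate)
#'
#' Fits a weighted least-squares regression through the origin of candidate
#' effect sizes on reference effect sizes, weighting each variant by the
#' inverse squared candidate standard error. Under a misclassification model
#' in which a fraction pi of labelled cases are true cases, observed log
#' odds ratios are attenuated approximately by pi, so the fitted slope
#' lower-bounds the positive predictive value of the candidate case
#' definition (the minPPV).
#'
#' The slope is `sum(w x y) / sum(w x^2)` with `w = 1 / se_y^2`. Its
#' standard error is `sqrt(phi / sum(w x^2))` where the multiplicative
#' overdispersion scale `phi = max(1, sum(w (y - b x)^2) / (n - 1))` is
#' clamped at 1 so the SE is never shrunk below the fixed-weight value.
#' With `weights = "both"` the reference SE enters the weight denominator
#' as `se_y^2 + b^2 se_x^2`, iterated to convergence.
#'
#' @param pairs Paired-effects tibble from [harmonize()] (columns `x`, `y`,
#'   `se_y`, optionally `se_x` and `variant_id`).
#' @param level Confidence level for the stored interval (default 0.95).
#' @param weights `"candidate"` (default) weights by `1/se_y^2` only;
#'   `"both"` also propagates the reference SE.
#' @return An object of class `ivw_fit`: a list with elements `slope`, `se`,
#'   `ci_lo`, `ci_hi`, `level`, `n_variants`, `dispersion_scale` and the
#'   input `pairs` (with fitted weights and residuals appended).
#' @seealso [tidy.ivw_fit()], [glance.ivw_fit()], [autoplot.ivw_fit()],
#'   [slope_ci()]
#' @export
#' @examples
#' pairs <- tibble::tibble(x = c(0.1, 0.2, 0.4),
#'                         y = c(0.05, 0.12, 0.25),
#'                         se_y = c(0.05, 0.04, 0.05))
#' fit <- ivw_slope(pairs)
#' fit$slope  # 57/93
ivw_slope <- function(pairs, level = 0.95, weights = c("candidate", "both")) {
  weights <- match.arg(weights)
  stopifnot(all(c("x", "y", "se_y") %in% names(pairs)))
  n <- nrow(pairs)
  if (n < 2) {
    rlang::abort("At least 2 paired effects are required.",
                 class = "minppv_insufficient_data")
  }
  if (any(pairs$se_y <= 0) || any(!is.finite(pairs$se_y))) {
    rlang::abort("All candidate standard errors must be positive and finite.",
                 class = "minppv_invalid_se")
  }
  if (all(pairs$x == 0)) {
    rlang::abort("All reference effects are zero: slope is unidentified.",
                 class = "minppv_degenerate_regressor")
  }

  x <- pairs$x
  y <- pairs$y

  fit_once <- function(w) sum(w * x * y) / sum(w * x^2)

  w <- 1 / pairs$se_y^2
  b <- fit_once(w)
  if (weights == "both") {
    if (!"se_x" %in% names(pairs) || any(!is.finite(pairs$se_x))) {
      rlang::abort("weights = 'both' requires finite se_x for every pair.",
                   class = "minppv_invalid_se")
    }
    for (i in seq_len(50)) {
      w <- 1 / (pairs$se_y^2 + b^2 * pairs$se_x^2)
      b_new <- fit_once(w)
      if (abs(b_new - b) < 1e-12) { b <- b_new; break }
      b <- b_new
    }
  }

  resid <- y - b * x
  phi <- max(1, sum(w * resid^2) / (n - 1))
  se <- sqrt(phi / sum(w * x^2))
  z <- stats::qnorm(1 - (1 - level) / 2)

  pairs$weight <- w
  pairs$residual <- resid

  structure(
    list(slope = b, se = se,
         ci_lo = b - z * se, ci_hi = b + z * se,
         level = level, n_variants = n,
         dispersion_scale = phi,
         weights_mode = weights,
         pairs = pairs),
    class = "ivw_fit"
  )
}

#' Confidence interval for an IVW slope
#'
#' Symmetric normal-quantile interval around the fitted slope. At the level
#' stored in the fit (default 0.95) this equals the interval recorded in the
#' `ivw_fit` object.
#'
#' @param est An `ivw_fit` object.
#' @param level Confidence level in (0, 1).
#' @return Named numeric vector `c(lo, hi)`.
#' @export
slope_ci <- function(est, level = 0.95) {
  stopifnot(inherits(est, "ivw_fit"))
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    rlang::abort("`level` must be a single number in (0, 1).",
                 class = "minppv_invalid_level")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(lo = est$slope - z * est$se, hi = est$slope + z * est$se)
}

#' @export
print.ivw_fit <- function(x, ...) {
  cat(sprintf(
    "IVW regression through the origin (%d variants)\n", x$n_variants))
  cat(sprintf("  slope (minPPV): %.4f  SE %.4f  %g%% CI [%.4f, %.4f]\n",
              x$slope, x$se, 100 * x$level, x$ci_lo, x$ci_hi))
  cat(sprintf("  overdispersion scale: %.3f\n", x$dispersion_scale))
  invisible(x)
}

#' Tidy an IVW fit
#'
#' @param x An `ivw_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @method tidy ivw_fit
#' @export
tidy.ivw_fit <- function(x, ...) {
  tibble::tibble(
    term = "slope",
    estimate = x$slope,
    std.error = x$se,
    conf.low = x$ci_lo,
    conf.high = x$ci_hi
  )
}

#' One-row model summary of an IVW fit
#'
#' @param x An `ivw_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `slope`, `se`, `ci_lo`, `ci_hi`,
#'   `n_variants`, `dispersion_scale`.
#' @method glance ivw_fit
#' @export
glance.ivw_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, se = x$se,
    ci_lo = x$ci_lo, ci_hi = x$ci_hi,
    n_variants = x$n_variants,
    dispersion_scale = x$dispersion_scale
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Scatter plot of candidate vs reference effects with the IVW fit
#'
#' Reproduces the standard diagnostic figure: candidate effect size against
#' reference effect size per variant, error bars of one candidate SE, the
#' fitted through-origin slope and its confidence band, and the identity
#' line for comparison.
#'
#' @param object An `ivw_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ivw_fit
#' @export
autoplot.ivw_fit <- function(object, ...) {
  pairs <- object$pairs
  xr <- range(c(0, pairs$x))
  band <- tibble::tibble(
    x = seq(xr[1], xr[2], length.out = 100)
  )
  band$fit <- object$slope * band$x
  band$lo <- object$ci_lo * band$x
  band$hi <- object$ci_hi * band$x

  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$x, ymin = pmin(.data$lo, .data$hi),
                   ymax = pmax(.data$lo, .data$hi)),
      inherit.aes = FALSE, fill = "red", alpha = 0.15) +
    ggplot2::geom_line(data = band,
                       ggplot2::aes(x = .data$x, y = .data$fit),
                       inherit.aes = FALSE, colour = "red") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$y - .data$se_y, ymax = .data$y + .data$se_y),
      width = 0, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Reference effect size (log OR)",
      y = "Candidate effect size (log OR)",
      title = sprintf("IVW slope %.3f [%.3f, %.3f] (minPPV)",
                      object$slope, object$ci_lo, object$ci_hi)
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
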
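# Exponential penetration-depth estimation from a measured shell profile.

#' Fit an exponential penetration depth to a radial profile
#'
#' Models the aggregate intensity as `A * exp(-depth / lambda)` and
#' estimates the decay length `lambda` (pixels) by least squares between
#' the measured shell percentages and the model-predicted percentages.
#'
#' When a [compute_depth_map()] is supplied, the prediction uses the
#' organoid's actual per-pixel depth distribution (same binning rule as
#' the measurement), which removes the discretization bias of the
#' idealized disk; otherwise a closed-form perfect-disk approximation is
#' used.
#'
#' @param profile A `radial_profile` from [measure_profile()].
#' @param depth Optional `depth_map` of the same organoid.
#' @param lambda_range Search interval in pixels (default 0.5 to twice
#'   the radius).
#' @return An object of class `penetration_fit` with the estimate
#'   (`lambda_px`), observed and fitted percentages and the residual sum
#'   of squares.  `coef()` returns the estimate.
#' @export
fit_penetration <- function(profile, depth = NULL, lambda_range = NULL) {
  stopifnot(inherits(profile, "radial_profile"))
  obs <- profile$percent
  R <- profile$own_radius_px
  if (is.null(lambda_range)) lambda_range <- c(0.5, 2 * R)
  K <- length(obs)
  if (!is.null(depth)) {
    stopifnot(inherits(depth, "depth_map"))
    d <- depth$depth[depth$depth > 0]
    lab <- shell_index_of(d, profile$width_px, K)
    predict_pct <- function(l) {
      wgt <- exp(-d / l)
      s <- rowsum(wgt, lab)
      out <- numeric(K)
      out[as.integer(rownames(s))] <- s
      100 * out / sum(wgt)
    }
  } else {
    model_of <- function(l) model_exponential(l)
    predict_pct <- function(l)
      100 * closed_form_fractions(model_of(l), R, profile$depth_lo_px,
                                  profile$depth_hi_px)
  }
  sse <- function(l) sum((obs - predict_pct(l))^2)
  opt <- stats::optimize(sse, lambda_range)
  lam <- opt$minimum
  structure(
    list(lambda_px = lam, sse = opt$objective, observed = obs,
         fitted = predict_pct(lam), mid_depth_px = profile$mid_depth_px,
         own_radius_px = R, width_px = profile$width_px,
         method = if (is.null(depth)) "closed-form disk" else "per-pixel depth",
         meta = profile$meta),
    class = "penetration_fit"
  )
}

#' @export
coef.penetration_fit <- function(object, ...) c(lambda_px = object$lambda_px)

#' @export
print.penetration_fit <- function(x, ...) {
  cat(sprintf("<penetration_fit> lambda = %.2f px (%s, radius %.1f px, SSE %.3g)\n",
              x$lambda_px, x$method, x$own_radius_px, x$sse))
  invisible(x)
}

#' @export
fitted.penetration_fit <- function(object, ...) object$fitted

#' @export
residuals.penetration_fit <- function(object, ...) object$observed - object$fitted

#' @export
plot.penetration_fit <- function(x, ...) {
  graphics::plot(x$mid_depth_px, x$observed, pch = 16,
                 xlab = "shell mid-depth (px)", ylab = "% of total IntDen", ...)
  graphics::lines(x$mid_depth_px, x$fitted, col = "firebrick")
  graphics::legend("topright", legend = c("measured",
                   sprintf("exponential fit (lambda = %.1f px)", x$lambda_px)),
                   pch = c(16, NA), lty = c(NA, 1), col = c("black", "firebrick"),
                   bty = "n")
  invisible(x)
}
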
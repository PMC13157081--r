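# Radial signal models for the synthetic generator and the penetration
# fit.  Depth is measured from the organoid border (surface) inward; on a
# perfect disk of radius R, tissue at depth d lies on a circle of radius
# R - d, so the closed-form shell integrals carry the weight (R - d).

#' Radial signal models
#'
#' Constructors for the radial distribution models of the aggregate
#' channel used by [generate_section()] and [expected_profile()]:
#'
#' * `model_uniform()` — constant intensity throughout the tissue.
#' * `model_crust(depth_px)` — all signal within `depth_px` of the surface
#'   (the "crust" pattern of freshly exposed organoids).
#' * `model_exponential(decay_px)` — intensity decaying as
#'   `exp(-depth / decay_px)`; larger decay lengths mean deeper
#'   penetration.
#' * `model_channels(count, width_px, depth_px)` — straight radial
#'   corridors with a Gaussian cross-section running from the border
#'   toward the center, mimicking cell-to-cell transfer routes.
#' * `model_punctate(cluster_count, cluster_radius_px, depth_frac_range)`
#'   — Gaussian clumps at random angles, with center depths drawn
#'   uniformly from the given fraction-of-radius range.
#'
#' @param depth_px,decay_px,width_px,cluster_radius_px Lengths in pixels.
#' @param count,cluster_count Positive integer.
#' @param depth_frac_range Length-2 numeric in \[0, 1\].
#' @return An object of class `radial_model`.
#' @name radial_models
NULL

new_model <- function(type, ...) {
  structure(c(list(type = type), list(...)), class = "radial_model")
}

#' @rdname radial_models
#' @export
model_uniform <- function() new_model("uniform")

#' @rdname radial_models
#' @export
model_crust <- function(depth_px) {
  stopifnot(is.numeric(depth_px), length(depth_px) == 1L, depth_px > 0)
  new_model("crust", depth_px = depth_px)
}

#' @rdname radial_models
#' @export
model_exponential <- function(decay_px) {
  stopifnot(is.numeric(decay_px), length(decay_px) == 1L, decay_px > 0)
  new_model("exponential", decay_px = decay_px)
}

#' @rdname radial_models
#' @export
model_channels <- function(count = 3, width_px = 10, depth_px = 150) {
  stopifnot(count >= 1, width_px > 0, depth_px > 0)
  new_model("channels", count = as.integer(count), width_px = width_px,
            depth_px = depth_px)
}

#' @rdname radial_models
#' @export
model_punctate <- function(cluster_count = 8, cluster_radius_px = 12,
                           depth_frac_range = c(0, 0.3)) {
  stopifnot(cluster_count >= 1, cluster_radius_px > 0,
            length(depth_frac_range) == 2L,
            all(depth_frac_range >= 0), all(depth_frac_range <= 1),
            depth_frac_range[1] <= depth_frac_range[2])
  new_model("punctate", cluster_count = as.integer(cluster_count),
            cluster_radius_px = cluster_radius_px,
            depth_frac_range = depth_frac_range)
}

#' @export
print.radial_model <- function(x, ...) {
  pars <- x[setdiff(names(x), "type")]
  cat(sprintf("<radial_model> %s(%s)\n", x$type,
              paste(names(pars), vapply(pars, function(p)
                paste(format(p), collapse = ","), ""),
                sep = "=", collapse = ", ")))
  invisible(x)
}

has_closed_form <- function(model) {
  model$type %in% c("uniform", "crust", "exponential")
}

# Integral of (R - d) * f(d) over [a, b] for the closed-form models.
# uniform: f = 1; crust(delta): f = 1 on [0, delta); exponential(lambda):
# f = exp(-d / lambda), antiderivative F(d) = exp(-d/l) (l^2 - l (R - d)).
model_band_integral <- function(model, R, a, b) {
  switch(model$type,
    uniform = {
      Fd <- function(d) R * d - d^2 / 2
      Fd(b) - Fd(a)
    },
    crust = {
      delta <- min(model$depth_px, R)
      a2 <- pmin(a, delta); b2 <- pmin(b, delta)
      Fd <- function(d) R * d - d^2 / 2
      pmax(Fd(b2) - Fd(a2), 0)
    },
    exponential = {
      l <- model$decay_px
      Fd <- function(d) exp(-d / l) * (l^2 - l * (R - d))
      Fd(b) - Fd(a)
    },
    stop("no closed form for model '", model$type, "'", call. = FALSE)
  )
}

# Closed-form fraction of total signal in each depth band [lo_i, hi_i] on
# a perfect disk of radius R.
closed_form_fractions <- function(model, R, lo, hi) {
  num <- mapply(function(a, b) model_band_integral(model, R, a, b), lo, hi)
  tot <- model_band_integral(model, R, 0, R)
  as.numeric(num) / tot
}
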
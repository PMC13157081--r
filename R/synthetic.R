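# Synthetic organoid-section generator.  Produces sections with a known
# tissue geometry and a known radial distribution of the aggregate
# channel, together with the exact noiseless profile, so every stage of
# the pipeline can be validated without microscopy data.

#' Specification of a synthetic organoid section
#'
#' Describes the geometry (radius, ellipticity, low-order boundary
#' roughness), the radial signal model (see [radial_models]), the
#' fluorescence amplitudes and the noise of one generated section.
#' Noise follows the standard fluorescence approximation: Poisson shot
#' noise on the expected photon count plus Gaussian read noise.
#'
#' @param radius_px Nominal organoid radius in pixels (geometric mean of
#'   the ellipse semi-axes; default 300).
#' @param ellipticity Axis ratio >= 1 (default 1, a circle).
#' @param boundary_roughness Total relative amplitude of the Fourier
#'   boundary perturbation (modes 3-8); 0 for a smooth outline.  Values
#'   up to ~0.2 keep the outline simply connected.
#' @param model A [radial_models] object (default
#'   `model_exponential(40)`).
#' @param signal_amplitude Peak aggregate intensity in counts
#'   (default 1000).
#' @param background Constant background level added everywhere
#'   (default 2; the aggregate channel of a background-subtracted
#'   acquisition is nearly dark outside the labelled deposits).
#' @param poisson Apply Poisson shot noise (default TRUE).
#' @param gaussian_sd Gaussian read-noise SD in counts (default 2).
#' @param marker_texture_scale Correlation length (pixels) of the
#'   cell-marker texture (default 15).
#' @param field_px Image height and width (default 1024 x 1024).
#' @param seed Integer seed making the section fully reproducible.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(radius_px = 300, ellipticity = 1,
                           boundary_roughness = 0,
                           model = model_exponential(40),
                           signal_amplitude = 1000, background = 2,
                           poisson = TRUE, gaussian_sd = 2,
                           marker_texture_scale = 15,
                           field_px = c(1024, 1024), seed = 1) {
  stopifnot(inherits(model, "radial_model"))
  if (radius_px <= 0) stop("'radius_px' must be positive", call. = FALSE)
  if (ellipticity < 1) stop("'ellipticity' must be >= 1", call. = FALSE)
  if (boundary_roughness < 0 || boundary_roughness >= 0.5)
    stop("'boundary_roughness' must be in [0, 0.5)", call. = FALSE)
  if (signal_amplitude <= 0) stop("'signal_amplitude' must be positive", call. = FALSE)
  if (background < 0 || gaussian_sd < 0)
    stop("'background' and 'gaussian_sd' must be non-negative", call. = FALSE)
  if (length(field_px) != 2L || any(field_px < 16))
    stop("'field_px' must be two dimensions >= 16", call. = FALSE)
  len <- switch(model$type, crust = model$depth_px,
                exponential = model$decay_px, channels = model$depth_px, 0)
  if (len > radius_px)
    stop("model depth/decay length exceeds the organoid radius", call. = FALSE)
  extent <- radius_px * sqrt(ellipticity) * (1 + boundary_roughness)
  if (2 * extent + 8 > min(field_px))
    stop("organoid does not fit in the field: increase 'field_px' or ",
         "reduce 'radius_px'", call. = FALSE)
  structure(
    list(radius_px = radius_px, ellipticity = ellipticity,
         boundary_roughness = boundary_roughness, model = model,
         signal_amplitude = signal_amplitude, background = background,
         poisson = poisson, gaussian_sd = gaussian_sd,
         marker_texture_scale = marker_texture_scale,
         field_px = as.integer(field_px), seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> radius %g px, model %s, amplitude %g, seed %d\n",
              x$radius_px, x$model$type, x$signal_amplitude, x$seed))
  invisible(x)
}

# Random draws that define one section's geometry and model placement.
# Kept separate from rendering so the same draws can be re-rendered at a
# finer grid for numeric integration of the expected profile.
draw_boundary_modes <- function(spec) {
  if (spec$boundary_roughness <= 0)
    return(list(amps = numeric(6), phases = numeric(6)))
  raw <- stats::runif(6)
  list(amps = spec$boundary_roughness * raw / sum(raw),
       phases = stats::runif(6, 0, 2 * pi))
}

draw_model_params <- function(spec) {
  m <- spec$model
  switch(m$type,
    channels = list(angles = stats::runif(m$count, 0, 2 * pi)),
    punctate = list(angles = stats::runif(m$cluster_count, 0, 2 * pi),
                    depth_fracs = stats::runif(m$cluster_count,
                                               m$depth_frac_range[1],
                                               m$depth_frac_range[2])),
    NULL
  )
}

boundary_scale_at <- function(geom, theta) {
  if (all(geom$amps == 0)) return(rep(1, length(theta)))
  s <- rep(1, length(theta))
  for (i in 1:6) s <- s + geom$amps[i] * cos((i + 2) * theta + geom$phases[i])
  s
}

# Deterministic rendering of mask, depth map and noiseless signal field
# at an arbitrary scale (pixels per original pixel).
render_section_field <- function(spec, geom, mpar, scale = 1, dims = NULL) {
  if (is.null(dims)) dims <- as.integer(round(spec$field_px * scale))
  cy <- (dims[1] + 1) / 2; cx <- (dims[2] + 1) / 2
  R <- spec$radius_px * scale
  a <- R * sqrt(spec$ellipticity)   # column (x) semi-axis
  b <- R / sqrt(spec$ellipticity)   # row (y) semi-axis
  dy <- matrix(seq_len(dims[1]) - cy, dims[1], dims[2])
  dx <- matrix(seq_len(dims[2]) - cx, dims[1], dims[2], byrow = TRUE)
  rho <- sqrt((dx / a)^2 + (dy / b)^2)
  if (any(geom$amps != 0)) {
    theta <- atan2(dy, dx)
    s <- matrix(boundary_scale_at(geom, theta), dims[1], dims[2])
    mask <- rho <= s
  } else {
    mask <- rho <= 1
  }
  depth <- EBImage::imageData(EBImage::distmap(matrix(as.numeric(mask), dims[1])))
  radius <- max(depth)
  A <- spec$signal_amplitude
  m <- spec$model
  field <- switch(m$type,
    uniform = A * mask,
    crust = {
      out <- matrix(0, dims[1], dims[2])
      out[depth > 0 & depth < m$depth_px * scale] <- A
      out
    },
    exponential = {
      out <- matrix(0, dims[1], dims[2])
      sel <- depth > 0
      out[sel] <- A * exp(-depth[sel] / (m$decay_px * scale))
      out
    },
    channels = {
      out <- matrix(0, dims[1], dims[2])
      sigma <- m$width_px * scale / 2
      for (j in seq_along(mpar$angles)) {
        th <- mpar$angles[j]
        sb <- boundary_scale_at(geom, th)
        t_edge <- sb / sqrt((cos(th) / a)^2 + (sin(th) / b)^2)
        ex <- cx + t_edge * cos(th); ey <- cy + t_edge * sin(th)
        wx <- dx + cx - ex; wy <- dy + cy - ey
        along <- -(wx * cos(th) + wy * sin(th))   # inward direction
        perp2 <- wx^2 + wy^2 - along^2
        contrib <- A * exp(-perp2 / (2 * sigma^2))
        contrib[along < 0 | along > m$depth_px * scale] <- 0
        out <- out + contrib
      }
      out * mask
    },
    punctate = {
      out <- matrix(0, dims[1], dims[2])
      sigma <- m$cluster_radius_px * scale / 2
      for (j in seq_along(mpar$angles)) {
        th <- mpar$angles[j]
        sb <- boundary_scale_at(geom, th)
        t_edge <- sb / sqrt((cos(th) / a)^2 + (sin(th) / b)^2)
        tc <- (1 - mpar$depth_fracs[j]) * t_edge
        px <- cx + tc * cos(th); py <- cy + tc * sin(th)
        r2 <- (dx + cx - px)^2 + (dy + cy - py)^2
        out <- out + A * exp(-r2 / (2 * sigma^2))
      }
      out * mask
    },
    stop("unknown model type", call. = FALSE)
  )
  list(mask = mask, depth = depth, field = field, radius_px = radius,
       dims = dims)
}

apply_noise <- function(noiseless, spec) {
  img <- noiseless + spec$background
  if (spec$poisson)
    img <- matrix(stats::rpois(length(img), as.vector(img)), nrow(img))
  if (spec$gaussian_sd > 0)
    img <- img + stats::rnorm(length(img), 0, spec$gaussian_sd)
  pmax(round(img), 0)
}

# Per-pixel binning of the noiseless field into depth shells and regions;
# written out inline so the ground truth does not share code with the
# measurement path in radial.R.
truth_percents <- function(depth, mask, field, width_px) {
  d <- depth[mask]
  v <- field[mask]
  total <- sum(v)
  radius <- max(d)
  K <- as.integer(ceiling(radius / width_px))
  shell <- floor(d / width_px) + 1
  shell[shell > K] <- K
  shell_sum <- vapply(split(v, factor(shell, levels = seq_len(K))), sum, 0)
  reg <- findInterval(d / radius, c(0.2, 0.4, 0.6, 0.8)) + 1
  region_sum <- vapply(split(v, factor(reg, levels = 1:5)), sum, 0)
  list(shell_percent = unname(100 * shell_sum / total),
       region_percent = stats::setNames(100 * region_sum / total, REGION_NAMES),
       radius_px = radius, n_shells = K)
}

#' Generate a synthetic organoid section with known ground truth
#'
#' Renders the tissue mask, a textured cell-marker channel and an
#' aggregate (`signal`) channel following the radial model of `spec`,
#' applies Poisson + Gaussian noise, and returns both the noisy
#' [section_image()] and a `ground_truth` object holding the noiseless
#' raster, the true mask and the exact expected shell/region percentages
#' (per-pixel binning of the noiseless field).  Fully deterministic for a
#' given spec (the seed is part of the spec).
#'
#' @param spec A [synthetic_spec()].
#' @param width_px Shell width used for the ground-truth profile
#'   (default 25).
#' @param meta Optional [experiment_meta()]; defaults to an id derived
#'   from the seed.
#' @return A list with elements `section` and `truth`.
#' @export
generate_section <- function(spec, width_px = 25, meta = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(meta)) meta <- experiment_meta(paste0("sim-", spec$seed))
  set.seed(spec$seed)
  geom <- draw_boundary_modes(spec)
  mpar <- draw_model_params(spec)
  rf <- render_section_field(spec, geom, mpar, scale = 1)
  signal <- apply_noise(rf$field, spec)
  marker_tex <- smooth_raster(matrix(stats::runif(prod(rf$dims)), rf$dims[1]),
                              spec$marker_texture_scale)
  rng <- range(marker_tex)
  marker_tex <- if (rng[2] > rng[1]) (marker_tex - rng[1]) / (rng[2] - rng[1])
                else matrix(1, rf$dims[1], rf$dims[2])
  marker <- apply_noise(1000 * (0.5 + 0.5 * marker_tex) * rf$mask, spec)
  tp <- truth_percents(rf$depth, rf$mask, rf$field, width_px)
  section <- section_image(list(cell_marker = marker, signal = signal),
                           meta = meta)
  truth <- structure(
    list(signal_noiseless = rf$field, mask = rf$mask,
         radius_px = tp$radius_px, width_px = width_px,
         n_shells = tp$n_shells,
         shell_percent = tp$shell_percent,
         region_percent = tp$region_percent,
         spec = spec),
    class = "ground_truth"
  )
  list(section = section, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> model %s, radius %.1f px, %d shells\n",
              x$spec$model$type, x$radius_px, x$n_shells))
  cat("expected region percents:\n")
  print(round(x$region_percent, 2))
  invisible(x)
}

#' Expected noiseless shell percentages for a synthetic spec
#'
#' Closed-form annulus integrals for the uniform, crust and exponential
#' models on a perfect disk; for elliptical, rough-boundary or
#' channel/punctate specs, numeric integration on a supersampled
#' rendering of the noiseless field (the model placement draws reuse the
#' spec's seed, so the result matches [generate_section()]).
#'
#' @param spec A [synthetic_spec()].
#' @param width_px Shell width (default 25).
#' @param supersample Supersampling factor for the numeric path
#'   (default 4).
#' @return Numeric vector of shell percentages (summing to 100).
#' @export
expected_profile <- function(spec, width_px = 25, supersample = 4) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$ellipticity == 1 && spec$boundary_roughness == 0 &&
      has_closed_form(spec$model)) {
    R <- spec$radius_px
    K <- ceiling(R / width_px)
    lo <- (seq_len(K) - 1) * width_px
    hi <- pmin(seq_len(K) * width_px, R)
    return(100 * closed_form_fractions(spec$model, R, lo, hi))
  }
  tp <- supersampled_truth(spec, width_px, supersample)
  tp$shell_percent
}

#' Expected noiseless region percentages for a synthetic spec
#'
#' Same conventions as [expected_profile()] but binned into the five
#' regions R1-R5 (20% bands of the surface-to-center distance).
#'
#' @inheritParams expected_profile
#' @return Named numeric vector (R1..R5) summing to 100.
#' @export
expected_regions <- function(spec, supersample = 4) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$ellipticity == 1 && spec$boundary_roughness == 0 &&
      has_closed_form(spec$model)) {
    R <- spec$radius_px
    lo <- seq(0, 0.8, 0.2) * R
    hi <- seq(0.2, 1, 0.2) * R
    return(stats::setNames(100 * closed_form_fractions(spec$model, R, lo, hi),
                           REGION_NAMES))
  }
  tp <- supersampled_truth(spec, 25, supersample)
  tp$region_percent
}

supersampled_truth <- function(spec, width_px, supersample) {
  set.seed(spec$seed)
  geom <- draw_boundary_modes(spec)
  mpar <- draw_model_params(spec)
  half <- ceiling(spec$radius_px * sqrt(spec$ellipticity) *
                    (1 + spec$boundary_roughness) * supersample) + 8L
  dims <- as.integer(c(2L * half + 1L, 2L * half + 1L))
  rf <- render_section_field(spec, geom, mpar, scale = supersample, dims = dims)
  truth_percents(rf$depth / supersample, rf$mask, rf$field, width_px)
}

#' Generate a nuclei + TUNEL test image with known counts
#'
#' Places `n_nuclei` non-overlapping nucleus disks at seeded random
#' positions, marks `round(n_nuclei * positive_fraction)` of them
#' TUNEL-positive at `amplitude_ratio` times the baseline TUNEL
#' intensity, and applies Poisson + Gaussian noise.
#'
#' @param n_nuclei Number of nuclei to place.
#' @param positive_fraction Fraction in \[0, 1\] marked positive.
#' @param amplitude_ratio TUNEL intensity ratio positive/negative
#'   (default 10).
#' @param seed Integer seed.
#' @param field_px Image dimensions (default 512 x 512).
#' @param nucleus_radius_px Nucleus disk radius (default 6).
#' @param min_center_distance_px Minimum distance between nucleus
#'   centers (default `2 * nucleus_radius_px + 8`, guaranteeing
#'   separated, non-overlapping nuclei).
#' @param baseline Baseline (negative) TUNEL intensity (default 50).
#' @return A list with `section` (a [section_image()] with `nuclei` and
#'   `tunel` channels) and `truth` (`centers`, `positive_index`,
#'   `n_positive`).
#' @export
generate_tunel_fixture <- function(n_nuclei, positive_fraction = 0.25,
                                   amplitude_ratio = 10, seed = 1,
                                   field_px = c(512, 512),
                                   nucleus_radius_px = 6,
                                   min_center_distance_px = NULL,
                                   baseline = 50) {
  stopifnot(n_nuclei >= 1, positive_fraction >= 0, positive_fraction <= 1,
            amplitude_ratio > 0)
  if (is.null(min_center_distance_px))
    min_center_distance_px <- 2 * nucleus_radius_px + 8
  set.seed(seed)
  margin <- nucleus_radius_px + 4
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centers) < n_nuclei) {
    tries <- tries + 1L
    if (tries > 200L * n_nuclei)
      stop("capacity error: cannot place ", n_nuclei,
           " non-overlapping nuclei in the field", call. = FALSE)
    cand <- c(stats::runif(1, margin, field_px[1] - margin),
              stats::runif(1, margin, field_px[2] - margin))
    if (nrow(centers) == 0 ||
        all((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 >=
              min_center_distance_px^2))
      centers <- rbind(centers, cand)
  }
  n_pos <- round(n_nuclei * positive_fraction)
  pos_idx <- if (n_pos > 0) sort(sample.int(n_nuclei, n_pos)) else integer(0)
  dy <- matrix(seq_len(field_px[1]), field_px[1], field_px[2])
  dx <- matrix(seq_len(field_px[2]), field_px[1], field_px[2], byrow = TRUE)
  nuc <- matrix(0, field_px[1], field_px[2])
  tun <- matrix(0, field_px[1], field_px[2])
  for (i in seq_len(n_nuclei)) {
    disk <- (dy - centers[i, 1])^2 + (dx - centers[i, 2])^2 <= nucleus_radius_px^2
    nuc[disk] <- 600
    tun[disk] <- baseline * if (i %in% pos_idx) amplitude_ratio else 1
  }
  noise_spec <- list(background = 2, poisson = TRUE, gaussian_sd = 2)
  nuc <- apply_noise(nuc, noise_spec)
  tun <- apply_noise(tun, noise_spec)
  colnames(centers) <- c("row", "col")
  list(
    section = section_image(list(nuclei = nuc, tunel = tun)),
    truth = list(centers = centers, positive_index = pos_idx,
                 n_positive = as.integer(n_pos), n_nuclei = as.integer(n_nuclei))
  )
}

#' Simulate a balanced region-by-timepoint percentage dataset
#'
#' Draws each organoid's R1-R5 composition from a Dirichlet distribution
#' (components `concentration * mean_percents / 100`), for two
#' timepoints.  With identical means at both timepoints this is a null
#' dataset for calibrating the region-by-timepoint ANOVA; different means
#' simulate a penetration shift.
#'
#' @param n_per_timepoint Organoids per timepoint (default 6).
#' @param timepoints Two timepoint labels in weeks (default `c(1, 4)`).
#' @param mean_percents Mean region percentages at the first timepoint
#'   (default the uniform-disk composition `c(36, 28, 20, 12, 4)`).
#' @param mean_percents_2 Means at the second timepoint (default: same
#'   as the first, i.e. a null dataset).
#' @param concentration Dirichlet concentration; larger values mean less
#'   organoid-to-organoid variability (default 300, giving region SDs of
#'   1-3 percentage points).
#' @param seed Optional seed.
#' @return A data frame with columns `organoid_id`, `timepoint_weeks`,
#'   `region`, `percent`, ready for [region_time_anova()].
#' @export
simulate_region_dataset <- function(n_per_timepoint = 6, timepoints = c(1, 4),
                                    mean_percents = c(36, 28, 20, 12, 4),
                                    mean_percents_2 = NULL,
                                    concentration = 300, seed = NULL) {
  stopifnot(length(mean_percents) == 5, all(mean_percents > 0),
            length(timepoints) == 2, n_per_timepoint >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mean_percents_2)) mean_percents_2 <- mean_percents
  stopifnot(length(mean_percents_2) == 5, all(mean_percents_2 > 0))
  draw_one <- function(means) {
    alpha <- concentration * means / sum(means)
    g <- stats::rgamma(5, shape = alpha)
    100 * g / sum(g)
  }
  rows <- list()
  k <- 0L
  for (it in 1:2) {
    means <- if (it == 1) mean_percents else mean_percents_2
    for (i in seq_len(n_per_timepoint)) {
      k <- k + 1L
      p <- draw_one(means)
      rows[[k]] <- data.frame(
        organoid_id = sprintf("org%02d_w%s", i, timepoints[it]),
        timepoint_weeks = timepoints[it],
        region = REGION_NAMES, percent = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
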
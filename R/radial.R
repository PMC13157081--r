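# Core radial quantification: depth map, concentric shells, integrated
# density profiles and the five-region summary.

#' Euclidean depth map of an organoid mask
#'
#' For every tissue pixel, the exact Euclidean distance (in pixels) to the
#' nearest background pixel; zero outside the mask.  The maximum depth is
#' the organoid's surface-to-center "radius".
#'
#' @param mask An `organoid_mask` from [segment_organoid()], or a
#'   logical/0-1 matrix.
#' @return An object of class `depth_map` with `depth` (numeric matrix)
#'   and `radius_px`.
#' @export
compute_depth_map <- function(mask) {
  m <- if (inherits(mask, "organoid_mask")) mask$mask else mask > 0
  stopifnot(is.matrix(m))
  if (!any(m)) stop("mask is empty", call. = FALSE)
  if (all(m))
    stop("mask covers the whole image: no background to measure depth from",
         call. = FALSE)
  depth <- EBImage::imageData(EBImage::distmap(matrix(as.numeric(m), nrow(m)),
                                               metric = "euclidean"))
  structure(list(depth = depth, radius_px = max(depth)), class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  cat(sprintf("<depth_map> %dx%d px, radius %.2f px\n",
              nrow(x$depth), ncol(x$depth), x$radius_px))
  invisible(x)
}

# depth -> shell index: half-open bands [(i-1)w, iw), final band closed at
# the radius.  EDT depths are >= 1 on the mask so band (0, w) is shell 1;
# a depth exactly at i*w falls in shell i+1 except at the very center.
shell_index_of <- function(depth, width, K) {
  pmin(floor(depth / width) + 1, K)
}

#' Build concentric depth shells over an organoid
#'
#' Partitions the tissue into `K = ceiling(radius / width)` depth bands of
#' `width_px` pixels, from the border (shell 1) to the center (shell K);
#' the innermost band is truncated and closed at the radius.
#'
#' @param dm A [compute_depth_map()] result.
#' @param width_px Shell width in pixels (default 25, the ROI size of the
#'   original macro).
#' @return An object of class `shell_set` with the interval table and a
#'   label raster (0 outside the mask).
#' @export
build_shells <- function(dm, width_px = 25) {
  stopifnot(inherits(dm, "depth_map"))
  if (!is.numeric(width_px) || length(width_px) != 1L || width_px <= 0)
    stop("'width_px' must be a positive number", call. = FALSE)
  r <- dm$radius_px
  K <- as.integer(ceiling(r / width_px))
  labels <- matrix(0L, nrow(dm$depth), ncol(dm$depth))
  sel <- dm$depth > 0
  labels[sel] <- as.integer(shell_index_of(dm$depth[sel], width_px, K))
  lo <- (seq_len(K) - 1) * width_px
  hi <- pmin(seq_len(K) * width_px, r)
  structure(
    list(width_px = width_px, n_shells = K, depth_lo_px = lo, depth_hi_px = hi,
         shell_labels = labels, radius_px = r),
    class = "shell_set"
  )
}

#' @export
print.shell_set <- function(x, ...) {
  cat(sprintf("<shell_set> %d shells of width %g px over radius %.2f px\n",
              x$n_shells, x$width_px, x$radius_px))
  invisible(x)
}

#' Measure the radial integrated-density profile of a signal channel
#'
#' Sums the signal intensity (ImageJ-style integrated density, IntDen)
#' within each depth shell and normalizes to the total IntDen within the
#' mask, yielding a percentage per shell.  `relative_position` places each
#' shell midpoint on the axis of the reference radius, by default the
#' organoid's own radius; use [rescale_to_largest()] to re-reference a
#' comparison group to its largest organoid.
#'
#' @param signal Numeric matrix (aggregate channel) or a [section_image()]
#'   with a `signal` channel.
#' @param shells A [build_shells()] result.
#' @param reference_radius_px Radius defining the relative-position axis;
#'   defaults to the organoid's own radius.
#' @param meta Optional [experiment_meta()] carried into results.
#' @param background_offset Constant subtracted from every pixel (clipped
#'   at zero) before summation.  Default 0: integrated densities are
#'   taken on the raw intensities, with no background subtraction.
#' @return An object of class `radial_profile`; see
#'   [as.data.frame.radial_profile()].
#' @export
measure_profile <- function(signal, shells, reference_radius_px = NULL,
                            meta = NULL, background_offset = 0) {
  if (inherits(signal, "section_image")) {
    if (is.null(meta)) meta <- signal$meta
    signal <- get_channel(signal, "signal")
  }
  stopifnot(inherits(shells, "shell_set"), is.matrix(signal))
  if (!identical(dim(signal), dim(shells$shell_labels)))
    stop("signal dimensions do not match the shell labels", call. = FALSE)
  if (is.null(meta)) meta <- experiment_meta("unknown")
  K <- shells$n_shells
  sel <- shells$shell_labels > 0
  labs <- factor(shells$shell_labels[sel], levels = seq_len(K))
  vals <- pmax(signal[sel] - background_offset, 0)
  total <- sum(vals)
  if (total <= 0)
    stop("no signal: total integrated density within the mask is zero; ",
         "organoid excluded from per-organoid normalization", call. = FALSE)
  intden <- vapply(split(vals, labs), sum, numeric(1))
  pixel_count <- as.integer(tabulate(as.integer(labs), K))
  mid <- (shells$depth_lo_px + shells$depth_hi_px) / 2
  ref <- if (is.null(reference_radius_px)) shells$radius_px else reference_radius_px
  if (ref <= 0) stop("'reference_radius_px' must be positive", call. = FALSE)
  structure(
    list(
      shell_index = seq_len(K),
      depth_lo_px = shells$depth_lo_px,
      depth_hi_px = shells$depth_hi_px,
      mid_depth_px = mid,
      pixel_count = pixel_count,
      intden = unname(intden),
      percent = unname(100 * intden / total),
      relative_position = mid / ref,
      total_intden = total,
      width_px = shells$width_px,
      own_radius_px = shells$radius_px,
      reference_radius_px = ref,
      meta = meta
    ),
    class = "radial_profile"
  )
}

#' @export
print.radial_profile <- function(x, digits = 3, ...) {
  cat(sprintf("<radial_profile> organoid '%s': %d shells (width %g px), radius %.1f px\n",
              x$meta$organoid_id, length(x$shell_index), x$width_px, x$own_radius_px))
  print(as.data.frame(x), digits = digits, row.names = FALSE)
  invisible(x)
}

#' Flatten a radial profile to the tabular result schema
#'
#' @param x A `radial_profile`.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @return A data frame with columns `organoid_id, shell_index,
#'   depth_lo_px, depth_hi_px, relative_position, pixel_count, intden,
#'   percent`.
#' @export
as.data.frame.radial_profile <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    organoid_id = x$meta$organoid_id,
    shell_index = x$shell_index,
    depth_lo_px = x$depth_lo_px,
    depth_hi_px = x$depth_hi_px,
    relative_position = x$relative_position,
    pixel_count = x$pixel_count,
    intden = x$intden,
    percent = x$percent,
    stringsAsFactors = FALSE
  )
}

#' Plot a radial profile
#'
#' Percentage of total IntDen per shell against relative position along
#' the surface-to-center axis, with the five region boundaries marked.
#'
#' @param x A `radial_profile`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.radial_profile <- function(x, ...) {
  graphics::plot(x$relative_position, x$percent, type = "b", pch = 16,
                 xlab = "relative distance from surface (fraction of reference radius)",
                 ylab = "% of total IntDen", ...)
  rb <- seq(0.2, 0.8, by = 0.2) * x$own_radius_px / x$reference_radius_px
  graphics::abline(v = rb, lty = 3, col = "grey50")
  invisible(x)
}

REGION_NAMES <- paste0("R", 1:5)

# depth fraction -> region 1..5 with half-open bands [0,.2),...,[.8,1].
region_index_of <- function(frac) {
  findInterval(frac, c(0.2, 0.4, 0.6, 0.8)) + 1L
}

#' Summarize a signal channel into the five radial regions R1-R5
#'
#' Each tissue pixel is assigned to a region by its depth as a fraction of
#' this organoid's own radius (R1 = outermost 20% of the surface-to-center
#' distance, ..., R5 = innermost 20%), and the integrated density per
#' region is normalized to the organoid total.
#'
#' @param signal Numeric matrix or [section_image()] with a `signal`
#'   channel.
#' @param dm A [compute_depth_map()] result.
#' @param meta Optional [experiment_meta()].
#' @param background_offset Constant subtracted (clipped at zero) before
#'   summation; default 0, no background subtraction.
#' @return An object of class `region_summary` with `percents` (named R1
#'   to R5, summing to 100) and `own_radius_px`.
#' @export
summarize_regions <- function(signal, dm, meta = NULL, background_offset = 0) {
  if (inherits(signal, "section_image")) {
    if (is.null(meta)) meta <- signal$meta
    signal <- get_channel(signal, "signal")
  }
  stopifnot(inherits(dm, "depth_map"), is.matrix(signal))
  if (!identical(dim(signal), dim(dm$depth)))
    stop("signal dimensions do not match the depth map", call. = FALSE)
  if (is.null(meta)) meta <- experiment_meta("unknown")
  sel <- dm$depth > 0
  frac <- dm$depth[sel] / dm$radius_px
  reg <- factor(region_index_of(frac), levels = 1:5)
  vals <- pmax(signal[sel] - background_offset, 0)
  total <- sum(vals)
  if (total <= 0)
    stop("no signal: total integrated density within the mask is zero; ",
         "organoid excluded from per-organoid normalization", call. = FALSE)
  intden <- vapply(split(vals, reg), sum, numeric(1))
  percents <- 100 * intden / total
  names(percents) <- REGION_NAMES
  structure(list(percents = percents, own_radius_px = dm$radius_px, meta = meta),
            class = "region_summary")
}

#' @export
print.region_summary <- function(x, digits = 2, ...) {
  cat(sprintf("<region_summary> organoid '%s' (radius %.1f px)\n",
              x$meta$organoid_id, x$own_radius_px))
  print(round(x$percents, digits))
  invisible(x)
}

#' Flatten a region summary to the tabular result schema
#'
#' @param x A `region_summary`.
#' @param row.names,optional,... Unused.
#' @return A data frame with columns `organoid_id, region, percent`.
#' @export
as.data.frame.region_summary <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(organoid_id = x$meta$organoid_id, region = REGION_NAMES,
             percent = unname(x$percents), stringsAsFactors = FALSE)
}

#' Re-reference a comparison group to its largest organoid
#'
#' Organoids of different sizes are compared on a shared axis: every
#' shell's `relative_position` becomes its mid-depth divided by the
#' largest radius in the group.  Region membership is deliberately NOT
#' altered; regions remain fractions of each organoid's own radius.
#'
#' @param profiles A list of `radial_profile` objects.
#' @return The same list with `reference_radius_px` and
#'   `relative_position` updated.
#' @export
rescale_to_largest <- function(profiles) {
  if (inherits(profiles, "radial_profile")) profiles <- list(profiles)
  if (!is.list(profiles) || length(profiles) == 0L ||
      !all(vapply(profiles, inherits, logical(1), "radial_profile")))
    stop("'profiles' must be a non-empty list of radial_profile objects",
         call. = FALSE)
  ref <- max(vapply(profiles, function(p) p$own_radius_px, numeric(1)))
  lapply(profiles, function(p) {
    p$reference_radius_px <- ref
    p$relative_position <- p$mid_depth_px / ref
    p
  })
}

#' One-call radial quantification of a section
#'
#' Convenience wrapper: segment the organoid from the cell-marker channel,
#' build the depth map and shells, and return both the shell profile and
#' the R1-R5 region summary.
#'
#' @param img A [section_image()] with `cell_marker` and `signal`
#'   channels, or `signal`/`mask` supplied directly.
#' @param width_px Shell width (default 25).
#' @param mask Optional precomputed `organoid_mask` (skips segmentation).
#' @param ... Passed to [segment_organoid()].
#' @return A list with `mask`, `depth`, `shells`, `profile`, `regions`.
#' @export
quantify_section <- function(img, width_px = 25, mask = NULL, ...) {
  stopifnot(inherits(img, "section_image"))
  if (is.null(mask)) mask <- segment_organoid(img, ...)
  dm <- compute_depth_map(mask)
  shells <- build_shells(dm, width_px)
  profile <- measure_profile(img, shells, meta = img$meta)
  regions <- summarize_regions(img, dm, meta = img$meta)
  list(mask = mask, depth = dm, shells = shells, profile = profile,
       regions = regions)
}
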
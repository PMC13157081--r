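#' Experiment metadata for one organoid section
#'
#' Records which organoid a section came from and how it was treated.
#' Untreated controls carry `protein = "none"` and `route = "none"`; a
#' treated organoid must state both the protein and the exposure route.
#'
#' @param organoid_id Character scalar identifying the organoid.
#' @param protein One of `"aSYN"`, `"abeta"`, `"tau"`, `"none"`.
#' @param route Exposure route: `"direct"` (fibrils added free to the
#'   medium), `"astrocyte"` (delivered inside pre-exposed astrocytes) or
#'   `"none"`.
#' @param timepoint_weeks Non-negative integer, weeks post exposure.
#' @return An object of class `experiment_meta`.
#' @examples
#' experiment_meta("org1", "abeta", "direct", 1)
#' @export
experiment_meta <- function(organoid_id,
                            protein = c("none", "aSYN", "abeta", "tau"),
                            route = c("none", "direct", "astrocyte"),
                            timepoint_weeks = 0) {
  protein <- match.arg(protein)
  route <- match.arg(route)
  if (!is.character(organoid_id) || length(organoid_id) != 1L || is.na(organoid_id))
    stop("'organoid_id' must be a single character string", call. = FALSE)
  if ((protein == "none") != (route == "none"))
    stop("'protein' is \"none\" if and only if 'route' is \"none\" (untreated control)",
         call. = FALSE)
  tw <- timepoint_weeks
  if (!is.numeric(tw) || length(tw) != 1L || is.na(tw) || tw < 0 || tw != round(tw))
    stop("'timepoint_weeks' must be a single non-negative integer", call. = FALSE)
  structure(
    list(organoid_id = organoid_id, protein = protein, route = route,
         timepoint_weeks = as.integer(tw)),
    class = "experiment_meta"
  )
}

#' @export
print.experiment_meta <- function(x, ...) {
  cat(sprintf("<experiment_meta> organoid '%s', protein %s, route %s, week %d\n",
              x$organoid_id, x$protein, x$route, x$timepoint_weeks))
  invisible(x)
}

CHANNEL_NAMES <- c("cell_marker", "signal", "nuclei", "tunel")

#' Multi-channel organoid section image
#'
#' Bundles the 2D intensity rasters of one organoid cryosection (any subset
#' of the channels `cell_marker`, `signal`, `nuclei`, `tunel`) with its
#' experiment metadata.  All channels must share dimensions and contain
#' finite, non-negative intensities.
#'
#' @param channels Named list of numeric matrices.  Names must be drawn
#'   from `cell_marker` (tissue marker, e.g. vimentin), `signal` (the Cy3
#'   aggregate channel), `nuclei` (DAPI) and `tunel`.
#' @param meta An [experiment_meta()] object.
#' @param pixel_size_um Optional positive pixel size in micrometers
#'   (default 1; all geometry is computed in pixel units).
#' @return An object of class `section_image`.
#' @export
section_image <- function(channels, meta = experiment_meta("unknown"),
                          pixel_size_um = 1) {
  if (!is.list(channels) || length(channels) < 1L || is.null(names(channels)))
    stop("'channels' must be a non-empty named list of matrices", call. = FALSE)
  bad <- setdiff(names(channels), CHANNEL_NAMES)
  if (length(bad))
    stop("unknown channel name(s): ", paste(bad, collapse = ", "),
         " (expected subset of ", paste(CHANNEL_NAMES, collapse = ", "), ")",
         call. = FALSE)
  dims <- NULL
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.matrix(ch) || !is.numeric(ch))
      stop("channel '", nm, "' must be a numeric matrix", call. = FALSE)
    if (anyNA(ch) || any(!is.finite(ch)) || any(ch < 0))
      stop("channel '", nm, "' must contain finite non-negative intensities",
           call. = FALSE)
    if (is.null(dims)) dims <- dim(ch)
    else if (!identical(dims, dim(ch)))
      stop("channel '", nm, "' has dimensions ", paste(dim(ch), collapse = "x"),
           " but expected ", paste(dims, collapse = "x"), call. = FALSE)
  }
  if (!inherits(meta, "experiment_meta"))
    stop("'meta' must be an experiment_meta object", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    stop("'pixel_size_um' must be a positive number", call. = FALSE)
  structure(
    list(channels = channels, meta = meta, pixel_size_um = pixel_size_um),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<section_image> %dx%d px, channels: %s\n", d[1], d[2],
              paste(names(x$channels), collapse = ", ")))
  print(x$meta)
  invisible(x)
}

#' @export
dim.section_image <- function(x) dim(x$channels[[1]])

# Internal: fetch a channel or fail with a clear message.
get_channel <- function(img, name) {
  stopifnot(inherits(img, "section_image"))
  ch <- img$channels[[name]]
  if (is.null(ch))
    stop("section has no '", name, "' channel", call. = FALSE)
  ch
}
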
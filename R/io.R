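#' Read one organoid section from per-channel TIFF files
#'
#' Reads one single-plane grayscale TIFF per channel and assembles a
#' [section_image()].  Integer TIFFs (8 or 16 bit) are read losslessly as
#' raw counts; 32-bit float TIFFs are read at their stored values.
#'
#' @param paths Named character vector of file paths; names are channel
#'   names (`cell_marker`, `signal`, `nuclei`, `tunel`).
#' @param meta An [experiment_meta()] object.
#' @param pixel_size_um Optional pixel size in micrometers.
#' @return A [section_image()].
#' @seealso [write_section()]
#' @export
read_section <- function(paths, meta = experiment_meta("unknown"),
                         pixel_size_um = 1) {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("'paths' must be a named character vector (channel name -> file)",
         call. = FALSE)
  channels <- lapply(names(paths), function(nm) read_channel_tiff(paths[[nm]], nm))
  names(channels) <- names(paths)
  section_image(channels, meta = meta, pixel_size_um = pixel_size_um)
}

read_channel_tiff <- function(path, name) {
  if (!file.exists(path))
    stop("channel '", name, "': file not found: ", path, call. = FALSE)
  planes <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE),
    error = function(e) stop("channel '", name, "': cannot read TIFF (",
                             conditionMessage(e), ")", call. = FALSE)
  )
  if (length(planes) != 1L)
    stop("channel '", name, "': multi-plane TIFF with ", length(planes),
         " planes; single-plane images are required", call. = FALSE)
  img <- planes[[1]]
  if (length(dim(img)) != 2L)
    stop("channel '", name, "': not a single-sample grayscale image", call. = FALSE)
  fmt <- attr(img, "sample.format")
  if (!is.null(fmt) && identical(fmt, "float")) {
    x <- unclass(img)
    attributes(x) <- list(dim = dim(img))
    return(x)
  }
  # integer image: re-read unscaled so counts survive bit-exactly
  x <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(x) <- "double"
  x
}

#' Write the channels of a section to TIFF files
#'
#' Integer-valued rasters are written as 8- or 16-bit grayscale TIFF
#' (whichever is the smallest width that holds the data) and round-trip
#' bit-exactly through [read_section()].
#'
#' @param img A [section_image()].
#' @param paths Named character vector mapping channel names to output
#'   paths; must name a subset of the channels present.
#' @return Invisibly, the paths written.
#' @export
write_section <- function(img, paths) {
  stopifnot(inherits(img, "section_image"))
  if (is.null(names(paths)))
    stop("'paths' must be named by channel", call. = FALSE)
  for (nm in names(paths)) {
    ch <- get_channel(img, nm)
    write_channel_tiff(ch, paths[[nm]], nm)
  }
  invisible(paths)
}

write_channel_tiff <- function(x, path, name = "raster") {
  if (any(x != round(x)))
    stop("channel '", name, "': only integer-valued rasters can be written ",
         "(float TIFF output is not supported)", call. = FALSE)
  mx <- max(x)
  if (mx > 65535)
    stop("channel '", name, "': intensities exceed 16-bit range", call. = FALSE)
  bits <- if (mx > 255) 16L else 8L
  scale <- 2^bits - 1
  ok <- tryCatch(tiff::writeTIFF(x / scale, path, bits.per.sample = bits),
                 error = function(e) stop("cannot write TIFF '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Write a label raster (shells, regions or nuclei) as 16-bit TIFF
#'
#' @param labels Integer matrix of labels (0 = background).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(is.matrix(labels))
  write_channel_tiff(round(labels), path, "labels")
}

PROFILE_COLUMNS <- c("organoid_id", "shell_index", "depth_lo_px", "depth_hi_px",
                     "relative_position", "pixel_count", "intden", "percent")
REGION_COLUMNS <- c("organoid_id", "region", "percent")

#' Write result records to a CSV table
#'
#' Writes profile rows (`organoid_id, shell_index, depth_lo_px,
#' depth_hi_px, relative_position, pixel_count, intden, percent`) or region
#' rows (`organoid_id, region, percent`) as a UTF-8 CSV with a header and
#' `.` as decimal separator.  An empty record set yields a header-only
#' table; pass `schema` to pick which header.
#'
#' @param records A data frame of results, e.g. from
#'   [as.data.frame.radial_profile()] or [as.data.frame.region_summary()],
#'   or a list of such data frames (row-bound).
#' @param path Output CSV path.
#' @param schema `"profile"` or `"region"`; only consulted when `records`
#'   is empty, otherwise inferred from the columns present.
#' @return Invisibly, `path`.
#' @export
write_results <- function(records, path, schema = c("profile", "region")) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  if (is.null(records) || nrow(records) == 0L) {
    schema <- match.arg(schema)
    cols <- if (schema == "profile") PROFILE_COLUMNS else REGION_COLUMNS
    records <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  } else {
    cols <- if (all(PROFILE_COLUMNS %in% names(records))) PROFILE_COLUMNS
            else if (all(REGION_COLUMNS %in% names(records))) REGION_COLUMNS
            else stop("records do not match the profile or region schema",
                      call. = FALSE)
    records <- records[, cols, drop = FALSE]
  }
  fail <- function(c) stop("cannot write results to '", path, "': ",
                           conditionMessage(c), call. = FALSE)
  tryCatch(
    utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8"),
    error = fail, warning = fail
  )
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_results <- function(path) {
  utils::read.csv(path, fileEncoding = "UTF-8")
}
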
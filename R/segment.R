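# Tissue and nuclei segmentation.
#
# The organoid mask is derived from the cell-marker channel (vimentin in
# the original assay) by smoothing, Otsu thresholding, morphological
# closing, keeping the largest 8-connected component and filling holes.
# The channel is rescaled to [0, 1] before smoothing, which makes the mask
# exactly invariant under affine intensity changes (offset and gain).

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a small union-find pass over label pairs.
label_components8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask))))
  n <- max(lab)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  parent <- seq_len(n)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find_root(pairs[k, 1]); rb <- find_root(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find_root, integer(1))
  compact <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- compact[lab[lab > 0]]
  out
}

# Gaussian smoothing that degrades gracefully on tiny images (EBImage's
# filter must not exceed the image size).
smooth_raster <- function(x, sigma) {
  if (sigma <= 0) return(x)
  radius <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  limit <- min(dim(x))
  if (radius > limit) radius <- if (limit %% 2L == 1L) limit else limit - 1L
  if (radius < 3L) return(x)
  EBImage::imageData(EBImage::gblur(x, sigma = sigma, radius = radius))
}

# Otsu threshold on an intensity raster rescaled to [0, 1].
otsu_mask <- function(x, sigma) {
  rng <- range(x)
  if (rng[2] <= rng[1]) return(NULL)
  y <- (x - rng[1]) / (rng[2] - rng[1])
  y <- smooth_raster(y, sigma)
  th <- EBImage::otsu(EBImage::Image(y), range = c(0, 1), levels = 256)
  y > th
}

#' Segment the organoid tissue mask from the cell-marker channel
#'
#' Pipeline: rescale to unit range, Gaussian smoothing
#' (`smoothing_sigma_px`), global Otsu threshold, morphological closing
#' (disk of radius `closing_radius_px`), keep the largest 8-connected
#' component, fill interior holes.  The result is the tissue mask whose
#' border defines depth zero for the radial analysis.
#'
#' @param cell_marker Numeric matrix (the tissue marker channel) or a
#'   [section_image()] with a `cell_marker` channel.
#' @param smoothing_sigma_px Gaussian sigma in pixels (default 2).
#' @param min_area_px Minimum acceptable mask area; smaller results raise
#'   a "no organoid found" error (default 10000).
#' @param closing_radius_px Disk radius for morphological closing
#'   (default 3).
#' @return An object of class `organoid_mask` with elements `mask`
#'   (logical matrix) and `area_px`.
#' @export
segment_organoid <- function(cell_marker, smoothing_sigma_px = 2,
                             min_area_px = 10000, closing_radius_px = 3) {
  if (inherits(cell_marker, "section_image"))
    cell_marker <- get_channel(cell_marker, "cell_marker")
  stopifnot(is.matrix(cell_marker))
  if (!any(cell_marker > 0))
    stop("no organoid found: cell-marker channel has no positive intensities",
         call. = FALSE)
  bw <- otsu_mask(cell_marker, smoothing_sigma_px)
  if (is.null(bw) || !any(bw))
    stop("no organoid found: no foreground after thresholding", call. = FALSE)
  if (closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_radius_px) + 1L,
                                shape = "disc")
    bw <- EBImage::imageData(EBImage::closing(matrix(as.numeric(bw), nrow(bw)),
                                              brush)) > 0
  }
  lab <- label_components8(bw)
  areas <- tabulate(lab[lab > 0])
  if (!length(areas))
    stop("no organoid found: no foreground after closing", call. = FALSE)
  keep <- which.max(areas)
  bw <- lab == keep
  bw <- EBImage::imageData(EBImage::fillHull(matrix(as.numeric(bw), nrow(bw)))) > 0
  area <- sum(bw)
  if (area < min_area_px)
    stop("no organoid found: largest component has ", area,
         " px, below min_area_px = ", min_area_px, call. = FALSE)
  structure(list(mask = bw, area_px = area), class = "organoid_mask")
}

#' @export
print.organoid_mask <- function(x, ...) {
  cat(sprintf("<organoid_mask> %dx%d px, area %d px\n",
              nrow(x$mask), ncol(x$mask), x$area_px))
  invisible(x)
}

# Internal contract check used by tests: exactly one 8-connected
# component, no interior holes, consistent area.
validate_organoid_mask <- function(om) {
  stopifnot(inherits(om, "organoid_mask"))
  m <- om$mask
  if (sum(m) != om$area_px) return("area_px does not match mask")
  lab <- label_components8(m)
  if (max(lab) != 1L) return("mask is not a single 8-connected component")
  # hole check: 4-connected background components must all touch the border
  bg <- EBImage::imageData(EBImage::bwlabel(matrix(as.numeric(!m), nrow(m))))
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  if (length(setdiff(unique(bg[bg > 0]), border_labels)) > 0)
    return("mask has interior holes")
  TRUE
}

#' Segment and count nuclei in a DAPI channel
#'
#' Smoothing and Otsu thresholding produce a foreground mask; touching
#' nuclei are split by a watershed on the Euclidean distance transform,
#' with the watershed neighbourhood sized from `min_separation_px`;
#' components smaller than `min_nucleus_area_px` are discarded.
#'
#' @param nuclei Numeric matrix (DAPI channel) or a [section_image()] with
#'   a `nuclei` channel.
#' @param sigma_px Gaussian smoothing sigma (default 1).
#' @param min_nucleus_area_px Minimum component area kept (default 20).
#' @param min_separation_px Minimum peak separation used to size the
#'   watershed neighbourhood (default 8).
#' @return An object of class `nuclei_labels` with `labels` (integer
#'   matrix, 0 = background), `count` and `centroids` (count x 2 matrix of
#'   row/col centers).  An empty image yields `count = 0`.
#' @export
segment_nuclei <- function(nuclei, sigma_px = 1, min_nucleus_area_px = 20,
                           min_separation_px = 8) {
  if (inherits(nuclei, "section_image"))
    nuclei <- get_channel(nuclei, "nuclei")
  stopifnot(is.matrix(nuclei))
  empty <- function() structure(
    list(labels = matrix(0L, nrow(nuclei), ncol(nuclei)), count = 0L,
         centroids = matrix(numeric(0), 0, 2,
                            dimnames = list(NULL, c("row", "col")))),
    class = "nuclei_labels")
  if (!any(nuclei > 0)) return(empty())
  bw <- otsu_mask(nuclei, sigma_px)
  if (is.null(bw) || !any(bw)) return(empty())
  dm <- EBImage::distmap(matrix(as.numeric(bw), nrow(bw)))
  # neighborhood radius a quarter of the separation scale: peaks closer
  # than min_separation_px merge, well-separated maxima stay distinct
  ext <- max(1L, as.integer(round(min_separation_px / 4)))
  lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1, ext = ext))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_nucleus_area_px)
  if (!length(keep)) return(empty())
  relabel <- integer(length(areas))
  relabel[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  sel <- lab > 0
  out[sel] <- relabel[lab[sel]]
  idx <- which(out > 0, arr.ind = TRUE)
  l <- out[out > 0]
  cent <- cbind(row = as.numeric(tapply(idx[, 1], l, mean)),
                col = as.numeric(tapply(idx[, 2], l, mean)))
  structure(list(labels = out, count = length(keep), centroids = cent),
            class = "nuclei_labels")
}

#' @export
print.nuclei_labels <- function(x, ...) {
  cat(sprintf("<nuclei_labels> %d nuclei in %dx%d px\n",
              x$count, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}
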
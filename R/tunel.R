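# TUNEL-positive nucleus counting against total DAPI nuclei.

# 1D Otsu threshold over a vector of values (between-class variance
# maximization on a 256-bin histogram).  Returns Inf when the values
# carry no spread.
otsu_threshold_1d <- function(v, levels = 256) {
  rng <- range(v)
  if (rng[2] <= rng[1]) return(Inf)
  breaks <- seq(rng[1], rng[2], length.out = levels + 1)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), levels)
  mids <- (breaks[-1] + breaks[-(levels + 1)]) / 2
  w <- cumsum(counts)
  mu <- cumsum(counts * mids)
  n <- w[levels]; mu_t <- mu[levels]
  w0 <- w[-levels]; mu0 <- mu[-levels]
  valid <- w0 > 0 & w0 < n
  bc <- rep(-Inf, levels - 1)
  bc[valid] <- (mu_t * w0[valid] - n * mu0[valid])^2 /
    (w0[valid] * (n - w0[valid]))
  k <- which.max(bc)
  breaks[k + 1]
}

#' Count TUNEL-positive nuclei
#'
#' A nucleus is scored positive when its mean TUNEL intensity exceeds a
#' threshold.  By default the threshold is found by Otsu's method on the
#' per-nucleus mean-intensity distribution, guarded by a minimum
#' fold-change between the two intensity classes so that a field with no
#' genuine positives is not split within its noise; pass `threshold` for
#' a fully deterministic absolute criterion (then each nucleus is scored
#' independently of all others).
#'
#' @param nuclei_labels A `nuclei_labels` object from [segment_nuclei()].
#' @param tunel Numeric matrix (TUNEL channel) or a [section_image()]
#'   with a `tunel` channel; same dimensions as the labels.
#' @param threshold Optional absolute intensity threshold overriding the
#'   Otsu rule.
#' @param min_fold_change With the Otsu rule, the positive class must
#'   have a mean at least this many times the negative class mean,
#'   otherwise no nucleus is called positive (default 2; set 0 to
#'   disable).
#' @param meta Optional [experiment_meta()].
#' @return An object of class `tunel_result` with `n_nuclei`,
#'   `n_positive`, `fraction_percent`, the threshold used, the
#'   per-nucleus means and the positivity calls.
#' @export
count_tunel <- function(nuclei_labels, tunel, threshold = NULL,
                        min_fold_change = 2, meta = NULL) {
  stopifnot(inherits(nuclei_labels, "nuclei_labels"))
  if (inherits(tunel, "section_image")) {
    if (is.null(meta)) meta <- tunel$meta
    tunel <- get_channel(tunel, "tunel")
  }
  stopifnot(is.matrix(tunel))
  if (!identical(dim(tunel), dim(nuclei_labels$labels)))
    stop("TUNEL raster dimensions do not match the nuclei labels", call. = FALSE)
  if (is.null(meta)) meta <- experiment_meta("unknown")
  n <- nuclei_labels$count
  if (n == 0L)
    stop("no nuclei: cannot compute a TUNEL-positive fraction", call. = FALSE)
  sel <- nuclei_labels$labels > 0
  means <- as.numeric(tapply(tunel[sel],
                             factor(nuclei_labels$labels[sel], levels = seq_len(n)),
                             mean))
  if (is.null(threshold)) {
    thr <- otsu_threshold_1d(means)
    if (is.finite(thr) && min_fold_change > 0) {
      lo <- means[means <= thr]; hi <- means[means > thr]
      if (!length(hi) || mean(hi) < min_fold_change * max(mean(lo), .Machine$double.eps))
        thr <- Inf
    }
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    thr <- threshold
  }
  positive <- means > thr
  structure(
    list(n_nuclei = n, n_positive = sum(positive),
         fraction_percent = 100 * sum(positive) / n,
         threshold = thr, nucleus_means = means, positive = positive,
         meta = meta),
    class = "tunel_result"
  )
}

#' @export
print.tunel_result <- function(x, ...) {
  cat(sprintf("<tunel_result> %d / %d nuclei TUNEL-positive (%.1f%%), threshold %s\n",
              x$n_positive, x$n_nuclei, x$fraction_percent,
              if (is.finite(x$threshold)) sprintf("%.3g", x$threshold) else "none"))
  invisible(x)
}
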
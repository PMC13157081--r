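# Statistical layer: normality pre-tests, region x timepoint two-way
# ANOVA with Sidak-corrected per-region comparisons, and one-way ANOVA
# with comparisons against a control group.

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, clipped to \[0, 1\].  Monotone in `p` and equal
#' to `p` at `m = 1`.
#'
#' @param p Numeric vector of raw p-values.
#' @param m Number of comparisons in the family (default `length(p)`).
#' @return Adjusted p-values.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE), m >= 1)
  pmin(1, pmax(0, 1 - (1 - p)^m))
}

#' Significance stars
#'
#' The ladder used throughout the package figures and tables:
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.005, `****` p < 0.0001.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes (`""` when not significant).
#' @export
p_stars <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x < 0.0001) "****"
    else if (x < 0.005) "***"
    else if (x < 0.01) "**"
    else if (x < 0.05) "*"
    else ""
  }, character(1))
}

# D'Agostino-Pearson omnibus K^2: combines transformed sample skewness
# (D'Agostino 1970) and kurtosis (Anscombe & Glynn 1983) into a chi-square
# statistic with 2 df.  Requires n >= 8 for the skewness transform.
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  if (m2 <= 0) stop("zero variance sample", call. = FALSE)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness transform
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  if (y == 0) y <- 1
  Zg1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis transform
  Eb2 <- 3 * (n - 1) / (n + 1)
  varb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(varb2)
  sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtbeta1 * (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
  term1 <- 1 - 2 / (9 * A)
  denom <- 1 + xk * sqrt(2 / (A - 4))
  term2 <- if (denom == 0) NA_real_
           else sign(denom) * ((1 - 2 / A) / abs(denom))^(1 / 3)
  Zg2 <- (term1 - term2) / sqrt(2 / (9 * A))
  K2 <- Zg1^2 + Zg2^2
  list(statistic = K2, p.value = stats::pchisq(K2, df = 2, lower.tail = FALSE))
}

#' Normality pre-tests
#'
#' Runs the D'Agostino-Pearson omnibus test (requires n >= 8; reported as
#' `NA` below that) and the Shapiro-Wilk test (requires n >= 3) on one
#' sample, the screening step applied to each dataset before ANOVA.
#'
#' @param values Numeric vector, n >= 3.
#' @return A list of class `normality_tests` with `dagostino_stat`,
#'   `dagostino_p`, `shapiro_stat`, `shapiro_p` and `n`.
#' @export
normality_tests <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values)) values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3)
    stop("normality tests require at least 3 observations", call. = FALSE)
  sw <- stats::shapiro.test(values)
  if (n >= 8) {
    dp <- dagostino_pearson(values)
    ds <- dp$statistic; dpv <- dp$p.value
  } else {
    ds <- NA_real_; dpv <- NA_real_
  }
  structure(
    list(dagostino_stat = ds, dagostino_p = dpv,
         shapiro_stat = unname(sw$statistic), shapiro_p = sw$p.value, n = n),
    class = "normality_tests"
  )
}

#' @export
print.normality_tests <- function(x, ...) {
  cat(sprintf("<normality_tests> n = %d\n", x$n))
  if (is.na(x$dagostino_stat))
    cat("  D'Agostino-Pearson: unavailable (n < 8)\n")
  else
    cat(sprintf("  D'Agostino-Pearson K2 = %.4f, p = %.4g\n",
                x$dagostino_stat, x$dagostino_p))
  cat(sprintf("  Shapiro-Wilk       W  = %.4f, p = %.4g\n",
              x$shapiro_stat, x$shapiro_p))
  invisible(x)
}

validate_region_dataset <- function(data, sum_tol) {
  req <- c("organoid_id", "timepoint_weeks", "region", "percent")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("region dataset is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  regs <- sort(unique(as.character(data$region)))
  if (!identical(regs, sort(REGION_NAMES)))
    stop("design error: 'region' must contain exactly the levels R1..R5",
         call. = FALSE)
  tps <- sort(unique(data$timepoint_weeks))
  if (length(tps) != 2L)
    stop("design error: exactly two timepoints are required, got ",
         length(tps), call. = FALSE)
  tab <- table(data$region, data$timepoint_weeks)
  if (length(unique(as.vector(tab))) != 1L || any(tab < 2))
    stop("design error: unbalanced design; every region x timepoint cell ",
         "must hold the same n >= 2 organoids", call. = FALSE)
  sums <- tapply(data$percent, interaction(data$organoid_id, data$timepoint_weeks,
                                           drop = TRUE), sum)
  if (any(abs(sums - 100) > sum_tol))
    stop("per-organoid region percentages must sum to 100 (tolerance ",
         sum_tol, ")", call. = FALSE)
  tps
}

#' Region-by-timepoint two-way ANOVA with Sidak-corrected comparisons
#'
#' Fits a balanced two-way ANOVA (region x timepoint, with interaction)
#' to per-organoid region percentages, then compares the two timepoints
#' within each region using the pooled residual mean square from the full
#' model, with Sidak adjustment over the five regions (the GraphPad-style
#' "multiple comparisons of mean values between time points").
#'
#' @param data Data frame with columns `organoid_id`, `timepoint_weeks`,
#'   `region` (levels R1..R5) and `percent`; every region x timepoint cell
#'   must hold the same number (>= 2) of organoids, and each organoid's
#'   five percentages must sum to 100.
#' @param sum_tol Tolerance for the per-organoid sum-to-100 check
#'   (default 1e-6).
#' @param logit Analyze `log(p / (1 - p))` of the region proportions
#'   instead of the raw percentages (default FALSE: percentages are
#'   compositional but are analyzed untransformed, as is conventional
#'   for this assay).
#' @return An object of class `region_anova` with the ANOVA table
#'   (`$anova`) and the per-region comparison table (`$comparisons`:
#'   means and SDs per timepoint, raw and Sidak-adjusted p, star codes).
#' @export
region_time_anova <- function(data, sum_tol = 1e-6, logit = FALSE) {
  data <- as.data.frame(data)
  tps <- validate_region_dataset(data, sum_tol)
  y <- data$percent
  if (logit) {
    p <- pmin(pmax(y / 100, 1e-6), 1 - 1e-6)
    y <- log(p / (1 - p))
  }
  d <- data.frame(
    region = factor(as.character(data$region), levels = REGION_NAMES),
    timepoint = factor(data$timepoint_weeks, levels = tps),
    percent = y
  )
  n_cell <- nrow(d) / 10L
  fit <- stats::aov(percent ~ region * timepoint, data = d)
  an <- suppressWarnings(stats::anova(fit))  # perfect-fit warning precedes the degenerate-data error
  ms_res <- an["Residuals", "Mean Sq"]
  df_res <- an["Residuals", "Df"]
  ms_scale <- sum(an$`Sum Sq`) / sum(an$Df)
  if (!is.finite(ms_res) || ms_res <= 1e-12 * max(ms_scale, .Machine$double.eps))
    stop("degenerate data: zero residual variance", call. = FALSE)
  anova_tab <- data.frame(
    term = c("region", "timepoint", "region:timepoint", "residuals"),
    df = an$Df, sumsq = an$`Sum Sq`, meansq = an$`Mean Sq`,
    F = an$`F value`, p = an$`Pr(>F)`,
    stringsAsFactors = FALSE
  )
  m <- length(REGION_NAMES)
  comp <- do.call(rbind, lapply(REGION_NAMES, function(rg) {
    v1 <- d$percent[d$region == rg & d$timepoint == tps[1]]
    v2 <- d$percent[d$region == rg & d$timepoint == tps[2]]
    diff <- mean(v2) - mean(v1)
    se <- sqrt(ms_res * (1 / length(v1) + 1 / length(v2)))
    tval <- diff / se
    p <- 2 * stats::pt(-abs(tval), df_res)
    data.frame(region = rg,
               mean_t1 = mean(v1), sd_t1 = stats::sd(v1),
               mean_t2 = mean(v2), sd_t2 = stats::sd(v2),
               diff = diff, t = tval, df = df_res, p = p,
               stringsAsFactors = FALSE)
  }))
  comp$p_adj <- sidak_adjust(comp$p, m)
  comp$stars <- p_stars(comp$p_adj)
  structure(
    list(anova = anova_tab, comparisons = comp, timepoints = tps,
         n_per_cell = n_cell, m = m),
    class = "region_anova"
  )
}

#' @export
print.region_anova <- function(x, digits = 4, ...) {
  cat(sprintf("<region_anova> timepoints %s vs %s weeks, n = %d per cell\n",
              x$timepoints[1], x$timepoints[2], x$n_per_cell))
  cat("ANOVA:\n")
  print(format(x$anova, digits = digits), row.names = FALSE)
  cat(sprintf("Per-region comparisons (Sidak, m = %d):\n", x$m))
  print(format(x$comparisons, digits = digits), row.names = FALSE)
  invisible(x)
}

#' One-way ANOVA with comparisons against a control group
#'
#' One-way ANOVA over all groups, followed by pooled-variance t-tests of
#' each treatment against the control with Sidak adjustment over the
#' number of treatments -- a closed-form stand-in for Dunnett's procedure
#' (slightly conservative).  Intended for scalar per-organoid readouts
#' such as TUNEL-positive fractions or blot intensities.
#'
#' @param groups Named list of numeric vectors (one per group, each
#'   n >= 2).
#' @param control_label Name of the control group in `groups`.
#' @return An object of class `control_comparison` with the overall F
#'   test and the per-treatment comparison table.
#' @export
one_way_vs_control <- function(groups, control_label) {
  if (!is.list(groups) || is.null(names(groups)) || length(groups) < 2L)
    stop("'groups' must be a named list with at least two groups", call. = FALSE)
  if (!control_label %in% names(groups))
    stop("control group '", control_label, "' not found", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group needs at least 2 observations", call. = FALSE)
  d <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1))),
                   levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = d)
  an <- suppressWarnings(stats::anova(fit))
  ms_res <- an["Residuals", "Mean Sq"]
  df_res <- an["Residuals", "Df"]
  ms_scale <- sum(an$`Sum Sq`) / sum(an$Df)
  if (!is.finite(ms_res) || ms_res <= 1e-12 * max(ms_scale, .Machine$double.eps))
    stop("degenerate data: zero residual variance", call. = FALSE)
  treat <- setdiff(names(groups), control_label)
  m <- length(treat)
  ctrl <- groups[[control_label]]
  comp <- do.call(rbind, lapply(treat, function(g) {
    v <- groups[[g]]
    diff <- mean(v) - mean(ctrl)
    se <- sqrt(ms_res * (1 / length(v) + 1 / length(ctrl)))
    tval <- diff / se
    p <- 2 * stats::pt(-abs(tval), df_res)
    data.frame(group = g, n = length(v), mean = mean(v),
               diff_vs_control = diff, t = tval, df = df_res, p = p,
               stringsAsFactors = FALSE)
  }))
  comp$p_adj <- sidak_adjust(comp$p, m)
  comp$stars <- p_stars(comp$p_adj)
  structure(
    list(F = an["group", "F value"], p = an["group", "Pr(>F)"],
         df = c(an["group", "Df"], df_res), comparisons = comp,
         control = control_label, m = m),
    class = "control_comparison"
  )
}

#' @export
print.control_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("<control_comparison> one-way ANOVA F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  cat(sprintf("Comparisons vs '%s' (Sidak, m = %d):\n", x$control, x$m))
  print(format(x$comparisons, digits = digits), row.names = FALSE)
  invisible(x)
}
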
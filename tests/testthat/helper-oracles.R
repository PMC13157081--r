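# Shared fixtures and independent oracles, built in code at test time.

# Brute-force Euclidean distance transform: for every foreground pixel,
# exhaustive search for the nearest background pixel.
brute_force_edt <- function(m) {
  bg <- which(!m, arr.ind = TRUE)
  fg <- which(m, arr.ind = TRUE)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(fg))) {
    out[fg[i, 1], fg[i, 2]] <-
      sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2))
  }
  out
}

# Random simply-shaped blob (union of disks) kept away from the border.
random_blob <- function(n = 48, seed = 1) {
  set.seed(seed)
  rows <- matrix(seq_len(n), n, n)
  cols <- t(rows)
  m <- matrix(FALSE, n, n)
  for (k in 1:4) {
    cr <- sample(12:(n - 12), 1)
    cc <- sample(12:(n - 12), 1)
    r <- sample(3:7, 1)
    m <- m | ((rows - cr)^2 + (cols - cc)^2 <= r^2)
  }
  m
}

# Disk raster: amplitude inside a centred disk, background outside.
make_disk <- function(n, radius, amp = 1000, bg = 10) {
  c0 <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- t(rows)
  out <- matrix(bg, n, n)
  out[(rows - c0)^2 + (cols - c0)^2 <= radius^2] <- amp
  out
}

disk_mask <- function(n, radius) make_disk(n, radius, amp = 1, bg = 0) > 0

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Lossless 90-degree rotation of a matrix.
rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])

# Textbook balanced two-way ANOVA decomposition (factors A = region with
# a = 5 levels, B = timepoint with b = 2 levels, n per cell), computed
# directly from sums of squares.
oracle_twoway <- function(region, timepoint, y) {
  region <- as.character(region)
  timepoint <- as.character(timepoint)
  a <- length(unique(region))
  b <- length(unique(timepoint))
  n <- length(y) / (a * b)
  g <- mean(y)
  mA <- tapply(y, region, mean)
  mB <- tapply(y, timepoint, mean)
  mAB <- tapply(y, paste(region, timepoint), mean)
  ssA <- n * b * sum((mA - g)^2)
  ssB <- n * a * sum((mB - g)^2)
  cell_of <- paste(region, timepoint)
  cells <- unique(data.frame(region = region, timepoint = timepoint))
  int_terms <- mAB[paste(cells$region, cells$timepoint)] -
    mA[cells$region] - mB[cells$timepoint] + g
  ssAB <- n * sum(int_terms^2)
  ssE <- sum((y - mAB[cell_of])^2)
  ssT <- sum((y - g)^2)
  dfA <- a - 1; dfB <- b - 1; dfAB <- dfA * dfB; dfE <- a * b * (n - 1)
  msE <- ssE / dfE
  list(
    ssA = ssA, ssB = ssB, ssAB = ssAB, ssE = ssE, ssT = ssT,
    dfE = dfE, msE = msE,
    FA = (ssA / dfA) / msE, FB = (ssB / dfB) / msE,
    FAB = (ssAB / dfAB) / msE,
    pA = pf((ssA / dfA) / msE, dfA, dfE, lower.tail = FALSE),
    pB = pf((ssB / dfB) / msE, dfB, dfE, lower.tail = FALSE),
    pAB = pf((ssAB / dfAB) / msE, dfAB, dfE, lower.tail = FALSE)
  )
}

# Balanced compositional toy dataset (per-organoid percentages sum to
# 100), n = 2 organoids per region x timepoint cell.
toy_region_dataset <- function() {
  vals <- list(
    w1_org1 = c(40, 25, 15, 12, 8),
    w1_org2 = c(38, 27, 16, 11, 8),
    w4_org1 = c(25, 25, 20, 15, 15),
    w4_org2 = c(23, 27, 21, 14, 15)
  )
  do.call(rbind, lapply(names(vals), function(nm) {
    wk <- if (grepl("^w1", nm)) 1 else 4
    data.frame(organoid_id = nm, timepoint_weeks = wk,
               region = paste0("R", 1:5), percent = vals[[nm]],
               stringsAsFactors = FALSE)
  }))
}
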
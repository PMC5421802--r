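# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (EBImage, phyper, rank-based AUC, lm).

# 4-connected component count by explicit flood fill
flood_fill_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || seen[i, j]) next
    count <- count + 1
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            mask[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          queue <- c(queue, list(q))
        }
      }
    }
  }
  count
}

# eccentricity from raw second central moments of a pixel set
moment_eccentricity <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 1]; y <- idx[, 2]
  mxx <- mean((x - mean(x))^2); myy <- mean((y - mean(y))^2)
  mxy <- mean((x - mean(x)) * (y - mean(y)))
  common <- sqrt((mxx - myy)^2 + 4 * mxy^2)
  l1 <- (mxx + myy + common) / 2
  l2 <- (mxx + myy - common) / 2
  sqrt(1 - l2 / l1)
}

# rasterize a disk / axis-aligned ellipse
raster_disk <- function(r, pad = 4) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  xs <- matrix(rep(seq_len(n), n), n, n)
  ys <- matrix(rep(seq_len(n), each = n), n, n)
  (xs - c0)^2 + (ys - c0)^2 <= r^2
}

raster_ellipse <- function(a, b, pad = 4) {
  nx <- 2 * (a + pad) + 1; ny <- 2 * (b + pad) + 1
  cx <- a + pad + 1; cy <- b + pad + 1
  xs <- matrix(rep(seq_len(nx), ny), nx, ny)
  ys <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
}

# AUC by exhaustive pair counting (ties count 1/2)
brute_force_auc <- function(cancer, healthy) {
  tot <- 0
  for (a in cancer) for (b in healthy)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cancer) * length(healthy))
}

# one-tailed Fisher p by full enumeration of tables with the same margins,
# probabilities from log binomial coefficients (no phyper/dhyper)
fisher_enum_oracle <- function(ref_t, var_t, ref_n, var_n) {
  m <- var_t + var_n; n <- ref_t + ref_n; k <- ref_t + var_t
  xs <- max(0, k - n):min(k, m)
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  p <- exp(logp - max(logp))
  sum(p[xs >= var_t]) / sum(p)
}

# closed-form least squares via the normal equations
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

random_insert <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# standard separable test fixture: round nuclei, no noise, gateable classes
separable_fixture <- function(seed, n_ctc = 3, n_wbc = 6, n_dual = 1,
                              n_neg = 1, size = c(192L, 192L)) {
  generate_fixture(fixture_config(
    size, cells = fixture_cells(n_ctc, n_wbc, n_dual, n_neg,
                                wbc_n_lobes = 1L),
    noise_sd = 0, seed = seed))
}

default_gates <- function() gate_config(ck_epcam_positive_threshold = 500,
                                        cd45_positive_threshold = 500)
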
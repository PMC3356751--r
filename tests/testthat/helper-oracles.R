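# Independent oracles and small fixture builders used across tests.

# direct rasterization of a disk, independent of make_grain_mask()
disk_mask <- function(r_px, scale = 0.01, margin = 5L) {
  n <- 2L * ceiling(r_px) + 2L * margin + 1L
  ctr <- (n + 1) / 2
  xy <- seq_len(n) - ctr
  grain_mask(outer(xy^2, xy^2, `+`) <= r_px^2, scale, "disk")
}

# rasterized ellipse rotated by angle (radians), pixel-center rule
ellipse_mask <- function(a_px, b_px, angle = 0, scale = 0.01, margin = 5L) {
  n <- 2L * ceiling(a_px) + 2L * margin + 1L
  ctr <- (n + 1) / 2
  yy <- matrix(seq_len(n) - ctr, n, n)
  xx <- matrix(rep(seq_len(n) - ctr, each = n), n, n)
  u <- xx * cos(angle) + yy * sin(angle)
  v <- -xx * sin(angle) + yy * cos(angle)
  grain_mask((u / a_px)^2 + (v / b_px)^2 <= 1, scale, "ellipse")
}

# exhaustive between-class-variance Otsu (loop over all thresholds)
brute_force_otsu <- function(v) {
  v <- as.integer(round(v))
  best_t <- 0L; best_bcv <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo); w1 <- length(hi)
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best_bcv) { best_bcv <- bcv; best_t <- t }
  }
  best_t
}

# exhaustive maximum pairwise pixel-center distance
brute_force_max_dist <- function(mask) {
  idx <- which(mask$pixels != 0L)
  nr <- nrow(mask$pixels)
  y <- ((idx - 1L) %% nr) + 1L
  x <- ((idx - 1L) %/% nr) + 1L
  max(stats::dist(cbind(x, y))) * mask$scale_mm_per_px
}

# random connected-ish blob on a small canvas: union of random disks
random_blob <- function(seed, canvas = 60L) {
  withr::with_seed(seed, {
    n <- canvas
    m <- matrix(0L, n, n)
    ndisk <- sample(2:5, 1)
    cx0 <- runif(1, n / 3, 2 * n / 3); cy0 <- runif(1, n / 3, 2 * n / 3)
    for (d in seq_len(ndisk)) {
      r <- runif(1, 3, 9)
      cx <- cx0 + runif(1, -10, 10); cy <- cy0 + runif(1, -10, 10)
      yy <- matrix(seq_len(n) - cy, n, n)
      xx <- matrix(rep(seq_len(n) - cx, each = n), n, n)
      m[xx^2 + yy^2 <= r^2] <- 1L
    }
    if (sum(m) < 2L) m[c(10L, 50L)] <- 1L
    grain_mask(m, 0.01, paste0("blob", seed))
  })
}

# hand-computed Kruskal-Wallis H with tie correction
brute_force_kw_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, 0L))
  N <- length(x)
  rk <- rank(x)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(rk, g, function(r) length(r) * mean(r)^2)) - 3 * (N + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# permutation p-value for the mean-rank difference of groups i, j within
# the joint ranking of all groups (null reference for Dunn's z)
perm_rank_p <- function(groups, i, j, nperm = 2000L, seed = 1L) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, 0L))
  rk <- rank(x)
  obs <- abs(mean(rk[g == i]) - mean(rk[g == j]))
  withr::with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(nperm)) {
      gp <- sample(g)
      d <- abs(mean(rk[gp == i]) - mean(rk[gp == j]))
      if (d >= obs - 1e-12) cnt <- cnt + 1L
    }
    (cnt + 1) / (nperm + 1)
  })
}

# small filling-series params for unit tests (problem size only; the
# package defaults carry the study conditions)
small_series <- function(n = 6L, seed = 1L, cv = 0.05,
                         scale = 0.015) {
  filling_series_params(n_per_group = n, noise_cv = cv,
                        scale_mm_per_px = scale, seed = seed)
}
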
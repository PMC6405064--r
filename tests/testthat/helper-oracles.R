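# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: closed forms, brute force, rank arithmetic.

# closed-form paired t on differences
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  p <- 2 * pt(-abs(t), n - 1)
  list(t = t, df = n - 1, p = p)
}

# brute-force sums-of-squares one-way ANOVA
oracle_anova_F <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  k <- length(groups)
  N <- length(all)
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = F, p = pf(F, k - 1, N - k, lower.tail = FALSE))
}

# rank-arithmetic Kruskal-Wallis H with tie correction
oracle_kw_H <- function(groups) {
  all <- unlist(groups)
  r <- rank(all)
  N <- length(all)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(all)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# closed-form simple OLS
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  yhat <- a + b * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = b, intercept = a, r_squared = r2)
}

# Brute-force Hildebrand local thickness on a small 3-D mask, with the same
# discrete conventions as the package documents (distance to nearest
# background voxel centre, array zero-padded; diameter = 2*r voxels) but
# computed by direct pairwise search, no EDT, no propagation order.
oracle_local_thickness <- function(mask, voxel_size = 1) {
  dims <- dim(mask)
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  nf <- nrow(fg)
  # inscribed radius at every foreground voxel
  r <- numeric(nf)
  for (i in seq_len(nf)) {
    v <- fg[i, ]
    d_pad <- min(v, dims + 1 - v)
    if (nrow(bg)) {
      d_bg <- sqrt(min(colSums((t(bg) - v)^2)))
      r[i] <- min(d_bg, d_pad)
    } else r[i] <- d_pad
  }
  th <- numeric(nf)
  for (i in seq_len(nf)) {
    u <- fg[i, ]
    d <- sqrt(colSums((t(fg) - u)^2))
    th[i] <- max(r[d <= r])
  }
  out <- array(0, dim = dims)
  out[mask] <- 2 * th * voxel_size
  out
}

# analytic chord length of a sphere/disk of radius R at offset t
chord_length <- function(R, t) 2 * sqrt(pmax(R^2 - t^2, 0))

# small solid-disk scene (one slice) for scan tests
disk_scene <- function(n = 128, radius = 30, density = 2.71, voxel_size = 0.8) {
  xs <- seq_len(n) - (n + 1) / 2
  d2 <- outer(xs^2, xs^2, "+")
  vol <- array(0, dim = c(n, n, 1))
  vol[, , 1] <- ifelse(d2 <= radius^2, density, 0)
  list(density = vol, voxel_size = voxel_size,
       interior = array(d2 <= (radius - 4)^2, dim = c(n, n, 1)))
}

# logical hollow-sphere mask (no reconstruction involved)
hollow_sphere_mask <- function(n, r_outer, wall) {
  xs <- seq_len(n) - (n + 1) / 2
  d <- sqrt(outer(outer(xs^2, xs^2, "+"), xs^2, "+"))
  d > (r_outer - wall) & d <= r_outer
}

# deterministic local seed helper
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  force(code)
}
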
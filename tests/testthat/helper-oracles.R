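# Independent oracles: deliberately naive implementations used to freeze
# expected values. They never share code paths with the package internals.

# Exhaustive Otsu: try every unique value as threshold, compute the
# between-class variance directly from the pixel partition.
oracle_otsu <- function(v) {
  v <- as.numeric(v)
  n <- length(v)
  u <- sort(unique(v))
  best <- -Inf
  bt <- NA_real_
  for (thr in u[-length(u)]) {
    lo <- v[v <= thr]
    hi <- v[v > thr]
    b <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (b > best) {
      best <- b
      bt <- thr
    }
  }
  list(threshold = bt, n_lower = sum(v <= bt), bcv = best)
}

# Dense 2-D convolution with replicate boundary (double loop).
oracle_conv2_replicate <- function(img, K) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(K); kc <- ncol(K)
  cy <- (kr + 1) %/% 2; cx <- (kc + 1) %/% 2
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (a in seq_len(kr)) for (b in seq_len(kc)) {
      ii <- min(max(i + a - cy, 1), nr)
      jj <- min(max(j + b - cx, 1), nc)
      s <- s + img[ii, jj] * K[a, b]
    }
    out[i, j] <- s
  }
  out
}

# Truncated, renormalised Gaussian kernel matching the package's contract
# (radius = ceiling(3 sigma)), built independently as an explicit 2-D outer
# product for the dense oracle.
oracle_gauss_kernel2 <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  outer(k, k)
}

# Pixel-loop statistics over a mask.
oracle_mask_stats <- function(img, mask) {
  s <- 0; n <- 0; mx <- -Inf
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    if (mask[i, j] > 0) {
      s <- s + img[i, j]; n <- n + 1
      if (img[i, j] > mx) mx <- img[i, j]
    }
  }
  mu <- s / n
  ss <- 0
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    if (mask[i, j] > 0) ss <- ss + (img[i, j] - mu)^2
  }
  list(mean = mu, variance = ss / n, max = mx)
}

# Pixel-loop window mean.
oracle_window_mean <- function(img, y, x, hw) {
  s <- 0; n <- 0
  for (i in (y - hw):(y + hw)) for (j in (x - hw):(x + hw)) {
    s <- s + img[i, j]; n <- n + 1
  }
  s / n
}

# Fraction of a symmetric 2-D Gaussian (sd per axis) captured by a square
# window of half-width hw (pixel edges at +-(hw + 0.5)) whose centre is
# displaced by (dy, dx) from the Gaussian centre.
oracle_gauss_window_fraction <- function(dy, dx, hw, sd) {
  e <- hw + 0.5
  fy <- pnorm((e - dy) / sd) - pnorm((-e - dy) / sd)
  fx <- pnorm((e - dx) / sd) - pnorm((-e - dx) / sd)
  fy * fx
}

# Exact two-sided Mann-Whitney p by enumeration of all group labelings of
# the pooled sample (midranks handle ties).
oracle_mwu_enum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  obs <- u_of(seq_len(n1))
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, u_of)
  p <- 2 * min(mean(us <= obs), mean(us >= obs))
  list(U = obs, p = min(1, p))
}

# Split a sorted frame sequence into tracks wherever more than max_gap
# consecutive frames are missing (single-spot exhaustive linker).
oracle_split_by_gap <- function(frames, max_gap) {
  frames <- sort(frames)
  split(frames, cumsum(c(0, diff(frames) > max_gap + 1)))
}

# Brute-force lexicographic track sort (ascending first frame, descending
# total PCP).
oracle_sort_order <- function(first_frame, total_pcp) {
  key <- order(first_frame, -total_pcp)
  key
}
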
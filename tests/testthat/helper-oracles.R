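# Independent oracles and small utilities used across the suite.

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# dense 2-D convolution with a truncated normalized Gaussian kernel and
# symmetric-reflection padding, written as explicit loops (oracle for the
# separable implementation)
brute_gaussian <- function(plane, sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  w1 <- dnorm(seq(-r, r), sd = sigma); w1 <- w1 / sum(w1)
  k <- outer(w1, w1)
  n <- nrow(plane); m <- ncol(plane)
  refl <- function(i, n) {
    while (i < 1L || i > n) {
      if (i < 1L) i <- 1L - i
      if (i > n) i <- 2L * n + 1L - i
    }
    i
  }
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r)
      acc <- acc + k[di + r + 1L, dj + r + 1L] *
        plane[refl(i + di, n), refl(j + dj, m)]
    out[i, j] <- acc
  }
  out
}

# brute-force moment-preserving threshold: for every candidate threshold,
# solve the two representative levels that preserve the first two moments
# exactly and score the third-moment mismatch; return the argmin candidate
brute_moments_threshold <- function(vals) {
  vals <- as.numeric(vals)
  u <- sort(unique(vals))
  m1 <- mean(vals); m2 <- mean(vals^2); m3 <- mean(vals^3)
  v <- m2 - m1^2
  best <- NA_real_; best_err <- Inf
  for (t in u[-length(u)]) {
    p <- mean(vals <= t)
    z0 <- m1 - sqrt(v * (1 - p) / p)
    z1 <- m1 + sqrt(v * p / (1 - p))
    err <- abs(p * z0^3 + (1 - p) * z1^3 - m3)
    if (err < best_err) { best_err <- err; best <- t }
  }
  best
}

# brute-force binary erosion with a Euclidean disk structuring element,
# image borders counting as background
brute_erode <- function(bw, r) {
  n <- nrow(bw); m <- ncol(bw)
  offs <- expand.grid(di = -r:r, dj = -r:r)
  offs <- offs[offs$di^2 + offs$dj^2 <= r^2, ]
  out <- matrix(FALSE, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (!bw[i, j]) next
    ok <- TRUE
    for (k in seq_len(nrow(offs))) {
      ii <- i + offs$di[k]; jj <- j + offs$dj[k]
      if (ii < 1L || ii > n || jj < 1L || jj > m || !bw[ii, jj]) { ok <- FALSE; break }
    }
    out[i, j] <- ok
  }
  out
}

# pixel set of the outer boundary: foreground pixels with an edge-adjacent
# (4-neighbour) background pixel, borders counting as background — the inner
# boundary an 8-connected contour traces
boundary_set <- function(bw) {
  n <- nrow(bw); m <- ncol(bw)
  out <- matrix(FALSE, n, m)
  nb <- cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (!bw[i, j]) next
    for (k in 1:4) {
      ii <- i + nb[k, 1L]; jj <- j + nb[k, 2L]
      if (ii < 1L || ii > n || jj < 1L || jj > m || !bw[ii, jj])
        out[i, j] <- TRUE
    }
  }
  which(out, arr.ind = TRUE)
}

# deterministic spike train with the given rate per segment (regular firing)
regular_spikes <- function(rate_hz, from, to) {
  if (rate_hz <= 0) return(numeric(0))
  seq(from + 1 / (2 * rate_hz), to, by = 1 / rate_hz)
}

disk_mask <- function(size, radius, ctr = (size + 1) / 2) {
  xy <- expand.grid(r = seq_len(size), c = seq_len(size))
  matrix((xy$r - ctr)^2 + (xy$c - ctr)^2 <= radius^2, size, size)
}
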
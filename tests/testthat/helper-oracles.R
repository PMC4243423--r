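# Brute-force reference implementations, independent of the package's
# compiled/vectorized code paths.

pad_map <- function(i, n, edge) {
  if (edge == "replicate") return(min(max(i, 1L), n))
  while (i < 1L || i > n) {            # reflect: 0 -> 1, -1 -> 2
    if (i < 1L) i <- 1L - i + 0L
    if (i > n) i <- 2L * n - i + 1L
  }
  i
}

oracle_median <- function(img, mh = 3L, nw = 3L, edge = "reflect") {
  M <- nrow(img); N <- ncol(img)
  rh <- mh %/% 2L; rw <- nw %/% 2L
  out <- img
  for (m in seq_len(M)) for (n in seq_len(N)) {
    vals <- numeric(0)
    for (di in -rh:rh) for (dj in -rw:rw)
      vals <- c(vals, img[pad_map(m + di, M, edge), pad_map(n + dj, N, edge)])
    out[m, n] <- sort(vals)[(length(vals) + 1L) %/% 2L]
  }
  out
}

# exhaustive between-class-variance maximization over the same candidate
# cuts (bin upper edges), class statistics taken from the raw values
oracle_otsu <- function(x, bins = 256L) {
  r <- range(x)
  breaks <- seq(r[1], r[2], length.out = bins + 1L)
  cand <- breaks[2:bins]
  sigma <- vapply(cand, function(t) {
    in0 <- x < t
    n0 <- sum(in0); n1 <- length(x) - n0
    if (n0 == 0 || n1 == 0) return(-Inf)
    n0 * n1 * (mean(x[in0]) - mean(x[!in0]))^2
  }, numeric(1))
  best <- which(sigma >= max(sigma) - 1e-12 * max(abs(sigma), 1))
  (cand[min(best)] + cand[max(best)]) / 2
}

se_offsets <- function(se) {
  rh <- nrow(se) %/% 2L; rw <- ncol(se) %/% 2L
  which(se == TRUE, arr.ind = TRUE) - rep(c(rh + 1L, rw + 1L), each = sum(se))
}

oracle_erode <- function(mask, se) {
  off <- se_offsets(se)
  M <- nrow(mask); N <- ncol(mask)
  out <- mask
  for (m in seq_len(M)) for (n in seq_len(N)) {
    keep <- TRUE
    for (i in seq_len(nrow(off))) {
      ii <- m + off[i, 1]; jj <- n + off[i, 2]
      if (ii < 1 || ii > M || jj < 1 || jj > N || !mask[ii, jj]) keep <- FALSE
    }
    out[m, n] <- keep
  }
  out
}

oracle_dilate <- function(mask, se) {
  off <- se_offsets(se)
  M <- nrow(mask); N <- ncol(mask)
  out <- mask
  for (m in seq_len(M)) for (n in seq_len(N)) {
    hit <- FALSE
    for (i in seq_len(nrow(off))) {
      ii <- m + off[i, 1]; jj <- n + off[i, 2]
      if (ii >= 1 && ii <= M && jj >= 1 && jj <= N && mask[ii, jj]) hit <- TRUE
    }
    out[m, n] <- hit
  }
  out
}

oracle_local_mean <- function(guide, mask, se, complement = FALSE) {
  off <- se_offsets(se)
  M <- nrow(mask); N <- ncol(mask)
  out <- matrix(NA_real_, M, N)
  for (m in seq_len(M)) for (n in seq_len(N)) {
    vals <- numeric(0)
    for (i in seq_len(nrow(off))) {
      ii <- m + off[i, 1]; jj <- n + off[i, 2]
      if (ii < 1 || ii > M || jj < 1 || jj > N) next
      if (mask[ii, jj] != complement) vals <- c(vals, guide[ii, jj])
    }
    if (length(vals)) out[m, n] <- mean(vals)
  }
  out
}

oracle_distance <- function(cube, ref) {
  d <- dim(cube)
  out <- matrix(0, d[1], d[2])
  for (m in seq_len(d[1])) for (n in seq_len(d[2])) {
    s <- 0
    for (k in seq_len(d[3])) s <- s + abs(cube$values[m, n, k] - ref$values[k])
    out[m, n] <- s / d[3]
  }
  out
}

# element-by-element storage index for each ENVI interleave (1-based)
oracle_storage_index <- function(m, n, k, M, N, K, interleave) {
  switch(interleave,
         BSQ = ((k - 1) * M + (m - 1)) * N + n,
         BIL = ((m - 1) * K + (k - 1)) * N + n,
         BIP = ((m - 1) * N + (n - 1)) * K + k)
}
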
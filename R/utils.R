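# Internal numeric helpers shared across modules.

# Row-wise median of a matrix ignoring NA, even counts averaged.
# Vectorised: one global order() instead of per-row median() calls.
rowMediansNA <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  if (k == 1L) return(m[, 1L])
  cnt <- rowSums(!is.na(m))
  o <- order(row(m), m, na.last = TRUE)
  s <- matrix(m[o], nrow = n, ncol = k, byrow = TRUE)
  lo <- pmax((cnt + 1L) %/% 2L, 1L)
  hi <- pmax((cnt + 2L) %/% 2L, 1L)
  med <- (s[cbind(seq_len(n), lo)] + s[cbind(seq_len(n), hi)]) / 2
  med[cnt == 0L] <- NA_real_
  med
}

# Even-odd rule point-in-polygon test, vectorised over points.
# Ring: closed (first == last) two-column matrix. Points exactly on a
# vertical edge are resolved by the half-open crossing rule.
pointsInRing <- function(px, py, ring) {
  xs <- ring[, 1]
  ys <- ring[, 2]
  nv <- length(xs) - 1L
  inside <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    cross <- ((ys[i] > py) != (ys[j] > py))
    if (any(cross)) {
      xint <- xs[i] + (py - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
      inside <- xor(inside, cross & (px < xint))
    }
    j <- i
  }
  inside
}

# Largest-remainder apportionment of `total` integer units across `shares`.
# Ties on remainders go to the earlier index.
largestRemainder <- function(shares, total) {
  if (total == 0L) return(integer(length(shares)))
  s <- shares / sum(shares)
  raw <- s * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Box blur with reflecting edges, via cumulative sums; r = half-width.
boxBlur <- function(m, r) {
  pad <- function(v, r) c(rev(v[seq_len(r)]), v, rev(v[length(v) - seq_len(r) + 1L]))
  smooth1 <- function(v, r) {
    p <- pad(v, r)
    cs <- cumsum(p)
    w <- 2L * r + 1L
    (cs[(w):length(cs)] - c(0, cs[seq_len(length(cs) - w)])) [seq_along(v)] / w
  }
  m <- apply(m, 2L, smooth1, r = r)
  t(apply(m, 1L, smooth1, r = r))
}

# Smoothly varying random field in [rank/N], used for contiguous cloud blobs.
smoothNoiseField <- function(h, w, scale) {
  r <- max(2L, as.integer(round(scale)))
  boxBlur(matrix(stats::rnorm(h * w), h, w), r)
}

# Truncate (floor) to integer percent, the display convention for UA/PA/OA
# in printed accuracy tables. NA passes through.
truncPercent <- function(x) {
  out <- floor(x + 1e-9)
  out[is.na(x)] <- NA
  out
}

# Pixel-centre coordinates of an h x w grid, column-major order
# (x = col - 0.5 rightwards, y = row - 0.5 downwards, origin top-left).
pixelCentres <- function(h, w) {
  list(x = rep(seq_len(w) - 0.5, each = h),
       y = rep(seq_len(h) - 0.5, times = w))
}

# Connected components of equal-valued 4-neighbourhoods; returns the count.
# Iterative label minimisation over vectorised neighbour comparisons.
countPatches <- function(grid) {
  h <- nrow(grid); w <- ncol(grid)
  lab <- matrix(seq_len(h * w), h, w)
  repeat {
    new <- lab
    same <- grid[-1, , drop = FALSE] == grid[-h, , drop = FALSE]
    up <- pmin(lab[-1, , drop = FALSE], lab[-h, , drop = FALSE])
    new[-1, ][same] <- pmin(new[-1, , drop = FALSE], up)[same]
    new[-h, ][same] <- pmin(new[-h, , drop = FALSE], up)[same]
    same <- grid[, -1, drop = FALSE] == grid[, -w, drop = FALSE]
    lt <- pmin(lab[, -1, drop = FALSE], lab[, -w, drop = FALSE])
    new[, -1][same] <- pmin(new[, -1, drop = FALSE], lt)[same]
    new[, -w][same] <- pmin(new[, -w, drop = FALSE], lt)[same]
    if (identical(new, lab)) break
    lab <- new
  }
  length(unique(as.vector(lab)))
}
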
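# Independent brute-force oracles, deliberately written with explicit loops
# so they share no code with the implementations they check.

# symmetric Hausdorff distance: boundary by explicit neighbour loops, then
# max over each boundary of the min distance to the other
brute_hausdorff <- function(a, b) {
  boundary <- function(m) {
    out <- NULL
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      if (m[i, j] == 0) next
      edge <- i == 1 || j == 1 || i == nrow(m) || j == ncol(m) ||
        m[i - 1, j] == 0 || m[i + 1, j] == 0 || m[i, j - 1] == 0 || m[i, j + 1] == 0
      if (edge) out <- rbind(out, c(i, j))
    }
    out
  }
  pa <- boundary(a); pb <- boundary(b)
  directed <- function(p, q) max(apply(p, 1, function(x)
    min(sqrt((q[, 1] - x[1])^2 + (q[, 2] - x[2])^2))))
  max(directed(pa, pb), directed(pb, pa))
}

# rasterization ray-march oracle along a ray from 0-based point `from` in
# direction `dir`: region membership at the 0.5 level of the bilinearly
# interpolated binary mask (the package's boundary convention), evaluated by
# an independent scalar loop at a much finer step; returns the distances to
# the first lumen exit and the last vessel exit (midpoint convention)
brute_ray <- function(lumen_mask, vessel_mask, from, dir, step = 0.05) {
  dir <- dir / sqrt(sum(dir^2))
  interp <- function(m, r, c) {
    r <- min(max(r, 0), nrow(m) - 1); c <- min(max(c, 0), ncol(m) - 1)
    i <- min(floor(r), nrow(m) - 2); j <- min(floor(c), ncol(m) - 2)
    fr <- r - i; fc <- c - j
    m[i + 1, j + 1] * (1 - fr) * (1 - fc) + m[i + 1, j + 2] * (1 - fr) * fc +
      m[i + 2, j + 1] * fr * (1 - fc) + m[i + 2, j + 2] * fr * fc
  }
  ts <- seq(0, 2 * nrow(lumen_mask), by = step)
  k <- length(ts)
  lum <- ves <- logical(k)
  for (s in seq_len(k)) {
    r <- from[1] + ts[s] * dir[1]; c <- from[2] + ts[s] * dir[2]
    if (r < 0 || c < 0 || r > nrow(lumen_mask) - 1 || c > ncol(lumen_mask) - 1) {
      k <- s - 1; break
    }
    lum[s] <- interp(lumen_mask, r, c) >= 0.5
    ves[s] <- interp(vessel_mask, r, c) >= 0.5
  }
  ts <- ts[seq_len(k)]; lum <- lum[seq_len(k)]; ves <- ves[seq_len(k)]
  first_lumen_exit <- which(lum[-k] & !lum[-1])[1]
  vessel_exits <- which(ves[-k] & !ves[-1])
  list(r_in = if (is.na(first_lumen_exit)) NA
              else (ts[first_lumen_exit] + ts[first_lumen_exit + 1]) / 2,
       r_out = if (!length(vessel_exits)) NA
               else (ts[max(vessel_exits)] + ts[max(vessel_exits) + 1]) / 2)
}
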
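# Independent oracles and small fixture builders used across the suite.

PX <- 662.65 / 2048 # um per pixel, field-of-view calibration

# Brute-force box count: enumerate every L x L cell of a fixed mesh anchored
# at the mask origin and count the occupied ones. Intentionally independent
# of arborfract::box_count.
brute_force_box_count <- function(mask, L) {
  nr <- nrow(mask); nc <- ncol(mask)
  n <- 0L
  for (r0 in seq(1, nr, by = L)) {
    for (c0 in seq(1, nc, by = L)) {
      cell <- mask[r0:min(r0 + L - 1, nr), c0:min(c0 + L - 1, nc)]
      if (any(cell > 0)) n <- n + 1L
    }
  }
  n
}

# Exhaustive extreme-point hull oracle: a point is extreme iff it lies
# strictly inside no triangle formed by three other points; extreme points
# are angularly sorted about their centroid and the area taken by shoelace.
oracle_hull_area <- function(pts) {
  n <- nrow(pts)
  in_triangle <- function(p, a, b, c) {
    s1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    s2 <- (c[1] - b[1]) * (p[2] - b[2]) - (c[2] - b[2]) * (p[1] - b[1])
    s3 <- (a[1] - c[1]) * (p[2] - c[2]) - (a[2] - c[2]) * (p[1] - c[1])
    (s1 >= 0 && s2 >= 0 && s3 >= 0) || (s1 <= 0 && s2 <= 0 && s3 <= 0)
  }
  extreme <- rep(TRUE, n)
  combs <- utils::combn(n, 3)
  for (i in seq_len(n)) {
    for (k in seq_len(ncol(combs))) {
      tri <- combs[, k]
      if (i %in% tri) next
      if (in_triangle(pts[i, ], pts[tri[1], ], pts[tri[2], ], pts[tri[3], ])) {
        extreme[i] <- FALSE
        break
      }
    }
  }
  v <- pts[extreme, , drop = FALSE]
  ctr <- colMeans(v)
  v <- v[order(atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])), , drop = FALSE]
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# straight horizontal 1-px line mask
line_mask <- function(len_px, pad = 4) {
  m <- matrix(0L, 2 * pad + 1, len_px + 2 * pad)
  m[pad + 1, (pad + 1):(pad + len_px)] <- 1L
  m
}

# (row, col) indices of a filled disk, for painting fixtures
disk_px_fixture <- function(center_rc, radius_px, dim_px) {
  g <- expand.grid(r = seq_len(dim_px[1]), c = seq_len(dim_px[2]))
  keep <- (g$r - center_rc[1])^2 + (g$c - center_rc[2])^2 <= radius_px^2
  as.matrix(g[keep, ])
}

# filled disk mask
disk_mask <- function(radius_px, pad = 4) {
  n <- 2 * (radius_px + pad) + 1
  ctr <- radius_px + pad + 1
  g <- expand.grid(r = 1:n, c = 1:n)
  m <- matrix(0L, n, n)
  m[as.matrix(g[(g$r - ctr)^2 + (g$c - ctr)^2 <= radius_px^2, ])] <- 1L
  m
}

# single-segment arbor geometry in um
segment_geometry <- function(x0, y0, x1, y1) {
  structure(list(segments = matrix(c(x0, y0, x1, y1), 1, 4),
                 parent = 0L, level = 0L, soma_center = c(x0, y0),
                 nominal_dimension = NA, branch_ratio = NA),
            class = "arbor_geometry")
}
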
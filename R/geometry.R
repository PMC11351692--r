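#' Branch length ratio for a target similarity dimension
#'
#' A binary tree in which every child branch is `r` times the length of its
#' parent has similarity dimension `D` when `2 * r^D = 1`, i.e.
#' `r = 2^(-1/D)`. This is the analytic oracle used to build trees of known
#' dimension.
#'
#' @param target_D similarity dimension in `[1, 2]`.
#' @return branch length ratio `r` in `(0, 1/sqrt(2)]`.
#' @examples
#' branch_ratio(2)    # 1/sqrt(2)
#' branch_ratio(1.2)  # ~0.56123
#' @export
branch_ratio <- function(target_D) {
  check_dimension(target_D)
  2^(-1 / target_D)
}

check_dimension <- function(target_D) {
  if (!is.numeric(target_D) || length(target_D) != 1L || is.na(target_D) ||
      target_D < 1 || target_D > 2) {
    stop("`target_D` must be a single number in [1, 2] (1 is a degenerate ",
         "boundary, intended for testing only)", call. = FALSE)
  }
  invisible(target_D)
}

#' Generate a self-similar binary tree of known similarity dimension
#'
#' Builds a planar binary tree rooted at `soma_center`: a trunk of length
#' `trunk_length` that splits repeatedly into two children, each rotated by
#' `+/- branch_angle` (plus optional seeded jitter) relative to its parent and
#' scaled by `r = 2^(-1/target_D)`. For `branch_angle = 90` and
#' `r <= 1/sqrt(2)` the layout is the classical H-tree, which is
#' self-avoiding, so the set's box dimension equals the similarity dimension.
#'
#' @param target_D target similarity dimension in `[1, 2]`.
#' @param depth number of branching generations (>= 1); the tree has
#'   `2^(depth+1) - 1` segments.
#' @param trunk_length trunk length in um.
#' @param branch_angle child rotation relative to the parent, degrees
#'   (default 90, the self-avoiding H-tree layout).
#' @param jitter_deg half-width of the uniform per-branch angular jitter in
#'   degrees (default 0; seeded).
#' @param initial_angle direction of the trunk in degrees (default 90,
#'   pointing down the image +y axis).
#' @param soma_center length-2 numeric, um.
#' @param seed optional integer seed making the jittered tree reproducible.
#' @return an object of class `arbor_geometry`: list with `segments`
#'   (n x 4 matrix, columns `x0, y0, x1, y1` in um), `parent` (integer vector,
#'   0 for the trunk), `level` (0-based generation), `soma_center`,
#'   `nominal_dimension`, `branch_ratio`.
#' @examples
#' tr <- self_similar_tree(1.2, depth = 4, trunk_length = 100)
#' sum(segment_lengths(tr))
#' @export
self_similar_tree <- function(target_D, depth, trunk_length,
                              branch_angle = 90, jitter_deg = 0,
                              initial_angle = 90, soma_center = c(0, 0),
                              seed = NULL) {
  check_dimension(target_D)
  if (depth < 1 || depth != round(depth)) stop("`depth` must be an integer >= 1")
  if (trunk_length <= 0) stop("`trunk_length` must be positive")
  if (!is.null(seed)) set.seed(seed)
  r <- branch_ratio(target_D)
  if (r > 1 / sqrt(2) + 1e-9) stop("branch ratio exceeds the self-avoidance limit")
  finest <- trunk_length * r^depth
  if (finest < AF_PIXEL_SIZE) {
    warning("finest branch (", signif(finest, 3),
            " um) is below one pixel at the default calibration")
  }

  n_seg <- 2^(depth + 1) - 1
  segments <- matrix(NA_real_, n_seg, 4,
                     dimnames = list(NULL, c("x0", "y0", "x1", "y1")))
  parent <- integer(n_seg)
  level <- integer(n_seg)
  k <- 0L
  grow <- function(p, ang, len, lev, par) {
    q <- p + len * c(cos(ang * pi / 180), sin(ang * pi / 180))
    k <<- k + 1L
    id <- k
    segments[id, ] <<- c(p, q)
    parent[id] <<- par
    level[id] <<- lev
    if (lev < depth) {
      j1 <- if (jitter_deg > 0) runif(1, -jitter_deg, jitter_deg) else 0
      j2 <- if (jitter_deg > 0) runif(1, -jitter_deg, jitter_deg) else 0
      grow(q, ang + branch_angle + j1, len * r, lev + 1L, id)
      grow(q, ang - branch_angle + j2, len * r, lev + 1L, id)
    }
  }
  grow(as.numeric(soma_center), initial_angle, trunk_length, 0L, 0L)

  structure(list(segments = segments, parent = parent, level = level,
                 soma_center = as.numeric(soma_center),
                 nominal_dimension = target_D, branch_ratio = r),
            class = "arbor_geometry")
}

#' Segment lengths of an arbor geometry (um)
#' @param geometry an `arbor_geometry`.
#' @return numeric vector of Euclidean segment lengths.
#' @export
segment_lengths <- function(geometry) {
  s <- geometry$segments
  if (is.null(s) || nrow(s) == 0L) return(numeric(0))
  sqrt((s[, 3] - s[, 1])^2 + (s[, 4] - s[, 2])^2)
}

#' @export
print.arbor_geometry <- function(x, ...) {
  cat("arbor_geometry:", nrow(x$segments), "segments, total length",
      round(sum(segment_lengths(x)), 2), "um\n")
  if (!is.null(x$nominal_dimension) && !is.na(x$nominal_dimension)) {
    cat("  nominal similarity dimension:", x$nominal_dimension,
        "(branch ratio", round(x$branch_ratio, 5), ")\n")
  }
  cat("  soma at (", paste(round(x$soma_center, 2), collapse = ", "), ") um\n")
  invisible(x)
}

#' Binary masks of known fractal dimension for estimator calibration
#'
#' `line` (D = 1), `filled_square` (D = 2) and `koch_curve` (the triadic Koch
#' curve, D = log(4)/log(3) ~ 1.26186). Koch iterations default to
#' `floor(log(extent)/log(3))` so the smallest generator segment spans at
#' least one pixel.
#'
#' @param kind one of `"line"`, `"filled_square"`, `"koch_curve"`.
#' @param extent mask side length in px (>= 64).
#' @param iterations Koch iterations; `NULL` chooses the finest admissible.
#' @return integer 0/1 matrix `extent x extent` with attribute
#'   `"true_dimension"`.
#' @export
calibration_shape <- function(kind = c("line", "filled_square", "koch_curve"),
                              extent = 512, iterations = NULL) {
  kind <- match.arg(kind)
  if (extent < 64) stop("`extent` must be at least 64 px")
  mask <- matrix(0L, extent, extent)
  true_D <- switch(kind,
    line = {
      mask[round(extent / 2), ] <- 1L
      1
    },
    filled_square = {
      mask[] <- 1L
      2
    },
    koch_curve = {
      if (is.null(iterations)) iterations <- floor(log(extent) / log(3))
      if (extent / 3^iterations < 1) {
        stop("`iterations` too large: smallest Koch feature would be < 1 px")
      }
      pts <- koch_points(iterations) * (extent - 1) + 1
      segs <- cbind(pts[-nrow(pts), , drop = FALSE], pts[-1, , drop = FALSE])
      ij <- draw_segments_px(segs, c(extent, extent))
      mask[ij] <- 1L
      log(4) / log(3)
    })
  attr(mask, "true_dimension") <- true_D
  mask
}

# vertices of the triadic Koch curve spanning the unit square, cols (x, y)
koch_points <- function(iterations) {
  p <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE)
  rot <- matrix(c(cos(pi / 3), sin(pi / 3), -sin(pi / 3), cos(pi / 3)), 2, 2)
  for (k in seq_len(iterations)) {
    a <- p[-nrow(p), , drop = FALSE]
    b <- p[-1, , drop = FALSE]
    d <- (b - a) / 3
    m1 <- a + d
    m3 <- a + 2 * d
    m2 <- m1 + t(rot %*% t(d))
    out <- matrix(NA_real_, 4 * nrow(a) + 1, 2)
    out[seq(1, by = 4, length.out = nrow(a)), ] <- a
    out[seq(2, by = 4, length.out = nrow(a)), ] <- m1
    out[seq(3, by = 4, length.out = nrow(a)), ] <- m2
    out[seq(4, by = 4, length.out = nrow(a)), ] <- m3
    out[nrow(out), ] <- p[nrow(p), ]
    p <- out
  }
  p[, 2] <- p[, 2] - min(p[, 2])
  p
}
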
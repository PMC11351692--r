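# --- box counting ------------------------------------------------------------

#' Log-spaced box sizes
#'
#' @param max_px largest size, px.
#' @param per_decade sizes per decade of the log-spaced ladder.
#' @return increasing integer vector of box sizes starting at 1 px.
#' @export
box_sizes <- function(max_px, per_decade = 12) {
  if (max_px < 1) stop("`max_px` must be >= 1")
  s <- unique(round(10^(seq(0, log10(max_px), by = 1 / per_decade))))
  s[s >= 1 & s <= max_px]
}

#' Box-counting table of a binary mask
#'
#' For each box size `L` the mask is covered by a mesh of `L x L` squares
#' and the number of occupied squares is recorded; the "minimal covering" is
#' approximated by taking the minimum over `n_offsets` mesh origins (the
#' origin plus half-`L` shifts in x, y, and both).
#'
#' @param mask binary matrix, an [arbor_trace], or a [calibrated_image]
#'   (nonzero pixels are foreground).
#' @param sizes box side lengths in px; default log-spaced between 1 px and
#'   half the larger mask side (12 per decade).
#' @param n_offsets number of mesh origins tried per size (1, 2, or 4).
#' @param pixel_size um/px for the `L_um` column (taken from calibrated
#'   input).
#' @return data.frame of class `box_count_table` with columns
#'   `L_px, L_um, N`; attribute `offsets_tried`.
#' @export
box_count <- function(mask, sizes = NULL, n_offsets = 4, pixel_size = NULL) {
  if (inherits(mask, "arbor_trace")) {
    if (is.null(pixel_size)) pixel_size <- mask$pixel_size
    mask <- mask$mask
  }
  if (inherits(mask, "calibrated_image")) {
    if (is.null(pixel_size)) pixel_size <- mask$pixel_size
    mask <- mask$pixels
  }
  if (is.null(pixel_size)) pixel_size <- AF_PIXEL_SIZE
  coords <- which(mask > 0, arr.ind = TRUE)
  if (nrow(coords) == 0) stop("empty mask", call. = FALSE)
  if (is.null(sizes)) sizes <- box_sizes(floor(max(dim(mask)) / 2))
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 1)) stop("box sizes must be >= 1 px")
  n_offsets <- max(1L, min(4L, as.integer(n_offsets)))
  key_mult <- 2^26
  counts <- vapply(sizes, function(L) {
    h <- L %/% 2L
    offs <- list(c(0L, 0L), c(h, 0L), c(0L, h), c(h, h))
    if (L == 1L) offs <- offs[1]
    offs <- offs[seq_len(min(n_offsets, length(offs)))]
    min(vapply(offs, function(o) {
      length(unique((coords[, 1] - 1L + o[1]) %/% L * key_mult +
                      (coords[, 2] - 1L + o[2]) %/% L))
    }, 0))
  }, 0)
  structure(data.frame(L_px = sizes, L_um = sizes * pixel_size, N = counts),
            class = c("box_count_table", "data.frame"),
            offsets_tried = n_offsets, pixel_size = pixel_size)
}

# --- scaling cut-offs --------------------------------------------------------

#' Estimate the dendrite (stroke) width of a mask
#'
#' Width is taken as `2 * median(EDT) - 1` pixels, where the Euclidean
#' distance transform (distance to the nearest background pixel) is evaluated
#' on the skeleton of the mask, then converted to um. For a bar of odd width
#' `w` px this returns exactly `w` px; quantization error is at most 1 px.
#'
#' @param mask binary matrix / [arbor_trace] / [calibrated_image].
#' @param pixel_size um/px.
#' @return width in um.
#' @export
estimate_dendrite_width <- function(mask, pixel_size = NULL) {
  if (inherits(mask, "arbor_trace")) {
    if (is.null(pixel_size)) pixel_size <- mask$pixel_size
    mask <- mask$mask
  }
  if (inherits(mask, "calibrated_image")) {
    if (is.null(pixel_size)) pixel_size <- mask$pixel_size
    mask <- mask$pixels
  }
  if (is.null(pixel_size)) pixel_size <- AF_PIXEL_SIZE
  m <- (mask > 0) * 1
  if (!any(m > 0)) stop("empty mask", call. = FALSE)
  skel <- skeletonize(m)
  edt <- as.matrix(EBImage::distmap(EBImage::Image(m)))
  w_px <- 2 * median(edt[skel > 0]) - 1
  max(w_px, 1) * pixel_size
}

#' Scaling-range cut-offs for the box-counting fit
#'
#' The fine cut-off equals the dendrite width (the smallest feature of the
#' trace); the coarse cut-off equals `coarse_frac` (default 20\%) of the
#' arbor width, where the arbor width is the larger side of the trace's
#' tight bounding box (`arbor_width = "bbox"`) or the maximum caliper
#' (Feret) diameter (`arbor_width = "feret"`).
#'
#' @param mask binary matrix / [arbor_trace] / [calibrated_image].
#' @param dendrite_width fine cut-off in um; `NULL` to estimate via
#'   [estimate_dendrite_width].
#' @param pixel_size um/px.
#' @param coarse_frac fraction of the arbor width used as coarse cut-off.
#' @param fine_factor multiplier applied to the dendrite width.
#' @param arbor_width `"bbox"` or `"feret"`.
#' @return list `(L_min, L_max)` in um, class `scaling_cutoffs`.
#' @export
scaling_cutoffs <- function(mask, dendrite_width = NULL, pixel_size = NULL,
                            coarse_frac = 0.2, fine_factor = 1,
                            arbor_width = c("bbox", "feret")) {
  arbor_width <- match.arg(arbor_width)
  if (inherits(mask, "arbor_trace")) {
    if (is.null(pixel_size)) pixel_size <- mask$pixel_size
    mask <- mask$mask
  }
  if (inherits(mask, "calibrated_image")) {
    if (is.null(pixel_size)) pixel_size <- mask$pixel_size
    mask <- mask$pixels
  }
  if (is.null(pixel_size)) pixel_size <- AF_PIXEL_SIZE
  coords <- which(mask > 0, arr.ind = TRUE)
  if (nrow(coords) == 0) stop("empty mask", call. = FALSE)
  if (is.null(dendrite_width)) {
    dendrite_width <- estimate_dendrite_width(mask, pixel_size)
  }
  width_um <- if (arbor_width == "bbox") {
    (max(diff(range(coords[, 1])), diff(range(coords[, 2]))) + 1) * pixel_size
  } else {
    hull <- coords[chull(coords[, 2], coords[, 1]), , drop = FALSE]
    max(as.matrix(stats::dist(hull))) * pixel_size
  }
  L_min <- fine_factor * dendrite_width
  L_max <- coarse_frac * width_um
  if (L_max <= L_min) {
    stop("insufficient scaling range: coarse cut-off (", signif(L_max, 4),
         " um) does not exceed the fine cut-off (", signif(L_min, 4), " um)",
         call. = FALSE)
  }
  structure(list(L_min = L_min, L_max = L_max), class = "scaling_cutoffs")
}

# --- dimension fit -----------------------------------------------------------

#' Fit the box-counting dimension within the scaling window
#'
#' Ordinary least-squares fit of `log N` against `log L` restricted to box
#' sizes with `L_min <= L_um <= L_max`; `D` is minus the slope.
#'
#' @param table a [box_count] table.
#' @param cutoffs a [scaling_cutoffs] list, or `c(L_min, L_max)` in um.
#' @return object of class `d_estimate`: list with `D`, `intercept`,
#'   `r_squared`, `L_min`, `L_max` (um), `n_points_in_fit`, and the window
#'   subset of the table.
#' @export
estimate_dimension <- function(table, cutoffs) {
  if (!is.list(cutoffs)) cutoffs <- list(L_min = cutoffs[1], L_max = cutoffs[2])
  inw <- table$L_um >= cutoffs$L_min - 1e-12 & table$L_um <= cutoffs$L_max + 1e-12
  if (sum(inw) < 3) {
    stop("insufficient scaling range: fewer than 3 box sizes inside the ",
         "cut-off window", call. = FALSE)
  }
  x <- log(table$L_um[inw])
  y <- log(table$N[inw])
  fit <- lm(y ~ x)
  ssr <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  structure(list(D = -unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r_squared = if (sst > 0) 1 - ssr / sst else 1,
                 L_min = cutoffs$L_min, L_max = cutoffs$L_max,
                 n_points_in_fit = sum(inw),
                 table = cbind(table, in_fit_window = inw)),
            class = "d_estimate")
}

#' @export
print.d_estimate <- function(x, ...) {
  cat(sprintf("box-counting dimension D = %.4f (r^2 = %.4f, %d sizes in [%.3g, %.3g] um)\n",
              x$D, x$r_squared, x$n_points_in_fit, x$L_min, x$L_max))
  invisible(x)
}

#' Box-counting fractal dimension of a trace, end to end
#'
#' Convenience wrapper: estimates the dendrite width, derives the scaling
#' cut-offs, box-counts, and fits `D`.
#'
#' @inheritParams box_count
#' @inheritParams scaling_cutoffs
#' @param per_decade box sizes per decade.
#' @return a [estimate_dimension] result.
#' @export
fractal_dimension <- function(mask, pixel_size = NULL, n_offsets = 4,
                              per_decade = 12, coarse_frac = 0.2,
                              fine_factor = 1, dendrite_width = NULL,
                              arbor_width = "bbox") {
  if (inherits(mask, "arbor_trace")) {
    if (is.null(pixel_size)) pixel_size <- mask$pixel_size
    mask <- mask$mask
  }
  if (inherits(mask, "calibrated_image")) {
    if (is.null(pixel_size)) pixel_size <- mask$pixel_size
    mask <- mask$pixels
  }
  if (is.null(pixel_size)) pixel_size <- AF_PIXEL_SIZE
  cut <- scaling_cutoffs(mask, dendrite_width = dendrite_width,
                         pixel_size = pixel_size, coarse_frac = coarse_frac,
                         fine_factor = fine_factor,
                         arbor_width = arbor_width)
  coords <- which(mask > 0, arr.ind = TRUE)
  ext <- max(diff(range(coords[, 1])), diff(range(coords[, 2]))) + 1
  tab <- box_count(mask, sizes = box_sizes(floor(ext / 2), per_decade),
                   n_offsets = n_offsets, pixel_size = pixel_size)
  estimate_dimension(tab, cut)
}

# --- convex hull coverage ----------------------------------------------------

shoelace_area <- function(v) {
  n <- nrow(v)
  if (n < 3) return(0)
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Convex-hull coverage S of a trace or point set
#'
#' The spatial coverage `S` is the shoelace area of the convex hull of the
#' trace's foreground pixel centres (in um). Fewer than three points, or a
#' collinear point set, yield `S = 0` with a warning.
#'
#' @param x an [arbor_trace], a binary mask matrix (at least 3 columns), or
#'   an n x 2 matrix of points in um (two-column input is always read as a
#'   point set).
#' @param pixel_size um/px for mask input.
#' @return object of class `coverage_result`: list with `S_um2` and
#'   `hull` (vertices, um).
#' @export
convex_hull_area <- function(x, pixel_size = NULL) {
  if (inherits(x, "arbor_trace")) {
    if (is.null(pixel_size)) pixel_size <- x$pixel_size
    x <- x$mask
  }
  if (is.matrix(x) && ncol(x) == 2) {
    pts <- x
  } else {
    if (is.null(pixel_size)) pixel_size <- AF_PIXEL_SIZE
    coords <- which(x > 0, arr.ind = TRUE)
    pts <- cbind(px_to_um(coords[, 2], pixel_size),
                 px_to_um(coords[, 1], pixel_size))
  }
  degenerate <- function() {
    warning("fewer than 3 non-collinear points: S = 0", call. = FALSE)
    structure(list(S_um2 = 0, hull = pts), class = "coverage_result")
  }
  if (nrow(pts) < 3) return(degenerate())
  h <- chull(pts[, 1], pts[, 2])
  hull <- pts[h, , drop = FALSE]
  area <- shoelace_area(hull)
  if (area == 0) return(degenerate())
  structure(list(S_um2 = area, hull = hull), class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat("convex hull coverage S =", round(x$S_um2, 2), "um^2 (",
      nrow(x$hull), "hull vertices )\n")
  invisible(x)
}

#' Scaling plot of a box-count table and fitted dimension
#'
#' @param x a `d_estimate`.
#' @param ... passed to [plot].
#' @export
plot.d_estimate <- function(x, ...) {
  tab <- x$table
  graphics::plot(tab$L_um, tab$N, log = "xy", xlab = "box size L (um)",
                 ylab = "N(L)", pch = ifelse(tab$in_fit_window, 19, 1), ...)
  lx <- range(tab$L_um[tab$in_fit_window])
  graphics::lines(lx, exp(x$intercept - x$D * log(lx)), col = 2)
  invisible(x)
}
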
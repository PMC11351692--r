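# --- raster primitives -------------------------------------------------------

# Rasterize line segments with integer-coordinate interpolation (no
# anti-aliasing). `segs_px` is an n x 4 matrix (x0, y0, x1, y1) in 1-based
# pixel coordinates (x = column, y = row); returns a 2-column (row, col)
# index matrix of covered pixels, clipped to `dim_px = c(nrow, ncol)`.
draw_segments_px <- function(segs_px, dim_px) {
  out <- vector("list", nrow(segs_px))
  for (i in seq_len(nrow(segs_px))) {
    x0 <- segs_px[i, 1]; y0 <- segs_px[i, 2]
    x1 <- segs_px[i, 3]; y1 <- segs_px[i, 4]
    n_steps <- max(abs(x1 - x0), abs(y1 - y0))
    t <- seq(0, 1, length.out = max(2, ceiling(n_steps) + 1))
    xs <- round(x0 + t * (x1 - x0))
    ys <- round(y0 + t * (y1 - y0))
    ok <- xs >= 1 & xs <= dim_px[2] & ys >= 1 & ys <= dim_px[1]
    out[[i]] <- cbind(ys[ok], xs[ok])
  }
  do.call(rbind, out)
}

# filled disk pixel indices, centre (row, col), radius in px
disk_px <- function(center_rc, radius_px, dim_px) {
  r0 <- max(1, floor(center_rc[1] - radius_px))
  r1 <- min(dim_px[1], ceiling(center_rc[1] + radius_px))
  c0 <- max(1, floor(center_rc[2] - radius_px))
  c1 <- min(dim_px[2], ceiling(center_rc[2] + radius_px))
  if (r1 < r0 || c1 < c0) return(matrix(integer(0), 0, 2))
  g <- expand.grid(row = r0:r1, col = c0:c1)
  keep <- (g$row - center_rc[1])^2 + (g$col - center_rc[2])^2 <= radius_px^2
  as.matrix(g[keep, , drop = FALSE])
}

um_to_px <- function(u, pixel_size) round(u / pixel_size + 0.5)
px_to_um <- function(p, pixel_size) (p - 0.5) * pixel_size

# --- calibrated image --------------------------------------------------------

#' Construct a calibrated image
#'
#' @param pixels 2-D non-negative numeric matrix (rows = y, cols = x).
#' @param pixel_size physical pixel size, um/px (> 0).
#' @param region optional electrode boundary polygon, n x 2 matrix in um;
#'   must lie within the raster bounds.
#' @return object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_size = AF_PIXEL_SIZE, region = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) stop("`pixels` must be a numeric matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number")
  }
  if (!is.null(region)) {
    region <- as.matrix(region)
    lim <- dim(pixels)[2:1] * pixel_size
    if (any(region[, 1] < 0 | region[, 1] > lim[1] |
            region[, 2] < 0 | region[, 2] > lim[2])) {
      stop("`region` polygon extends outside the raster bounds")
    }
  }
  structure(list(pixels = pixels, pixel_size = pixel_size, region = region),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("calibrated_image: %d x %d px (%.2f x %.2f um), %.5f um/px\n",
              d[1], d[2], d[1] * x$pixel_size, d[2] * x$pixel_size, x$pixel_size))
  invisible(x)
}

as_pixels <- function(x) {
  if (inherits(x, "calibrated_image")) x$pixels else x
}

# --- rasterization of vector geometry ---------------------------------------

#' Rasterize an arbor geometry into a calibrated image with ground truth
#'
#' Strokes are drawn by integer-coordinate line interpolation (no
#' anti-aliasing) at intensity 1; `stroke_width > 1` thickens them with a
#' disc structuring element. An optional soma disk and additive Gaussian
#' background noise (clamped at 0) emulate a fluorescence image. The returned
#' manifest records the exact vector ground truth.
#'
#' @param geometry an [arbor_geometry][self_similar_tree] (um coordinates).
#' @param pixel_size um/px.
#' @param stroke_width stroke width in px (>= 1).
#' @param soma_radius soma disk radius in um (0 = none).
#' @param noise_sd standard deviation of additive Gaussian background noise,
#'   in intensity units (foreground = 1).
#' @param seed integer seed for the noise (bit-identical images for equal
#'   seeds).
#' @param canvas_px canvas size `c(nrow, ncol)` in px. `NULL` auto-sizes to
#'   the geometry bounding box plus `margin_px`, after translating the
#'   geometry so it fits; when given, the geometry is drawn at its stated
#'   coordinates and any segment falling outside is an error.
#' @param margin_px margin used when auto-sizing, px.
#' @param min_canvas_px lower bound on the auto-sized canvas side, px.
#' @return list with elements `image` (a [calibrated_image]) and `manifest`
#'   (class `ground_truth_manifest`).
#' @export
rasterize_geometry <- function(geometry, pixel_size = AF_PIXEL_SIZE,
                               stroke_width = 1, soma_radius = 0,
                               noise_sd = 0, seed = NULL,
                               canvas_px = NULL, margin_px = 8,
                               min_canvas_px = 0) {
  if (pixel_size <= 0) stop("`pixel_size` must be positive")
  if (stroke_width < 1) stop("`stroke_width` must be >= 1 px")
  segs <- geometry$segments
  soma <- geometry$soma_center
  shift <- c(0, 0)
  if (is.null(canvas_px)) {
    if (!is.null(segs) && nrow(segs) > 0) {
      xr <- range(c(segs[, 1], segs[, 3]))
      yr <- range(c(segs[, 2], segs[, 4]))
    } else {
      xr <- yr <- c(0, 0)
    }
    pad_um <- (margin_px + stroke_width + soma_radius / pixel_size) * pixel_size
    shift <- c(pad_um - xr[1], pad_um - yr[1])
    side_um <- max(diff(xr), diff(yr)) + 2 * pad_um
    side <- max(ceiling(side_um / pixel_size), min_canvas_px, 16)
    canvas_px <- c(side, side)
  }
  img <- matrix(0, canvas_px[1], canvas_px[2])

  if (!is.null(segs) && nrow(segs) > 0) {
    sx <- cbind(segs[, 1] + shift[1], segs[, 2] + shift[2],
                segs[, 3] + shift[1], segs[, 4] + shift[2])
    px <- cbind(um_to_px(sx[, 1], pixel_size), um_to_px(sx[, 2], pixel_size),
                um_to_px(sx[, 3], pixel_size), um_to_px(sx[, 4], pixel_size))
    out <- which(px[, c(1, 3)] < 1 | px[, c(1, 3)] > canvas_px[2] |
                 px[, c(2, 4)] < 1 | px[, c(2, 4)] > canvas_px[1],
                 arr.ind = TRUE)
    if (length(out) > 0) {
      stop("segment ", sort(unique(out[, 1]))[1],
           " extends outside the raster", call. = FALSE)
    }
    ij <- draw_segments_px(px, canvas_px)
    img[ij] <- 1
    if (stroke_width > 1) {
      brush <- EBImage::makeBrush(2 * floor(stroke_width / 2) + 1, "disc")
      img <- as.matrix(EBImage::dilate(EBImage::Image(img), brush))
    }
  }
  soma_img <- if (is.null(soma)) NULL else soma + shift
  if (soma_radius > 0 && !is.null(soma)) {
    ctr <- c(um_to_px(soma_img[2], pixel_size), um_to_px(soma_img[1], pixel_size))
    img[disk_px(ctr, soma_radius / pixel_size, canvas_px)] <- 1
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    img <- img + matrix(rnorm(length(img), 0, noise_sd), nrow(img))
    img[img < 0] <- 0
  }

  manifest <- ground_truth_manifest(
    total_length = sum(segment_lengths(geometry)),
    nominal_dimension = geometry$nominal_dimension,
    orientation = "arbor",
    soma_positions = if (is.null(soma_img)) NULL else matrix(soma_img, ncol = 2),
    stroke_width = stroke_width, noise_sd = noise_sd, seed = seed,
    pixel_size = pixel_size)
  list(image = calibrated_image(img, pixel_size), manifest = manifest)
}

#' Ground-truth manifest for a synthetic image
#'
#' @param total_length total vector length of the drawn geometry, um.
#' @param nominal_dimension similarity dimension, or `NA` if not applicable.
#' @param orientation orientation descriptor, e.g. `"uniform"`,
#'   `"aligned 0"`, `"arbor"`.
#' @param soma_positions n x 2 matrix of soma centres, um.
#' @param stroke_width px.
#' @param noise_sd intensity units.
#' @param seed integer or `NULL`.
#' @param pixel_size um/px.
#' @return object of class `ground_truth_manifest`.
#' @export
ground_truth_manifest <- function(total_length, nominal_dimension = NA,
                                  orientation = "uniform",
                                  soma_positions = NULL, stroke_width = 1,
                                  noise_sd = 0, seed = NULL,
                                  pixel_size = AF_PIXEL_SIZE) {
  structure(list(total_length = total_length,
                 nominal_dimension = nominal_dimension,
                 orientation = orientation,
                 soma_positions = soma_positions,
                 stroke_width = stroke_width,
                 noise_sd = noise_sd, seed = seed,
                 pixel_size = pixel_size),
            class = "ground_truth_manifest")
}

#' @export
print.ground_truth_manifest <- function(x, ...) {
  cat("ground_truth_manifest: total length", round(x$total_length, 3),
      "um; orientation", x$orientation, "\n")
  invisible(x)
}

#' Synthetic multi-segment network field
#'
#' Draws `n_segments` straight processes of equal physical length at seeded
#' random positions, either all at a fixed angle (`angle_mode = "aligned"`)
#' or with orientations i.i.d. uniform on [0, 180) degrees
#' (`angle_mode = "uniform"`). Segment centres are placed so every segment
#' lies fully inside the field, making the manifest's `total_length` exact.
#'
#' @param n_segments number of segments (>= 1).
#' @param angle_mode `"uniform"` or `"aligned"`.
#' @param theta angle in degrees used when `angle_mode = "aligned"`.
#' @param field_px field side length in px.
#' @param segment_length_um segment length in um.
#' @param pixel_size um/px.
#' @param stroke_width px.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed integer seed.
#' @return list with `image` ([calibrated_image]) and `manifest`.
#' @export
network_field <- function(n_segments, angle_mode = c("uniform", "aligned"),
                          theta = 0, field_px = 2048,
                          segment_length_um = 100,
                          pixel_size = AF_PIXEL_SIZE, stroke_width = 1,
                          noise_sd = 0, seed = NULL) {
  angle_mode <- match.arg(angle_mode)
  if (n_segments < 1) stop("`n_segments` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  side_um <- field_px * pixel_size
  half <- segment_length_um / 2
  margin <- half + 2 * pixel_size
  if (2 * margin >= side_um) stop("segments do not fit inside the field")
  ang <- if (angle_mode == "aligned") rep(theta, n_segments) else runif(n_segments, 0, 180)
  cx <- runif(n_segments, margin, side_um - margin)
  cy <- runif(n_segments, margin, side_um - margin)
  dx <- half * cos(ang * pi / 180)
  dy <- half * sin(ang * pi / 180)
  segs <- cbind(cx - dx, cy - dy, cx + dx, cy + dy)
  geometry <- structure(list(segments = segs,
                             parent = rep(0L, n_segments),
                             level = rep(0L, n_segments),
                             soma_center = NULL,
                             nominal_dimension = NA, branch_ratio = NA),
                        class = "arbor_geometry")
  ras <- rasterize_geometry(geometry, pixel_size = pixel_size,
                            stroke_width = stroke_width, noise_sd = noise_sd,
                            seed = if (noise_sd > 0) seed else NULL,
                            canvas_px = c(field_px, field_px))
  ras$manifest$orientation <-
    if (angle_mode == "aligned") paste("aligned", theta) else "uniform"
  ras$manifest$seed <- seed
  ras
}
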
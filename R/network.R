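# --- process length ----------------------------------------------------------

#' Total process length of a skeleton graph, optionally clipped to a region
#'
#' Sums the chain lengths of all edges; when `region` is given, only chain
#' steps whose midpoint lies inside the polygon contribute.
#'
#' @param graph a [skeleton_graph][build_skeleton_graph].
#' @param region optional polygon, n x 2 matrix in um.
#' @return total length in um (0 for an empty graph).
#' @export
total_process_length <- function(graph, region = NULL) {
  if (is.null(graph) || nrow(graph$edges) == 0) return(0)
  if (is.null(region)) return(sum(graph$edges$length_um))
  region <- as.matrix(region)
  ps <- graph$pixel_size
  total <- 0
  for (pl in graph$polylines) {
    if (nrow(pl) < 2) next
    d <- abs(diff(pl))
    step <- ifelse(d[, 1] + d[, 2] == 2, sqrt(2), 1) * ps
    mx <- px_to_um((pl[-nrow(pl), 2] + pl[-1, 2]) / 2 + 0.0, ps)
    my <- px_to_um((pl[-nrow(pl), 1] + pl[-1, 1]) / 2 + 0.0, ps)
    inside <- pracma::inpolygon(mx, my, region[, 1], region[, 2],
                                boundary = TRUE)
    total <- total + sum(step[inside])
  }
  total
}

#' Normalized process length N_CNT
#'
#' Total process length on the electrode divided by the electrode surface
#' area: `N_CNT = N_LCNT / A_CNT` in um^-1.
#'
#' @param total_length total process length `N_LCNT`, um.
#' @param electrode_area electrode area `A_CNT`, um^2 (> 0).
#' @return N_CNT in um^-1.
#' @examples
#' n_cnt(100, 1000) # 0.1
#' @export
n_cnt <- function(total_length, electrode_area) {
  if (!is.numeric(electrode_area) || electrode_area <= 0) {
    stop("`electrode_area` must be positive", call. = FALSE)
  }
  total_length / electrode_area
}

#' Glial coverage fraction G_Si
#'
#' Fraction of the (smooth substrate) region covered by the glial mask:
#' `sum(glia & region) / sum(region)`.
#'
#' @param glia_mask binary matrix of glial foreground.
#' @param region_mask binary matrix marking the substrate region; same shape.
#' @return fraction in \[0, 1\].
#' @export
glial_coverage <- function(glia_mask, region_mask) {
  g <- as_pixels(glia_mask) > 0
  r <- as_pixels(region_mask) > 0
  if (!all(dim(g) == dim(r))) stop("masks must have identical dimensions")
  n_region <- sum(r)
  if (n_region == 0) stop("empty region", call. = FALSE)
  sum(g & r) / n_region
}

# --- orientation coherency ---------------------------------------------------

#' Structure-tensor orientation coherency of a calibrated image
#'
#' The image is Gaussian-smoothed (`tensor_sigma`), intensity gradients are
#' taken by central differences, and the structure tensor
#' `J = [[gx^2, gx*gy], [gx*gy, gy^2]]` is summed over the centre square crop
#' (energy weighting). Coherency is `(l1 - l2)/(l1 + l2)` for eigenvalues
#' `l1 >= l2 >= 0`: 1 for total alignment in one direction, 0 for a
#' uniformly distributed alignment. The mean orientation (degrees in
#' \[0, 180), measured from the +x axis towards +y) is that of the dominant
#' structure direction (perpendicular to the dominant gradient).
#'
#' @param image [calibrated_image] or numeric matrix.
#' @param crop_side side of the centre square analysed, um; default
#'   `1.8/2.145` of the image side (`NULL` analyses that default crop; use
#'   `Inf` for the full image).
#' @param tensor_sigma Gaussian pre-smoothing sigma, px.
#' @param pixel_size um/px for matrix input.
#' @return object of class `orientation_result`: list with `coherency`,
#'   `mean_orientation_deg` (`NA` when flagged), `energy`, `no_signal`,
#'   `crop_px` (rows/cols analysed).
#' @export
orientation_coherency <- function(image, crop_side = NULL, tensor_sigma = 2,
                                  pixel_size = NULL) {
  if (inherits(image, "calibrated_image") && is.null(pixel_size)) {
    pixel_size <- image$pixel_size
  }
  if (is.null(pixel_size)) pixel_size <- AF_PIXEL_SIZE
  px <- as_pixels(image)
  n1 <- nrow(px); n2 <- ncol(px)
  if (is.null(crop_side)) crop_side <- min(n1, n2) * pixel_size * 1.8 / 2.145
  side_px <- min(floor(crop_side / pixel_size), n1, n2)
  if (side_px < 3) stop("crop side must span at least 3 px", call. = FALSE)

  sm <- if (tensor_sigma > 0) {
    as.matrix(EBImage::gblur(EBImage::Image(px), sigma = tensor_sigma))
  } else px
  gx <- matrix(0, n1, n2); gy <- matrix(0, n1, n2)
  if (n2 >= 3) gx[, 2:(n2 - 1)] <- (sm[, 3:n2] - sm[, 1:(n2 - 2)]) / 2
  if (n1 >= 3) gy[2:(n1 - 1), ] <- (sm[3:n1, ] - sm[1:(n1 - 2), ]) / 2

  r0 <- floor((n1 - side_px) / 2)
  c0 <- floor((n2 - side_px) / 2)
  rows <- (r0 + 1):(r0 + side_px)
  cols <- (c0 + 1):(c0 + side_px)
  gxc <- gx[rows, cols]; gyc <- gy[rows, cols]
  jxx <- sum(gxc^2); jyy <- sum(gyc^2); jxy <- sum(gxc * gyc)
  energy <- jxx + jyy
  if (energy <= 0) {
    return(structure(list(coherency = 0, mean_orientation_deg = NA_real_,
                          energy = 0, no_signal = TRUE,
                          crop_px = c(side_px, side_px)),
                     class = "orientation_result"))
  }
  spread <- sqrt((jxx - jyy)^2 + 4 * jxy^2)
  coherency <- spread / energy
  # dominant gradient direction, then rotate 90 deg to the structure direction
  grad_deg <- atan2(2 * jxy, jxx - jyy) * 90 / pi
  ori <- (grad_deg + 90) %% 180
  structure(list(coherency = coherency, mean_orientation_deg = ori,
                 energy = energy, no_signal = FALSE,
                 crop_px = c(side_px, side_px)),
            class = "orientation_result")
}

#' @export
print.orientation_result <- function(x, ...) {
  if (x$no_signal) {
    cat("orientation_result: no signal (zero gradient energy), coherency 0\n")
  } else {
    cat(sprintf("orientation_result: coherency %.4f, mean orientation %.1f deg\n",
                x$coherency, x$mean_orientation_deg))
  }
  invisible(x)
}

#' Electrode-level network summary
#'
#' @param total_length total process length, um.
#' @param electrode_area electrode area, um^2.
#' @param g_si glial coverage fraction (optional).
#' @param coherency orientation coherency (optional).
#' @param mean_orientation_deg mean orientation (optional).
#' @return one-row data.frame with `N_LCNT_um, A_CNT_um2, N_CNT, G_Si,
#'   coherency, mean_orientation_deg`.
#' @export
network_summary <- function(total_length, electrode_area, g_si = NA,
                            coherency = NA, mean_orientation_deg = NA) {
  data.frame(N_LCNT_um = total_length, A_CNT_um2 = electrode_area,
             N_CNT = n_cnt(total_length, electrode_area), G_Si = g_si,
             coherency = coherency,
             mean_orientation_deg = mean_orientation_deg)
}
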
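# --- TIFF --------------------------------------------------------------------

#' Read a single-channel TIFF as a calibrated image
#'
#' @param path file path.
#' @param pixel_size um/px.
#' @return a [calibrated_image] (first channel if multi-channel).
#' @export
read_image_tiff <- function(path, pixel_size = AF_PIXEL_SIZE) {
  if (!file.exists(path)) stop("input image not found: ", path, call. = FALSE)
  img <- EBImage::readImage(path)
  px <- EBImage::imageData(img)
  if (length(dim(px)) > 2) px <- px[, , 1]
  # EBImage stores x = first index; convert to row = y, col = x
  calibrated_image(t(px), pixel_size = pixel_size)
}

#' Write a calibrated image (or mask) as a single-channel TIFF
#'
#' Intensities are clamped to \[0, 1\].
#'
#' @param image [calibrated_image] or numeric matrix.
#' @param path output path.
#' @export
write_image_tiff <- function(image, path) {
  px <- as_pixels(image)
  px[px < 0] <- 0
  mx <- max(px)
  if (mx > 1) px <- px / mx
  EBImage::writeImage(EBImage::Image(t(px)), path, type = "tiff")
  invisible(path)
}

# --- SWC ---------------------------------------------------------------------

#' Write an arbor geometry or arbor trace as SWC
#'
#' SWC columns: `id type x y z radius parent`, coordinates in um, z = 0.
#' The soma node has type 1, dendrite nodes type 3. For an
#' [arbor_trace][extract_arbor], radii are half the measured local edge
#' width; for vector geometry, half `stroke_width_um`.
#'
#' @param x an [arbor_geometry][self_similar_tree] or `arbor_trace`.
#' @param path output path.
#' @param graph the source `skeleton_graph` (required for traces).
#' @param stroke_width_um dendrite width used for geometry radii.
#' @return the path, invisibly.
#' @export
write_swc <- function(x, path, graph = NULL, stroke_width_um = AF_PIXEL_SIZE) {
  if (inherits(x, "arbor_geometry")) {
    rows <- swc_from_geometry(x, stroke_width_um)
  } else if (inherits(x, "arbor_trace")) {
    if (is.null(graph)) stop("writing a trace as SWC requires `graph`")
    rows <- swc_from_trace(x, graph)
  } else {
    stop("`x` must be an arbor_geometry or arbor_trace")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id type x y z radius parent (um)", con)
  write.table(rows, con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

swc_from_geometry <- function(geometry, stroke_width_um) {
  segs <- geometry$segments
  soma <- geometry$soma_center
  n <- nrow(segs)
  # node 1 = soma; node i+1 = endpoint of segment i (segment start is the
  # parent segment's endpoint, or the soma for the trunk)
  data.frame(id = c(1L, seq_len(n) + 1L),
             type = c(1L, rep(3L, n)),
             x = c(soma[1], segs[, 3]), y = c(soma[2], segs[, 4]),
             z = 0,
             radius = c(stroke_width_um, rep(stroke_width_um / 2, n)),
             parent = c(-1L, ifelse(geometry$parent == 0L, 1L,
                                    geometry$parent + 1L)))
}

swc_from_trace <- function(trace, graph) {
  edges <- graph$edges
  ps <- graph$pixel_size
  rows <- list(data.frame(id = 1L, type = 1L, x = trace$soma_center[1],
                          y = trace$soma_center[2], z = 0,
                          radius = max(trace$soma_radius, ps), parent = -1L))
  next_id <- 2L
  node_swc <- c()  # skeleton node id -> swc id
  node_swc[as.character(trace$attach_node)] <- 1L
  todo <- trace$edge_ids
  frontier <- trace$attach_node
  while (length(todo) > 0 && length(frontier) > 0) {
    u <- frontier[1]; frontier <- frontier[-1]
    inc <- todo[edges$from[todo] == u | edges$to[todo] == u]
    for (e in inc) {
      todo <- setdiff(todo, e)
      v <- if (edges$from[e] == u) edges$to[e] else edges$from[e]
      pl <- graph$polylines[[e]]
      und <- graph$nodes[graph$nodes$node == u, ]
      if (sum(abs(pl[1, ] - c(und$row, und$col))) >
          sum(abs(pl[nrow(pl), ] - c(und$row, und$col)))) {
        pl <- pl[rev(seq_len(nrow(pl))), , drop = FALSE]
      }
      par <- node_swc[as.character(u)]
      w <- edges$mean_width_um[e] / 2
      for (k in 2:nrow(pl)) {
        rows[[length(rows) + 1L]] <- data.frame(
          id = next_id, type = 3L, x = px_to_um(pl[k, 2], ps),
          y = px_to_um(pl[k, 1], ps), z = 0, radius = w, parent = par)
        par <- next_id
        next_id <- next_id + 1L
      }
      if (is.na(node_swc[as.character(v)])) {
        node_swc[as.character(v)] <- par
        frontier <- c(frontier, v)
      }
    }
  }
  do.call(rbind, rows)
}

# --- manifests and configs ---------------------------------------------------

#' Write a ground-truth manifest (or any list) as JSON
#' @param manifest a [ground_truth_manifest] or plain list.
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON manifest
#' @param path file path.
#' @return named list.
#' @export
read_manifest <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Read a plain-text `key = value` rule configuration file
#'
#' Lines starting with `#` are comments; numeric values are converted.
#'
#' @param path file path.
#' @return a [rule_config] with the file's entries overriding the defaults.
#' @export
read_rule_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- rule_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  cfg
}
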
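# --- connected components ----------------------------------------------------

# 8-connected component labeling: 4-connected pass (EBImage::bwlabel), then
# union of label pairs that touch diagonally
label_components8 <- function(mask) {
  m <- (as_pixels(mask) > 0) * 1
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(m)))
  n_lab <- max(lab)
  if (n_lab <= 1) return(lab)
  pairs <- NULL
  for (sh in list(c(1, 1), c(1, -1))) {
    a <- lab[-nrow(lab), , drop = FALSE]
    b <- lab[-1, , drop = FALSE]
    if (sh[2] == 1) {
      a <- a[, -ncol(a), drop = FALSE]; b <- b[, -1, drop = FALSE]
    } else {
      a <- a[, -1, drop = FALSE]; b <- b[, -ncol(b), drop = FALSE]
    }
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) pairs <- rbind(pairs, unique(cbind(a[sel], b[sel])))
  }
  parent <- seq_len(n_lab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (!is.null(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n_lab), find, 0L)
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# --- binarization ------------------------------------------------------------

#' Binarize a calibrated image
#'
#' Global Otsu or adaptive (local mean) thresholding, followed by removal of
#' connected components smaller than `min_object_px`.
#'
#' @param image a [calibrated_image] or a numeric matrix.
#' @param method `"global_otsu"` or `"adaptive"`.
#' @param min_object_px connected components (8-connectivity) smaller than
#'   this are removed.
#' @param adaptive_window window half-size in px for the adaptive method.
#' @param adaptive_offset offset above the local mean for the adaptive method
#'   (fraction of the intensity range).
#' @return integer 0/1 mask, same dimensions as the image.
#' @export
binarize <- function(image, method = c("global_otsu", "adaptive"),
                     min_object_px = 0, adaptive_window = 15,
                     adaptive_offset = 0.05) {
  method <- match.arg(method)
  px <- as_pixels(image)
  rng <- range(px)
  if (diff(rng) == 0) stop("no signal: image has zero dynamic range", call. = FALSE)
  norm <- (px - rng[1]) / diff(rng)
  if (method == "global_otsu") {
    thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    mask <- (norm > thr) * 1L
  } else {
    mask <- as.matrix(EBImage::thresh(EBImage::Image(norm),
                                      w = adaptive_window, h = adaptive_window,
                                      offset = adaptive_offset)) * 1L
  }
  storage.mode(mask) <- "integer"
  if (min_object_px > 0 && any(mask > 0)) {
    lab <- label_components8(mask)
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_object_px)
    if (length(drop) > 0) mask[lab %in% drop] <- 0L
  }
  mask
}

# --- thinning ----------------------------------------------------------------

# shift a matrix by (dr, dc), zero-filling
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 - dr):min(nr, nr - dr)
  cs <- max(1, 1 - dc):min(nc, nc - dc)
  out[rs + dr, cs + dc] <- m[rs, cs]
  out
}

#' Topology-preserving skeletonization (Guo-Hall thinning)
#'
#' Iteratively deletes simple boundary pixels in two sub-iterations until the
#' mask is one pixel wide (no 2 x 2 foreground block remains) while
#' preserving 8-connectivity of the foreground. Idempotent on already thin
#' input.
#'
#' @param mask 0/1 matrix (or logical); must contain at least one foreground
#'   pixel.
#' @return integer 0/1 skeleton matrix.
#' @export
skeletonize <- function(mask) {
  m <- (as_pixels(mask) > 0) * 1L
  if (!any(m > 0)) stop("empty mask", call. = FALSE)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours, clockwise: P2=N, P3=NE, P4=E, P5=SE, P6=S, P7=SW, P8=W, P9=NW
      p2 <- shift_mat(m, 1, 0);  p3 <- shift_mat(m, 1, -1)
      p4 <- shift_mat(m, 0, -1); p5 <- shift_mat(m, -1, -1)
      p6 <- shift_mat(m, -1, 0); p7 <- shift_mat(m, -1, 1)
      p8 <- shift_mat(m, 0, 1);  p9 <- shift_mat(m, 1, 1)
      C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
           (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
      n1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      n2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      n_min <- pmin(n1, n2)
      o <- if (sub == 1) ((p2 | p3 | !p5) & p4) else ((p6 | p7 | !p9) & p8)
      del <- m == 1L & C == 1 & n_min >= 2 & n_min <= 3 & !o
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# --- skeleton graph ----------------------------------------------------------

# 8-neighbour offsets (row, col)
NB8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
             dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

# chain length in px units with sqrt(2) diagonal steps
chain_length_px <- function(poly) {
  if (nrow(poly) < 2) return(0)
  d <- abs(diff(poly))
  sum(ifelse(d[, 1] + d[, 2] == 2, sqrt(2), 1))
}

#' Build a skeleton graph from a one-pixel-wide skeleton
#'
#' Endpoints (degree 1) and junctions (degree >= 3) of the 8-connected
#' skeleton become nodes; maximal degree-2 pixel chains between them become
#' edges. Edge length is the chain length with axial steps of `pixel_size`
#' and diagonal steps of `pixel_size * sqrt(2)`. When `image` / `mask` are
#' supplied, each edge also carries the mean underlying intensity and the
#' mean local width (from the distance transform of the pre-skeleton mask).
#'
#' @param skeleton 0/1 one-pixel-wide matrix (from [skeletonize]).
#' @param image optional intensity source: [calibrated_image] or matrix.
#' @param mask optional pre-skeletonization binary mask for width estimates.
#' @param pixel_size um/px (taken from `image` if it is a
#'   [calibrated_image]).
#' @return object of class `skeleton_graph`: list with `nodes`
#'   (data.frame: `node, row, col, x_um, y_um, degree`), `edges`
#'   (data.frame: `edge, from, to, length_um, mean_intensity, mean_width_um,
#'   n_px`), `polylines` (list of (row, col) matrices), `pixel_size`, and
#'   `graph` (an igraph with edge weights in um).
#' @export
build_skeleton_graph <- function(skeleton, image = NULL, mask = NULL,
                                 pixel_size = NULL) {
  if (inherits(image, "calibrated_image") && is.null(pixel_size)) {
    pixel_size <- image$pixel_size
  }
  if (is.null(pixel_size)) pixel_size <- AF_PIXEL_SIZE
  skel <- (as_pixels(skeleton) > 0)
  nr <- nrow(skel); nc <- ncol(skel)
  img_px <- if (is.null(image)) NULL else as_pixels(image)
  width_px <- NULL
  if (!is.null(mask)) {
    edt <- as.matrix(EBImage::distmap(EBImage::Image((as_pixels(mask) > 0) * 1)))
    width_px <- 2 * edt - 1
  }

  skel_int <- skel * 1L
  deg <- matrix(0L, nr, nc)
  for (k in seq_len(nrow(NB8))) {
    deg <- deg + shift_mat(skel_int, NB8[k, 1], NB8[k, 2])
  }
  deg[!skel] <- 0L

  px <- which(skel)                       # linear indices, column-major scan
  is_node <- skel & (deg != 2L)
  node_lin <- which(is_node)
  consumed <- matrix(FALSE, nr, nc)       # chain pixels already walked

  nbrs <- function(lin) {
    r <- ((lin - 1L) %% nr) + 1L
    c <- ((lin - 1L) %/% nr) + 1L
    rr <- r + NB8[, 1]; cc <- c + NB8[, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    cand <- (cc[ok] - 1L) * nr + rr[ok]
    cand[skel[cand]]
  }
  lin_rc <- function(lin) cbind(((lin - 1L) %% nr) + 1L, ((lin - 1L) %/% nr) + 1L)

  polylines <- list()
  edge_from <- integer(0); edge_to <- integer(0)
  step_keys <- character(0)

  walk <- function(start, nxt) {
    # walk from node pixel `start` through chain pixel(s) to the next node
    path <- c(start, nxt)
    prev <- start; cur <- nxt
    while (!is_node[cur]) {
      consumed[cur] <<- TRUE
      nb <- nbrs(cur)
      nb <- nb[nb != prev & !consumed[nb]]
      if (length(nb) == 0L) {
        # closed back onto the start (tight loop)
        return(path)
      }
      prev <- cur
      cur <- nb[1]
      path <- c(path, cur)
    }
    path
  }

  add_edge <- function(path) {
    polylines[[length(polylines) + 1L]] <<- lin_rc(path)
    edge_from <<- c(edge_from, path[1])
    edge_to <<- c(edge_to, path[length(path)])
  }

  for (p in node_lin) {
    for (q in nbrs(p)) {
      if (is_node[q]) {
        key <- paste(min(p, q), max(p, q))
        if (!(key %in% step_keys)) {
          step_keys <- c(step_keys, key)
          add_edge(c(p, q))
        }
      } else if (!consumed[q]) {
        add_edge(walk(p, q))
      }
    }
  }
  # pure cycles: remaining unconsumed degree-2 pixels not adjacent to a node
  remaining <- skel & !is_node & !consumed
  remaining[which(remaining)][vapply(which(remaining), function(l)
    any(is_node[nbrs(l)]), logical(1))] <- FALSE
  while (any(remaining)) {
    s <- which(remaining)[1]
    is_node[s] <- TRUE
    node_lin <- c(node_lin, s)
    nb <- nbrs(s)
    add_edge(walk(s, nb[1]))
    remaining <- remaining & !consumed
    remaining[s] <- FALSE
  }

  node_lin <- sort(unique(c(node_lin, edge_from, edge_to)))
  node_id <- setNames(seq_along(node_lin), node_lin)
  rc <- lin_rc(node_lin)
  nodes <- data.frame(node = seq_along(node_lin), row = rc[, 1], col = rc[, 2],
                      x_um = px_to_um(rc[, 2], pixel_size),
                      y_um = px_to_um(rc[, 1], pixel_size),
                      degree = deg[node_lin])

  n_e <- length(polylines)
  len_um <- vapply(polylines, function(pl) chain_length_px(pl) * pixel_size, 0)
  mi <- vapply(polylines, function(pl) {
    if (is.null(img_px)) NA_real_ else mean(img_px[pl])
  }, 0)
  mw <- vapply(polylines, function(pl) {
    if (is.null(width_px)) 1 * pixel_size else mean(width_px[pl]) * pixel_size
  }, 0)
  edges <- data.frame(edge = seq_len(n_e),
                      from = unname(node_id[as.character(edge_from)]),
                      to = unname(node_id[as.character(edge_to)]),
                      length_um = len_um, mean_intensity = mi,
                      mean_width_um = mw,
                      n_px = vapply(polylines, nrow, 0L))

  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$from, to = edges$to, weight = edges$length_um,
               edge = edges$edge),
    directed = FALSE,
    vertices = data.frame(name = nodes$node))
  structure(list(nodes = nodes, edges = edges, polylines = polylines,
                 pixel_size = pixel_size, dim = c(nr, nc), graph = g),
            class = "skeleton_graph")
}

#' Construct a skeleton graph from explicit nodes and edges
#'
#' Intended for small hand-built graphs in tests and examples; positions are
#' in um and each edge is a straight polyline between its endpoints.
#'
#' @param nodes data.frame with columns `node, x_um, y_um`.
#' @param edges data.frame with columns `from, to`, optional `length_um`,
#'   `mean_intensity`, `mean_width_um`.
#' @param pixel_size um/px used to synthesize pixel polylines.
#' @return a `skeleton_graph`.
#' @export
skeleton_graph <- function(nodes, edges, pixel_size = 1) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  nodes$row <- um_to_px(nodes$y_um, pixel_size)
  nodes$col <- um_to_px(nodes$x_um, pixel_size)
  n_e <- nrow(edges)
  polylines <- vector("list", n_e)
  for (i in seq_len(n_e)) {
    a <- nodes[nodes$node == edges$from[i], ]
    b <- nodes[nodes$node == edges$to[i], ]
    ij <- draw_segments_px(cbind(a$col, a$row, b$col, b$row),
                           c(max(nodes$row) + 2, max(nodes$col) + 2))
    polylines[[i]] <- ij
  }
  if (is.null(edges$length_um)) {
    edges$length_um <- vapply(seq_len(n_e), function(i) {
      a <- nodes[nodes$node == edges$from[i], ]
      b <- nodes[nodes$node == edges$to[i], ]
      sqrt((a$x_um - b$x_um)^2 + (a$y_um - b$y_um)^2)
    }, 0)
  }
  if (is.null(edges$mean_intensity)) edges$mean_intensity <- 1
  if (is.null(edges$mean_width_um)) edges$mean_width_um <- pixel_size
  edges$edge <- seq_len(n_e)
  edges$n_px <- vapply(polylines, nrow, 0L)
  deg <- table(factor(c(edges$from, edges$to), levels = nodes$node))
  nodes$degree <- as.integer(deg[as.character(nodes$node)])
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$from, to = edges$to, weight = edges$length_um,
               edge = edges$edge),
    directed = FALSE, vertices = data.frame(name = nodes$node))
  structure(list(nodes = nodes, edges = edges, polylines = polylines,
                 pixel_size = pixel_size,
                 dim = c(max(nodes$row) + 2, max(nodes$col) + 2), graph = g),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat("skeleton_graph:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges, total",
      round(sum(x$edges$length_um), 2), "um\n")
  invisible(x)
}

#' Total edge length of a skeleton graph (um)
#' @param graph a `skeleton_graph`.
#' @return total length in um.
#' @export
graph_length <- function(graph) sum(graph$edges$length_um)

# --- soma detection ----------------------------------------------------------

#' Detect somas as distance-transform maxima
#'
#' Pixels whose distance to the background is at least `min_radius` form
#' candidate blobs; each 8-connected blob is reported as one soma at its
#' distance-transform maximum (the first such pixel in column-major scan
#' order on ties, which makes the result deterministic). Two somas closer
#' than `min_radius` merge into a single blob and are reported once.
#'
#' @param image [calibrated_image] or matrix (used for calibration only).
#' @param mask binary mask of the cells.
#' @param min_radius minimum soma radius in um.
#' @param pixel_size um/px (taken from `image` when calibrated).
#' @return data.frame with columns `soma, x_um, y_um, radius_um, row, col`
#'   (zero rows when nothing qualifies).
#' @export
detect_somas <- function(image, mask, min_radius = 3,
                         pixel_size = NULL) {
  if (inherits(image, "calibrated_image") && is.null(pixel_size)) {
    pixel_size <- image$pixel_size
  }
  if (is.null(pixel_size)) pixel_size <- AF_PIXEL_SIZE
  m <- (as_pixels(mask) > 0) * 1
  if (!any(m > 0)) stop("empty mask", call. = FALSE)
  edt <- as.matrix(EBImage::distmap(EBImage::Image(m)))
  cand <- (edt >= min_radius / pixel_size) * 1L
  if (!any(cand > 0)) {
    return(data.frame(soma = integer(0), x_um = numeric(0), y_um = numeric(0),
                      radius_um = numeric(0), row = integer(0), col = integer(0)))
  }
  lab <- label_components8(cand)
  ids <- sort(unique(lab[lab > 0]))
  out <- lapply(ids, function(i) {
    lin <- which(lab == i)
    best <- lin[which.max(edt[lin])]
    data.frame(row = ((best - 1L) %% nrow(m)) + 1L,
               col = ((best - 1L) %/% nrow(m)) + 1L,
               radius_um = edt[best] * pixel_size)
  })
  out <- do.call(rbind, out)
  data.frame(soma = seq_len(nrow(out)),
             x_um = px_to_um(out$col, pixel_size),
             y_um = px_to_um(out$row, pixel_size),
             radius_um = out$radius_um, row = out$row, col = out$col)
}

# --- arbor extraction --------------------------------------------------------

#' Traversal rule configuration for arbor extraction
#'
#' @param attach_radius_um maximum distance from a soma centre (beyond its
#'   own radius) to the nearest skeleton node, um.
#' @param max_angle_deg maximum angle between an edge's outgoing direction
#'   and the radial direction from the soma (the "no doubling back past 90
#'   degrees" rule).
#' @param w_width,w_intensity weights of the width- and intensity-continuity
#'   terms of the soma-assignment similarity score.
#' @param direction_steps number of initial polyline steps over which the
#'   outgoing edge direction is averaged.
#' @return a list of class `rule_config`.
#' @export
rule_config <- function(attach_radius_um = 5, max_angle_deg = 90,
                        w_width = 0.5, w_intensity = 0.5,
                        direction_steps = 5) {
  structure(list(attach_radius_um = attach_radius_um,
                 max_angle_deg = max_angle_deg,
                 w_width = w_width, w_intensity = w_intensity,
                 direction_steps = direction_steps),
            class = "rule_config")
}

# outgoing unit direction of edge `e` leaving node `node_id` (um coords)
edge_direction_at <- function(graph, e, node_id, steps = 5) {
  pl <- graph$polylines[[e]]
  nd <- graph$nodes[graph$nodes$node == node_id, ]
  ps <- graph$pixel_size
  first_rc <- pl[1, ]; last_rc <- pl[nrow(pl), ]
  at_start <- sum(abs(first_rc - c(nd$row, nd$col))) <=
    sum(abs(last_rc - c(nd$row, nd$col)))
  if (!at_start) pl <- pl[rev(seq_len(nrow(pl))), , drop = FALSE]
  k <- min(nrow(pl), steps + 1)
  v <- c((pl[k, 2] - pl[1, 2]) * ps, (pl[k, 1] - pl[1, 1]) * ps)
  n <- sqrt(sum(v^2))
  if (n == 0) c(0, 0) else v / n
}

#' Extract the arbor of one soma from a skeleton graph
#'
#' Traverses the graph outward from the skeleton node nearest to the soma,
#' encoding the tracing rules: (1) no edge is visited twice; (2) an edge is
#' only admitted if its outgoing direction makes at most `max_angle_deg`
#' with the radial direction from the soma at the node where it attaches —
#' an edge violating this rule is admitted only when no admissible route
#' reaches its territory ("no other interpretation is possible"), in which
#' case the least-violating connecting edge is taken; (3) the traversal
#' stops at any other soma in `somas`. The admitted edge set is computed as
#' a fixpoint, so it does not depend on node enumeration order.
#'
#' @param graph a `skeleton_graph`.
#' @param soma soma centre: numeric `c(x_um, y_um)`, or a one-row data.frame
#'   as returned by [detect_somas].
#' @param somas optional data.frame of all detected somas (used as traversal
#'   barriers, rule 3).
#' @param config a [rule_config].
#' @return object of class `arbor_trace`: list with `soma_center`,
#'   `soma_radius`, `edge_ids`, `attach_node`, `length_um`, `pixel_size` and
#'   a `mask` rendering of the trace at the source resolution.
#' @export
extract_arbor <- function(graph, soma, somas = NULL, config = rule_config()) {
  if (is.data.frame(soma)) {
    soma_center <- c(soma$x_um[1], soma$y_um[1])
    soma_radius <- if (!is.null(soma$radius_um)) soma$radius_um[1] else 0
  } else {
    soma_center <- as.numeric(soma)
    soma_radius <- 0
  }
  nodes <- graph$nodes
  d2 <- sqrt((nodes$x_um - soma_center[1])^2 + (nodes$y_um - soma_center[2])^2)
  attach_node <- min(nodes$node[d2 <= min(d2) + 1e-12])
  if (min(d2) > soma_radius + config$attach_radius_um) {
    stop("soma is not near any skeleton node (nearest node at ",
         round(min(d2), 2), " um)", call. = FALSE)
  }

  # rule 3 barriers: nodes inside another soma
  barrier <- rep(FALSE, nrow(nodes))
  if (!is.null(somas) && nrow(somas) > 0) {
    for (i in seq_len(nrow(somas))) {
      ctr <- c(somas$x_um[i], somas$y_um[i])
      if (sum((ctr - soma_center)^2) < 1e-12) next
      rad <- max(somas$radius_um[i], graph$pixel_size)
      di <- sqrt((nodes$x_um - ctr[1])^2 + (nodes$y_um - ctr[2])^2)
      barrier <- barrier | (di <= rad)
    }
  }
  names(barrier) <- nodes$node

  # work positionally: node/edge ids may be stored in any order
  edges <- graph$edges
  n_e <- nrow(edges)
  n_n <- nrow(nodes)
  from_pos <- match(edges$from, nodes$node)
  to_pos <- match(edges$to, nodes$node)
  attach_pos <- match(attach_node, nodes$node)
  cos_lim <- cos(config$max_angle_deg * pi / 180)

  # radial-rule score of every edge at each of its two attachment nodes,
  # computed once: cosine of (outgoing edge direction, radial from soma);
  # nodes inside the soma admit all directions
  radial_score <- function(node_pos, node_id, e) {
    rx <- nodes$x_um[node_pos] - soma_center[1]
    ry <- nodes$y_um[node_pos] - soma_center[2]
    nr <- sqrt(rx^2 + ry^2)
    free <- nr < pmax(soma_radius, graph$pixel_size)
    out <- numeric(length(e))
    for (k in seq_along(e)) {
      if (free[k]) {
        out[k] <- 1
      } else {
        dir <- edge_direction_at(graph, e[k], node_id[k],
                                 config$direction_steps)
        out[k] <- (dir[1] * rx[k] + dir[2] * ry[k]) / nr[k]
      }
    }
    out
  }
  score_from <- radial_score(from_pos, edges$from, seq_len(n_e))
  score_to <- radial_score(to_pos, edges$to, seq_len(n_e))

  admitted <- rep(FALSE, n_e)
  reached <- rep(FALSE, n_n)
  reached[attach_pos] <- TRUE
  open_end <- function() {
    # admissible, not yet admitted edges attached to a reached node
    (!admitted) & ((reached[from_pos] & score_from >= cos_lim - 1e-12) |
                     (reached[to_pos] & score_to >= cos_lim - 1e-12))
  }
  sweep <- function() {
    repeat {
      take <- open_end()
      if (!any(take)) break
      admitted[take] <<- TRUE
      ends <- c(from_pos[take], to_pos[take])
      reached[ends[!barrier[ends]]] <<- TRUE
    }
  }
  sweep()

  # completion: territory of this soma that no admissible route reaches is
  # attached through its least-violating connecting edge (rule 2's escape:
  # "unless no other interpretation is possible")
  keep <- nodes$node[!barrier | nodes$node == attach_node]
  g_blocked <- igraph::induced_subgraph(graph$graph, as.character(keep))
  comp <- igraph::components(g_blocked)
  att_comp <- comp$membership[as.character(attach_node)]
  territory_pos <- match(as.integer(names(comp$membership)[
    comp$membership == att_comp]), nodes$node)
  repeat {
    unreached <- rep(FALSE, n_n)
    unreached[territory_pos] <- !reached[territory_pos]
    if (!any(unreached)) break
    cand <- which(!admitted &
                    (unreached[from_pos] | unreached[to_pos]) &
                    (reached[from_pos] | reached[to_pos]))
    if (length(cand) == 0) break
    sc <- ifelse(reached[from_pos[cand]], score_from[cand], score_to[cand])
    top <- cand[sc >= max(sc) - 1e-12]
    e <- top[which.min(edges$edge[top])] # deterministic tie-break
    admitted[e] <- TRUE
    ends <- c(from_pos[e], to_pos[e])
    reached[ends[!barrier[ends]]] <- TRUE
    sweep()
  }

  edge_ids <- sort(edges$edge[admitted])
  mask <- matrix(0L, graph$dim[1], graph$dim[2])
  for (i in which(admitted)) mask[graph$polylines[[i]]] <- 1L
  structure(list(soma_center = soma_center, soma_radius = soma_radius,
                 attach_node = attach_node, edge_ids = edge_ids,
                 length_um = sum(edges$length_um[admitted]),
                 pixel_size = graph$pixel_size, mask = mask),
            class = "arbor_trace")
}

#' @export
print.arbor_trace <- function(x, ...) {
  cat("arbor_trace:", length(x$edge_ids), "edges,",
      round(x$length_um, 2), "um, soma at (",
      paste(round(x$soma_center, 2), collapse = ", "), ") um\n")
  invisible(x)
}

#' Extract all arbors and resolve contested edges between somas
#'
#' Runs [extract_arbor] for every soma (the remaining somas acting as
#' barriers) and assigns every edge claimed by more than one soma using a
#' similarity score: weighted absolute difference between the edge's mean
#' width / mean intensity and the mean over the claiming soma's uncontested
#' edges (width and intensity continuity). Ties are broken towards the soma
#' with the shorter connecting path, then towards the lower soma index.
#'
#' @inheritParams extract_arbor
#' @param somas data.frame as returned by [detect_somas].
#' @return list of `arbor_trace`, one per soma row.
#' @export
extract_arbors <- function(graph, somas, config = rule_config()) {
  traces <- lapply(seq_len(nrow(somas)), function(i)
    extract_arbor(graph, somas[i, ], somas = somas, config = config))
  claims <- table(unlist(lapply(traces, `[[`, "edge_ids")))
  contested <- as.integer(names(claims[claims > 1]))
  if (length(contested) > 0) {
    edges <- graph$edges
    rng <- diff(range(edges$mean_intensity))
    int_norm <- if (is.finite(rng) && rng > 0) {
      (edges$mean_intensity - min(edges$mean_intensity)) / rng
    } else {
      rep(0, nrow(edges))
    }
    row_of <- function(ids) match(ids, edges$edge)
    for (e in contested) {
      ei <- row_of(e)
      claimers <- which(vapply(traces, function(tr) e %in% tr$edge_ids, TRUE))
      score <- vapply(claimers, function(i) {
        own <- row_of(setdiff(traces[[i]]$edge_ids, contested))
        if (length(own) == 0) own <- row_of(traces[[i]]$edge_ids)
        config$w_width *
          abs(edges$mean_width_um[ei] - mean(edges$mean_width_um[own])) +
          config$w_intensity * abs(int_norm[ei] - mean(int_norm[own]))
      }, 0)
      best <- claimers[score <= min(score) + 1e-12]
      if (length(best) > 1) {
        pathlen <- vapply(best, function(i) {
          suppressWarnings(igraph::distances(
            graph$graph,
            v = as.character(traces[[i]]$attach_node),
            to = as.character(edges$from[ei]))[1, 1])
        }, 0)
        best <- best[pathlen <= min(pathlen) + 1e-12]
      }
      keep <- best[1]
      for (i in setdiff(claimers, keep)) {
        traces[[i]]$edge_ids <- setdiff(traces[[i]]$edge_ids, e)
        traces[[i]]$mask[graph$polylines[[ei]]] <- 0L
        traces[[i]]$length_um <-
          sum(edges$length_um[row_of(traces[[i]]$edge_ids)])
      }
    }
  }
  traces
}
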
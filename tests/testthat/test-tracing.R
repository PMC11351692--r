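test_that("binarization recovers noise-free strokes exactly and flags no signal", {
  tree <- self_similar_tree(1.25, 5, 70, seed = 4)
  ras <- rasterize_geometry(tree, pixel_size = PX)
  mask <- binarize(ras$image)
  expect_identical(mask > 0, ras$image$pixels > 0)
  expect_error(binarize(matrix(0, 32, 32)), "no signal")
  expect_error(binarize(matrix(0.7, 32, 32)), "no signal")
})

test_that("binarization of noisy strokes recovers >=99% with <=1% spurious", {
  tree <- self_similar_tree(1.25, 6, 90, jitter_deg = 5, seed = 8)
  clean <- rasterize_geometry(tree, pixel_size = PX)
  noisy <- rasterize_geometry(tree, pixel_size = PX, noise_sd = 0.1, seed = 21)
  truth <- clean$image$pixels > 0
  mask <- binarize(noisy$image, min_object_px = 5) > 0
  recovered <- sum(mask & truth) / sum(truth)
  spurious <- sum(mask & !truth) / sum(!truth)
  expect_gte(recovered, 0.99)
  expect_lte(spurious, 0.01)
})

test_that("skeletonization thins to one pixel and is idempotent", {
  bar <- matrix(0L, 21, 41)
  bar[9:13, 5:35] <- 1L
  sk <- skeletonize(bar)
  # single centreline row, same orientation
  rows <- unique(which(sk == 1L, arr.ind = TRUE)[, 1])
  expect_length(rows, 1)
  expect_equal(rows, 11)
  # no 2x2 foreground block anywhere
  blk <- sk[-nrow(sk), -ncol(sk)] & sk[-1, -ncol(sk)] &
    sk[-nrow(sk), -1] & sk[-1, -1]
  expect_false(any(blk))
  expect_identical(skeletonize(sk), sk)

  thin <- line_mask(20)
  expect_identical(skeletonize(thin), thin)

  disk <- disk_mask(10)
  skd <- skeletonize(disk)
  expect_true(all(disk[skd == 1L] == 1L)) # contained in the disk
  ctr <- (dim(disk) + 1) / 2
  rc <- which(skd == 1L, arr.ind = TRUE)
  expect_lte(max(abs(sweep(rc, 2, ctr))), 3) # degenerates towards the centre

  expect_error(skeletonize(matrix(0L, 8, 8)), "empty")
})

test_that("skeleton graph measures chain lengths with the sqrt(2) diagonal rule", {
  m <- matrix(0L, 21, 21)
  m[11, 5:15] <- 1L # 11-px horizontal line
  g <- build_skeleton_graph(m, pixel_size = PX)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$length_um, 10 * PX, tolerance = 1e-9)

  m2 <- matrix(0L, 21, 21)
  for (i in 0:10) m2[5 + i, 5 + i] <- 1L # 11-px perfect diagonal
  g2 <- build_skeleton_graph(m2, pixel_size = PX)
  expect_equal(graph_length(g2), 10 * sqrt(2) * PX, tolerance = 1e-9)

  # edge length equals its polyline's summed step lengths
  pl <- g2$polylines[[1]]
  d <- abs(diff(pl))
  expect_equal(g2$edges$length_um[1],
               sum(ifelse(rowSums(d) == 2, sqrt(2), 1)) * PX,
               tolerance = 1e-9)
})

test_that("skeleton graph node degrees reflect the topology", {
  m <- matrix(0L, 31, 31)
  m[16, 5:15] <- 1L
  for (i in 1:8) {
    m[16 - i, 15 + i] <- 1L
    m[16 + i, 15 + i] <- 1L
  }
  g <- build_skeleton_graph(m, pixel_size = 1)
  expect_equal(sort(g$nodes$degree), c(1, 1, 1, 3))
  expect_equal(nrow(g$edges), 3)
})

test_that("graph length is invariant under rotation", {
  nf <- network_field(12, "uniform", field_px = 384, segment_length_um = 40,
                      pixel_size = 1, seed = 5)
  m <- (nf$image$pixels > 0) * 1L
  sk <- skeletonize(m)
  len <- function(mm) graph_length(build_skeleton_graph(mm, pixel_size = 1))
  l0 <- len(sk)
  l90 <- len(t(sk)[ncol(sk):1, , drop = FALSE]) # exact 90-degree rotation
  expect_equal(l90, l0, tolerance = 1e-9)
  # 45 degrees: bilinear resampling spreads 1-px lines into a band, so
  # threshold low and re-thin; tolerance covers the resampling noise
  r45 <- as.matrix(EBImage::rotate(EBImage::Image(m), 45, bg.col = 0)) > 0.2
  l45 <- len(skeletonize(r45 * 1L))
  expect_lt(abs(l45 - l0) / l0, 0.03)
})

test_that("skeleton length reproduces manifest length up to digitization bias", {
  # the sqrt(2)-step chain convention overestimates isotropic digital lines
  # by (4/pi)(sin 45 + (sqrt(2)-1)(1 - cos 45)) - 1 = +5.47% in expectation;
  # beyond that, no length may be lost or double-counted
  for (s in 1:3) {
    nf <- network_field(20, "uniform", field_px = 1024,
                        segment_length_um = 100, seed = s)
    g <- build_skeleton_graph(skeletonize(binarize(nf$image)),
                              pixel_size = nf$image$pixel_size)
    ratio <- graph_length(g) / nf$manifest$total_length
    expect_gte(ratio, 1.00)
    expect_lte(ratio, 1.085)
  }
  # axis-aligned fields have no diagonal steps, so the measured length is
  # exactly (foreground pixels - runs) * pixel_size, even when collinear
  # segments merge
  al <- network_field(20, "aligned", theta = 0, field_px = 1024,
                      segment_length_um = 100, seed = 4)
  mask <- binarize(al$image)
  ga <- build_skeleton_graph(skeletonize(mask),
                             pixel_size = al$image$pixel_size)
  n_runs <- igraph::count_components(ga$graph)
  expect_equal(graph_length(ga),
               (sum(mask > 0) - n_runs) * al$image$pixel_size,
               tolerance = 1e-9)
})

test_that("somas are detected at disk centres and thin strokes yield none", {
  m <- matrix(0L, 200, 200)
  centers <- list(c(50, 50), c(150, 60), c(100, 150))
  for (ctr in centers) {
    m[disk_px_fixture(ctr, 15, c(200, 200))] <- 1L
  }
  s <- detect_somas(m, m, min_radius = 5, pixel_size = 1)
  expect_equal(nrow(s), 3)
  found <- s[order(s$row, s$col), ]
  truth <- do.call(rbind, centers)
  truth <- truth[order(truth[, 1], truth[, 2]), ]
  expect_true(all(abs(found$row - truth[, 1]) <= 1))
  expect_true(all(abs(found$col - truth[, 2]) <= 1))
  expect_true(all(abs(s$radius_um - 15) <= 1.5))

  thin <- line_mask(60)
  expect_equal(nrow(detect_somas(thin, thin, min_radius = 3, pixel_size = 1)), 0)
})

test_that("merged somas are reported deterministically", {
  m <- matrix(0L, 120, 120)
  m[disk_px_fixture(c(60, 50), 12, c(120, 120))] <- 1L
  m[disk_px_fixture(c(60, 66), 12, c(120, 120))] <- 1L # closer than min radius
  a <- detect_somas(m, m, min_radius = 8, pixel_size = 1)
  b <- detect_somas(m, m, min_radius = 8, pixel_size = 1)
  expect_identical(a, b)
  expect_lte(nrow(a), 2)
})

test_that("an isolated arbor is traced to its full connected component", {
  tree <- self_similar_tree(1.3, depth = 7, trunk_length = 80,
                            jitter_deg = 5, seed = 2)
  ras <- rasterize_geometry(tree, pixel_size = PX, soma_radius = 5)
  mask <- binarize(ras$image)
  g <- build_skeleton_graph(skeletonize(mask), image = ras$image, mask = mask,
                            pixel_size = PX)
  somas <- detect_somas(ras$image, mask, min_radius = 3)
  expect_equal(nrow(somas), 1)
  tr <- extract_arbor(g, somas[1, ], somas = somas)
  expect_setequal(tr$edge_ids, g$edges$edge)
  # trace length matches the manifest up to the digitization bias of the
  # sqrt(2) step convention (+5.5% expected for isotropic directions) plus
  # the skeletonized soma disk
  expect_lt(abs(tr$length_um - ras$manifest$total_length) /
              ras$manifest$total_length, 0.12)
  expect_gte(tr$length_um, ras$manifest$total_length * 0.98)
})

test_that("disjoint arbors are never mixed and missing somas error", {
  t1 <- self_similar_tree(1.2, 5, 60, seed = 1, soma_center = c(0, 0))
  t2 <- self_similar_tree(1.2, 5, 60, seed = 2, soma_center = c(400, 380))
  both <- structure(list(segments = rbind(t1$segments, t2$segments),
                         parent = c(t1$parent, t2$parent),
                         level = c(t1$level, t2$level),
                         soma_center = t1$soma_center,
                         nominal_dimension = 1.2, branch_ratio = t1$branch_ratio),
                    class = "arbor_geometry")
  ras <- rasterize_geometry(both, pixel_size = PX)
  mask <- binarize(ras$image)
  g <- build_skeleton_graph(skeletonize(mask), pixel_size = PX)
  # which nodes belong to which component
  memb <- igraph::components(g$graph)$membership
  expect_equal(max(memb), 2)
  shift <- ras$manifest$soma_positions[1, ] - t1$soma_center
  somaA <- c(t1$soma_center + shift)
  trA <- extract_arbor(g, somaA, config = rule_config(attach_radius_um = 8))
  compA <- memb[as.character(g$edges$from[match(trA$edge_ids, g$edges$edge)])]
  expect_length(unique(compA), 1)
  # far-away query point errors
  expect_error(extract_arbor(g, somaA + c(5000, 5000)), "not near")
})

test_that("a doubling-back edge is excluded when an admissible route exists", {
  # soma s at the origin with two primary processes: s-u (up) and s-p.
  # Node b is connected both by u-b, which points back towards the soma at
  # 135 degrees to the radial at u, and by p-b, which is admissible (~57
  # degrees); b continues outward to c. The 135-degree edge must stay out.
  nodes <- data.frame(node = 1:5,
                      x_um = c(0, 0, 5, 9, 15) + 2,
                      y_um = c(0, 10, 3, 1, 0) + 2)
  # 1=s, 2=u, 3=p, 4=b, 5=c
  edges <- data.frame(from = c(1, 1, 2, 3, 4),
                      to   = c(2, 3, 4, 4, 5))
  g <- skeleton_graph(nodes, edges, pixel_size = 1)
  tr <- extract_arbor(g, c(2, 2), config = rule_config(attach_radius_um = 2))
  expect_false(3 %in% tr$edge_ids) # edge 3 = u-b, the doubling-back edge
  expect_setequal(tr$edge_ids, c(1, 2, 4, 5))

  # with the admissible route removed, u-b is the only interpretation left
  g2 <- skeleton_graph(nodes, edges[-4, ], pixel_size = 1)
  tr2 <- extract_arbor(g2, c(2, 2), config = rule_config(attach_radius_um = 2))
  expect_setequal(tr2$edge_ids, c(1, 2, 3, 4))
})

test_that("arbor extraction does not depend on node enumeration order", {
  tree <- self_similar_tree(1.25, 6, 70, jitter_deg = 6, seed = 13)
  ras <- rasterize_geometry(tree, pixel_size = PX, soma_radius = 4)
  mask <- binarize(ras$image)
  g <- build_skeleton_graph(skeletonize(mask), pixel_size = PX)
  somas <- detect_somas(ras$image, mask, min_radius = 2.5)
  tr <- extract_arbor(g, somas[1, ], somas = somas)

  # permute node/edge storage order and re-extract
  set.seed(1)
  perm <- sample(nrow(g$nodes))
  g2 <- g
  g2$nodes <- g$nodes[perm, ]
  eperm <- sample(nrow(g$edges))
  g2$edges <- g$edges[eperm, ]
  g2$polylines <- g$polylines[eperm]
  g2$edges$edge <- g$edges$edge[eperm]
  tr2 <- extract_arbor(g2, somas[1, ], somas = somas)
  expect_setequal(tr2$edge_ids, tr$edge_ids)
})

test_that("contested edges are assigned by width/intensity continuity", {
  # chain soma1 - n2 - n3 - soma2 - n5: the bridge edge (n2-n3) is thick and
  # bright like soma 1's processes; soma 2 owns a thin faint uncontested
  # process (n4-n5), so continuity must hand the bridge to soma 1
  nodes <- data.frame(node = 1:5,
                      x_um = c(2, 12, 32, 42, 52),
                      y_um = c(2, 2, 2, 2, 2))
  edges <- data.frame(from = c(1, 2, 3, 4), to = c(2, 3, 4, 5),
                      mean_width_um = c(2.0, 2.1, 0.5, 0.5),
                      mean_intensity = c(0.9, 0.88, 0.3, 0.3))
  g <- skeleton_graph(nodes, edges, pixel_size = 1)
  somas <- data.frame(soma = 1:2, x_um = c(2, 42), y_um = c(2, 2),
                      radius_um = c(1, 1), row = c(2, 2), col = c(2, 42))
  trs <- extract_arbors(g, somas, rule_config(attach_radius_um = 2))
  expect_true(2 %in% trs[[1]]$edge_ids)  # bridge goes to the matching soma
  expect_false(2 %in% trs[[2]]$edge_ids)
  expect_true(all(c(3, 4) %in% trs[[2]]$edge_ids)) # thin edges stay with soma 2
  # every edge assigned exactly once
  all_ids <- c(trs[[1]]$edge_ids, trs[[2]]$edge_ids)
  expect_equal(sort(all_ids), 1:4)
})
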
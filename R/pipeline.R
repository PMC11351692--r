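# --- configuration -----------------------------------------------------------

#' Pipeline configuration
#'
#' Central configuration shared by all pipeline stages; defaults follow the
#' imaging conventions this package emulates (0.32356 um/px, 2.145-mm square
#' electrode, centre 1.8-mm analysis crop, 20\% coarse cut-off).
#'
#' @param pixel_size um/px.
#' @param electrode_side electrode side length, um.
#' @param crop_side coherency crop side, um.
#' @param n_offsets box-count mesh origins per size.
#' @param per_decade box sizes per decade.
#' @param fine_factor fine cut-off multiplier of the dendrite width.
#' @param coarse_frac coarse cut-off fraction of the arbor width (in (0,1)).
#' @param min_soma_radius soma detection threshold, um.
#' @param min_object_px speckle-removal threshold, px.
#' @param binarize_method `"global_otsu"` or `"adaptive"`.
#' @param rules a [rule_config].
#' @param tensor_sigma structure-tensor smoothing, px.
#' @param seed integer seed threaded through stochastic stages.
#' @param output_dir where [run_pipeline] writes results.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size = AF_PIXEL_SIZE,
                            electrode_side = 2145, crop_side = 1800,
                            n_offsets = 4, per_decade = 12,
                            fine_factor = 1, coarse_frac = 0.2,
                            min_soma_radius = 3, min_object_px = 5,
                            binarize_method = "global_otsu",
                            rules = rule_config(), tensor_sigma = 2,
                            seed = 1, output_dir = "arborfract-out") {
  stopifnot(pixel_size > 0, electrode_side > 0, crop_side > 0,
            coarse_frac > 0, coarse_frac < 1, fine_factor > 0)
  structure(list(pixel_size = pixel_size, electrode_side = electrode_side,
                 crop_side = crop_side, n_offsets = n_offsets,
                 per_decade = per_decade, fine_factor = fine_factor,
                 coarse_frac = coarse_frac,
                 min_soma_radius = min_soma_radius,
                 min_object_px = min_object_px,
                 binarize_method = binarize_method, rules = rules,
                 tensor_sigma = tensor_sigma, seed = seed,
                 output_dir = output_dir),
            class = "pipeline_config")
}

# --- single-image analysis ---------------------------------------------------

#' Analyse one calibrated image: trace arbors, measure D and S
#'
#' Binarize, skeletonize, build the skeleton graph, detect somas, extract
#' one arbor per soma, and measure the box-counting dimension and hull
#' coverage of each.
#'
#' @param image a [calibrated_image].
#' @param config a [pipeline_config].
#' @return list with `mask`, `skeleton`, `graph`, `somas`, `traces`, and
#'   `arbors` (data.frame: `neuron_id, x_um, y_um, D, r_squared, L_min_um,
#'   L_max_um, S_um2, length_um`).
#' @export
analyze_image <- function(image, config = pipeline_config()) {
  mask <- binarize(image, method = config$binarize_method,
                   min_object_px = config$min_object_px)
  skel <- skeletonize(mask)
  graph <- build_skeleton_graph(skel, image = image, mask = mask,
                                pixel_size = image$pixel_size)
  somas <- detect_somas(image, mask, min_radius = config$min_soma_radius)
  traces <- if (nrow(somas) > 0) {
    extract_arbors(graph, somas, config$rules)
  } else {
    list()
  }
  arbors <- do.call(rbind, lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    row <- data.frame(neuron_id = i, x_um = tr$soma_center[1],
                      y_um = tr$soma_center[2], D = NA_real_,
                      r_squared = NA_real_, L_min_um = NA_real_,
                      L_max_um = NA_real_, S_um2 = NA_real_,
                      length_um = tr$length_um)
    est <- tryCatch(fractal_dimension(tr, n_offsets = config$n_offsets,
                                      per_decade = config$per_decade,
                                      coarse_frac = config$coarse_frac,
                                      fine_factor = config$fine_factor),
                    error = function(e) NULL)
    if (!is.null(est)) {
      row$D <- est$D; row$r_squared <- est$r_squared
      row$L_min_um <- est$L_min; row$L_max_um <- est$L_max
    }
    row$S_um2 <- suppressWarnings(convex_hull_area(tr)$S_um2)
    row
  }))
  if (is.null(arbors)) {
    arbors <- data.frame(neuron_id = integer(0), x_um = numeric(0),
                         y_um = numeric(0), D = numeric(0),
                         r_squared = numeric(0), L_min_um = numeric(0),
                         L_max_um = numeric(0), S_um2 = numeric(0),
                         length_um = numeric(0))
  }
  list(mask = mask, skeleton = skel, graph = graph, somas = somas,
       traces = traces, arbors = arbors)
}

# --- end-to-end pipeline -----------------------------------------------------

#' Run the full analysis pipeline over a set of electrode images
#'
#' For each input image: arbor tracing plus per-arbor D and S, and
#' electrode-level metrics (total process length, N_CNT over the configured
#' electrode area, orientation coherency, and G_Si when a glia image is
#' given). Writes `arbors.csv`, `electrodes.csv`, SWC traces, a group
#' comparison table when two DIV groups are present, and a JSON run manifest
#' (config, seed, package version); outputs are deterministic for a fixed
#' config and seed.
#'
#' @param inputs data.frame with columns `path` (neuron-channel TIFF),
#'   `electrode_id`, `div`, and optional `glia_path`.
#' @param config a [pipeline_config].
#' @param write logical: write results under `config$output_dir`.
#' @return list with `arbors`, `electrodes`, `comparison` (or `NULL`),
#'   `failures`; invisibly.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(), write = TRUE) {
  if (!is.data.frame(inputs) || !all(c("path", "electrode_id", "div") %in%
                                     names(inputs))) {
    stop("`inputs` must be a data.frame with columns path, electrode_id, div")
  }
  missing <- inputs$path[!file.exists(inputs$path)]
  if (length(missing) > 0) {
    stop("input image not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  set.seed(config$seed)
  out_dir <- config$output_dir
  if (write) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  arbors <- list(); electrodes <- list(); failures <- character(0)
  for (i in seq_len(nrow(inputs))) {
    eid <- inputs$electrode_id[i]
    res <- tryCatch({
      img <- read_image_tiff(inputs$path[i], pixel_size = config$pixel_size)
      an <- analyze_image(img, config)
      a <- an$arbors
      if (nrow(a) > 0) {
        a$electrode_id <- eid; a$div <- inputs$div[i]
      }
      area <- config$electrode_side^2
      coh <- orientation_coherency(img, crop_side = config$crop_side,
                                   tensor_sigma = config$tensor_sigma)
      g_si <- NA_real_
      if (!is.null(inputs$glia_path) && !is.na(inputs$glia_path[i]) &&
          nzchar(inputs$glia_path[i])) {
        glia <- read_image_tiff(inputs$glia_path[i], config$pixel_size)
        gmask <- binarize(glia, method = config$binarize_method,
                          min_object_px = config$min_object_px)
        region <- matrix(1L, nrow(gmask), ncol(gmask))
        g_si <- glial_coverage(gmask, region)
      }
      e <- cbind(data.frame(electrode_id = eid, div = inputs$div[i]),
                 network_summary(total_process_length(an$graph), area,
                                 g_si = g_si, coherency = coh$coherency,
                                 mean_orientation_deg = coh$mean_orientation_deg))
      if (write && length(an$traces) > 0) {
        for (k in seq_along(an$traces)) {
          write_swc(an$traces[[k]],
                    file.path(out_dir, sprintf("%s_neuron%02d.swc", eid, k)),
                    graph = an$graph)
        }
      }
      list(a = a, e = e)
    }, error = function(err) {
      warning("electrode ", eid, " failed: ", conditionMessage(err),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) {
      failures <- c(failures, as.character(eid))
    } else {
      arbors[[length(arbors) + 1L]] <- res$a
      electrodes[[length(electrodes) + 1L]] <- res$e
    }
  }
  arbors <- do.call(rbind, arbors)
  electrodes <- do.call(rbind, electrodes)

  comparison <- NULL
  divs <- unique(inputs$div)
  if (!is.null(arbors) && length(divs) == 2 && nrow(arbors) > 0) {
    g1 <- arbors[arbors$div == divs[1], ]
    g2 <- arbors[arbors$div == divs[2], ]
    if (nrow(g1) >= 2 && nrow(g2) >= 2) {
      e1 <- electrodes[electrodes$div == divs[1], ]
      e2 <- electrodes[electrodes$div == divs[2], ]
      measures <- list(
        S = list(x = g1$S_um2[!is.na(g1$S_um2)], y = g2$S_um2[!is.na(g2$S_um2)]),
        D = list(x = g1$D[!is.na(g1$D)], y = g2$D[!is.na(g2$D)]))
      if (nrow(e1) >= 2 && nrow(e2) >= 2) {
        measures <- c(list(N_CNT = list(x = e1$N_CNT, y = e2$N_CNT)), measures)
      }
      comparison <- comparison_table(measures,
                                     labels = paste(divs, "DIV"),
                                     pairing = FALSE)
    }
  }

  if (write) {
    if (!is.null(arbors)) {
      write.csv(arbors, file.path(out_dir, "arbors.csv"), row.names = FALSE)
    }
    if (!is.null(electrodes)) {
      write.csv(electrodes, file.path(out_dir, "electrodes.csv"),
                row.names = FALSE)
    }
    if (!is.null(comparison)) {
      write.csv(comparison, file.path(out_dir, "comparison.csv"),
                row.names = FALSE)
    }
    manifest <- list(config = unclass(config), seed = config$seed,
                     package_version = as.character(utils::packageVersion("arborfract")),
                     inputs = inputs, failures = failures)
    manifest$config$rules <- unclass(manifest$config$rules)
    write_manifest(manifest, file.path(out_dir, "run_manifest.json"))
  }
  invisible(list(arbors = arbors, electrodes = electrodes,
                 comparison = comparison, failures = failures))
}

# --- synthetic experiments ---------------------------------------------------

#' Dimension-recovery experiment on self-similar trees
#'
#' Generates `n_seeds` self-similar trees of similarity dimension
#' `target_D`, rasterizes each at 1-px stroke width on a canvas of at least
#' `min_canvas_px`, and estimates the box-counting dimension with the
#' dendrite-width / 20\%-of-arbor-width cut-offs. Per-seed trunk lengths are
#' drawn from `span_um * (1 - r^2) * U(0.85, 1.2)` and the initial
#' orientation is uniform, which averages out the log-periodic phase of the
#' exactly self-similar geometry; branch angles carry +/-`jitter_deg` of
#' seeded jitter. Tree depth is the larger of `min_depth` and the value
#' placing the finest (terminal) branch near `finest_branch_um`, so terminal
#' branches stay several pixels long and register as line elements rather
#' than dots.
#'
#' @param target_D nominal similarity dimension.
#' @param n_seeds number of replicate trees.
#' @param seed base seed; replicate i uses `seed + i - 1`.
#' @param span_um target arbor span, um.
#' @param pixel_size um/px.
#' @param jitter_deg branch-angle jitter half-width, degrees.
#' @param finest_branch_um target terminal-branch length, um.
#' @param min_depth minimum branching depth.
#' @param min_canvas_px minimum canvas side, px.
#' @param config [pipeline_config] supplying estimator settings.
#' @return data.frame with one row per seed (`seed, D_hat, r_squared,
#'   depth, trunk_um, n_points`), attribute `mean_D`.
#' @export
dimension_recovery_experiment <- function(target_D, n_seeds = 10, seed = 1,
                                          span_um = 566,
                                          pixel_size = AF_PIXEL_SIZE,
                                          jitter_deg = 5,
                                          finest_branch_um = 1.8,
                                          min_depth = 8,
                                          min_canvas_px = 2048,
                                          config = pipeline_config()) {
  r <- branch_ratio(target_D)
  rows <- lapply(seq_len(n_seeds), function(i) {
    s <- seed + i - 1
    set.seed(s)
    trunk <- span_um * (1 - r^2) * runif(1, 0.85, 1.2)
    depth <- max(min_depth,
                 round(log(trunk / finest_branch_um) / log(1 / r)))
    tree <- self_similar_tree(target_D, depth = depth, trunk_length = trunk,
                              jitter_deg = jitter_deg,
                              initial_angle = runif(1, 0, 360))
    ras <- rasterize_geometry(tree, pixel_size = pixel_size, stroke_width = 1,
                              min_canvas_px = min_canvas_px)
    est <- fractal_dimension(ras$image, n_offsets = config$n_offsets,
                             per_decade = config$per_decade,
                             coarse_frac = config$coarse_frac,
                             fine_factor = config$fine_factor)
    data.frame(seed = s, D_hat = est$D, r_squared = est$r_squared,
               depth = depth, trunk_um = trunk,
               n_points = est$n_points_in_fit)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_D") <- mean(out$D_hat)
  out
}

#' Coherency of seeded synthetic fields
#'
#' Generates `n_seeds` network fields (uniform or aligned orientations) and
#' returns the structure-tensor coherency of each, over the configured
#' centre crop.
#'
#' @param n_seeds replicates.
#' @param seed base seed.
#' @param n_segments segments per field.
#' @param angle_mode `"uniform"` or `"aligned"`.
#' @param theta angle for aligned mode, degrees.
#' @param field_px field side, px.
#' @param segment_length_um segment length, um.
#' @param config [pipeline_config].
#' @return data.frame `(seed, coherency, mean_orientation_deg)`, attribute
#'   `mean_coherency`.
#' @export
coherency_experiment <- function(n_seeds = 10, seed = 1, n_segments = 200,
                                 angle_mode = "uniform", theta = 0,
                                 field_px = 2048, segment_length_um = 100,
                                 config = pipeline_config()) {
  crop <- field_px * config$pixel_size * config$crop_side / config$electrode_side
  rows <- lapply(seq_len(n_seeds), function(i) {
    nf <- network_field(n_segments, angle_mode = angle_mode, theta = theta,
                        field_px = field_px,
                        segment_length_um = segment_length_um,
                        pixel_size = config$pixel_size, seed = seed + i - 1)
    oc <- orientation_coherency(nf$image, crop_side = crop,
                                tensor_sigma = config$tensor_sigma)
    data.frame(seed = seed + i - 1, coherency = oc$coherency,
               mean_orientation_deg = oc$mean_orientation_deg)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_coherency") <- mean(out$coherency)
  out
}
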
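# Deterministic label -> RGB color via golden-ratio hue stepping.
label_color <- function(id, s = 0.9, v = 1) {
  hue <- (id * 0.618033988749895) %% 1
  grDevices::col2rgb(grDevices::hsv(hue, s, v)) / 255
}

# Deterministic palette for cell classes (sorted class names).
class_palette <- function(classes) {
  classes <- sort(unique(classes))
  cols <- lapply(seq_along(classes), function(i) label_color(i, s = 1, v = 1))
  names(cols) <- classes
  cols
}

#' Render a quality-control overlay image
#'
#' Draws any combination of layers over the (grayscale) base image:
#' labeled fiber masks colored per label, pruned skeleton paths, cell
#' markers colored by class, and neighborhood-outline circles.  Color
#' assignment is a deterministic function of label/class, so re-rendering
#' the same inputs yields byte-identical files.
#'
#' @param plane base [image_plane].
#' @param mask optional `fiber_mask`; labeled pixels are tinted per label.
#' @param skeletons optional list of `fiber_skeleton`; paths drawn in the
#'   label color at full saturation.
#' @param cells optional cell table (`x`, `y`, `class_label`); markers are
#'   3 px discs colored by class.
#' @param outlines optional data.frame (`x`, `y`, `radius`) of
#'   neighborhood circles to draw.
#' @param out_path output PNG path.
#' @param opacity mask tint opacity in \[0, 1\].
#' @return (invisibly) `out_path`.
#' @export
render_overlay <- function(plane, mask = NULL, skeletons = NULL,
                           cells = NULL, outlines = NULL,
                           out_path, opacity = 0.5) {
  stopifnot(inherits(plane, "image_plane"))
  h <- nrow(plane$pixels); w <- ncol(plane$pixels)
  base <- plane$pixels / 255
  rgb <- array(rep(base, 3), dim = c(h, w, 3))
  if (!is.null(mask)) {
    labels <- if (inherits(mask, "fiber_mask")) mask$labels else mask
    if (!identical(dim(labels), dim(plane$pixels))) {
      stop("mask shape does not match the base image")
    }
    for (k in seq_len(max(labels))) {
      px <- which(labels == k)
      if (!length(px)) next
      col <- label_color(k)
      for (ch in 1:3) {
        layer <- rgb[, , ch]
        layer[px] <- (1 - opacity) * layer[px] + opacity * col[ch]
        rgb[, , ch] <- layer
      }
    }
  }
  if (!is.null(skeletons)) {
    for (fs in skeletons) {
      ok <- fs$path[, "y"] >= 0 & fs$path[, "y"] < h &
            fs$path[, "x"] >= 0 & fs$path[, "x"] < w
      if (!all(ok)) stop("skeleton path outside the base image")
      idx <- coord_index(fs$path)
      col <- label_color(fs$fiber_id)
      for (ch in 1:3) {
        layer <- rgb[, , ch]
        layer[idx] <- col[ch]
        rgb[, , ch] <- layer
      }
    }
  }
  if (!is.null(cells) && nrow(cells)) {
    pal <- class_palette(cells$class_label)
    for (i in seq_len(nrow(cells))) {
      cx <- round(cells$x[i]); cy <- round(cells$y[i])
      if (cx < 0 || cy < 0 || cx >= w || cy >= h) {
        stop("cell marker outside the base image")
      }
      col <- pal[[as.character(cells$class_label[i])]]
      ys <- max(0, cy - 2):min(h - 1, cy + 2)
      xs <- max(0, cx - 2):min(w - 1, cx + 2)
      disc <- expand.grid(y = ys, x = xs)
      disc <- disc[(disc$y - cy)^2 + (disc$x - cx)^2 <= 4, ]
      idx <- cbind(disc$y + 1L, disc$x + 1L)
      for (ch in 1:3) {
        layer <- rgb[, , ch]
        layer[idx] <- col[ch]
        rgb[, , ch] <- layer
      }
    }
  }
  if (!is.null(outlines) && nrow(outlines)) {
    for (i in seq_len(nrow(outlines))) {
      r <- outlines$radius[i]
      ang <- seq(0, 2 * pi, length.out = max(64, ceiling(2 * pi * r)))
      xs <- round(outlines$x[i] + r * cos(ang))
      ys <- round(outlines$y[i] + r * sin(ang))
      keep <- xs >= 0 & xs < w & ys >= 0 & ys < h
      idx <- unique(cbind(ys[keep] + 1L, xs[keep] + 1L))
      for (ch in 1:3) {
        layer <- rgb[, , ch]
        layer[idx] <- if (ch == 1) 1 else 1  # white circle
        rgb[, , ch] <- layer
      }
    }
  }
  png::writePNG(rgb, out_path)
  invisible(out_path)
}

#' Run the full pipeline on one image (or the default synthetic scene)
#'
#' Executes segmentation, fiber-feature extraction, spatial profiling,
#' profile clustering and overlay rendering, writing all artifacts plus a
#' machine-readable run manifest into `outdir`.  With no input image, a
#' seeded synthetic scene with planted fiber-dense and fiber-free regions
#' is generated so the pipeline is runnable end-to-end out of the box.
#' The run is fully deterministic for a fixed config and inputs.
#'
#' @param config a [run_config].
#' @param image_path optional input image (TIFF/PNG).
#' @param cells_path optional cell table CSV.
#' @param outdir output directory.
#' @param cluster_k number of profile clusters (skipped if fewer cells).
#' @return (invisibly) named list of output file paths.
#' @export
run_pipeline <- function(config = run_config(threshold_method = "fixed",
                                             threshold_value = 110),
                         image_path = NULL, cells_path = NULL,
                         outdir = "fibercell_out", cluster_k = 2L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  inputs <- list()
  if (is.null(image_path)) {
    sp <- stage("fixtures", planted_spatial_scene(seed = config$random_seed))
    plane <- sp$scene$plane
    cells <- sp$cells
    inputs$image <- "synthetic:planted_spatial_scene"
    inputs$cells <- "synthetic:planted_spatial_scene"
  } else {
    plane <- stage("read_image", read_image(image_path, config$channel,
                                            config$pixel_size_um))
    inputs$image <- normalizePath(image_path)
    cells <- NULL
    if (!is.null(cells_path)) {
      cells <- stage("read_cells",
                     read_cell_table(cells_path,
                                     image_size = rev(dim(plane$pixels))))
      inputs$cells <- normalizePath(cells_path)
    }
  }
  message(sprintf("[segment] image %d x %d px",
                  ncol(plane$pixels), nrow(plane$pixels)))
  seg <- stage("segment", segment_fibers(plane, config))
  message(sprintf("[segment] %d fibers labeled", seg$mask$label_count))
  fibers <- stage("features", build_fiber_table(seg, plane, config))
  message(sprintf("[features] %d fiber records", nrow(fibers)))
  out <- list()
  out$mask <- file.path(outdir, "mask.tif")
  write_mask(seg$mask, out$mask)
  out$fibers <- file.path(outdir, "fibers.csv")
  write_fiber_table(fibers, out$fibers)
  profiles <- NULL
  if (!is.null(cells) && nrow(cells)) {
    profiles <- stage("spatial",
                      build_profiles(cells, fibers, config,
                                     image_size = rev(dim(plane$pixels))))
    message(sprintf("[spatial] %d profiles (radius %g px)",
                    nrow(profiles), config$neighborhood_radius_px))
    out$profiles <- file.path(outdir, "profiles.csv")
    write_profile_table(profiles, out$profiles)
    if (nrow(profiles) >= cluster_k && cluster_k >= 1) {
      labels <- stage("cluster", cluster_profiles(profiles, k = cluster_k))
      clusters <- data.frame(object_id = profiles$object_id,
                             cluster = as.integer(labels))
      out$clusters <- file.path(outdir, "clusters.csv")
      write_table_csv(clusters, out$clusters)
      message(sprintf("[cluster] k = %d: sizes %s", cluster_k,
                      paste(table(labels), collapse = "/")))
    }
  }
  out$overlay <- file.path(outdir, "overlay.png")
  stage("overlay", render_overlay(plane, mask = seg$mask,
                                  skeletons = seg$skeletons,
                                  cells = cells, out_path = out$overlay))
  manifest <- list(
    package = "fibercell",
    version = as.character(utils::packageVersion("fibercell")),
    inputs = inputs,
    config = config[!vapply(config, is.null, logical(1))],
    outputs = lapply(out, basename),
    counts = list(fibers = nrow(fibers),
                  cells = if (is.null(cells)) 0L else nrow(cells),
                  profiles = if (is.null(profiles)) 0L else nrow(profiles))
  )
  out$manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, out$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  message("[done] artifacts in ", outdir)
  invisible(out)
}
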
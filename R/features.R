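#' Fiber length: curve length between the two endpoints
#'
#' The skeleton path is resampled every `step` pixels (endpoints always
#' kept) and the Euclidean lengths of the resulting chords are summed.
#' Resampling removes the staircase overestimate inherent to per-pixel
#' chain codes on digitized oblique lines while remaining exact for
#' horizontal, vertical and diagonal paths.
#'
#' @param skeleton a `fiber_skeleton`.
#' @param step resampling stride in path pixels (default 5).
#' @return curve length in pixels; 0 for a degenerate single-pixel path.
#' @export
fiber_length <- function(skeleton, step = 5L) {
  path <- skeleton$path
  n <- nrow(path)
  if (n < 2) return(0)
  idx <- unique(c(seq(1L, n, by = step), n))
  dy <- diff(path[idx, "y"])
  dx <- diff(path[idx, "x"])
  sum(sqrt(dy^2 + dx^2))
}

#' Fiber thickness: mean skeleton-to-outline distance
#'
#' For every skeleton pixel the Euclidean distance to the nearest
#' background pixel of the fiber's mask component is taken (Euclidean
#' distance transform); the feature is the mean over skeleton pixels.
#' This equals the fiber's half-width; `2 * thickness` is emitted as
#' `width_px` in the fiber table for comparability with width-based tools.
#'
#' @param skeleton a `fiber_skeleton`.
#' @param mask_component logical matrix of the fiber's mask component, in
#'   the same frame as the skeleton coordinates.
#' @return mean distance in pixels.
#' @export
fiber_thickness <- function(skeleton, mask_component) {
  stopifnot(is.logical(mask_component))
  if (skeleton$n_pixels == 0) stop("empty skeleton")
  dt <- as.matrix(EBImage::distmap(mask_component * 1))
  mean(dt[coord_index(skeleton$path)])
}

#' Fiber angle: orientation of the endpoint-to-endpoint chord
#'
#' Angle in degrees between the +x axis and the chord joining the two
#' skeleton endpoints, in Cartesian sense (the raster y axis is flipped so
#' angles grow counterclockwise), folded into \[0, 180) since fibers are
#' undirected.
#'
#' @param skeleton a `fiber_skeleton`.
#' @return angle in degrees in \[0, 180); `NA` when the endpoints
#'   coincide (degenerate fiber).
#' @export
fiber_angle <- function(skeleton) {
  e <- skeleton$endpoints
  dx <- unname(e[2, "x"] - e[1, "x"])
  dy <- -unname(e[2, "y"] - e[1, "y"])  # flip raster y to Cartesian
  if (dx == 0 && dy == 0) return(NA_real_)
  (atan2(dy, dx) * 180 / pi) %% 180
}

#' Fiber intensity: mean image intensity along the skeleton
#'
#' Arithmetic mean of the (0--255 scaled) image values at the skeleton
#' pixels.
#'
#' @param skeleton a `fiber_skeleton`.
#' @param plane the source [image_plane].
#' @return mean intensity in \[0, 255\].
#' @export
fiber_intensity <- function(skeleton, plane) {
  stopifnot(inherits(plane, "image_plane"))
  p <- skeleton$path
  if (any(p[, "y"] < 0 | p[, "x"] < 0 |
          p[, "y"] >= nrow(plane$pixels) | p[, "x"] >= ncol(plane$pixels))) {
    stop("skeleton pixel outside the image plane")
  }
  mean(plane$pixels[coord_index(p)])
}

#' Fiber straightness: chord-to-curve length ratio
#'
#' The Euclidean distance between the endpoints divided by the curve
#' length, so a perfectly straight fiber scores 1 and increasingly curled
#' fibers score toward 0.  The ratio is clamped to \[0, 1\] against float
#' round-off.
#'
#' @param skeleton a `fiber_skeleton`.
#' @return straightness in \[0, 1\]; `NA` for a zero-length curve.
#' @export
fiber_straightness <- function(skeleton) {
  curve <- fiber_length(skeleton)
  if (curve <= 0) return(NA_real_)
  e <- skeleton$endpoints
  chord <- sqrt(sum((e[2, ] - e[1, ])^2))
  min(max(chord / curve, 0), 1)
}

# Fold an absolute angle difference (degrees) into [0, 90] for
# undirected lines.
fold_angle_90 <- function(delta) {
  d <- abs(delta) %% 180
  pmin(d, 180 - d)
}

#' Fiber alignment with its neighborhood
#'
#' Neighbors are the other fibers whose reference point lies within
#' `radius_px` of this fiber's reference point.  For each neighbor the
#' inter-fiber angle \eqn{\alpha_i} is the orientation difference folded
#' into \[0, 90\] degrees (fibers are undirected); alignment is the mean of
#' \eqn{\cos\alpha_i}, so a locally parallel field scores 1 and a
#' perpendicular neighbor contributes 0.
#'
#' @param i index (row) of the processing fiber in `fibers`.
#' @param fibers data.frame with columns `x`, `y` (reference points) and
#'   `angle_deg`.
#' @param radius_px neighborhood radius in pixels.
#' @return list with `alignment` (`NA` when no neighbors or angles
#'   undefined) and `n` (neighbor count).
#' @export
fiber_alignment <- function(i, fibers, radius_px) {
  stopifnot(radius_px > 0, i >= 1, i <= nrow(fibers))
  d <- sqrt((fibers$x - fibers$x[i])^2 + (fibers$y - fibers$y[i])^2)
  nb <- which(d <= radius_px & seq_len(nrow(fibers)) != i)
  nb <- nb[!is.na(fibers$angle_deg[nb])]
  if (length(nb) == 0 || is.na(fibers$angle_deg[i])) {
    return(list(alignment = NA_real_, n = length(nb)))
  }
  alpha <- fold_angle_90(fibers$angle_deg[nb] - fibers$angle_deg[i])
  list(alignment = mean(cos(alpha * pi / 180)), n = length(nb))
}

#' Alignment and neighbor counts for every fiber in a table
#'
#' Vectorized convenience over [fiber_alignment].
#'
#' @param fibers data.frame with `x`, `y`, `angle_deg`.
#' @param radius_px neighborhood radius in pixels.
#' @return data.frame with columns `alignment` and `n_neighbor_fibers`.
#' @export
alignment_all <- function(fibers, radius_px) {
  out <- lapply(seq_len(nrow(fibers)), fiber_alignment,
                fibers = fibers, radius_px = radius_px)
  data.frame(alignment = vapply(out, `[[`, numeric(1), "alignment"),
             n_neighbor_fibers = vapply(out, `[[`, numeric(1), "n"))
}

#' Assemble the single-fiber feature table
#'
#' One row per fiber with its location (skeleton centroid, 0-based pixel
#' coordinates) and the six features: length, thickness, angle, intensity,
#' straightness and alignment.  Features undefined on degenerate fibers
#' are `NA` (written as empty cells), never 0.  Micrometer columns are
#' added when the plane carries a pixel size.
#'
#' @param segmentation a `fiber_segmentation` from [segment_fibers], or a
#'   list with `mask` and `skeletons`.
#' @param plane the source [image_plane].
#' @param config a [run_config] (alignment radius, pixel size).
#' @return data.frame ordered by `fiber_id` with columns `fiber_id`, `x`,
#'   `y`, `length_px` (`length_um`), `thickness_px`, `width_px`,
#'   `angle_deg`, `intensity_mean`, `straightness`, `alignment`,
#'   `n_neighbor_fibers`.
#' @export
build_fiber_table <- function(segmentation, plane, config = run_config()) {
  mask <- segmentation$mask
  skeletons <- segmentation$skeletons
  n <- length(skeletons)
  cols <- c("fiber_id", "x", "y", "length_px", "thickness_px", "width_px",
            "angle_deg", "intensity_mean", "straightness", "alignment",
            "n_neighbor_fibers")
  if (n == 0) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    return(df)
  }
  labels <- mask$labels
  rows <- lapply(skeletons, function(fs) {
    comp <- labels == fs$fiber_id
    thick <- fiber_thickness(fs, comp)
    data.frame(
      fiber_id = fs$fiber_id,
      x = mean(fs$path[, "x"]),
      y = mean(fs$path[, "y"]),
      length_px = fiber_length(fs),
      thickness_px = thick,
      width_px = 2 * thick,
      angle_deg = fiber_angle(fs),
      intensity_mean = fiber_intensity(fs, plane),
      straightness = fiber_straightness(fs)
    )
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$fiber_id), , drop = FALSE]
  al <- alignment_all(df, config$alignment_radius_px)
  df$alignment <- al$alignment
  df$n_neighbor_fibers <- as.integer(al$n_neighbor_fibers)
  if (!is.null(plane$pixel_size_um %||% config$pixel_size_um)) {
    psz <- plane$pixel_size_um %||% config$pixel_size_um
    df$length_um <- df$length_px * psz
    df <- df[, c("fiber_id", "x", "y", "length_px", "length_um",
                 "thickness_px", "width_px", "angle_deg", "intensity_mean",
                 "straightness", "alignment", "n_neighbor_fibers")]
  } else {
    df <- df[, cols]
  }
  rownames(df) <- NULL
  df
}
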
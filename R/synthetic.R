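#' Specify one synthetic fiber
#'
#' A fiber is a stroked parametric curve: straight segment, sinusoid, or
#' circular arc, with a stroke width, an orientation, a peak intensity and
#' a cross-profile (flat or Gaussian).  The analytic arc length is
#' computed in closed form (straight, arc) or by adaptive quadrature of
#' the parametric speed (sinusoid) and stored as ground truth.
#'
#' Local curve frames are centered on `center` and rotated by `theta_deg`
#' in the Cartesian sense (the chord of every curve is horizontal in the
#' local frame, so the rendered chord orientation equals `theta_deg`).
#'
#' @param kind `"straight"`, `"sinusoid"` or `"arc"`.
#' @param center `c(x, y)` raster pixel coordinates of the curve center.
#' @param length chord-axis extent in pixels (straight: the full length;
#'   sinusoid: the extent along the axis).
#' @param width stroke width in pixels (full width).
#' @param theta_deg orientation of the chord in degrees, \[0, 180).
#' @param peak peak intensity, 0--255.
#' @param profile `"flat"` or `"gaussian"` cross-profile.
#' @param profile_sigma Gaussian cross-profile sigma (default `width / 4`).
#' @param amplitude,period sinusoid amplitude and period, pixels.
#' @param radius,arc_angle_deg circle radius and subtended angle for
#'   `kind = "arc"`.
#' @return object of class `fiber_spec` with element `arc_length`.
#' @export
fiber_spec <- function(kind = c("straight", "sinusoid", "arc"),
                       center = c(0, 0), length = 100, width = 5,
                       theta_deg = 0, peak = 200,
                       profile = c("flat", "gaussian"),
                       profile_sigma = NULL,
                       amplitude = 10, period = 50,
                       radius = 50, arc_angle_deg = 90) {
  kind <- match.arg(kind)
  profile <- match.arg(profile)
  if (width <= 0) stop("width must be positive")
  arc_length <- switch(kind,
    straight = length,
    sinusoid = {
      om <- 2 * pi / period
      f <- function(t) sqrt(1 + (amplitude * om * cos(om * t))^2)
      stats::integrate(f, 0, length, rel.tol = 1e-10,
                       subdivisions = 1000L)$value
    },
    arc = radius * arc_angle_deg * pi / 180
  )
  structure(
    list(kind = kind, center = center, length = length, width = width,
         theta_deg = theta_deg, peak = peak, profile = profile,
         profile_sigma = profile_sigma %||% (width / 4),
         amplitude = amplitude, period = period,
         radius = radius, arc_angle_deg = arc_angle_deg,
         arc_length = arc_length),
    class = "fiber_spec"
  )
}

#' Dense sample points along a fiber's center curve
#'
#' @param spec a [fiber_spec].
#' @param step arc-length sampling step, pixels.
#' @return n x 2 matrix of raster (x, y) coordinates.
#' @export
curve_points <- function(spec, step = 0.25) {
  pts <- switch(spec$kind,
    straight = {
      t <- seq(-spec$length / 2, spec$length / 2, by = step)
      cbind(t, 0)
    },
    sinusoid = {
      t <- seq(0, spec$length, by = step)
      om <- 2 * pi / spec$period
      cbind(t - spec$length / 2, spec$amplitude * sin(om * t))
    },
    arc = {
      phi <- spec$arc_angle_deg * pi / 180
      u <- seq(-phi / 2, phi / 2, by = step / spec$radius)
      cbind(spec$radius * sin(u), spec$radius * (cos(u) - 1))
    })
  th <- spec$theta_deg * pi / 180
  # rotate in Cartesian sense, then flip y back into the raster frame
  x <- spec$center[1] + pts[, 1] * cos(th) - pts[, 2] * sin(th)
  y <- spec$center[2] - (pts[, 1] * sin(th) + pts[, 2] * cos(th))
  cbind(x = x, y = y)
}

#' Render a synthetic fiber scene with exact ground truth
#'
#' Fibers are stroked onto a constant background (pixel intensity = peak
#' at distance <= width/2 from the center curve, flat or Gaussian
#' fall-off), composed by maximum, then additive Gaussian noise is applied
#' and the result clipped to \[0, 255\] and quantized to 8 bit.  The truth
#' object records every fiber's spec, its exact rasterized footprint and a
#' footprint label image.
#'
#' @param specs list of [fiber_spec].
#' @param image_size `c(width, height)` pixels.
#' @param background background intensity, 0--255.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param seed RNG seed; identical seeds give identical scenes.
#' @return list with `plane` (an [image_plane]) and `truth` (class
#'   `scene_truth`: `specs`, `footprints` list of pixel index vectors,
#'   `footprint_labels` matrix, `n_fibers`, scene parameters).
#' @export
render_scene <- function(specs, image_size = c(512, 512), background = 20,
                         noise_sigma = 10, seed = 1L) {
  w <- image_size[1]; h <- image_size[2]
  canvas <- matrix(background, h, w)
  label_img <- matrix(0L, h, w)
  footprints <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    pts <- curve_points(sp)
    half <- sp$width / 2
    if (any(pts[, "x"] < half | pts[, "x"] > w - 1 - half |
            pts[, "y"] < half | pts[, "y"] > h - 1 - half)) {
      stop(sprintf("fiber %d extends outside the image bounds", k))
    }
    bb_x <- floor(min(pts[, "x"]) - half - 1):ceiling(max(pts[, "x"]) + half + 1)
    bb_y <- floor(min(pts[, "y"]) - half - 1):ceiling(max(pts[, "y"]) + half + 1)
    bb_x <- bb_x[bb_x >= 0 & bb_x <= w - 1]
    bb_y <- bb_y[bb_y >= 0 & bb_y <= h - 1]
    dmin <- matrix(Inf, length(bb_y), length(bb_x))
    win <- ceiling(half) + 1L
    for (p in seq_len(nrow(pts))) {
      px <- pts[p, "x"]; py <- pts[p, "y"]
      xi <- which(abs(bb_x - px) <= win)
      yi <- which(abs(bb_y - py) <= win)
      if (length(xi) == 0 || length(yi) == 0) next
      dd <- sqrt(outer((bb_y[yi] - py)^2, (bb_x[xi] - px)^2, "+"))
      dmin[yi, xi] <- pmin(dmin[yi, xi], dd)
    }
    hit <- which(dmin <= half, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    gy <- bb_y[hit[, 1]] + 1L   # matrix rows (1-based)
    gx <- bb_x[hit[, 2]] + 1L
    lin <- gy + (gx - 1L) * h
    val <- if (sp$profile == "flat") rep(sp$peak, nrow(hit)) else {
      sp$peak * exp(-dmin[hit]^2 / (2 * sp$profile_sigma^2))
    }
    canvas[lin] <- pmax(canvas[lin], background + val)
    newpx <- label_img[lin] == 0L
    label_img[lin[newpx]] <- k
    footprints[[k]] <- sort(lin)
  }
  noisy <- with_seed(seed, canvas + stats::rnorm(length(canvas),
                                                 sd = noise_sigma))
  noisy <- round(pmin(pmax(noisy, 0), 255))
  plane <- image_plane(matrix(noisy, h, w))
  truth <- structure(
    list(specs = specs, footprints = footprints,
         footprint_labels = label_img, n_fibers = length(specs),
         image_size = image_size, background = background,
         noise_sigma = noise_sigma, seed = seed),
    class = "scene_truth"
  )
  list(plane = plane, truth = truth)
}

#' Place non-overlapping straight fibers at random
#'
#' Rejection sampling: fiber center segments are drawn uniformly and a
#' candidate is accepted only if every pairwise segment distance exceeds
#' `min_gap` plus the stroke half-widths, so rendered footprints never
#' touch and the scene's true fiber count is exact.
#'
#' @param n number of fibers.
#' @param image_size `c(width, height)`.
#' @param length_range,width_range uniform sampling ranges, pixels.
#' @param min_gap minimum clearance between fiber outlines, pixels.
#' @param peak peak intensity.
#' @param seed RNG seed.
#' @param max_tries rejection-sampling budget per fiber.
#' @return list of [fiber_spec].
#' @export
place_straight_fibers <- function(n, image_size = c(512, 512),
                                  length_range = c(40, 90),
                                  width_range = c(3, 6),
                                  min_gap = 8, peak = 200, seed = 1L,
                                  max_tries = 4000L) {
  w <- image_size[1]; h <- image_size[2]
  with_seed(seed, {
    specs <- list()
    ends <- list()
    halfw <- numeric(0)
    for (k in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        L <- stats::runif(1, length_range[1], length_range[2])
        wd <- stats::runif(1, width_range[1], width_range[2])
        th <- stats::runif(1, 0, 180)
        margin <- L / 2 + wd / 2 + 2
        cx <- stats::runif(1, margin, w - 1 - margin)
        cy <- stats::runif(1, margin, h - 1 - margin)
        thr <- th * pi / 180
        e1 <- c(cx - L / 2 * cos(thr), cy + L / 2 * sin(thr))
        e2 <- c(cx + L / 2 * cos(thr), cy - L / 2 * sin(thr))
        ok <- TRUE
        for (j in seq_along(ends)) {
          need <- min_gap + wd / 2 + halfw[j]
          if (segment_distance(e1, e2, ends[[j]][1:2], ends[[j]][3:4]) < need) {
            ok <- FALSE
            break
          }
        }
        if (ok) {
          specs[[k]] <- fiber_spec("straight", center = c(cx, cy),
                                   length = L, width = wd, theta_deg = th,
                                   peak = peak)
          ends[[k]] <- c(e1, e2)
          halfw[k] <- wd / 2
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf("could not place fiber %d of %d without overlap", k, n))
      }
    }
    specs
  })
}

#' Scatter cells uniformly within named rectangular regions
#'
#' @param regions named list of regions, each `list(xmin, xmax, ymin,
#'   ymax)` in pixels; regions must not overlap.
#' @param counts_per_class named list: for each region name, a named
#'   integer vector of class -> count.
#' @param seed RNG seed.
#' @return data.frame `cell_id`, `x`, `y`, `class_label`, `region` (the
#'   planted region membership, the ground-truth label).
#' @export
scatter_cells <- function(regions, counts_per_class, seed = 1L) {
  stopifnot(length(regions) > 0, !is.null(names(regions)))
  for (nm in names(regions)) {
    r <- regions[[nm]]
    if (r$xmax <= r$xmin || r$ymax <= r$ymin) {
      stop("region '", nm, "' has zero area")
    }
  }
  for (a in seq_along(regions)) {
    for (b in seq_len(a - 1L)) {
      ra <- regions[[a]]; rb <- regions[[b]]
      if (ra$xmin < rb$xmax && rb$xmin < ra$xmax &&
          ra$ymin < rb$ymax && rb$ymin < ra$ymax) {
        stop("regions '", names(regions)[b], "' and '", names(regions)[a],
             "' overlap")
      }
    }
  }
  with_seed(seed, {
    rows <- list()
    for (nm in names(regions)) {
      r <- regions[[nm]]
      cls <- counts_per_class[[nm]]
      for (cl in names(cls)) {
        nc <- cls[[cl]]
        if (nc > 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            x = stats::runif(nc, r$xmin, r$xmax),
            y = stats::runif(nc, r$ymin, r$ymax),
            class_label = cl, region = nm)
        }
      }
    }
    df <- do.call(rbind, rows)
    df <- cbind(cell_id = seq_len(nrow(df)), df)
    rownames(df) <- NULL
    df
  })
}

#' Generate the standard validation suite of synthetic scenes
#'
#' Four scene families with exact ground truth, written as 8-bit TIFF
#' images plus truth CSVs: a count-recovery grid (N disjoint fibers), a
#' feature-recovery grid (straight fibers over a length x width x
#' orientation grid), an alignment field (fiber positions and angles for
#' the isotropic and parallel closed-form limits), and a spatial-profile
#' scene (fiber-dense and fiber-free regions with scattered cells).
#'
#' @param outdir output directory (created if needed).
#' @param seed master seed; every scene derives its own seed from it.
#' @param counts fiber counts for the count-recovery family.
#' @return (invisibly) named list of the files written, grouped by family.
#' @export
make_benchmark_suite <- function(outdir, seed = 17L,
                                 counts = c(5, 10, 20, 50)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  # family 1: count recovery
  cdir <- file.path(outdir, "counts")
  dir.create(cdir, showWarnings = FALSE)
  for (n in counts) {
    sz <- if (n <= 20) c(512, 512) else c(900, 900)
    specs <- place_straight_fibers(n, image_size = sz, seed = seed + n)
    sc <- render_scene(specs, image_size = sz, background = 20,
                       noise_sigma = 15, seed = seed + n)
    img <- file.path(cdir, sprintf("scene_n%02d.tif", n))
    tiff::writeTIFF(sc$plane$pixels / 255, img, bits.per.sample = 8L)
    truth <- data.frame(
      fiber_id = seq_along(specs),
      x = vapply(specs, function(s) s$center[1], numeric(1)),
      y = vapply(specs, function(s) s$center[2], numeric(1)),
      length = vapply(specs, `[[`, numeric(1), "arc_length"),
      width = vapply(specs, `[[`, numeric(1), "width"),
      theta_deg = vapply(specs, `[[`, numeric(1), "theta_deg"))
    tcsv <- file.path(cdir, sprintf("truth_n%02d.csv", n))
    write_table_csv(truth, tcsv)
    manifest$counts <- c(manifest$counts, img, tcsv)
  }
  # family 2: feature recovery grid
  fdir <- file.path(outdir, "features")
  dir.create(fdir, showWarnings = FALSE)
  grid <- feature_grid_specs()
  for (gi in seq_along(grid)) {
    nm <- names(grid)[gi]
    sc <- render_scene(grid[[nm]]$specs, image_size = grid[[nm]]$image_size,
                       background = 20, noise_sigma = 10,
                       seed = seed + 100L + gi)
    img <- file.path(fdir, paste0(nm, ".tif"))
    tiff::writeTIFF(sc$plane$pixels / 255, img, bits.per.sample = 8L)
    write_table_csv(grid[[nm]]$truth, file.path(fdir, paste0(nm, ".csv")))
    manifest$features <- c(manifest$features, img)
  }
  # family 3: alignment fields (tables of positions/angles)
  adir <- file.path(outdir, "alignment")
  dir.create(adir, showWarnings = FALSE)
  iso <- isotropic_fiber_field(2500, field_size = 2000, seed = seed)
  write_table_csv(iso, file.path(adir, "isotropic.csv"))
  par <- iso
  par$angle_deg <- 42
  write_table_csv(par, file.path(adir, "parallel.csv"))
  manifest$alignment <- file.path(adir, c("isotropic.csv", "parallel.csv"))
  # family 4: spatial-profile scene
  sdir <- file.path(outdir, "spatial")
  dir.create(sdir, showWarnings = FALSE)
  sp <- planted_spatial_scene(seed = seed)
  img <- file.path(sdir, "scene.tif")
  tiff::writeTIFF(sp$scene$plane$pixels / 255, img, bits.per.sample = 8L)
  write_table_csv(sp$cells, file.path(sdir, "cells.csv"))
  manifest$spatial <- c(img, file.path(sdir, "cells.csv"))
  invisible(manifest)
}

# Straight-fiber grid used for feature-recovery validation:
# L x w x theta, one image per (L, w), six orientations per image.
feature_grid_specs <- function(lengths = c(50, 100, 200),
                               widths = c(3, 5, 7),
                               thetas = seq(0, 150, by = 30)) {
  out <- list()
  for (L in lengths) {
    for (w in widths) {
      cell <- L + 40
      ncol_ <- 3
      nrow_ <- ceiling(length(thetas) / ncol_)
      sz <- c(ncol_ * cell, nrow_ * cell)
      specs <- list()
      truth <- NULL
      for (i in seq_along(thetas)) {
        cx <- ((i - 1) %% ncol_) * cell + cell / 2
        cy <- ((i - 1) %/% ncol_) * cell + cell / 2
        specs[[i]] <- fiber_spec("straight", center = c(cx, cy), length = L,
                                 width = w, theta_deg = thetas[i],
                                 peak = 200)
        truth <- rbind(truth, data.frame(length = L, width = w,
                                         theta_deg = thetas[i],
                                         x = cx, y = cy))
      }
      out[[sprintf("L%03d_w%d", L, w)]] <-
        list(specs = specs, truth = truth, image_size = sz)
    }
  }
  out
}

# Random fiber reference points + orientations, uniform over the field
# and over [0, 180): the isotropic limit where mean pairwise alignment
# approaches E[cos(alpha)] = 2/pi.
isotropic_fiber_field <- function(n, field_size = 2000, seed = 1L) {
  with_seed(seed, data.frame(
    fiber_id = seq_len(n),
    x = stats::runif(n, 0, field_size),
    y = stats::runif(n, 0, field_size),
    angle_deg = stats::runif(n, 0, 180)))
}

# A scene with a fiber-dense left half and a fiber-free right half, plus
# tumor cells scattered over both halves (truth = region membership) and
# some immune cells.  Used to validate planted-structure recovery by
# profile clustering.
planted_spatial_scene <- function(image_size = c(600, 300), n_fibers = 40,
                                  n_tumor_per_side = 60, n_immune = 40,
                                  seed = 1L) {
  w <- image_size[1]; h <- image_size[2]
  specs <- place_straight_fibers(n_fibers, image_size = c(w / 2, h),
                                 length_range = c(30, 60),
                                 width_range = c(3, 5),
                                 min_gap = 4, seed = seed)
  scene <- render_scene(specs, image_size = image_size, background = 20,
                        noise_sigma = 12, seed = seed)
  margin <- 10
  cells <- scatter_cells(
    regions = list(
      dense = list(xmin = margin, xmax = w / 2 - margin,
                   ymin = margin, ymax = h - margin),
      empty = list(xmin = w / 2 + margin, xmax = w - margin,
                   ymin = margin, ymax = h - margin)),
    counts_per_class = list(
      dense = c(tumor = n_tumor_per_side, immune = ceiling(n_immune / 2)),
      empty = c(tumor = n_tumor_per_side, immune = floor(n_immune / 2))),
    seed = seed + 1L)
  list(scene = scene, cells = cells, specs = specs)
}
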
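#' Foreground-background separation by global thresholding
#'
#' Pixels with intensity greater than or equal to the threshold become
#' foreground.  `value = "otsu"` picks the threshold automatically by
#' Otsu's method on the 0--255 histogram.
#'
#' @param plane an [image_plane].
#' @param value numeric threshold in \[0, 255\], or `"otsu"`.
#' @return logical matrix, same shape as the plane.
#' @export
threshold_simple <- function(plane, value = "otsu") {
  stopifnot(inherits(plane, "image_plane"))
  px <- plane$pixels
  if (identical(value, "otsu") || identical(value, "auto")) {
    value <- EBImage::otsu(EBImage::Image(px / 255), range = c(0, 1)) * 255
  } else {
    if (!is_scalar_number(value) || value < 0 || value > 255) {
      stop("threshold value must be in [0, 255] or \"otsu\"")
    }
  }
  px >= value
}

# Gaussian and Gaussian-derivative separable kernels at scale sigma.
gauss_kernels <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  g1 <- -x / sigma^2 * g           # first derivative
  g2 <- (x^2 - sigma^2) / sigma^4 * g  # second derivative
  list(g = g, g1 = g1, g2 = g2)
}

#' Frangi vesselness response of an image
#'
#' Multiscale ridge detector for bright curvilinear structures (fibers,
#' vessels).  At each Gaussian scale the Hessian eigenvalues
#' \eqn{|\lambda_1| \le |\lambda_2|} feed the classical vesselness
#' \eqn{V = \exp(-R_b^2 / 2\beta^2)\,(1 - \exp(-S^2 / 2c^2))} with
#' \eqn{R_b = \lambda_1/\lambda_2}, \eqn{S = \sqrt{\lambda_1^2 +
#' \lambda_2^2}}, restricted to \eqn{\lambda_2 < 0} (bright ridges); the
#' response is \eqn{\sigma^2}-normalized and maximized over scales.
#'
#' @param plane an [image_plane].
#' @param sigmas positive Gaussian scales in pixels.
#' @param beta blob-ness sensitivity (default 0.5, the standard choice).
#' @return numeric matrix of the raw (un-normalized) vesselness response.
#' @export
frangi_vesselness <- function(plane, sigmas = c(1, 2, 3), beta = 0.5) {
  stopifnot(inherits(plane, "image_plane"))
  if (length(sigmas) == 0) stop("at least one sigma is required")
  if (any(sigmas <= 0)) stop("sigmas must be positive")
  px <- plane$pixels
  best <- matrix(0, nrow(px), ncol(px))
  if (diff(range(px)) == 0) return(best)  # flat image: no ridges
  for (s in sigmas) {
    k <- gauss_kernels(s)
    # separable Gaussian-derivative convolutions; kernel[row, col] = (y, x)
    hxx <- ebi_filter(px, outer(k$g, k$g2)) * s^2
    hyy <- ebi_filter(px, outer(k$g2, k$g)) * s^2
    hxy <- ebi_filter(px, outer(k$g1, k$g1)) * s^2
    half_tr <- (hxx + hyy) / 2
    disc <- sqrt(pmax(((hxx - hyy) / 2)^2 + hxy^2, 0))
    e1 <- half_tr + disc
    e2 <- half_tr - disc
    # order by magnitude: l1 small, l2 large
    swap <- abs(e1) > abs(e2)
    l1 <- ifelse(swap, e2, e1)
    l2 <- ifelse(swap, e1, e2)
    S2 <- l1^2 + l2^2
    c2 <- max(S2) / 4   # c = half the maximal Frobenius norm
    if (c2 == 0) next
    rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * c2)))
    v[l2 >= 0] <- 0   # bright-ridge polarity
    best <- pmax(best, v)
  }
  best
}

ebi_filter <- function(px, kernel) {
  as.matrix(EBImage::filter2(EBImage::Image(px), kernel,
                             boundary = "replicate"))
}

#' Foreground separation with the Frangi vesselness filter
#'
#' The multiscale vesselness response is min-max normalized to \[0, 1\]
#' per image and thresholded at `cutoff`.
#'
#' @inheritParams frangi_vesselness
#' @param cutoff cutoff in (0, 1\] on the normalized response.
#' @return logical matrix, same shape as the plane.
#' @export
threshold_frangi <- function(plane, sigmas = c(1, 2, 3), cutoff = 0.15) {
  if (!is_scalar_number(cutoff) || cutoff <= 0 || cutoff > 1) {
    stop("cutoff must lie in (0, 1]")
  }
  v <- frangi_vesselness(plane, sigmas)
  rng <- range(v)
  if (rng[2] == rng[1]) {
    return(matrix(FALSE, nrow(v), ncol(v)))
  }
  vn <- (v - rng[1]) / (rng[2] - rng[1])
  vn >= cutoff
}

#' Label connected foreground components as candidate fibers
#'
#' Components smaller than `min_size_px` pixels are removed; survivors are
#' relabeled consecutively from 1 in raster (column-major) order of their
#' first pixel.  Default connectivity is 8 so thin diagonal fibers do not
#' fragment.
#'
#' @param foreground logical matrix from a thresholding step.
#' @param connectivity 4 or 8.
#' @param min_size_px minimum component area in pixels.
#' @return object of class `fiber_mask`: list with integer matrix `labels`
#'   (0 = background) and `label_count`.
#' @export
label_components <- function(foreground, connectivity = 8L, min_size_px = 0L) {
  stopifnot(is.logical(foreground), is.matrix(foreground))
  stopifnot(connectivity %in% c(4L, 8L))
  h <- nrow(foreground)
  w <- ncol(foreground)
  labels <- matrix(0L, h, w)
  idx <- which(foreground)
  if (length(idx)) {
    rank_of <- integer(h * w)
    rank_of[idx] <- seq_along(idx)
    shifts <- list(c(0L, 1L), c(1L, 0L))
    if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
    edges <- list()
    for (s in shifts) {
      nb <- shift_mat(foreground, s[1], s[2], fill = FALSE)
      both <- which(foreground & nb)
      if (length(both)) {
        nb_idx <- both + s[1] + s[2] * h
        edges[[length(edges) + 1L]] <- cbind(rank_of[both], rank_of[nb_idx])
      }
    }
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    if (length(edges)) {
      g <- igraph::add_edges(g, t(do.call(rbind, edges)))
    }
    memb <- igraph::components(g)$membership
    sizes <- tabulate(memb)
    keep <- sizes >= min_size_px
    # relabel survivors consecutively in order of first pixel appearance
    new_id <- integer(length(sizes))
    first_seen <- memb[!duplicated(memb)]
    kept_order <- first_seen[keep[first_seen]]
    new_id[kept_order] <- seq_along(kept_order)
    labels[idx] <- new_id[memb]
  }
  structure(list(labels = labels, label_count = max(labels)),
            class = "fiber_mask")
}

#' @export
print.fiber_mask <- function(x, ...) {
  cat(sprintf("<fiber_mask> %d x %d px, %d labeled fibers\n",
              ncol(x$labels), nrow(x$labels), x$label_count))
  invisible(x)
}

#' Topology-preserving thinning of one component to a 1-px skeleton
#'
#' Guo-Hall iterative thinning: border pixels are peeled in two
#' alternating subiterations until the component is one pixel wide, which
#' preserves 8-connectivity and endpoints and, unlike Zhang-Suen, does not
#' over-erode even-width diagonal strokes.  If thinning annihilates a tiny
#' blob completely, its innermost pixel (maximal distance to the
#' background) is kept so every component yields a non-empty skeleton.
#'
#' @param mask logical matrix containing one connected component.
#' @return logical matrix of skeleton pixels, same shape as `mask`.
#' @export
skeletonize_component <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask)) stop("cannot skeletonize an empty component")
  p <- mask
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      del <- gh_deletable(p, sub)
      if (any(del)) {
        p[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (!any(p)) {
    dt <- as.matrix(EBImage::distmap(mask * 1))
    p[which.max(dt)] <- TRUE
  }
  p
}

# One Guo-Hall subiteration: logical matrix of pixels to delete.
# Neighbors P2..P9 clockwise from north.  C is the connectivity number,
# N the minimum of the two 4-pair neighbor counts, m the subiteration
# direction condition.
gh_deletable <- function(p, sub) {
  pn <- p * 1L
  P2 <- shift_mat(pn, -1L,  0L); P3 <- shift_mat(pn, -1L,  1L)
  P4 <- shift_mat(pn,  0L,  1L); P5 <- shift_mat(pn,  1L,  1L)
  P6 <- shift_mat(pn,  1L,  0L); P7 <- shift_mat(pn,  1L, -1L)
  P8 <- shift_mat(pn,  0L, -1L); P9 <- shift_mat(pn, -1L, -1L)
  C <- ((1L - P2) & (P3 | P4)) + ((1L - P4) & (P5 | P6)) +
       ((1L - P6) & (P7 | P8)) + ((1L - P8) & (P9 | P2))
  N1 <- (P9 | P2) + (P3 | P4) + (P5 | P6) + (P7 | P8)
  N2 <- (P2 | P3) + (P4 | P5) + (P6 | P7) + (P8 | P9)
  N <- pmin(N1, N2)
  m <- if (sub == 1L) ((P6 | P7 | (1L - P9)) & P8)
       else ((P2 | P3 | (1L - P5)) & P4)
  p & (C == 1L) & (N >= 2L) & (N <= 3L) & (m == 0L)
}

# Build the weighted 8-neighbor pixel graph of a skeleton.
# Nodes are skeleton pixels (0-based y,x); edges weigh 1 orthogonal,
# sqrt(2) diagonal.
skeleton_graph <- function(coords) {
  n <- nrow(coords)
  key <- coords[, "y"] * 1e6 + coords[, "x"]
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  shifts <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  for (k in 1:4) {
    dy <- shifts[k, 1]; dx <- shifts[k, 2]
    j <- match((coords[, "y"] + dy) * 1e6 + (coords[, "x"] + dx), key)
    hit <- !is.na(j)
    if (any(hit)) {
      from <- c(from, which(hit)); to <- c(to, j[hit])
      wt <- c(wt, rep(if (dx != 0 && dy != 0) sqrt(2) else 1, sum(hit)))
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to))
    igraph::E(g)$weight <- wt
  }
  list(graph = g, coords = coords)
}

#' Prune a raw skeleton to its single longest geodesic path
#'
#' The skeleton pixels form a graph (8-neighbor edges, weight 1 orthogonal
#' and sqrt(2) diagonal).  Cycles, if any artifact loops survive thinning,
#' are first broken by a maximum-weight spanning tree; the returned fiber
#' curve is the longest geodesic path between two leaf pixels, so all side
#' branches and spikes are discarded and the result has exactly two
#' endpoints.  Among equal-length paths the one whose start endpoint is
#' smallest in (y, x) lexicographic order (then smallest end) is chosen,
#' making the output deterministic.
#'
#' @param skeleton logical matrix of skeleton pixels (one component), or a
#'   2-column matrix of 0-based (y, x) coordinates.
#' @param fiber_id id stored on the result.
#' @return object of class `fiber_skeleton`: list with `fiber_id`, `path`
#'   (ordered n x 2 matrix of 0-based y, x), `endpoints` (2 x 2 matrix),
#'   `n_pixels`, and `degenerate` (TRUE for a single-pixel skeleton).
#' @export
prune_to_longest_path <- function(skeleton, fiber_id = 1L) {
  coords <- if (is.logical(skeleton)) mask_coords(skeleton) else {
    stopifnot(is.matrix(skeleton), ncol(skeleton) == 2)
    m <- skeleton
    colnames(m) <- c("y", "x")
    m
  }
  if (nrow(coords) == 0) stop("cannot prune an empty skeleton")
  if (nrow(coords) == 1) {
    return(new_fiber_skeleton(fiber_id, coords, degenerate = TRUE))
  }
  sg <- skeleton_graph(coords)
  g <- sg$graph
  comp <- igraph::components(g)
  if (comp$no > 1) {
    # keep the largest fragment (ties: the one holding the smallest (y,x))
    sizes <- comp$csize
    cand <- which(sizes == max(sizes))
    pick <- cand[1]
    if (length(cand) > 1) {
      firsts <- vapply(cand, function(cc) {
        v <- which(comp$membership == cc)
        min(coords[v, "y"] * 1e6 + coords[v, "x"])
      }, numeric(1))
      pick <- cand[which.min(firsts)]
    }
    keep <- which(comp$membership == pick)
    coords <- coords[keep, , drop = FALSE]
    if (nrow(coords) == 1) {
      return(new_fiber_skeleton(fiber_id, coords, degenerate = TRUE))
    }
    sg <- skeleton_graph(coords)
    g <- sg$graph
  }
  if (igraph::ecount(g) >= igraph::vcount(g)) {
    # artifact loops: break cycles keeping maximal total edge weight
    w <- igraph::E(g)$weight
    g <- igraph::mst(g, weights = max(w) + 1 - w)
  }
  deg <- igraph::degree(g)
  leaves <- which(deg <= 1)
  D <- igraph::distances(g, v = leaves, to = leaves,
                         weights = igraph::E(g)$weight)
  dmax <- max(D)
  hits <- which(D >= dmax - 1e-9, arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  if (nrow(hits) == 0) hits <- matrix(c(1L, 1L), 1)  # single leaf (n == 1)
  lex <- function(v) coords[v, "y"] * 1e6 + coords[v, "x"]
  cand <- t(apply(hits, 1, function(h) {
    a <- leaves[h[1]]; b <- leaves[h[2]]
    if (lex(a) <= lex(b)) c(a, b) else c(b, a)
  }))
  ord <- order(lex(cand[, 1]), lex(cand[, 2]))
  best <- cand[ord[1], ]
  vp <- igraph::shortest_paths(g, from = best[1], to = best[2],
                               weights = igraph::E(g)$weight)$vpath[[1]]
  path <- coords[as.integer(vp), , drop = FALSE]
  new_fiber_skeleton(fiber_id, path, degenerate = nrow(path) < 2)
}

#' Trim terminal staircase hooks from a pruned fiber curve
#'
#' Iterative thinning can leave a 1-px spur at a fiber tip that the
#' longest geodesic path wraps around, ending with a step that reverses
#' direction (negative dot product with the previous step).  Such
#' backtracking terminal pixels are artifacts of digitization, not fiber
#' shape; this step removes them from both ends.  Genuine curvature is
#' untouched: an 8-connected rasterized curve turns at most 45 degrees
#' per step, never reversing.
#'
#' @param skeleton a `fiber_skeleton`.
#' @return a `fiber_skeleton` with hooks removed and endpoints updated.
#' @export
trim_path_hooks <- function(skeleton) {
  p <- skeleton$path
  repeat {
    n <- nrow(p)
    if (n < 3) break
    v0 <- p[n - 1, ] - p[n - 2, ]
    v1 <- p[n, ] - p[n - 1, ]
    if (sum(v0 * v1) < 0) {
      p <- p[-n, , drop = FALSE]
      next
    }
    w0 <- p[2, ] - p[3, ]
    w1 <- p[1, ] - p[2, ]
    if (sum(w0 * w1) < 0) {
      p <- p[-1, , drop = FALSE]
      next
    }
    break
  }
  new_fiber_skeleton(skeleton$fiber_id, p, degenerate = nrow(p) < 2)
}

new_fiber_skeleton <- function(fiber_id, path, degenerate = FALSE) {
  colnames(path) <- c("y", "x")
  structure(
    list(fiber_id = as.integer(fiber_id),
         path = path,
         endpoints = path[c(1L, nrow(path)), , drop = FALSE],
         n_pixels = nrow(path),
         degenerate = degenerate),
    class = "fiber_skeleton"
  )
}

#' @export
print.fiber_skeleton <- function(x, ...) {
  cat(sprintf("<fiber_skeleton> id %d, %d px%s\n", x$fiber_id, x$n_pixels,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Segment, skeletonize, prune and label all fibers in an image
#'
#' Full fiber-extraction pipeline: foreground separation (simple/Otsu or
#' Frangi thresholding, or a user-supplied mask), connected-component
#' labeling with a debris size filter, per-component thinning, and pruning
#' of each skeleton to a branch-free curve.  Fibers whose pruned curve is
#' shorter than `min_fiber_length_px` are dropped and their labels removed;
#' surviving labels are renumbered consecutively so the mask and skeleton
#' list stay mutually consistent.
#'
#' @param plane an [image_plane].
#' @param config a [run_config].
#' @param foreground optional precomputed logical foreground mask (use when
#'   foreground separation was done in other software).
#' @return object of class `fiber_segmentation`: list with `mask` (a
#'   `fiber_mask`) and `skeletons` (list of `fiber_skeleton`, one per
#'   label, ids matching mask labels).
#' @export
segment_fibers <- function(plane, config = run_config(), foreground = NULL) {
  stopifnot(inherits(plane, "image_plane"), inherits(config, "run_config"))
  if (is.null(foreground)) {
    foreground <- switch(config$threshold_method,
      otsu = threshold_simple(plane, "otsu"),
      fixed = threshold_simple(plane, config$threshold_value),
      frangi = threshold_frangi(plane, config$frangi_sigmas,
                                config$frangi_cutoff))
  }
  if (!identical(dim(foreground), dim(plane$pixels))) {
    stop("foreground mask shape does not match the image")
  }
  fm <- label_components(foreground, config$connectivity, config$min_size_px)
  labels <- fm$labels
  skeletons <- list()
  keep_ids <- integer(0)
  for (k in seq_len(fm$label_count)) {
    comp_idx <- which(labels == k)
    comp <- matrix(FALSE, nrow(labels), ncol(labels))
    comp[comp_idx] <- TRUE
    # crop to the bounding box (1-px pad) for speed, then shift back
    ij <- which(comp, arr.ind = TRUE)
    r0 <- max(1L, min(ij[, 1]) - 1L); r1 <- min(nrow(comp), max(ij[, 1]) + 1L)
    c0 <- max(1L, min(ij[, 2]) - 1L); c1 <- min(ncol(comp), max(ij[, 2]) + 1L)
    sk <- skeletonize_component(comp[r0:r1, c0:c1, drop = FALSE])
    coords <- mask_coords(sk)
    coords[, "y"] <- coords[, "y"] + (r0 - 1L)
    coords[, "x"] <- coords[, "x"] + (c0 - 1L)
    fs <- if (config$prune) {
      trim_path_hooks(prune_to_longest_path(coords, fiber_id = k))
    } else {
      new_fiber_skeleton(k, coords, degenerate = nrow(coords) < 2)
    }
    if (!fs$degenerate && fiber_length(fs) >= config$min_fiber_length_px) {
      keep_ids <- c(keep_ids, k)
      skeletons[[length(skeletons) + 1L]] <- fs
    }
  }
  # drop filtered labels and renumber survivors consecutively
  remap <- integer(fm$label_count)
  remap[keep_ids] <- seq_along(keep_ids)
  nz <- labels > 0L
  labels[nz] <- remap[labels[nz]]
  for (i in seq_along(skeletons)) skeletons[[i]]$fiber_id <- i
  structure(
    list(mask = structure(list(labels = labels,
                               label_count = length(keep_ids)),
                          class = "fiber_mask"),
         skeletons = skeletons),
    class = "fiber_segmentation"
  )
}

#' @export
print.fiber_segmentation <- function(x, ...) {
  cat(sprintf("<fiber_segmentation> %d fibers\n", x$mask$label_count))
  invisible(x)
}
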
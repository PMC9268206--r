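# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: plain double loops, dense Floyd-Warshall, and
# direct enumeration.

# All-pairs shortest-path lengths on a pixel set (0-based y,x rows) with
# 8-neighbor edges (1 orthogonal, sqrt(2) diagonal), by Floyd-Warshall.
oracle_geodesics <- function(coords) {
  n <- nrow(coords)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dy <- abs(coords[i, 1] - coords[j, 1])
      dx <- abs(coords[i, 2] - coords[j, 2])
      if (i != j && dy <= 1 && dx <= 1) {
        D[i, j] <- if (dy + dx == 2) sqrt(2) else 1
      }
    }
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      nd <- D[i, k] + D[k, ]
      upd <- nd < D[i, ]
      D[i, upd] <- nd[upd]
    }
  }
  D
}

# Longest geodesic (graph diameter) endpoints and length by exhaustive
# pair enumeration, with the package's declared tie rule: smallest
# (y, x)-lexicographic start endpoint, then smallest end.
oracle_longest_path <- function(coords) {
  D <- oracle_geodesics(coords)
  dmax <- max(D[is.finite(D)])
  lex <- coords[, 1] * 1e6 + coords[, 2]
  best <- NULL
  for (i in seq_len(nrow(coords))) {
    for (j in seq_len(nrow(coords))) {
      if (i == j || !is.finite(D[i, j])) next
      if (D[i, j] < dmax - 1e-9) next
      a <- if (lex[i] <= lex[j]) c(i, j) else c(j, i)
      if (is.null(best) ||
          lex[a[1]] < lex[best[1]] ||
          (lex[a[1]] == lex[best[1]] && lex[a[2]] < lex[best[2]])) {
        best <- a
      }
    }
  }
  list(length = dmax, start = coords[best[1], ], end = coords[best[2], ])
}

# Grow a random tree of pixels on a grid: each new pixel must touch
# exactly one existing pixel (8-adjacency), so the pixel graph is acyclic.
random_pixel_tree <- function(n_nodes, grid = 25L) {
  occ <- matrix(FALSE, grid, grid)
  start <- c(sample.int(grid - 2, 1) + 1L, sample.int(grid - 2, 1) + 1L)
  occ[start[1], start[2]] <- TRUE
  coords <- matrix(start, 1, 2)
  nbh <- as.matrix(expand.grid(dy = -1:1, dx = -1:1))
  nbh <- nbh[!(nbh[, 1] == 0 & nbh[, 2] == 0), ]
  tries <- 0
  while (nrow(coords) < n_nodes && tries < 40 * n_nodes) {
    tries <- tries + 1
    base <- coords[sample.int(nrow(coords), 1), ]
    step <- nbh[sample.int(8, 1), ]
    cand <- base + step
    if (any(cand < 2) || any(cand > grid - 1)) next
    if (occ[cand[1], cand[2]]) next
    # count occupied 8-neighbors of the candidate
    touch <- 0
    for (k in 1:8) {
      p <- cand + nbh[k, ]
      if (occ[p[1], p[2]]) touch <- touch + 1
    }
    if (touch != 1) next
    occ[cand[1], cand[2]] <- TRUE
    coords <- rbind(coords, cand)
  }
  m <- coords - 1L  # 0-based
  colnames(m) <- c("y", "x")
  m
}

# Exhaustive double-loop neighbor counts (closed disc, self excluded).
oracle_counts <- function(proc, targ, radius) {
  out <- integer(nrow(proc))
  for (i in seq_len(nrow(proc))) {
    cnt <- 0L
    for (j in seq_len(nrow(targ))) {
      if (proc$kind[i] == targ$kind[j] &&
          proc$object_id[i] == targ$object_id[j]) next
      d <- sqrt((proc$x[i] - targ$x[j])^2 + (proc$y[i] - targ$y[j])^2)
      if (d <= radius) cnt <- cnt + 1L
    }
    out[i] <- cnt
  }
  out
}

# Exhaustive nearest-target scan (self excluded, ties -> smallest id).
oracle_nearest <- function(proc, targ) {
  dist <- rep(NA_real_, nrow(proc))
  id <- rep(NA_integer_, nrow(proc))
  for (i in seq_len(nrow(proc))) {
    best <- Inf
    bid <- NA_integer_
    for (j in seq_len(nrow(targ))) {
      if (proc$kind[i] == targ$kind[j] &&
          proc$object_id[i] == targ$object_id[j]) next
      d <- sqrt((proc$x[i] - targ$x[j])^2 + (proc$y[i] - targ$y[j])^2)
      if (d < best - 1e-12 ||
          (abs(d - best) <= 1e-12 && !is.na(bid) &&
           targ$object_id[j] < bid)) {
        best <- d
        bid <- targ$object_id[j]
      }
    }
    if (is.finite(best)) {
      dist[i] <- best
      id[i] <- bid
    }
  }
  data.frame(distance = dist, target_id = id)
}

# Random spatial-object table on a square field.
random_objects <- function(n, kind, field = 1000, id_offset = 0L) {
  data.frame(kind = kind, object_id = seq_len(n) + id_offset,
             x = runif(n, 0, field), y = runif(n, 0, field),
             class_label = kind)
}

# Render one straight fiber in a tight frame and return scene + config.
single_fiber_scene <- function(L, w, theta, peak = 200, noise = 8,
                               seed = 1L) {
  m <- L / 2 + w + 12
  sz <- ceiling(c(2 * m, 2 * m))
  sp <- fiber_spec("straight", center = c(m, m), length = L, width = w,
                   theta_deg = theta, peak = peak)
  render_scene(list(sp), image_size = sz, background = 20,
               noise_sigma = noise, seed = seed)
}

fixed_config <- function(value = 110, ...) {
  run_config(threshold_method = "fixed", threshold_value = value, ...)
}
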
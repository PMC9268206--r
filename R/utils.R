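# Internal helpers shared across modules.

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Shift a matrix by (dy, dx), filling exposed borders with `fill`.
shift_mat <- function(m, dy, dx, fill = 0L) {
  h <- nrow(m)
  w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1, 1 - dy):min(h, h - dy)
  xs <- max(1, 1 - dx):min(w, w - dx)
  if (length(ys) && length(xs)) {
    out[ys, xs] <- m[ys + dy, xs + dx]
  }
  out
}

# 0-based (y, x) pixel coordinates of TRUE entries, raster convention
# (x = column rightward, y = row downward).
mask_coords <- function(mask) {
  ij <- which(mask, arr.ind = TRUE)
  cbind(y = ij[, 1] - 1L, x = ij[, 2] - 1L)
}

# Matrix index pairs for 0-based (y, x) coordinates.
coord_index <- function(yx) {
  cbind(yx[, 1] + 1L, yx[, 2] + 1L)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimum distance between two 2-D segments p1-p2 and q1-q2 (each length-2
# numeric c(x, y)).  Used by the non-overlap placement sampler.
segment_distance <- function(p1, p2, q1, q2) {
  point_seg <- function(p, a, b) {
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
    sqrt(sum((a + t * ab - p)^2))
  }
  seg_intersect <- function(p1, p2, q1, q2) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
    d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
    (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
       ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
  }
  if (seg_intersect(p1, p2, q1, q2)) return(0)
  min(point_seg(p1, q1, q2), point_seg(p2, q1, q2),
      point_seg(q1, p1, p2), point_seg(q2, p1, p2))
}
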
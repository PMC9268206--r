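#' Build a unified spatial-object table from cells and fibers
#'
#' Cells and fibers live in one coordinate frame; an object is identified
#' by (kind, id) so a cell and a fiber may share a numeric id without
#' colliding.  Fibers contribute their reference point (skeleton centroid)
#' as position and `"fiber"` as class.
#'
#' @param cells cell table (data.frame with `cell_id`, `x`, `y`,
#'   `class_label`), or `NULL`.
#' @param fibers fiber table from [build_fiber_table], or `NULL`.
#' @return data.frame with `kind`, `object_id`, `x`, `y`, `class_label`.
#' @export
spatial_objects <- function(cells = NULL, fibers = NULL) {
  parts <- list()
  if (!is.null(cells) && nrow(cells)) {
    parts$cells <- data.frame(kind = "cell",
                              object_id = as.integer(cells$cell_id),
                              x = cells$x, y = cells$y,
                              class_label = as.character(cells$class_label))
  }
  if (!is.null(fibers) && nrow(fibers)) {
    parts$fibers <- data.frame(kind = "fiber",
                               object_id = as.integer(fibers$fiber_id),
                               x = fibers$x, y = fibers$y,
                               class_label = "fiber")
  }
  if (length(parts) == 0) {
    return(data.frame(kind = character(0), object_id = integer(0),
                      x = numeric(0), y = numeric(0),
                      class_label = character(0)))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# Pairwise Euclidean distance matrix between two object tables
# (rows of `a` x rows of `b`), vectorized.
object_distances <- function(a, b) {
  dx <- outer(a$x, b$x, "-")
  dy <- outer(a$y, b$y, "-")
  sqrt(dx^2 + dy^2)
}

# TRUE where row i of `a` and column j of `b` are the same object.
self_match <- function(a, b) {
  outer(paste(a$kind, a$object_id), paste(b$kind, b$object_id), "==")
}

#' Count target objects inside each processing object's neighborhood
#'
#' The "number" mode of spatial analysis: for every processing object,
#' the number of target objects whose center lies within the closed disc
#' of radius `radius_px` (boundary objects at distance exactly equal to
#' the radius are counted).  An object never counts itself.
#'
#' @param processing,targets spatial-object tables ([spatial_objects]
#'   rows, or any data.frame with `kind`, `object_id`, `x`, `y`).
#' @param radius_px neighborhood radius, pixels.
#' @return integer vector of counts, one per processing object.
#' @export
count_in_outline <- function(processing, targets, radius_px) {
  stopifnot(radius_px > 0)
  if (nrow(processing) == 0) return(integer(0))
  if (nrow(targets) == 0) return(integer(nrow(processing)))
  d <- object_distances(processing, targets)
  inside <- d <= radius_px & !self_match(processing, targets)
  as.integer(rowSums(inside))
}

#' Distance from each processing object to its nearest target
#'
#' The "distance" mode of spatial analysis, e.g. distance from a tumor
#' cell to the closest T-cell.  Self-matches are excluded; ties are broken
#' by the smallest target id.
#'
#' @param processing,targets spatial-object tables.
#' @param target_class restrict targets to this class label (optional).
#' @return data.frame with `distance` and `target_id` per processing
#'   object; both `NA` when no eligible target exists.
#' @export
nearest_distance <- function(processing, targets, target_class = NULL) {
  if (!is.null(target_class)) {
    targets <- targets[targets$class_label == target_class, , drop = FALSE]
  }
  n <- nrow(processing)
  out <- data.frame(distance = rep(NA_real_, n),
                    target_id = rep(NA_integer_, n))
  if (n == 0 || nrow(targets) == 0) return(out)
  targets <- targets[order(targets$object_id), , drop = FALSE]
  d <- object_distances(processing, targets)
  d[self_match(processing, targets)] <- Inf
  j <- apply(d, 1, which.min)  # first minimum = smallest id after ordering
  best <- d[cbind(seq_len(n), j)]
  ok <- is.finite(best)
  out$distance[ok] <- best[ok]
  out$target_id[ok] <- targets$object_id[j[ok]]
  out
}

#' Spatial neighborhood profiles for processing objects
#'
#' For every processing object (by default every cell of
#' `processing_class`), counts the neighboring cells of each class and the
#' neighboring fibers within the neighborhood outline, aggregates the
#' selected geometric features of those fibers, and optionally records
#' nearest-object distances per target class.  This is the join of the
#' single-cell and single-fiber tables in a spatially dependent manner.
#'
#' @param cells cell table (`cell_id`, `x`, `y`, `class_label`).
#' @param fibers fiber table from [build_fiber_table] (may be `NULL`).
#' @param config a [run_config]; `neighborhood_radius_px` sets the outline.
#' @param processing_class cell class used as processing objects
#'   (`NULL` = all cells).
#' @param count_classes cell classes to count (`NULL` = all present).
#' @param fiber_features fiber-table columns aggregated over neighboring
#'   fibers (mean, prefixed `mean_NF_`).
#' @param nearest_classes classes for which nearest-distance columns
#'   (`dist_<class>`) are added; may include `"fiber"`.
#' @param image_size optional `c(width, height)`: adds a `near_border`
#'   flag for objects closer than the radius to the image border (their
#'   outlines are truncated; no correction is applied).
#' @return data.frame, one row per processing object, deterministic order
#'   by cell id.
#' @export
build_profiles <- function(cells, fibers = NULL, config = run_config(),
                           processing_class = NULL,
                           count_classes = NULL,
                           fiber_features = c("length_px", "thickness_px",
                                              "straightness", "alignment"),
                           nearest_classes = character(0),
                           image_size = NULL) {
  radius <- config$neighborhood_radius_px
  objects <- spatial_objects(cells, fibers)
  cell_obj <- objects[objects$kind == "cell", , drop = FALSE]
  fiber_obj <- objects[objects$kind == "fiber", , drop = FALSE]
  proc <- if (is.null(processing_class)) cell_obj else {
    cell_obj[cell_obj$class_label %in% processing_class, , drop = FALSE]
  }
  proc <- proc[order(proc$object_id), , drop = FALSE]
  out <- data.frame(object_id = proc$object_id, kind = proc$kind,
                    x = proc$x, y = proc$y, class_label = proc$class_label)
  if (is.null(count_classes)) {
    count_classes <- sort(unique(cell_obj$class_label))
  }
  for (cl in count_classes) {
    tgt <- cell_obj[cell_obj$class_label == cl, , drop = FALSE]
    out[[paste0("n_", gsub("[^[:alnum:]]+", "_", cl))]] <-
      count_in_outline(proc, tgt, radius)
  }
  out$n_fibers <- count_in_outline(proc, fiber_obj, radius)
  if (!is.null(fibers) && nrow(fiber_obj)) {
    d <- object_distances(proc, fiber_obj)
    inside <- d <= radius
    fib_sorted <- fibers[match(fiber_obj$object_id, fibers$fiber_id), ,
                         drop = FALSE]
    for (ft in intersect(fiber_features, names(fib_sorted))) {
      vals <- fib_sorted[[ft]]
      out[[paste0("mean_NF_", sub("_px$", "", ft))]] <-
        vapply(seq_len(nrow(proc)), function(i) {
          v <- vals[inside[i, ]]
          v <- v[!is.na(v)]
          if (length(v)) mean(v) else NA_real_
        }, numeric(1))
    }
  } else {
    for (ft in fiber_features) {
      out[[paste0("mean_NF_", sub("_px$", "", ft))]] <-
        rep(NA_real_, nrow(proc))
    }
  }
  all_obj <- rbind(cell_obj, fiber_obj)
  for (cl in nearest_classes) {
    nd <- nearest_distance(proc, all_obj, target_class = cl)
    key <- gsub("[^[:alnum:]]+", "_", cl)
    out[[paste0("dist_", key)]] <- nd$distance
    out[[paste0("nearest_", key, "_id")]] <- nd$target_id
  }
  if (!is.null(image_size)) {
    out$near_border <- out$x < radius | out$y < radius |
      out$x > image_size[1] - 1 - radius | out$y > image_size[2] - 1 - radius
  }
  rownames(out) <- NULL
  out
}

#' Ward clustering of spatial profiles
#'
#' Hierarchical agglomerative clustering (Ward linkage on Euclidean
#' distances) of per-object neighborhood profiles.  Features are z-score
#' standardized first; columns containing missing aggregates get the
#' missing entries set to 0 after standardization plus a companion 0/1
#' presence column, so "no neighbors" is informative rather than silently
#' imputed to the mean.
#'
#' @param profiles data.frame from [build_profiles].
#' @param k number of clusters to cut the dendrogram into.
#' @param features columns to cluster on (`NULL` = all numeric profile
#'   columns except ids/coordinates).
#' @return integer vector of cluster labels (1..k), named by object id;
#'   the `hclust` tree is attached as attribute `"tree"`.
#' @export
cluster_profiles <- function(profiles, k, features = NULL) {
  stopifnot(nrow(profiles) >= 2)
  if (k > nrow(profiles)) stop("k exceeds the number of profiles")
  if (is.null(features)) {
    drop <- c("object_id", "kind", "x", "y", "class_label", "near_border")
    features <- setdiff(names(profiles)[vapply(profiles, is.numeric,
                                               logical(1))], drop)
    features <- grep("^nearest_.*_id$", features, value = TRUE, invert = TRUE)
  }
  X <- as.matrix(profiles[, features, drop = FALSE])
  Xs <- apply(X, 2, function(col) {
    obs <- col[!is.na(col)]
    s <- stats::sd(obs)
    z <- if (is.na(s) || s == 0) rep(0, length(col)) else {
      (col - mean(obs)) / s
    }
    z[is.na(col)] <- 0
    z
  })
  flags <- X[, colSums(is.na(X)) > 0, drop = FALSE]
  if (ncol(flags)) {
    present <- 1 - is.na(flags)
    colnames(present) <- paste0("has_", colnames(flags))
    Xs <- cbind(Xs, present)
  }
  tree <- stats::hclust(stats::dist(Xs), method = "ward.D2")
  labels <- stats::cutree(tree, k = k)
  names(labels) <- profiles$object_id
  attr(labels, "tree") <- tree
  labels
}
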
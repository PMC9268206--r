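#' Build a validated run configuration
#'
#' Central container for every tunable of the pipeline.  All lengths are in
#' pixels unless a `_um` suffix says otherwise; micrometer radii require
#' `pixel_size_um` to convert.
#'
#' @param threshold_method one of `"otsu"`, `"fixed"`, `"frangi"`.
#' @param threshold_value intensity cutoff in \[0, 255\] for
#'   `threshold_method = "fixed"`.
#' @param frangi_sigmas ascending positive Gaussian scales (px) for the
#'   vesselness filter; match the expected fiber half-widths.
#' @param frangi_cutoff cutoff in (0, 1\] on the min-max normalized
#'   vesselness response.
#' @param min_size_px connected components below this pixel area are
#'   discarded as debris before skeletonization.
#' @param min_fiber_length_px fibers whose pruned skeleton is shorter are
#'   dropped.
#' @param prune reduce each skeleton to its single longest geodesic path.
#' @param connectivity pixel connectivity for labeling, 4 or 8.
#' @param neighborhood_radius_px radius of the neighborhood outline used by
#'   the spatial module ("number" mode), pixels.
#' @param neighborhood_radius_um alternative radius in micrometers
#'   (converted via `pixel_size_um`; an error to use without it).
#' @param alignment_radius_px neighbor radius for the per-fiber alignment
#'   feature (independent of the spatial-analysis radius).
#' @param fiber_point_mode reference point of a fiber for spatial queries:
#'   `"centroid"` (skeleton centroid) or `"skeleton"` (nearest skeleton
#'   pixel).
#' @param channel 1-based channel/page index for multichannel images.
#' @param pixel_size_um physical pixel size, micrometers (optional).
#' @param random_seed seed for all randomized steps.
#' @return an object of class `run_config`.
#' @export
run_config <- function(threshold_method = c("otsu", "fixed", "frangi"),
                       threshold_value = 128,
                       frangi_sigmas = c(1, 2, 3),
                       frangi_cutoff = 0.15,
                       min_size_px = 20,
                       min_fiber_length_px = 10,
                       prune = TRUE,
                       connectivity = 8L,
                       neighborhood_radius_px = 100,
                       neighborhood_radius_um = NULL,
                       alignment_radius_px = 100,
                       fiber_point_mode = c("centroid", "skeleton"),
                       channel = 1L,
                       pixel_size_um = NULL,
                       random_seed = 1L) {
  threshold_method <- match.arg(threshold_method)
  fiber_point_mode <- match.arg(fiber_point_mode)
  stopifnot(connectivity %in% c(4L, 8L))
  if (!is.null(neighborhood_radius_um)) {
    if (is.null(pixel_size_um)) {
      stop("neighborhood_radius_um requires pixel_size_um to be set")
    }
    neighborhood_radius_px <- neighborhood_radius_um / pixel_size_um
  }
  if (neighborhood_radius_px <= 0) stop("neighborhood radius must be > 0")
  if (alignment_radius_px <= 0) stop("alignment radius must be > 0")
  if (length(frangi_sigmas) == 0 || any(frangi_sigmas <= 0) ||
      is.unsorted(frangi_sigmas, strictly = FALSE)) {
    stop("frangi_sigmas must be positive and ascending")
  }
  if (min_fiber_length_px < 2) stop("min_fiber_length_px must be >= 2")
  if (min_size_px < 0) stop("min_size_px must be >= 0")
  if (threshold_method == "fixed" &&
      (threshold_value < 0 || threshold_value > 255)) {
    stop("threshold_value must lie in [0, 255]")
  }
  structure(
    list(threshold_method = threshold_method,
         threshold_value = threshold_value,
         frangi_sigmas = frangi_sigmas,
         frangi_cutoff = frangi_cutoff,
         min_size_px = min_size_px,
         min_fiber_length_px = min_fiber_length_px,
         prune = prune,
         connectivity = as.integer(connectivity),
         neighborhood_radius_px = neighborhood_radius_px,
         alignment_radius_px = alignment_radius_px,
         fiber_point_mode = fiber_point_mode,
         channel = as.integer(channel),
         pixel_size_um = pixel_size_um,
         random_seed = as.integer(random_seed)),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-24s %s\n", k,
                if (is.null(v)) "<unset>" else paste(v, collapse = ",")))
  }
  invisible(x)
}

#' Read a run configuration from a flat key = value file
#'
#' Lines are `key = value`; `#` starts a comment; numeric vectors are
#' comma-separated; booleans are `true`/`false`.  Unknown keys are an
#' error.  Keys not present keep their [run_config] defaults.
#'
#' @param path config file path.
#' @param overrides named list applied on top of the file (CLI flags).
#' @return a `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    raw <- trimws(kv[2])
    vals[[key]] <- parse_config_value(raw)
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

parse_config_value <- function(raw) {
  if (tolower(raw) %in% c("true", "false")) return(tolower(raw) == "true")
  parts <- trimws(strsplit(raw, ",", fixed = TRUE)[[1]])
  num <- suppressWarnings(as.numeric(parts))
  if (!any(is.na(num))) return(num)
  raw
}

#' Write a run configuration to a flat key = value file
#' @param config a `run_config`.
#' @param path destination path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  keep <- !vapply(config, is.null, logical(1))
  lines <- vapply(names(config)[keep], function(k) {
    v <- config[[k]]
    if (is.logical(v)) v <- tolower(as.character(v))
    sprintf("%s = %s", k, paste(v, collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
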
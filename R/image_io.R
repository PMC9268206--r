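#' Construct an image plane
#'
#' An image plane is the package's in-memory representation of one 2-D
#' grayscale channel: a numeric matrix of intensities on the 0--255 scale
#' plus optional physical pixel size.  Matrix rows are image rows (y,
#' increasing downward), columns are image columns (x, increasing
#' rightward); all pixel coordinates elsewhere in the package are 0-based
#' in this frame.
#'
#' @param pixels numeric matrix of finite, non-negative intensities.
#' @param pixel_size_um optional physical size of one pixel, micrometers.
#' @param channel_name optional label for the source channel.
#' @return an object of class `image_plane`.
#' @export
image_plane <- function(pixels, pixel_size_um = NULL, channel_name = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix (one 2-D channel)")
  }
  if (any(!is.finite(pixels))) stop("image intensities must be finite")
  if (any(pixels < 0)) stop("image intensities must be non-negative")
  if (!is.null(pixel_size_um)) {
    if (!is_scalar_number(pixel_size_um) || pixel_size_um <= 0) {
      stop("`pixel_size_um` must be a single positive number")
    }
  }
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         channel_name = channel_name),
    class = "image_plane"
  )
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane> %d x %d px, intensity range [%g, %g]%s\n",
              ncol(x$pixels), nrow(x$pixels),
              min(x$pixels), max(x$pixels),
              if (is.null(x$pixel_size_um)) ""
              else sprintf(", %g um/px", x$pixel_size_um)))
  invisible(x)
}

#' @export
dim.image_plane <- function(x) dim(x$pixels)

# Bring raw pixel data onto the 0--255 working scale.  8-bit data passes
# through untouched; wider integer data and floating-point data are
# linearly min-max rescaled so the intensity feature's 0--255 contract
# always holds.  A constant image maps to all zeros.
rescale_to_8bit <- function(px) {
  rng <- range(px)
  integerish <- all(abs(px - round(px)) < 1e-9)
  if (integerish && rng[1] >= 0 && rng[2] <= 255) {
    return(px)
  }
  if (rng[2] == rng[1]) {
    return(array(0, dim = dim(px)))
  }
  (px - rng[1]) / (rng[2] - rng[1]) * 255
}

#' Read a grayscale image plane from TIFF or PNG
#'
#' Multipage TIFFs and multichannel arrays are reduced to one 2-D plane:
#' for a multipage TIFF the page given by `channel` is used (first page by
#' default); for an H x W x C array the slice `channel` is taken.  8-bit
#' intensities are preserved as read; 16-bit and floating-point data are
#' linearly min-max rescaled to 0--255.
#'
#' @param path file path; extension decides the reader (.tif/.tiff or .png).
#' @param channel 1-based page or channel index for multichannel input.
#' @param pixel_size_um optional micrometers per pixel, stored on the plane.
#' @return an [image_plane].
#' @export
read_image <- function(path, channel = 1L, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("image file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) > 1L) {
      if (channel < 1L || channel > length(pages)) {
        stop(sprintf("channel %d out of range: file has %d pages",
                     channel, length(pages)))
      }
      px <- pages[[channel]]
    } else {
      px <- pages[[1L]]
    }
  } else if (ext == "png") {
    px <- png::readPNG(path)
    # readPNG normalizes to [0, 1]; map onto the 8-bit working scale
    px <- px * 255
  } else {
    stop("unsupported image format: ", ext, " (TIFF or PNG expected)")
  }
  nd <- length(dim(px))
  if (nd == 3L) {
    if (channel < 1L || channel > dim(px)[3]) {
      stop(sprintf("channel %d out of range: image has %d channels",
                   channel, dim(px)[3]))
    }
    px <- px[, , channel]
  } else if (nd != 2L) {
    stop("image must have 2 or 3 dimensions, got ", nd)
  }
  px <- rescale_to_8bit(px)
  image_plane(matrix(as.numeric(px), nrow(px), ncol(px)),
              pixel_size_um = pixel_size_um,
              channel_name = as.character(channel))
}

#' Write a labeled fiber mask as single-channel TIFF
#'
#' Labels up to 65535 are stored as 16-bit, larger as 32-bit float.
#'
#' @param mask a `fiber_mask` (see [label_components]) or integer matrix.
#' @param path output .tif path.
#' @export
write_mask <- function(mask, path) {
  labels <- if (inherits(mask, "fiber_mask")) mask$labels else mask
  mx <- max(labels)
  if (mx <= 65535) {
    tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  } else {
    tiff::writeTIFF(labels / mx, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read a labeled mask written by [write_mask]
#' @param path .tif path.
#' @return a `fiber_mask`.
#' @export
read_mask <- function(path) {
  px <- tiff::readTIFF(path, as.is = TRUE)
  labels <- matrix(as.integer(round(px)), nrow(px), ncol(px))
  structure(list(labels = labels, label_count = max(labels)),
            class = "fiber_mask")
}

# Default header aliases for cell tables exported by third-party
# segmentation software (QuPath/KNIME-style pipelines vary in schema).
default_cell_aliases <- function() {
  list(
    cell_id = c("cell_id", "id", "cell id", "object_id", "object id", "label"),
    x = c("x", "x_px", "x coord", "cell x", "centroid_x", "centroid x"),
    y = c("y", "y_px", "y coord", "cell y", "centroid_y", "centroid y"),
    class_label = c("class_label", "class", "cell_type", "cell type",
                    "phenotype", "name")
  )
}

#' Read a single-cell table from CSV
#'
#' Expects a header with cell id, x/y pixel coordinates and a class label,
#' under any of the configured aliases (matched case-insensitively).  Extra
#' columns are passed through untouched.  Coordinates are pixels in the
#' image frame (0-based, x rightward, y downward).
#'
#' @param path CSV file path.
#' @param aliases named list mapping canonical column names (`cell_id`,
#'   `x`, `y`, `class_label`) to accepted header spellings.
#' @param image_size optional `c(width, height)`; when given, an
#'   `outside_image` logical column flags cells beyond the bounds.
#' @return data.frame with canonical columns first.
#' @export
read_cell_table <- function(path, aliases = default_cell_aliases(),
                            image_size = NULL) {
  if (!file.exists(path)) stop("cell table does not exist: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  lower <- tolower(trimws(names(df)))
  canon <- names(aliases)
  for (cn in canon) {
    hit <- which(lower %in% tolower(aliases[[cn]]))
    if (length(hit) == 0L) {
      stop(sprintf("cell table is missing required column '%s' (aliases: %s)",
                   cn, paste(aliases[[cn]], collapse = ", ")))
    }
    names(df)[hit[1L]] <- cn
  }
  for (cn in c("x", "y")) {
    if (!is.numeric(df[[cn]])) {
      bad <- suppressWarnings(as.numeric(df[[cn]]))
      if (any(is.na(bad))) {
        stop(sprintf("non-numeric value in coordinate column '%s'", cn))
      }
      df[[cn]] <- bad
    }
  }
  df$cell_id <- as.integer(df$cell_id)
  dup <- unique(df$cell_id[duplicated(df$cell_id)])
  if (length(dup)) {
    stop("duplicate cell_id in cell table: ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(as.character(df$class_label)))) {
    stop("class_label must be non-empty for every cell")
  }
  ord <- c(canon, setdiff(names(df), canon))
  df <- df[, ord, drop = FALSE]
  if (!is.null(image_size)) {
    df$outside_image <- df$x < 0 | df$y < 0 |
      df$x > image_size[1] - 1 | df$y > image_size[2] - 1
  }
  df
}

#' Write a fiber, profile or generic result table as CSV
#'
#' Values round-trip losslessly (full double precision); missing values are
#' written as empty cells, never as 0.
#'
#' @param records data.frame (may have zero rows; header is still written).
#' @param path output CSV path.
#' @export
write_table_csv <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_table_csv
#' @export
write_fiber_table <- function(records, path) write_table_csv(records, path)

#' @rdname write_table_csv
#' @export
write_profile_table <- function(profiles, path) write_table_csv(profiles, path)

#' Read back a CSV table written by [write_table_csv]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
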
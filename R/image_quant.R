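#' Segment nuclei by global Otsu thresholding
#'
#' Applies a two-class global Otsu threshold to the whole image, labels the
#' 8-connected foreground components, and discards components smaller than
#' `min_area`. Labels are assigned 1..K in raster-scan order of each
#' component's first pixel.
#'
#' @param img Numeric matrix of non-negative intensities.
#' @param min_area Minimum component area in pixels^2 (default 20, to
#'   suppress single-pixel noise objects).
#' @param log_space If `TRUE`, compute the Otsu threshold on
#'   `log1p`-transformed intensities (CellProfiler offers both variants);
#'   default `FALSE` uses raw intensities.
#' @return Integer label matrix (0 = background). A constant image yields
#'   zero nuclei with a warning rather than an error.
#' @export
segment_nuclei <- function(img, min_area = 20, log_space = FALSE) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  if (diff(range(img)) == 0) {
    warning("constant image: no nuclei segmented")
    return(matrix(0L, nrow(img), ncol(img)))
  }
  x <- if (log_space) log1p(img - min(img)) else img
  lo <- min(x); hi <- max(x)
  thr <- EBImage::otsu(EBImage::Image((x - lo) / (hi - lo))) * (hi - lo) + lo
  labels <- cpp_label_components(x > thr)
  filter_small_components(labels, min_area)
}

# Drop labelled components below min_area and relabel 1..K preserving
# raster-scan order of first pixels.
filter_small_components <- function(labels, min_area) {
  if (max(labels) == 0L) return(labels)
  sizes <- tabulate(labels)
  keep <- which(sizes >= min_area)
  if (length(keep) == 0L) return(matrix(0L, nrow(labels), ncol(labels)))
  remap <- integer(max(labels))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  nz <- labels > 0L
  out[nz] <- remap[labels[nz]]
  out
}

#' Expand nuclei to cells by a fixed distance
#'
#' Reproduces the CellProfiler-style secondary-object definition: every
#' background pixel within Euclidean distance `distance` of a nucleus is
#' assigned the label of the nearest nucleus (nearest nucleus pixel); exact
#' ties go to the lowest label; farther pixels stay background. Nucleus
#' pixels always retain their own label.
#'
#' @param nucleus_labels Integer label matrix from [segment_nuclei()].
#' @param distance Expansion distance in pixels (default 20, the fixed
#'   cell-border distance used for embryonic CNS sections).
#' @return An object of class `xy_cell_map`: list with `nucleus_labels`,
#'   `cell_labels`, `distance`.
#' @export
expand_cells <- function(nucleus_labels, distance = 20) {
  if (is.double(nucleus_labels)) storage.mode(nucleus_labels) <- "integer"
  stopifnot(is.matrix(nucleus_labels))
  if (!is.numeric(distance) || length(distance) != 1 || distance < 0) {
    stop("`distance` must be a single non-negative number")
  }
  cells <- cpp_expand_labels(nucleus_labels, distance)
  structure(list(nucleus_labels = nucleus_labels, cell_labels = cells,
                 distance = distance),
            class = "xy_cell_map")
}

#' Detect spots by top-hat filtering and thresholding
#'
#' White top-hat filtering with a disc structuring element removes smooth
#' background, then pixels above `threshold` are grouped into 8-connected
#' components; each component becomes one spot at its intensity-weighted
#' centroid (weights from the top-hat image), rounded to the nearest pixel.
#' The threshold is a deliberate per-channel manual parameter with no
#' default, mirroring per-sample manual thresholding.
#'
#' @param img Numeric intensity matrix for one gene channel.
#' @param gene Gene label to record for the detected spots.
#' @param tophat_radius Disc radius of the structuring element in pixels
#'   (at least 1); should exceed the spot radius.
#' @param threshold Intensity threshold on the top-hat image; must be > 0.
#' @return A [spot_table()] with `cell_id = NA` (unassigned).
#' @export
detect_spots <- function(img, gene, tophat_radius, threshold) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  if (tophat_radius < 1) stop("`tophat_radius` must be >= 1")
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("`threshold` must be > 0 (a non-positive threshold would call every pixel)")
  }
  brush <- EBImage::makeBrush(2L * as.integer(round(tophat_radius)) + 1L, "disc")
  th <- as.matrix(EBImage::whiteTopHat(EBImage::Image(img), brush))
  labels <- cpp_label_components(th > threshold)
  k <- max(labels)
  if (k == 0L) return(spot_table())
  idx <- which(labels > 0L)
  lab <- labels[idx]
  w <- th[idx]
  rr <- (idx - 1L) %% nrow(img) + 1L
  cc <- (idx - 1L) %/% nrow(img) + 1L
  wsum <- vapply(split(w, lab), sum, 0)
  r0 <- vapply(split(w * rr, lab), sum, 0) / wsum
  c0 <- vapply(split(w * cc, lab), sum, 0) / wsum
  spot_table(row = round(r0), col = round(c0), gene = gene)
}

#' Assign spots to parent cells
#'
#' Each spot receives the cell label at its pixel in the expanded cell-label
#' image; spots on background become unassigned (`NA`). Input row order is
#' preserved.
#'
#' @param spots A [spot_table()].
#' @param cells An `xy_cell_map` from [expand_cells()].
#' @return The spot table with `cell_id` filled in.
#' @export
assign_spots <- function(spots, cells) {
  assert_spot_table(spots)
  stopifnot(inherits(cells, "xy_cell_map"))
  lab <- cells$cell_labels
  bad <- which(spots$row < 1 | spots$row > nrow(lab) |
                 spots$col < 1 | spots$col > ncol(lab))
  if (length(bad)) {
    stop("spot coordinates outside the label image at row(s): ",
         paste(bad, collapse = ", "))
  }
  ids <- lab[cbind(spots$row, spots$col)]
  spots$cell_id <- ifelse(ids == 0L, NA_integer_, as.integer(ids))
  spots
}
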
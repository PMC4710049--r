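#' Per-cell transcript count profiles
#'
#' Counts the assigned spots of each declared gene per cell, including cells
#' with zero spots. Unassigned spots (`cell_id = NA`) are excluded from
#' profiles; their number is reported in the `n_unassigned` attribute.
#'
#' @param spots An assigned [spot_table()].
#' @param cells An `xy_cell_map`, an integer label matrix, or an integer
#'   vector of cell ids.
#' @param genes Character vector of declared gene labels; every spot gene
#'   must be in this set.
#' @return A tibble with `cell_id` and one count column per gene (attribute
#'   `n_unassigned` gives the number of excluded unassigned spots).
#' @export
profile_cells <- function(spots, cells, genes) {
  assert_spot_table(spots)
  if (inherits(cells, "xy_cell_map")) cells <- cells$cell_labels
  ids <- if (is.matrix(cells)) {
    v <- unique(as.integer(cells))
    sort(v[v > 0L])
  } else {
    sort(unique(as.integer(cells)))
  }
  if (!all(spots$gene %in% genes)) {
    stop("spot gene(s) outside the declared set: ",
         paste(setdiff(unique(spots$gene), genes), collapse = ", "))
  }
  assigned <- spots[!is.na(spots$cell_id), ]
  if (nrow(assigned) && !all(assigned$cell_id %in% ids)) {
    stop("spots reference cell id(s) absent from the cell map: ",
         paste(setdiff(unique(assigned$cell_id), ids), collapse = ", "))
  }
  prof <- tibble(cell_id = ids)
  for (g in genes) {
    sub <- assigned[assigned$gene == g, ]
    cnt <- integer(length(ids))
    if (nrow(sub)) {
      tab <- table(factor(sub$cell_id, levels = ids))
      cnt <- as.integer(tab)
    }
    prof[[g]] <- cnt
  }
  attr(prof, "n_unassigned") <- sum(is.na(spots$cell_id))
  prof
}

pair_levels <- c("no_signal", "x_eq_1", "y_eq_1", "mixed",
                 "x_specific", "y_specific")

#' Six-category X/Y cell classification
#'
#' Partitions cells by their X and Y homolog counts into the six mutually
#' exclusive categories used for the per-cell classification tables:
#' no signal (X=0, Y=0), X=1 (Y=0), Y=1 (X=0), mixed (X>=1 and Y>=1),
#' X-specific (X>=2, Y=0), and Y-specific (Y>=2, X=0). "Mixed" requires at
#' least one transcript of each homolog; this is the only reading under
#' which the six categories are mutually exclusive and sum to the printed
#' section totals.
#'
#' @param x_count,y_count Non-negative integer vectors (recycled).
#' @return Factor with levels `no_signal`, `x_eq_1`, `y_eq_1`, `mixed`,
#'   `x_specific`, `y_specific`.
#' @export
classify_pair <- function(x_count, y_count) {
  n <- max(length(x_count), length(y_count))
  x <- rep_len(as.integer(x_count), n)
  y <- rep_len(as.integer(y_count), n)
  stopifnot(all(x >= 0), all(y >= 0))
  out <- character(n)
  out[x == 0 & y == 0] <- "no_signal"
  out[x == 1 & y == 0] <- "x_eq_1"
  out[x == 0 & y == 1] <- "y_eq_1"
  out[x >= 1 & y >= 1] <- "mixed"
  out[x >= 2 & y == 0] <- "x_specific"
  out[x == 0 & y >= 2] <- "y_specific"
  factor(out, levels = pair_levels)
}

#' Summarize the six-category classification for one sample
#'
#' @param profiles Output of [profile_cells()].
#' @param x_gene,y_gene Column names of the X and Y homolog counts.
#' @return List of class `xy_class_summary` with `counts` (named integer
#'   vector over the six categories) and `total_cells`.
#' @export
summarize_pair <- function(profiles, x_gene, y_gene) {
  stopifnot(all(c(x_gene, y_gene) %in% names(profiles)))
  cls <- classify_pair(profiles[[x_gene]], profiles[[y_gene]])
  counts <- table(cls)
  structure(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 total_cells = nrow(profiles),
                 x_gene = x_gene, y_gene = y_gene),
            class = "xy_class_summary")
}

#' @export
print.xy_class_summary <- function(x, ...) {
  cat("X/Y cell classification (", x$x_gene, "/", x$y_gene, ")\n", sep = "")
  print(x$counts)
  cat("total cells:", x$total_cells, "\n")
  invisible(x)
}

#' Three-class view of expressing cells
#'
#' The derived classification of cells with at least two assigned signals as
#' X-specific, Y-specific or mixed, restricted over the six-way partition.
#'
#' @inheritParams summarize_pair
#' @return Named integer vector with `x_specific`, `y_specific`, `mixed`.
#' @export
expressing_view <- function(profiles, x_gene, y_gene) {
  x <- profiles[[x_gene]]; y <- profiles[[y_gene]]
  keep <- (x + y) >= 2
  cls <- classify_pair(x[keep], y[keep])
  c(x_specific = sum(cls == "x_specific"),
    y_specific = sum(cls == "y_specific"),
    mixed = sum(cls == "mixed"))
}

#' Four-gene co-expression summary
#'
#' Evaluates the overlapping co-expression categories for simultaneous
#' detection of the four gametologs PCDH11X (PX), PCDH11Y (PY), NLGN4X (NX)
#' and NLGN4Y (NY): each multi-gene category `A + B >= k` is read as "at
#' least one signal of each listed gene" (so categories overlap and need not
#' sum to the total). This reading is one of two consistent with the printed
#' category names and is flagged as the adopted convention.
#'
#' @param profiles Output of [profile_cells()].
#' @param genes Character vector of the four gene columns in order
#'   PX, PY, NX, NY.
#' @return Named integer vector of the 17 category counts.
#' @export
coexpression_summary <- function(profiles, genes) {
  stopifnot(length(genes) == 4, all(genes %in% names(profiles)))
  px <- profiles[[genes[1]]] >= 1; py <- profiles[[genes[2]]] >= 1
  nx <- profiles[[genes[3]]] >= 1; ny <- profiles[[genes[4]]] >= 1
  c(px_ge1 = sum(px), py_ge1 = sum(py), nx_ge1 = sum(nx), ny_ge1 = sum(ny),
    px_py_ge2 = sum(px & py), nx_ny_ge2 = sum(nx & ny),
    px_nx_ge2 = sum(px & nx), py_ny_ge2 = sum(py & ny),
    px_ny_ge2 = sum(px & ny), py_nx_ge2 = sum(py & nx),
    px_nx_ny_ge3 = sum(px & nx & ny), py_nx_ny_ge3 = sum(py & nx & ny),
    px_py_nx_ge3 = sum(px & py & nx), px_py_ny_ge3 = sum(px & py & ny),
    all_four_ge4 = sum(px & py & nx & ny),
    no_signal = sum(!px & !py & !nx & !ny),
    total = length(px))
}

#' Signals per 1000 cells
#'
#' The normalization used to compare sections of different size.
#'
#' @param signal_count Number of signals.
#' @param total_cells Number of cells in the section; must be > 0.
#' @return `1000 * signal_count / total_cells`.
#' @export
per_1000_cells <- function(signal_count, total_cells) {
  if (any(total_cells <= 0)) {
    stop("rate per 1000 cells is undefined for total_cells = 0")
  }
  1000 * signal_count / total_cells
}
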
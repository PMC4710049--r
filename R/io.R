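#' Write a spot table to CSV
#'
#' Comma-separated, UTF-8, header `row,col,gene,cell_id`; unassigned spots
#' (`NA`) are encoded as -1. Coordinates are 1-based pixel indices.
#'
#' @param spots A [spot_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(spots, path) {
  assert_spot_table(spots)
  out <- spots[, c("row", "col", "gene", "cell_id")]
  out$cell_id <- ifelse(is.na(out$cell_id), -1L, out$cell_id)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spot table from CSV
#'
#' Inverse of [write_spot_table()]: expects the exact header
#' `row,col,gene,cell_id`, integer coordinates, and -1 for unassigned spots.
#' Malformed rows are reported with their line number; if `genes` is given,
#' unknown gene labels are an error.
#'
#' @param path CSV path.
#' @param genes Optional declared gene set to validate against.
#' @return A [spot_table()].
#' @export
read_spot_table <- function(path, genes = NULL) {
  df <- read.csv(path, colClasses = "character")
  if (!identical(names(df), c("row", "col", "gene", "cell_id"))) {
    stop("expected header row,col,gene,cell_id in ", path)
  }
  num <- function(field) {
    v <- suppressWarnings(as.integer(df[[field]]))
    bad <- which(is.na(v) & !(df[[field]] %in% c("NA", "")))
    bad <- c(bad, which(df[[field]] %in% c("NA", "")))
    if (length(bad)) {
      stop("non-numeric ", field, " at line(s) ",
           paste(sort(bad) + 1L, collapse = ", "), " of ", path)
    }
    v
  }
  spots <- tibble(row = num("row"), col = num("col"),
                  gene = df$gene, cell_id = num("cell_id"))
  spots$cell_id[spots$cell_id == -1L] <- NA_integer_
  if (!is.null(genes) && nrow(spots) && !all(spots$gene %in% genes)) {
    stop("unknown gene(s) ",
         paste(setdiff(unique(spots$gene), genes), collapse = ", "),
         "; declared set: ", paste(genes, collapse = ", "))
  }
  spots
}

#' Read and write single-channel intensity images as TIFF
#'
#' Intensity images live on \[0, 1\]; values outside that range are clipped
#' with a warning on write (the 16-bit TIFF container stores \[0, 1\]).
#'
#' @param img Numeric matrix.
#' @param path TIFF path.
#' @return `path` invisibly (write); numeric matrix (read).
#' @export
write_image_tiff <- function(img, path) {
  stopifnot(is.matrix(img))
  if (any(img < 0) || any(img > 1)) {
    warning("image values outside [0, 1] were clipped for TIFF storage")
    img[img < 0] <- 0
    img[img > 1] <- 1
  }
  tiff::writeTIFF(img, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m
}

#' Read and write integer label images as TIFF
#'
#' Labels up to 65535 are stored losslessly in 16-bit TIFF.
#'
#' @param labels Integer matrix (0 = background).
#' @param path TIFF path.
#' @return `path` invisibly (write); integer matrix (read).
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(is.matrix(labels), max(labels) <= 65535L, min(labels) >= 0L)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

pipeline_defaults <- function() {
  list(
    schema_version = 1L,
    scene = NULL,            # scene_config or NULL when images are given
    nuclei_image = NULL,     # TIFF path (used when scene is NULL)
    channel_images = NULL,   # named list gene -> TIFF path
    x_gene = NULL, y_gene = NULL,
    min_area = 20, expansion_distance = 20,
    tophat_radius = 3, thresholds = NULL, # named per-gene numeric, required
    kernel_window = 150, kernel_sd = 25,
    eps = NULL, n_bins = 50, cutoff = 0.8, n_rand = 100,
    landmarks = NULL,        # list(left = 2x2, right = 2x2) or NULL
    seed = 1L,
    out_dir = NULL
  )
}

#' Read a pipeline run configuration from YAML
#'
#' Flat key/value schema (see [run_pipeline()] for the keys and defaults).
#' Unknown keys are rejected; a nested `scene` block is passed to
#' [scene_config()].
#'
#' @param path YAML path.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  build_run_config(vals)
}

#' @rdname read_run_config
#' @param vals Named list of configuration values (the YAML content).
#' @export
build_run_config <- function(vals) {
  defaults <- pipeline_defaults()
  bad <- setdiff(names(vals), names(defaults))
  if (length(bad)) stop("unknown run config keys: ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, vals, keep.null = TRUE)
  if (!is.null(cfg$scene) && !inherits(cfg$scene, "scene_config")) {
    cfg$scene$class_proportions <- unlist(cfg$scene$class_proportions)
    cfg$scene$genes <- unlist(cfg$scene$genes)
    cfg$scene <- do.call(scene_config, cfg$scene)
  }
  if (is.null(cfg$scene)) {
    for (k in c("nuclei_image", "channel_images", "x_gene", "y_gene")) {
      if (is.null(cfg[[k]])) stop("run config needs `", k, "` when no scene is given")
    }
  } else {
    if (is.null(cfg$x_gene)) cfg$x_gene <- unname(cfg$scene$genes["x"])
    if (is.null(cfg$y_gene)) cfg$y_gene <- unname(cfg$scene$genes["y"])
  }
  if (is.null(cfg$thresholds)) {
    stop("run config needs per-gene `thresholds` (manual thresholding has no default)")
  }
  cfg$thresholds <- unlist(cfg$thresholds)
  genes <- c(cfg$x_gene, cfg$y_gene)
  if (!all(genes %in% names(cfg$thresholds))) {
    stop("`thresholds` must name every gene: ", paste(genes, collapse = ", "))
  }
  class(cfg) <- "xy_run_config"
  cfg
}

#' Run the end-to-end quantification and spatial analysis
#'
#' Orchestrates the full analysis on one sample: segment nuclei, expand to
#' cells, detect and assign spots per gene channel, profile and classify
#' cells, normalize to counts per 1000 cells, build density maps, run the
#' label-permutation segregation test, and (when landmarks are given)
#' compare dorsal versus ventral regions. Inputs are either a synthetic
#' `scene` block (rendered internally) or paths to nuclei/channel TIFFs.
#' Given a seed the run is deterministic; rerunning a configuration
#' reproduces the report byte for byte.
#'
#' @param config Configuration list from [read_run_config()], or a plain
#'   list with the same keys (validated internally); see
#'   `pipeline_defaults()` in the source for keys and defaults.
#' @return Report list (also written as JSON when `out_dir` is set),
#'   containing cell totals, six-category counts, per-1000-cell rates,
#'   dominance proportions with confidence intervals, and flagged bins.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "xy_run_config")) config <- build_run_config(config)
  genes <- c(config$x_gene, config$y_gene)
  if (!is.null(config$scene)) {
    scene <- generate_scene(config$scene)
    channels <- render_scene(scene)
    nuclei_img <- channels$nuclei
    gene_imgs <- channels[genes]
  } else {
    nuclei_img <- read_image_tiff(config$nuclei_image)
    gene_imgs <- lapply(config$channel_images[genes], read_image_tiff)
  }

  nuclei <- segment_nuclei(nuclei_img, min_area = config$min_area)
  cells <- expand_cells(nuclei, distance = config$expansion_distance)
  spots <- do.call(rbind, lapply(genes, function(g) {
    detect_spots(gene_imgs[[g]], g, tophat_radius = config$tophat_radius,
                 threshold = config$thresholds[[g]])
  }))
  spots <- assign_spots(spots, cells)

  profiles <- profile_cells(spots, cells, genes)
  summary6 <- summarize_pair(profiles, config$x_gene, config$y_gene)
  n_x <- sum(spots$gene == config$x_gene)
  n_y <- sum(spots$gene == config$y_gene)
  total_cells <- summary6$total_cells

  kernel <- kernel_spec(config$kernel_window, config$kernel_sd)
  perm <- if (n_x >= 1 && n_y >= 1) {
    permutation_null(spots, dim(nuclei_img), config$x_gene, config$y_gene,
                     kernel = kernel, eps = config$eps,
                     n_bins = config$n_bins, cutoff = config$cutoff,
                     n_rand = config$n_rand, seed = config$seed)
  }

  report <- list(
    genes = as.list(stats::setNames(genes, c("x", "y"))),
    total_cells = total_cells,
    n_spots = stats::setNames(list(n_x, n_y), genes),
    n_unassigned = attr(profiles, "n_unassigned"),
    per_1000_cells = if (total_cells > 0) {
      stats::setNames(list(per_1000_cells(n_x, total_cells),
                           per_1000_cells(n_y, total_cells)), genes)
    },
    classification = as.list(summary6$counts),
    expressing_view = as.list(expressing_view(profiles, config$x_gene,
                                              config$y_gene))
  )
  if (!is.null(perm)) {
    report$segregation <- list(
      observed_props = as.list(perm$observed_props),
      ci_lower = as.list(perm$ci["lower", ]),
      ci_upper = as.list(perm$ci["upper", ]),
      outside_ci = as.list(perm$outside_ci),
      flagged_bins_over = which(perm$bin_flags == 1L),
      flagged_bins_under = which(perm$bin_flags == -1L),
      n_rand = perm$n_rand, eps = perm$eps, cutoff = perm$cutoff)
  }
  if (!is.null(config$landmarks)) {
    part <- dorsoventral_partition(nuclei_img > -Inf & !is.na(nuclei_img),
                                   config$landmarks$left,
                                   config$landmarks$right)
    report$region_ratios <-
      as.data.frame(region_ratio(spots, part, config$x_gene, config$y_gene))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_spot_table(spots, file.path(config$out_dir, "spots.csv"))
    write_label_tiff(cells$cell_labels,
                     file.path(config$out_dir, "cell_labels.tif"))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Printed per-cell classification tables
#'
#' The published per-section six-category cell counts for the PCDH11X/Y and
#' NLGN4X/Y padlock experiments (spinal cord and medulla oblongata
#' sections), as shipped in `inst/extdata/printed_cell_tables.csv`. Used as
#' reference input for partition checks and worked examples.
#'
#' @return Tibble with one row per section: `sample`, `tissue`, `gene`,
#'   `sex`, the six category counts and `total`.
#' @export
printed_cell_tables <- function() {
  path <- system.file("extdata", "printed_cell_tables.csv",
                      package = "xyspots", mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
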
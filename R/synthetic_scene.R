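#' Configure a synthetic tissue scene
#'
#' Describes a ground-truthed synthetic tissue section that mimics the
#' statistical structure of padlock-probe / rolling-circle-amplification
#' experiments on embryonic CNS sections: a tissue region holding hundreds to
#' thousands of nuclei, a per-cell expression class (no signal, X only,
#' Y only, or mixed), Poisson spot counts for expressing cells, and an
#' optional ventral enrichment of X-expressing cells that reproduces the
#' regionally clustered X homolog versus the homogeneously distributed
#' Y homolog.
#'
#' Default class proportions follow the per-cell classification tables of
#' male spinal-cord sections, where roughly 87 % of cells carry no signal and
#' X-only, Y-only and mixed cells appear at about 6 %, 6 % and 1 %.
#'
#' @param image_height,image_width Image size in pixels.
#' @param tissue_shape One of `"ellipse"`, `"half_annulus"`, `"full_frame"`.
#' @param n_cells Number of nuclei to place.
#' @param nucleus_radius_mean,nucleus_radius_sd Nucleus radius distribution
#'   (pixels); radii are clamped to be at least 1.
#' @param min_nucleus_separation Hard-core minimum distance between nucleus
#'   centers (pixels).
#' @param class_proportions Named numeric vector over
#'   `no_signal`, `x_only`, `y_only`, `mixed`; must sum to 1.
#' @param spots_per_expressing_cell_mean Poisson mean for spots per
#'   expressing cell; counts are conditioned on being at least 1
#'   (at least 2 for mixed cells, which must carry both labels).
#' @param ventral_x_enrichment Multiplier (>= 1) applied to the `x_only`
#'   probability for cells below the horizontal midline of the tissue
#'   bounding box, then renormalized per cell. 1 means class labels are
#'   spatially exchangeable.
#' @param spot_scatter_sd SD of the isotropic Gaussian spot displacement
#'   around the nucleus center (pixels); displacement is truncated to the
#'   expanded-cell radius (nucleus radius + `expansion`) so the true parent
#'   cell is unambiguous.
#' @param expansion Cell expansion distance used for the truncation radius
#'   (pixels).
#' @param spot_sigma SD of the rendered Gaussian spot bump (pixels).
#' @param spot_amplitude,background_level,noise_sd Rendered image intensity
#'   units (images live on \[0, 1\]).
#' @param false_positive_rate Expected number of spurious, uniformly placed
#'   spots per gene per scene (models autofluorescent RCA-like signals);
#'   default 0.
#' @param genes Length-2 named character vector `c(x = ..., y = ...)` naming
#'   the X and Y homolog channels.
#' @param seed Integer seed; all scene randomness derives from it through
#'   fixed per-stage offsets.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(image_height = 800, image_width = 800,
                         tissue_shape = c("ellipse", "half_annulus", "full_frame"),
                         n_cells = 2000,
                         nucleus_radius_mean = 4, nucleus_radius_sd = 0.7,
                         min_nucleus_separation = 11,
                         class_proportions = c(no_signal = 0.87, x_only = 0.06,
                                               y_only = 0.06, mixed = 0.01),
                         spots_per_expressing_cell_mean = 1.5,
                         ventral_x_enrichment = 1,
                         spot_scatter_sd = 3,
                         expansion = 20,
                         spot_sigma = 1.5,
                         spot_amplitude = 0.6,
                         background_level = 0.05,
                         noise_sd = 0.01,
                         false_positive_rate = 0,
                         genes = c(x = "PCDH11X", y = "PCDH11Y"),
                         seed = 1L) {
  tissue_shape <- match.arg(tissue_shape)
  cp <- class_proportions
  need <- c("no_signal", "x_only", "y_only", "mixed")
  if (!all(need %in% names(cp)) || length(cp) != 4L) {
    stop("class_proportions must be named over ", paste(need, collapse = ", "))
  }
  cp <- cp[need]
  if (any(cp < 0) || abs(sum(cp) - 1) > 1e-9) {
    stop("class_proportions must be non-negative and sum to 1 (within 1e-9)")
  }
  if (n_cells < 0) stop("n_cells must be >= 0")
  if (image_height < 1 || image_width < 1) stop("image dimensions must be >= 1")
  if (spots_per_expressing_cell_mean < 0) {
    stop("spots_per_expressing_cell_mean must be >= 0")
  }
  if (ventral_x_enrichment < 1) stop("ventral_x_enrichment must be >= 1")
  if (!all(c("x", "y") %in% names(genes))) {
    stop("genes must be a named vector with elements 'x' and 'y'")
  }
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0L || seed > 2147483000L) {
    stop("seed must be an integer in [0, 2^31 - 648]")
  }
  structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    tissue_shape = tissue_shape, n_cells = as.integer(n_cells),
    nucleus_radius_mean = nucleus_radius_mean,
    nucleus_radius_sd = nucleus_radius_sd,
    min_nucleus_separation = min_nucleus_separation,
    class_proportions = cp,
    spots_per_expressing_cell_mean = spots_per_expressing_cell_mean,
    ventral_x_enrichment = ventral_x_enrichment,
    spot_scatter_sd = spot_scatter_sd, expansion = expansion,
    spot_sigma = spot_sigma, spot_amplitude = spot_amplitude,
    background_level = background_level, noise_sd = noise_sd,
    false_positive_rate = false_positive_rate,
    genes = genes, seed = seed
  ), class = "scene_config")
}

#' Read a scene configuration from a YAML file
#'
#' Flat key/value file; keys are the arguments of [scene_config()]
#' (`class_proportions` and `genes` as named maps). Unknown keys are
#' rejected.
#'
#' @param path Path to a YAML file.
#' @return A `scene_config`.
#' @export
read_scene_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(scene_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown scene config keys: ", paste(bad, collapse = ", "))
  }
  if (!is.null(vals$class_proportions)) {
    vals$class_proportions <- unlist(vals$class_proportions)
  }
  if (!is.null(vals$genes)) vals$genes <- unlist(vals$genes)
  do.call(scene_config, vals)
}

tissue_mask_for <- function(config) {
  H <- config$image_height; W <- config$image_width
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  cr <- (H + 1) / 2; ccol <- (W + 1) / 2
  switch(config$tissue_shape,
    full_frame = matrix(TRUE, H, W),
    ellipse = ((rr - cr) / (0.45 * H))^2 + ((cc - ccol) / (0.45 * W))^2 <= 1,
    half_annulus = {
      rad <- sqrt((rr - cr)^2 + (cc - ccol)^2)
      m <- min(H, W)
      rad <= 0.45 * m & rad >= 0.18 * m & rr >= cr
    }
  )
}

# Hard-core placement by rejection sampling on a neighbor grid; errors after
# 1000 * n_cells failed attempts.
place_nuclei <- function(mask, n_cells, min_sep) {
  H <- nrow(mask); W <- ncol(mask)
  if (n_cells == 0L) return(cbind(row = numeric(), col = numeric()))
  cell <- max(min_sep, 1)
  gr <- ceiling(H / cell); gc <- ceiling(W / cell)
  grid <- vector("list", gr * gc)
  pts <- matrix(NA_real_, n_cells, 2)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 1000 * n_cells
  min_sep2 <- min_sep^2
  while (placed < n_cells) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("failed to place ", n_cells, " nuclei at separation ", min_sep,
           " after ", max_attempts, " attempts", call. = FALSE)
    }
    r <- runif(1, 1, H); c <- runif(1, 1, W)
    if (!mask[ceiling(r - 0.5), ceiling(c - 0.5)]) next
    gi <- ceiling(r / cell); gj <- ceiling(c / cell)
    ok <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      ni <- gi + di; nj <- gj + dj
      if (ni < 1 || ni > gr || nj < 1 || nj > gc) next
      for (k in grid[[ni + (nj - 1) * gr]]) {
        if ((pts[k, 1] - r)^2 + (pts[k, 2] - c)^2 < min_sep2) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (!ok) next
    placed <- placed + 1L
    pts[placed, ] <- c(r, c)
    idx <- gi + (gj - 1) * gr
    grid[[idx]] <- c(grid[[idx]], placed)
  }
  colnames(pts) <- c("row", "col")
  pts
}

# Zero-truncated Poisson draws (n >= lower).
rpois_truncated <- function(n, lambda, lower = 1L) {
  out <- rpois(n, lambda)
  bad <- which(out < lower)
  while (length(bad)) {
    out[bad] <- rpois(length(bad), lambda)
    bad <- bad[out[bad] < lower]
  }
  out
}

#' Generate a ground-truthed synthetic scene
#'
#' Places nuclei by hard-core rejection sampling inside the tissue mask,
#' draws a per-cell expression class (with optional ventral enrichment of
#' X-only cells below the tissue midline), and scatters transcript spots
#' around their parent nuclei. All randomness derives from `config$seed`
#' through fixed per-stage offsets, so scenes are bit-reproducible.
#'
#' @param config A [scene_config()].
#' @return An object of class `xy_scene`: a list with `config`,
#'   `tissue_mask` (logical matrix), `nuclei` (tibble with `row`, `col`,
#'   `radius`, `class`), and `spots` (a [spot_table()] whose `cell_id` is the
#'   true parent nucleus index, `NA` for false-positive spots).
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  H <- config$image_height; W <- config$image_width
  mask <- tissue_mask_for(config)

  set.seed(config$seed + 1L)
  centers <- place_nuclei(mask, config$n_cells, config$min_nucleus_separation)
  set.seed(config$seed + 2L)
  radii <- pmax(1, rnorm(config$n_cells, config$nucleus_radius_mean,
                         config$nucleus_radius_sd))

  set.seed(config$seed + 3L)
  cls_levels <- c("no_signal", "x_only", "y_only", "mixed")
  cp <- config$class_proportions
  n <- config$n_cells
  classes <- character(n)
  if (n > 0) {
    midline <- if (any(mask)) mean(range(which(rowSums(mask) > 0))) else (H + 1) / 2
    probs <- matrix(cp, n, 4, byrow = TRUE)
    if (config$ventral_x_enrichment > 1) {
      ventral <- centers[, "row"] > midline
      probs[ventral, 2] <- probs[ventral, 2] * config$ventral_x_enrichment
      probs <- probs / rowSums(probs)
    }
    u <- runif(n)
    cum <- t(apply(probs, 1, cumsum))
    classes <- cls_levels[1L + rowSums(u > cum)]
  }

  set.seed(config$seed + 4L)
  gx <- unname(config$genes["x"]); gy <- unname(config$genes["y"])
  rows <- integer(); cols <- integer(); gene <- character(); parent <- integer()
  expressing <- which(classes != "no_signal")
  for (i in expressing) {
    lower <- if (classes[i] == "mixed") 2L else 1L
    k <- rpois_truncated(1L, config$spots_per_expressing_cell_mean, lower)
    labs <- switch(classes[i],
      x_only = rep(gx, k),
      y_only = rep(gy, k),
      mixed = {
        nx <- sample(seq_len(k - 1L), 1L) # both labels present
        sample(c(rep(gx, nx), rep(gy, k - nx)))
      })
    rmax <- radii[i] + config$expansion
    pr <- numeric(k); pc <- numeric(k)
    for (s in seq_len(k)) {
      repeat {
        dr <- rnorm(1, 0, config$spot_scatter_sd)
        dc <- rnorm(1, 0, config$spot_scatter_sd)
        if (dr * dr + dc * dc <= rmax * rmax) break
      }
      pr[s] <- centers[i, "row"] + dr
      pc[s] <- centers[i, "col"] + dc
    }
    rows <- c(rows, pmin(H, pmax(1L, as.integer(round(pr)))))
    cols <- c(cols, pmin(W, pmax(1L, as.integer(round(pc)))))
    gene <- c(gene, labs)
    parent <- c(parent, rep(i, k))
  }
  if (config$false_positive_rate > 0 && any(mask)) {
    inside <- which(mask)
    for (g in c(gx, gy)) {
      nf <- rpois(1L, config$false_positive_rate)
      if (nf > 0) {
        pick <- sample(inside, nf, replace = TRUE)
        rows <- c(rows, as.integer((pick - 1L) %% H + 1L))
        cols <- c(cols, as.integer((pick - 1L) %/% H + 1L))
        gene <- c(gene, rep(g, nf))
        parent <- c(parent, rep(NA_integer_, nf))
      }
    }
  }

  structure(list(
    config = config, tissue_mask = mask,
    nuclei = tibble(row = centers[, "row"], col = centers[, "col"],
                    radius = radii[seq_len(n)], class = classes),
    spots = tibble(row = rows, col = cols, gene = gene,
                   cell_id = as.integer(parent))
  ), class = "xy_scene")
}

#' Render a scene to channel images
#'
#' Produces one nuclei channel (filled unit-intensity discs) and one channel
#' per gene (isotropic Gaussian bumps of height `spot_amplitude` at spot
#' pixels), each with `background_level` added and Gaussian noise of SD
#' `noise_sd`. Noise is drawn from the scene's seed stream, so rendering is
#' deterministic given the scene. Spots outside the image bounds are clipped
#' with a warning.
#'
#' @param scene An `xy_scene` from [generate_scene()].
#' @return Named list of numeric matrices: `nuclei` plus one per gene.
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "xy_scene"))
  cf <- scene$config
  H <- cf$image_height; W <- cf$image_width
  set.seed(cf$seed + 5L)

  nuc <- matrix(0, H, W)
  for (i in seq_len(nrow(scene$nuclei))) {
    r0 <- scene$nuclei$row[i]; c0 <- scene$nuclei$col[i]
    rad <- scene$nuclei$radius[i]
    rs <- max(1L, floor(r0 - rad)):min(H, ceiling(r0 + rad))
    cs <- max(1L, floor(c0 - rad)):min(W, ceiling(c0 + rad))
    d2 <- outer((rs - r0)^2, (cs - c0)^2, "+")
    nuc[rs, cs][d2 <= rad^2] <- 1
  }

  half <- max(1L, ceiling(4 * cf$spot_sigma))
  prof <- exp(-((-half:half)^2) / (2 * cf$spot_sigma^2))
  channels <- list(nuclei = nuc)
  for (g in unname(cf$genes)) {
    img <- matrix(0, H, W)
    sp <- scene$spots[scene$spots$gene == g, ]
    out_of_bounds <- sp$row < 1 | sp$row > H | sp$col < 1 | sp$col > W
    if (any(out_of_bounds)) {
      warning(sum(out_of_bounds), " ", g,
              " spot(s) outside image bounds were clipped")
      sp <- sp[!out_of_bounds, ]
    }
    for (s in seq_len(nrow(sp))) {
      r0 <- sp$row[s]; c0 <- sp$col[s]
      rs <- max(1L, r0 - half):min(H, r0 + half)
      cs <- max(1L, c0 - half):min(W, c0 + half)
      bump <- cf$spot_amplitude *
        outer(prof[rs - r0 + half + 1L], prof[cs - c0 + half + 1L])
      img[rs, cs] <- img[rs, cs] + bump
    }
    channels[[g]] <- img
  }
  lapply(channels, function(img) {
    img <- img + cf$background_level
    if (cf$noise_sd > 0) {
      img <- img + matrix(rnorm(H * W, 0, cf$noise_sd), H, W)
    }
    img
  })
}
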
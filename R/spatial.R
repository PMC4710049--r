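#' Gaussian kernel specification for signal density maps
#'
#' A rotationally symmetric 2-D Gaussian kernel truncated to a square
#' `window` x `window` support (the window is forced odd so the kernel is
#' center-defined). With `normalized = TRUE` the kernel has unit mass, so a
#' density map integrates to the number of interior spots; otherwise the raw
#' Gaussian profile (peak 1) is used for display-style maps.
#'
#' The defaults, a 150-pixel window with SD 25 pixels, are the kernel used
#' for signal density maps of embryonic spinal cord and medulla sections.
#'
#' @param window Kernel window in pixels (rounded up to the next odd size).
#' @param sd Gaussian standard deviation in pixels (> 0).
#' @param normalized Logical; unit-mass normalization.
#' @return Object of class `xy_kernel` with the separable 1-D profile `k1d`.
#' @export
kernel_spec <- function(window = 150, sd = 25, normalized = TRUE) {
  if (sd <= 0) stop("`sd` must be > 0")
  window <- as.integer(window)
  if (window < 1) stop("`window` must be >= 1")
  if (window %% 2L == 0L) window <- window + 1L
  half <- (window - 1L) %/% 2L
  k1d <- exp(-((-half:half)^2) / (2 * sd^2))
  if (normalized) k1d <- k1d / sum(k1d) # separable: 2-D mass = 1
  structure(list(window = window, sd = sd, normalized = normalized,
                 k1d = k1d, half = half),
            class = "xy_kernel")
}

#' Kernel density maps of transcript signals
#'
#' Each gene's spots form a binary image (one pixel per signal) that is
#' convolved with the truncated Gaussian kernel (zero padding, no boundary
#' correction). The result is linear in the spot set, and with a normalized
#' kernel the total mass of a map equals the number of interior spots.
#'
#' @param spots A [spot_table()]; coordinates must lie within `shape`.
#' @param shape Integer vector `c(height, width)` of the source image.
#' @param kernel A [kernel_spec()].
#' @param genes Genes to map; defaults to those present in `spots`.
#' @return Object of class `xy_density`: list with `maps` (named list of
#'   matrices), `counts`, `kernel`, `shape`.
#' @export
density_map <- function(spots, shape, kernel = kernel_spec(),
                        genes = unique(spots$gene)) {
  assert_spot_table(spots)
  stopifnot(inherits(kernel, "xy_kernel"), length(shape) == 2)
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  if (nrow(spots) &&
      any(spots$row < 1 | spots$row > H | spots$col < 1 | spots$col > W)) {
    stop("spot coordinates outside `shape`")
  }
  maps <- list(); counts <- integer()
  for (g in genes) {
    sub <- spots[spots$gene == g, ]
    maps[[g]] <- cpp_splat_density(as.integer(sub$row), as.integer(sub$col),
                                   H, W, kernel$k1d)
    counts[[g]] <- nrow(sub)
  }
  structure(list(maps = maps, counts = counts, kernel = kernel,
                 shape = c(H, W)),
            class = "xy_density")
}

default_purity_eps <- function(total) {
  pos <- total[total > 0]
  if (length(pos) == 0) return(Inf)
  1e-3 * mean(pos)
}

#' Y-purity field from X and Y density maps
#'
#' The purity of a pixel is the Y fraction of the local density,
#' `Y / (X + Y)`, a bounded proportion on \[0, 1\] (0 = pure X, 1 = pure Y).
#' Background pixels with total density below `eps` are masked (`NA`); by
#' default `eps` is 1e-3 times the mean positive total density.
#'
#' @param density_x,density_y Non-negative matrices of equal shape.
#' @param eps Density floor for masking; `NULL` for the default.
#' @return Object of class `xy_purity`: list with `purity` (matrix with `NA`
#'   for masked pixels) and `eps`.
#' @export
purity_field <- function(density_x, density_y, eps = NULL) {
  stopifnot(is.matrix(density_x), is.matrix(density_y),
            all(dim(density_x) == dim(density_y)))
  if (any(density_x < 0) || any(density_y < 0)) {
    stop("densities must be non-negative")
  }
  total <- density_x + density_y
  if (is.null(eps)) eps <- default_purity_eps(total)
  p <- matrix(NA_real_, nrow(total), ncol(total))
  ok <- total >= eps
  p[ok] <- pmin(1, pmax(0, density_y[ok] / total[ok]))
  structure(list(purity = p, eps = eps), class = "xy_purity")
}

purity_bins <- function(p, n_bins) {
  pmin(as.integer(floor(p * n_bins)), n_bins - 1L) + 1L
}

#' Purity histogram with dominance categories
#'
#' Equal-width bins on \[0, 1\] over the unmasked purity pixels, plus the
#' three dominance-category proportions: a pixel is Y dominant at purity of
#' at least `cutoff` (default 0.8, i.e. 80 % colour purity), X dominant at
#' purity of at most `1 - cutoff`, and mixed otherwise; boundaries are
#' inclusive.
#'
#' @param field An [purity_field()] result.
#' @param n_bins Number of equal-width bins (default 50).
#' @param cutoff Dominance purity cutoff in (0.5, 1\].
#' @return Object of class `xy_purity_hist`: `breaks`, `counts`, `freq`
#'   (relative frequencies), `proportions` (`x_dominant`, `mixed`,
#'   `y_dominant`), `cutoff`, `n_unmasked`.
#' @export
purity_histogram <- function(field, n_bins = 50, cutoff = 0.8) {
  stopifnot(inherits(field, "xy_purity"))
  p <- field$purity[!is.na(field$purity)]
  if (length(p) == 0) stop("all pixels are masked; cannot build a histogram")
  counts <- tabulate(purity_bins(p, n_bins), nbins = n_bins)
  props <- c(x_dominant = mean(p <= 1 - cutoff),
             mixed = mean(p > 1 - cutoff & p < cutoff),
             y_dominant = mean(p >= cutoff))
  structure(list(breaks = seq(0, 1, length.out = n_bins + 1L),
                 counts = counts, freq = counts / length(p),
                 proportions = props, cutoff = cutoff,
                 n_unmasked = length(p)),
            class = "xy_purity_hist")
}

#' Label-permutation null for spatial X/Y segregation
#'
#' Tests whether X and Y signals are spatially segregated beyond what label
#' exchangeability allows. Spot positions are held fixed while gene labels
#' are permuted uniformly (`n_rand` times, preserving both label counts
#' exactly); for each randomization, the density maps, purity field, purity
#' histogram and dominance proportions are recomputed. Histogram bins whose
#' observed frequency deviates from the randomized mean by more than 3 SD
#' are flagged (signed), and percentile 95 % confidence intervals
#' (2.5/97.5 percentiles over randomizations) are reported for the three
#' dominance-category proportions.
#'
#' The background mask is derived from the total density, which is invariant
#' under label permutation, so observed and randomized fields share one mask.
#'
#' @param spots Spot table restricted to the two genes of interest; at least
#'   one spot of each label.
#' @param shape `c(height, width)`.
#' @param x_gene,y_gene The two gene labels.
#' @param kernel A [kernel_spec()].
#' @param eps Density floor for masking (`NULL`: default rule).
#' @param n_bins,cutoff Histogram parameters, as in [purity_histogram()].
#' @param n_rand Number of randomizations (default 100; must be >= 2).
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `xy_perm_summary`; see Details. Fields include
#'   `observed` (the observed histogram), `bin_mean`, `bin_sd`, `bin_flags`
#'   (+1 over-represented / -1 under-represented / 0), `ci` (2 x 3 matrix),
#'   `outside_ci`, `perm_props`, `eps`, `seed`.
#' @export
permutation_null <- function(spots, shape, x_gene, y_gene,
                             kernel = kernel_spec(), eps = NULL,
                             n_bins = 50, cutoff = 0.8,
                             n_rand = 100, seed = 1L) {
  assert_spot_table(spots)
  spots <- spots[spots$gene %in% c(x_gene, y_gene), ]
  is_x <- spots$gene == x_gene
  if (nrow(spots) < 1) stop("need at least one labelled spot")
  # with a single label present every randomization is identical: the test
  # degenerates to SD 0 in every bin and no flags, which is what it returns
  if (n_rand < 2) stop("`n_rand` must be >= 2 to estimate bin SDs")
  H <- as.integer(shape[1]); W <- as.integer(shape[2])

  total <- cpp_splat_density(as.integer(spots$row), as.integer(spots$col),
                             H, W, kernel$k1d)
  if (is.null(eps)) eps <- default_purity_eps(total)

  dens <- density_map(spots, shape, kernel, genes = c(x_gene, y_gene))
  obs_field <- purity_field(dens$maps[[x_gene]], dens$maps[[y_gene]], eps)
  obs_hist <- purity_histogram(obs_field, n_bins, cutoff)

  n <- nrow(spots)
  set.seed(seed)
  xperm <- matrix(FALSE, n_rand, n)
  for (i in seq_len(n_rand)) xperm[i, ] <- is_x[sample.int(n)]
  # exchangeability: every randomization preserves the label multiset
  stopifnot(all(rowSums(xperm) == sum(is_x)))

  st <- cpp_perm_purity_stats(as.integer(spots$row), as.integer(spots$col),
                              xperm, total, kernel$k1d, eps,
                              as.integer(n_bins), cutoff)
  bin_mean <- colMeans(st$freq)
  bin_sd <- apply(st$freq, 2, sd)
  dev <- obs_hist$freq - bin_mean
  flags <- integer(n_bins)
  flags[dev > 3 * bin_sd] <- 1L
  flags[-dev > 3 * bin_sd] <- -1L

  perm_props <- st$props
  colnames(perm_props) <- c("x_dominant", "mixed", "y_dominant")
  ci <- apply(perm_props, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  rownames(ci) <- c("lower", "upper")
  obs_props <- obs_hist$proportions
  outside <- obs_props < ci["lower", ] | obs_props > ci["upper", ]

  structure(list(n_rand = n_rand, seed = seed, eps = eps,
                 n_bins = n_bins, cutoff = cutoff,
                 observed = obs_hist, field = obs_field,
                 bin_mean = bin_mean, bin_sd = bin_sd, bin_flags = flags,
                 observed_props = obs_props, ci = ci, outside_ci = outside,
                 perm_props = perm_props,
                 n_x = sum(is_x), n_y = sum(!is_x)),
            class = "xy_perm_summary")
}

#' @export
print.xy_perm_summary <- function(x, ...) {
  cat("Label-permutation null (", x$n_rand, " randomizations, seed ",
      x$seed, ")\n", sep = "")
  cat("observed proportions:\n")
  print(round(x$observed_props, 4))
  cat("95% CI under exchangeability:\n")
  print(round(x$ci, 4))
  cat("outside CI:", paste(names(x$outside_ci)[x$outside_ci], collapse = ", "),
      "\n")
  cat("flagged bins (+3SD):", sum(x$bin_flags == 1L),
      " (-3SD):", sum(x$bin_flags == -1L), "\n")
  invisible(x)
}

#' Map pixels of over-represented purity bins
#'
#' Marks the unmasked pixels whose purity falls in a histogram bin flagged
#' as over-represented by more than +3 SD against the permutation null
#' (the pixels plotted as deviating dots on tissue maps).
#'
#' @param field An [purity_field()] result.
#' @param flags Integer vector of per-bin flags (+1 = over-represented), as
#'   in the `bin_flags` field of [permutation_null()].
#' @return Logical matrix; masked pixels are `FALSE`.
#' @export
flag_pixels <- function(field, flags) {
  stopifnot(inherits(field, "xy_purity"))
  n_bins <- length(flags)
  out <- matrix(FALSE, nrow(field$purity), ncol(field$purity))
  ok <- !is.na(field$purity)
  if (any(flags == 1L) && any(ok)) {
    b <- purity_bins(field$purity[ok], n_bins)
    out[ok] <- flags[b] == 1L
  }
  out
}

#' Landmark-based dorsal/ventral partition
#'
#' The border is the line through the midpoints of two landmark point pairs,
#' one pair on each side of the section, each spanning the dorsal-to-ventral
#' extent. Mask pixels above the line (smaller row index) are dorsal; pixels
#' on or below it are ventral.
#'
#' @param mask Logical tissue mask.
#' @param left,right 2 x 2 numeric matrices, one landmark point `(row, col)`
#'   per row, giving the dorsal and ventral landmark of each side.
#' @return Object of class `xy_partition`: `region` (integer matrix,
#'   0 outside mask, 1 dorsal, 2 ventral) and the border midpoints.
#' @export
dorsoventral_partition <- function(mask, left, right) {
  stopifnot(is.matrix(mask), is.logical(mask))
  as_pair <- function(p, side) {
    p <- matrix(as.numeric(unlist(p)), 2, 2, byrow = !is.matrix(p))
    if (all(p[1, ] == p[2, ])) {
      stop("degenerate (coincident) landmark pair on the ", side, " side")
    }
    p
  }
  left <- as_pair(left, "left"); right <- as_pair(right, "right")
  for (p in list(left[1, ], left[2, ], right[1, ], right[2, ])) {
    r <- as.integer(round(p[1])); c <- as.integer(round(p[2]))
    if (r < 1 || r > nrow(mask) || c < 1 || c > ncol(mask) || !mask[r, c]) {
      stop("landmark point (", p[1], ", ", p[2], ") is outside the tissue mask")
    }
  }
  m_l <- colMeans(left); m_r <- colMeans(right)
  if (m_l[2] == m_r[2]) {
    stop("side midpoints share one column; the border line is undefined")
  }
  slope <- (m_r[1] - m_l[1]) / (m_r[2] - m_l[2])
  region <- matrix(0L, nrow(mask), ncol(mask))
  border_row <- m_l[1] + slope * (seq_len(ncol(mask)) - m_l[2])
  rr <- matrix(seq_len(nrow(mask)), nrow(mask), ncol(mask))
  br <- matrix(border_row, nrow(mask), ncol(mask), byrow = TRUE)
  region[mask & rr < br] <- 1L   # dorsal: above the line
  region[mask & rr >= br] <- 2L  # ventral: on or below
  structure(list(region = region, left_mid = m_l, right_mid = m_r,
                 slope = slope),
            class = "xy_partition")
}

#' Regional X:Y count ratios
#'
#' Counts X and Y spots in the dorsal and ventral regions and reports the
#' X:Y count ratio per region. A region without Y spots has an undefined
#' ratio (`NA`) and is flagged so the sample can be excluded from the
#' regional test.
#'
#' @param spots An assigned or raw [spot_table()].
#' @param partition An [dorsoventral_partition()] result.
#' @param x_gene,y_gene Gene labels.
#' @return Tibble with `region`, `n_x`, `n_y`, `ratio`, `defined`.
#' @export
region_ratio <- function(spots, partition, x_gene, y_gene) {
  assert_spot_table(spots)
  stopifnot(inherits(partition, "xy_partition"))
  reg <- partition$region[cbind(spots$row, spots$col)]
  out <- lapply(c(dorsal = 1L, ventral = 2L), function(code) {
    nx <- sum(reg == code & spots$gene == x_gene)
    ny <- sum(reg == code & spots$gene == y_gene)
    c(nx, ny)
  })
  nx <- unname(vapply(out, `[`, 0, 1)); ny <- unname(vapply(out, `[`, 0, 2))
  tibble(region = c("dorsal", "ventral"),
         n_x = as.integer(nx), n_y = as.integer(ny),
         ratio = ifelse(ny > 0, nx / ny, NA_real_),
         defined = ny > 0)
}

#' One-tailed Welch two-sample t-test
#'
#' Two-sample t-test assuming unequal variances (Welch-Satterthwaite
#' degrees of freedom) with a one-tailed alternative, as used for the
#' dorsal versus ventral comparison of regional expression ratios. Groups
#' with zero variance in both samples are reported as degenerate rather
#' than an error.
#'
#' @param group_a,group_b Numeric vectors (each of length >= 2).
#' @param alternative `"greater"` (mean of `group_a` larger) or `"less"`.
#' @return List with `t`, `df`, `p`, `degenerate`.
#' @export
welch_one_tailed <- function(group_a, group_b,
                             alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 observations")
  }
  if (var(group_a) == 0 && var(group_b) == 0) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  tt <- t.test(group_a, group_b, alternative = alternative, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value), degenerate = FALSE)
}
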
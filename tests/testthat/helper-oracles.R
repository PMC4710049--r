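# Brute-force oracles and fixture builders shared across the test files.
# Oracles are deliberately naive (per-pixel / per-column loops) and never
# call the code paths they check.

# Nearest-nucleus Euclidean expansion oracle: per-pixel scan over all
# nucleus pixels, ties to the lowest label.
oracle_expand <- function(labels, distance) {
  H <- nrow(labels); W <- ncol(labels)
  out <- matrix(0L, H, W)
  nuc <- which(labels > 0L, arr.ind = TRUE)
  if (nrow(nuc) == 0L) return(out)
  lab <- labels[nuc]
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      if (labels[r, c] > 0L) { out[r, c] <- labels[r, c]; next }
      d2 <- (nuc[, 1] - r)^2 + (nuc[, 2] - c)^2
      best <- min(d2)
      if (best <= distance^2) out[r, c] <- min(lab[d2 == best])
    }
  }
  out
}

# Per-spot containment oracle: nearest nucleus pixel within `distance`,
# ties to the lowest label, else unassigned.
oracle_assign <- function(spots, labels, distance) {
  nuc <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[nuc]
  vapply(seq_len(nrow(spots)), function(i) {
    d2 <- (nuc[, 1] - spots$row[i])^2 + (nuc[, 2] - spots$col[i])^2
    best <- min(d2)
    if (best <= distance^2) min(lab[d2 == best]) else NA_integer_
  }, integer(1))
}

# Per-column discriminating-site oracle.
oracle_sites <- function(hs) {
  xm <- do.call(rbind, strsplit(hs$x, ""))
  ym <- do.call(rbind, strsplit(hs$y, ""))
  keep <- logical(ncol(xm)); xb <- yb <- character(ncol(xm))
  for (j in seq_len(ncol(xm))) {
    ux <- unique(xm[, j]); uy <- unique(ym[, j])
    if (length(ux) == 1 && length(uy) == 1 &&
        ux %in% c("A", "C", "G", "T") && uy %in% c("A", "C", "G", "T") &&
        ux != uy) {
      keep[j] <- TRUE; xb[j] <- ux; yb[j] <- uy
    }
  }
  list(position = which(keep), x_base = xb[keep], y_base = yb[keep])
}

welch_oracle <- function(a, b, alternative = "greater") {
  na <- length(a); nb <- length(b)
  se2a <- var(a) / na; se2b <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 / (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
  p <- if (alternative == "greater") pt(t, df, lower.tail = FALSE) else pt(t, df)
  list(t = t, df = df, p = p)
}

# Filled disc painter for hand-built images.
paint_disc <- function(img, r0, c0, rad, value = 1) {
  rs <- max(1, floor(r0 - rad)):min(nrow(img), ceiling(r0 + rad))
  cs <- max(1, floor(c0 - rad)):min(ncol(img), ceiling(c0 + rad))
  d2 <- outer((rs - r0)^2, (cs - c0)^2, "+")
  img[rs, cs][d2 <= rad^2] <- value
  img
}

gaussian_bump <- function(H, W, r0, c0, amp = 1, sigma = 1.5) {
  amp * exp(-outer((seq_len(H) - r0)^2, (seq_len(W) - c0)^2, "+") /
              (2 * sigma^2))
}

# Uniform spots inside the centered ellipse with fair-coin X/Y labels:
# the exchangeable null of the segregation test.
uniform_coin_spots <- function(seed, n = 500, H = 600, W = 600) {
  set.seed(seed)
  rows <- integer(0); cols <- integer(0)
  while (length(rows) < n) {
    r <- runif(2 * n, 1, H); c <- runif(2 * n, 1, W)
    ok <- ((r - (H + 1) / 2) / (0.45 * H))^2 +
      ((c - (W + 1) / 2) / (0.45 * W))^2 <= 1
    rows <- c(rows, round(r[ok])); cols <- c(cols, round(c[ok]))
  }
  spot_table(rows[1:n], cols[1:n],
             ifelse(runif(n) < 0.5, "X", "Y"))
}

# Random nucleus label image: disjoint discs, labels in raster order of
# their first pixel (as segment_nuclei would produce).
random_disc_labels <- function(seed, H = 50, W = 50, n = 3, rad = 3, sep = 12) {
  set.seed(seed)
  centers <- matrix(numeric(0), 0, 2)
  while (nrow(centers) < n) {
    p <- c(runif(1, rad + 1, H - rad), runif(1, rad + 1, W - rad))
    if (nrow(centers) == 0 ||
        min((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2) >= sep^2) {
      centers <- rbind(centers, p)
    }
  }
  img <- matrix(0, H, W)
  for (i in seq_len(n)) img <- paint_disc(img, centers[i, 1], centers[i, 2], rad)
  xyspots:::cpp_label_components(img > 0)
}

random_homolog_set <- function(seed, len = 30, nx = NULL, ny = NULL) {
  set.seed(seed)
  if (is.null(nx)) nx <- sample(1:4, 1)
  if (is.null(ny)) ny <- sample(1:4, 1)
  alphabet <- c("A", "C", "G", "T", "N", "-")
  base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  mutate <- function() {
    s <- base
    k <- sample(0:6, 1)
    if (k > 0) {
      at <- sample(len, k)
      s[at] <- sample(alphabet, k, replace = TRUE)
    }
    paste(s, collapse = "")
  }
  homolog_set(replicate(nx, mutate()), replicate(ny, mutate()))
}
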
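test_that("kernel construction is odd-windowed and unit-mass", {
  k <- kernel_spec(150, 25)
  expect_equal(k$window, 151L)
  expect_length(k$k1d, 151L)
  expect_equal(sum(k$k1d), 1, tolerance = 1e-12)
  expect_error(kernel_spec(sd = 0), "sd")
  kr <- kernel_spec(150, 25, normalized = FALSE)
  expect_equal(max(kr$k1d), 1)
})

test_that("density maps conserve mass, peak at spots, and are linear", {
  k <- kernel_spec()
  one <- spot_table(200, 150, "X")
  d <- density_map(one, c(400, 400), k)
  expect_equal(sum(d$maps$X), 1, tolerance = 1e-9)
  peak <- which(d$maps$X == max(d$maps$X), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(200, 150))

  # linearity: map(A union B) = map(A) + map(B)
  set.seed(3)
  a <- spot_table(sample(100:300, 40), sample(100:300, 40), "X")
  b <- spot_table(sample(100:300, 25), sample(100:300, 25), "X")
  dab <- density_map(rbind(a, b), c(400, 400), k)$maps$X
  expect_equal(dab,
               density_map(a, c(400, 400), k)$maps$X +
                 density_map(b, c(400, 400), k)$maps$X,
               tolerance = 1e-12)

  # empty spot set: all-zero map, not an error
  d0 <- density_map(spot_table(), c(50, 50), k, genes = "X")
  expect_true(all(d0$maps$X == 0))
  expect_error(density_map(spot_table(500, 1, "X"), c(400, 400), k), "outside")
})

test_that("purity is the bounded Y fraction with background masking", {
  x <- matrix(1, 10, 10); y <- matrix(1, 10, 10)
  expect_true(all(purity_field(x, y)$purity == 0.5))
  expect_true(all(purity_field(0 * x, y, eps = 1e-6)$purity == 1))
  p <- purity_field(x, 4 * x, eps = 1e-6)
  expect_true(all(p$purity == 0.8))
  h <- purity_histogram(p, n_bins = 50, cutoff = 0.8)
  expect_equal(unname(h$proportions["y_dominant"]), 1)
  expect_error(purity_field(x - 2, y), "non-negative")
  # masking: all-background field cannot be summarized
  z <- matrix(0, 5, 5)
  expect_error(purity_histogram(purity_field(z, z)), "masked")
})

test_that("purity histograms bin, normalize and categorize correctly", {
  p <- matrix(0.5, 20, 50)
  p[, 1:15] <- 0.9 # 30 % of pixels y-dominant
  f <- structure(list(purity = p, eps = 0), class = "xy_purity")
  h <- purity_histogram(f, n_bins = 50, cutoff = 0.8)
  expect_equal(sum(h$counts), 1000L)
  expect_equal(sum(h$freq), 1)
  expect_equal(sum(h$proportions), 1)
  expect_equal(unname(h$proportions["y_dominant"]), 0.3)
  expect_equal(unname(h$proportions["mixed"]), 0.7)
  expect_equal(h$counts[26], 700L) # 0.5 falls in bin [0.50, 0.52)
  expect_equal(h$counts[46], 300L) # 0.9 falls in bin [0.90, 0.92)

  # raising the cutoff never increases the dominant proportions
  h2 <- purity_histogram(f, n_bins = 50, cutoff = 0.95)
  expect_lte(h2$proportions["y_dominant"], h$proportions["y_dominant"])
  expect_lte(h2$proportions["x_dominant"], h$proportions["x_dominant"])
})

test_that("the permutation null is exchangeable, seeded, and self-consistent", {
  sp <- uniform_coin_spots(1, n = 220, H = 300, W = 300)
  pn <- permutation_null(sp, c(300, 300), "X", "Y", n_rand = 60, seed = 5)
  pn2 <- permutation_null(sp, c(300, 300), "X", "Y", n_rand = 60, seed = 5)
  expect_identical(pn, pn2) # bit-identical under a fixed seed
  expect_true(all(pn$ci["lower", ] <= pn$ci["upper", ]))
  expect_equal(sum(pn$observed$proportions), 1)
  # the C++ randomization path agrees with the R histogram path on the
  # identity permutation
  obs_freq <- pn$observed$freq
  st <- xyspots:::cpp_perm_purity_stats(
    sp$row, sp$col, matrix(sp$gene == "X", 1),
    xyspots:::cpp_splat_density(sp$row, sp$col, 300L, 300L, kernel_spec()$k1d),
    kernel_spec()$k1d, pn$eps, 50L, 0.8)
  expect_equal(as.vector(st$freq), obs_freq, tolerance = 1e-12)
  expect_equal(as.vector(st$props), unname(pn$observed$proportions),
               tolerance = 1e-12)

  expect_error(permutation_null(sp, c(300, 300), "X", "Y", n_rand = 1),
               "n_rand")
  expect_error(permutation_null(spot_table(), c(10, 10), "X", "Y"),
               "labelled spot")
})

test_that("a single-label pattern degenerates to a zero-variance null", {
  sp <- spot_table(c(40, 60, 80, 90), c(40, 50, 60, 20), rep("X", 4))
  pn <- permutation_null(sp, c(120, 120), "X", "Y", n_rand = 10, seed = 2)
  expect_true(all(pn$bin_sd == 0))
  expect_true(all(pn$bin_flags == 0L))
  expect_false(any(pn$outside_ci))
})

test_that("flagged-pixel maps select exactly the over-represented bins", {
  p <- matrix(c(0.92, 0.5, 0.91, NA, 0.3, 0.93), 2, 3)
  f <- structure(list(purity = p, eps = 0), class = "xy_purity")
  flags <- integer(50); flags[47] <- 1L # bin (0.92, 0.94]
  m <- flag_pixels(f, flags)
  expect_equal(which(m), which(!is.na(p) & p >= 0.92 & p < 0.94))
  expect_false(any(flag_pixels(f, integer(50))))
  # counting identity against the bin frequencies
  h <- purity_histogram(f, n_bins = 50)
  expect_equal(sum(flag_pixels(f, flags)), h$counts[47])
})

test_that("dorsoventral partition matches a per-pixel line-side oracle", {
  mask <- matrix(TRUE, 40, 60)
  part <- dorsoventral_partition(mask, rbind(c(10, 5), c(30, 5)),
                                 rbind(c(10, 55), c(30, 55)))
  # symmetric landmarks: border at row 20, on-line pixels are ventral
  expect_equal(sum(part$region == 1L), 19 * 60)
  expect_equal(sum(part$region == 2L), 21 * 60)
  expect_equal(part$region[19, 30], 1L)
  expect_equal(part$region[20, 30], 2L)

  # slanted border against the oracle
  set.seed(8)
  mask2 <- matrix(runif(50 * 50) < 0.8, 50, 50)
  mask2[c(12, 40), 6] <- TRUE; mask2[c(8, 44), 45] <- TRUE
  part2 <- dorsoventral_partition(mask2, rbind(c(12, 6), c(40, 6)),
                                  rbind(c(8, 45), c(44, 45)))
  ml <- c(26, 6); mr <- c(26, 45)
  slope <- (mr[1] - ml[1]) / (mr[2] - ml[2])
  for (i in seq_len(50)) for (j in seq_len(50)) {
    expected <- if (!mask2[i, j]) 0L else {
      border <- ml[1] + slope * (j - ml[2])
      if (i < border) 1L else 2L
    }
    if (part2$region[i, j] != expected) {
      fail(sprintf("mismatch at (%d, %d)", i, j))
    }
  }
  succeed()

  expect_error(dorsoventral_partition(mask, rbind(c(10, 5), c(10, 5)),
                                      rbind(c(10, 55), c(30, 55))),
               "degenerate")
  expect_error(dorsoventral_partition(mask, rbind(c(100, 5), c(30, 5)),
                                      rbind(c(10, 55), c(30, 55))),
               "outside the tissue mask")
})

test_that("regional X:Y ratios and the Welch test match their oracles", {
  mask <- matrix(TRUE, 40, 40)
  part <- dorsoventral_partition(mask, rbind(c(10, 2), c(30, 2)),
                                 rbind(c(10, 39), c(30, 39)))
  sp <- rbind(
    spot_table(rep(5, 15), 1:15, c(rep("X", 10), rep("Y", 5))),    # dorsal
    spot_table(rep(35, 25), 1:25, c(rep("X", 20), rep("Y", 5))))   # ventral
  rr <- region_ratio(sp, part, "X", "Y")
  expect_equal(rr$ratio, c(2, 4))
  expect_true(all(rr$defined))
  # zero Y in a region flags the ratio undefined
  sp2 <- sp[sp$gene == "X" | sp$row == 5, ]
  rr2 <- region_ratio(sp2, part, "X", "Y")
  expect_true(is.na(rr2$ratio[rr2$region == "ventral"]))
  expect_false(rr2$defined[rr2$region == "ventral"])

  w <- welch_one_tailed(c(1, 2, 3), c(1, 2, 3), "greater")
  expect_equal(w$t, 0)
  expect_equal(w$p, 0.5)
  wd <- welch_one_tailed(c(2, 2, 2), c(2, 2, 2))
  expect_true(wd$degenerate)
  # independent closed-form oracle
  set.seed(9)
  for (i in 1:5) {
    a <- rnorm(4 + i); b <- rnorm(7, 0.5)
    for (alt in c("greater", "less")) {
      got <- welch_one_tailed(a, b, alt)
      ora <- welch_oracle(a, b, alt)
      expect_equal(got$t, ora$t, tolerance = 1e-6)
      expect_equal(got$df, ora$df, tolerance = 1e-6)
      expect_equal(got$p, ora$p, tolerance = 1e-6)
    }
  }
  expect_error(welch_one_tailed(1, c(1, 2)), "at least 2")
})

test_that("ventral X enrichment raises the ventral X:Y ratio", {
  ratios <- matrix(NA_real_, 6, 2)
  for (i in 1:6) {
    cf <- scene_config(image_height = 300, image_width = 300,
                       tissue_shape = "ellipse", n_cells = 250,
                       class_proportions = c(no_signal = 0.5, x_only = 0.25,
                                             y_only = 0.25, mixed = 0),
                       spots_per_expressing_cell_mean = 2,
                       ventral_x_enrichment = 3, seed = 40 + i)
    sc <- generate_scene(cf)
    part <- dorsoventral_partition(sc$tissue_mask,
                                   rbind(c(100, 150), c(200, 150)),
                                   rbind(c(100, 160), c(200, 160)))
    rr <- region_ratio(sc$spots, part, "PCDH11X", "PCDH11Y")
    ratios[i, ] <- rr$ratio
  }
  expect_gt(mean(ratios[, 2]), mean(ratios[, 1])) # ventral > dorsal
})
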
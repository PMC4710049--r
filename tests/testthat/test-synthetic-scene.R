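test_that("degenerate scenes and seeded reruns are handled exactly", {
  cf0 <- scene_config(image_height = 64, image_width = 64, n_cells = 0, seed = 3)
  sc0 <- generate_scene(cf0)
  expect_equal(nrow(sc0$nuclei), 0L)
  expect_equal(nrow(sc0$spots), 0L)

  cf <- scene_config(image_height = 150, image_width = 150, n_cells = 40,
                     class_proportions = c(no_signal = 0.4, x_only = 0.25,
                                           y_only = 0.25, mixed = 0.1),
                     seed = 11)
  expect_identical(generate_scene(cf), generate_scene(cf))
  sc <- generate_scene(cf)
  expect_identical(render_scene(sc), render_scene(sc))
})

test_that("config validation rejects malformed parameter sets", {
  expect_error(scene_config(class_proportions = c(no_signal = 0.5, x_only = 0.5,
                                                  y_only = 0.1, mixed = 0)),
               "sum to 1")
  expect_error(scene_config(n_cells = -1), "n_cells")
  expect_error(scene_config(image_height = 0), "dimensions")
  expect_error(scene_config(ventral_x_enrichment = 0.5), "ventral_x_enrichment")
})

test_that("nuclei respect the tissue mask and the hard-core separation", {
  for (shape in c("ellipse", "half_annulus")) {
    cf <- scene_config(image_height = 220, image_width = 260,
                       tissue_shape = shape, n_cells = 60,
                       min_nucleus_separation = 9, seed = 5)
    sc <- generate_scene(cf)
    expect_equal(nrow(sc$nuclei), 60L)
    expect_length(sc$nuclei$class, 60L)
    at <- cbind(ceiling(sc$nuclei$row - 0.5), ceiling(sc$nuclei$col - 0.5))
    expect_true(all(sc$tissue_mask[at]))
    d <- as.matrix(dist(cbind(sc$nuclei$row, sc$nuclei$col)))
    diag(d) <- Inf
    expect_gte(min(d), cf$min_nucleus_separation)
  }
})

test_that("impossible packing densities raise a placement-failure error", {
  cf <- scene_config(image_height = 30, image_width = 30,
                     tissue_shape = "full_frame", n_cells = 100,
                     min_nucleus_separation = 10, seed = 1)
  expect_error(generate_scene(cf), "failed to place")
})

test_that("realized class frequencies match the configured proportions", {
  p <- c(no_signal = 0.8, x_only = 0.1, y_only = 0.1, mixed = 0)
  cf <- scene_config(image_height = 800, image_width = 800,
                     tissue_shape = "full_frame", n_cells = 10000,
                     min_nucleus_separation = 4, nucleus_radius_mean = 1.5,
                     nucleus_radius_sd = 0.1, class_proportions = p, seed = 42)
  sc <- generate_scene(cf)
  cnt <- table(factor(sc$nuclei$class, levels = names(p)))
  expect_equal(unname(cnt[["mixed"]]), 0L)
  for (k in c("no_signal", "x_only", "y_only")) {
    tol <- 3 * sqrt(10000 * p[[k]] * (1 - p[[k]]))
    expect_lt(abs(cnt[[k]] - 10000 * p[[k]]), tol)
  }
})

test_that("spot labels and counts honour the per-class contract", {
  cf <- scene_config(image_height = 300, image_width = 300, n_cells = 150,
                     class_proportions = c(no_signal = 0.2, x_only = 0.3,
                                           y_only = 0.3, mixed = 0.2),
                     spots_per_expressing_cell_mean = 2, seed = 8)
  sc <- generate_scene(cf)
  gx <- unname(cf$genes["x"]); gy <- unname(cf$genes["y"])
  for (i in which(sc$nuclei$class != "no_signal")) {
    g <- sc$spots$gene[sc$spots$cell_id == i & !is.na(sc$spots$cell_id)]
    expect_gte(length(g), 1L)
    switch(sc$nuclei$class[i],
      x_only = expect_true(all(g == gx)),
      y_only = expect_true(all(g == gy)),
      mixed = { expect_true(any(g == gx)); expect_true(any(g == gy)) })
  }
  # no spots for silent cells
  silent <- which(sc$nuclei$class == "no_signal")
  expect_false(any(sc$spots$cell_id %in% silent))
})

test_that("rendering produces background, bumps, discs and seeded noise", {
  cf <- scene_config(image_height = 80, image_width = 80, n_cells = 4,
                     tissue_shape = "full_frame", min_nucleus_separation = 20,
                     class_proportions = c(no_signal = 1, x_only = 0,
                                           y_only = 0, mixed = 0),
                     noise_sd = 0, seed = 2)
  ch <- render_scene(generate_scene(cf))
  gx <- unname(cf$genes["x"])
  expect_true(all(ch[[gx]] == cf$background_level))
  expect_equal(sort(unique(as.vector(ch$nuclei))),
               cf$background_level + c(0, 1))

  cf1 <- scene_config(image_height = 80, image_width = 80, n_cells = 1,
                      tissue_shape = "full_frame",
                      class_proportions = c(no_signal = 0, x_only = 1,
                                            y_only = 0, mixed = 0),
                      spots_per_expressing_cell_mean = 1e-4,
                      noise_sd = 0, seed = 9)
  sc1 <- generate_scene(cf1)
  expect_equal(nrow(sc1$spots), 1L)
  img <- render_scene(sc1)[[gx]]
  peak <- which(img == max(img), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(sc1$spots$row[1], sc1$spots$col[1]))

  # noise is reproducible from the scene seed
  cf2 <- scene_config(image_height = 60, image_width = 60, n_cells = 3,
                      noise_sd = 0.05, seed = 13)
  sc2 <- generate_scene(cf2)
  expect_identical(render_scene(sc2), render_scene(sc2))
})

test_that("scene configs round-trip through YAML", {
  cf <- scene_config(image_height = 90, image_width = 120, n_cells = 10,
                     seed = 4)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(image_height = 90, image_width = 120, n_cells = 10,
                        seed = 4), path)
  expect_identical(read_scene_config(path), cf)
  yaml::write_yaml(list(image_height = 90, bogus_key = 1), path)
  expect_error(read_scene_config(path), "unknown scene config keys")
})
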
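test_that("chi-squared distance matches hand-computed values", {
  g <- c(100, rep(0, 13)); h <- c(0, 100, rep(0, 12))
  expect_equal(chi2_distance(g, g), 0)
  expect_equal(chi2_distance(g, h), 100)  # 0.5*(100^2/100 + 100^2/100)
  g2 <- c(50, 50, rep(0, 12)); h2 <- c(100, rep(0, 13))
  expect_equal(chi2_distance(g2, h2), 0.5 * (2500 / 150 + 2500 / 50),
               tolerance = 1e-12)
  expect_equal(chi2_distance(g2, h2), 33.33333, tolerance = 1e-6)
  expect_error(chi2_distance(c(50, 40), c(50, 50)), "normalised")
  # no-half variant
  expect_equal(chi2_distance(g2, h2, half = FALSE), 2 * chi2_distance(g2, h2))
})

test_that("chi-squared distance is symmetric, bounded and zero iff equal", {
  set.seed(21)
  for (i in 1:20) {
    g <- runif(14); g <- 100 * g / sum(g)
    h <- runif(14); h <- 100 * h / sum(h)
    expect_equal(chi2_distance(g, h), chi2_distance(h, g))
    expect_gte(chi2_distance(g, h), 0)
    expect_lte(chi2_distance(g, h), 100)
    expect_equal(chi2_distance(g, g), 0)
  }
})

test_that("clustering signatures are the per-region cluster percentages", {
  labels <- matrix(2L, 10, 10)
  labels[1:5, ] <- 1L
  mask <- region_mask(labels)
  texlab <- matrix(1L, 10, 10)
  texlab[labels == 1L][1:25] <- 2L  # half the egg region in cluster 2
  tex <- manual_texture_map(texlab, n_clusters = 3)
  s_egg <- clustering_signature(tex, mask, "egg")
  expect_equal(as.numeric(s_egg), c(50, 50, 0))
  s_nest <- clustering_signature(tex, mask, "nest")
  expect_equal(as.numeric(s_nest), c(100, 0, 0))
  expect_equal(sum(s_egg), 100)
  expect_error(clustering_signature(tex, mask, "external"), "no analysed pixels")
})

test_that("K-means texture clustering is deterministic and a Lloyd fixed point", {
  sc <- make_scene(scene_spec(size = c(48, 48), egg_n = 1,
                              egg_axes_px = c(6, 4), seed = 3))
  lab <- prepare_lab(sc, margin = 0)
  st <- apply_bank(lab, small_bank(scales = c(2, 4), n_orientations = 2))
  t1 <- cluster_textures(st, sc$mask, n_clusters = 3, seed = 5)
  t2 <- cluster_textures(st, sc$mask, n_clusters = 3, seed = 5)
  expect_identical(t1$labels, t2$labels)

  # assignment oracle: every pixel sits with its nearest cluster centroid
  sel <- which(sc$mask$labels != 0L)
  d <- dim(st$features)
  x <- matrix(st$features, d[1] * d[2], d[3])[sel[1:200], , drop = FALSE]
  t3 <- cluster_textures(structure(list(features = array(x, c(200, 1, d[3])),
                                        channel_order = st$channel_order),
                                   class = "feature_stack"),
                         region_mask(matrix(2L, 200, 1)),
                         n_clusters = 3, seed = 7)
  labs <- as.vector(t3$labels)
  centroids <- t(vapply(1:3, function(k) colMeans(x[labs == k, , drop = FALSE]),
                        numeric(d[3])))
  nearest <- apply(x, 1, function(v)
    which.min(colSums((t(centroids) - v)^2)))
  expect_equal(labs, unname(nearest))
})

test_that("constant features collapse to one cluster with empty boundaries", {
  st <- structure(list(features = array(1, c(10, 10, 4)),
                       channel_order = letters[1:4]), class = "feature_stack")
  mask <- region_mask(matrix(2L, 10, 10))
  expect_warning(tex <- cluster_textures(st, mask, n_clusters = 4, seed = 1),
                 "distinct")
  expect_equal(tex$n_clusters, 1L)
  expect_false(any(tex$boundaries))
})

test_that("texture boundaries are one pixel thick on the lower-label side", {
  labels <- matrix(1L, 6, 6)
  labels[, 4:6] <- 2L
  b <- nestcamo:::texture_boundaries(labels)
  expect_true(all(b[, 3]))
  expect_equal(sum(b), 6)
})

test_that("two-texture scene is recovered by k = 2 clustering", {
  sc <- make_scene(two_texture_spec(size = 128, seed = 6))
  mask <- exclude_border(sc$mask, 0.02)
  lab <- rgb_to_lab(sc$scene, STD, mask = mask)
  st <- apply_bank(lab, small_bank(scales = c(4, 8), n_orientations = 3))
  tex <- cluster_textures(st, mask, n_clusters = 2, seed = 5)
  sel <- which(mask$labels %in% c(2L, 3L, 4L))
  agree <- binary_agreement(tex$labels, mask$labels %in% c(2L, 3L), sel)
  expect_gte(agree, 0.95)
})

test_that("cluster-count selection returns the elbow of the correlation curve", {
  scenes <- lapply(1:2, function(s) {
    sc <- make_scene(scene_spec(size = c(64, 64), egg_n = 1,
                                egg_axes_px = c(8, 6), seed = s))
    prepare_lab(sc, margin = 0.02)
  })
  scenes <- lapply(scenes, function(l) { l })
  bank <- small_bank(scales = c(2, 4), n_orientations = 2)
  res <- select_n_clusters(scenes, bank, candidates = c(2, 4, 6), seed = 3)
  expect_true(res$n_clusters %in% c(2, 4, 6))
  expect_equal(nrow(res$curve), 3)
  expect_true(all(is.finite(res$curve$mean_correlation)))
  one <- select_n_clusters(scenes[1:2], bank, candidates = 2, seed = 3)
  expect_equal(one$n_clusters, 2)
  expect_error(select_n_clusters(scenes, bank, candidates = numeric(0)),
               "empty")
})

test_that("identical egg and external textures give near-unit correlation", {
  # same lightness/grain in all regions: egg and external signatures agree
  sc <- make_scene(scene_spec(size = c(64, 64), egg_n = 1, egg_axes_px = c(8, 6),
                              region_L = c(egg = 28, nest = 28, internal = 28,
                                           external = 28),
                              region_grain = c(egg = 2, nest = 2, internal = 2,
                                               external = 2),
                              region_contrast = c(egg = 6, nest = 6,
                                                  internal = 6, external = 6),
                              seed = 4))
  lab <- prepare_lab(sc, margin = 0.02)
  res <- select_n_clusters(list(lab), small_bank(scales = c(2, 4), n_orientations = 2),
                           candidates = c(2, 4), seed = 3)
  expect_true(all(res$curve$mean_correlation > 0.8))
})

test_that("scene_report emits the full per-image row schema", {
  sc <- make_scene(scene_spec(size = c(64, 64), egg_n = 1,
                              egg_axes_px = c(8, 6), seed = 12))
  lab <- prepare_lab(sc)
  bank <- small_bank(scales = c(2, 4), n_orientations = 2)
  row <- scene_report(lab, bank, n_clusters = 4, seed = 5, id = "img1")
  expect_equal(row$id, "img1")
  sig_cols <- grep("_sig", names(row), value = TRUE)
  expect_length(sig_cols, 4 * 4)
  for (r in c("egg", "nest", "internal", "external"))
    expect_equal(sum(row[, paste0(r, "_sig", 1:4)]), 100)
  expect_true(all(c("egg_border_pct", "score_egg_nest", "score_egg_external",
                    "score_nest_external") %in% names(row)))
  row2 <- scene_report(lab, bank, n_clusters = 4, seed = 5, id = "img1")
  attr(row, "texture_map") <- attr(row2, "texture_map") <- NULL
  expect_equal(row, row2)
})
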
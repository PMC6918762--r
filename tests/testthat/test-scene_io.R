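test_that("synthetic scenes round-trip through disk and load_scene", {
  sc <- make_scene(scene_spec(size = c(64, 64), egg_n = 1,
                              egg_axes_px = c(7, 5), seed = 5))
  paths <- write_scene(sc, withr::local_tempdir(), "rt")
  ld <- load_scene(paths[["image"]], paths[["mask"]], pixel_scale = 0.5)
  expect_s3_class(ld$scene, "rgb_scene")
  expect_equal(dim(ld$scene$pixels), c(64, 64, 3))
  expect_equal(unname(ld$mask$labels), unname(sc$mask$labels))
  # 16-bit storage keeps reflectance values to ~1e-5
  expect_lt(max(abs(ld$scene$pixels - sc$scene$pixels)), 1e-4)
  # egg length recovered from the mask matches the generated major axis
  expect_equal(ld$mask$egg_lengths_px, sc$mask$egg_lengths_px)
  expect_equal(sc$mask$egg_lengths_px, sc$truth$egg_major_axes_px,
               tolerance = 0.05)
})

test_that("masks with unknown region codes are rejected", {
  labels <- matrix(0L, 8, 8)
  labels[3, 3] <- 7L
  expect_error(region_mask(labels), "unknown region code")
  d <- withr::local_tempdir()
  png::writePNG(array(runif(64 * 3), c(8, 8, 3)), file.path(d, "img.png"))
  png::writePNG(labels / 255, file.path(d, "mask.png"))
  expect_error(load_scene(file.path(d, "img.png"), file.path(d, "mask.png"), 1),
               "unknown region code")
})

test_that("mismatched mask dimensions are a hard error", {
  d <- withr::local_tempdir()
  png::writePNG(array(runif(64 * 3), c(8, 8, 3)), file.path(d, "img.png"))
  png::writePNG(matrix(0, 6, 6), file.path(d, "mask.png"))
  expect_error(load_scene(file.path(d, "img.png"), file.path(d, "mask.png"), 1),
               "do not match")
})

test_that("polygon JSON masks rasterise by the even-odd rule at pixel centers", {
  d <- withr::local_tempdir()
  png::writePNG(array(0.5, c(10, 10, 3)), file.path(d, "img.png"))
  # rows 2..5, cols 3..7 (0-based vertex coords, half-open at centers)
  poly <- list(list(code = 2,
                    xy = list(c(1.5, 2.5), c(1.5, 7.5), c(5.5, 7.5), c(5.5, 2.5))))
  jsonlite::write_json(poly, file.path(d, "mask.json"), auto_unbox = TRUE)
  ld <- load_scene(file.path(d, "img.png"), file.path(d, "mask.json"), 1)
  expect_equal(sum(ld$mask$labels == 2L), 4 * 5)
  expect_true(all(ld$mask$labels[3:6, 4:8] == 2L))
})

test_that("exclude_border strips the expected frame and nothing else", {
  labels <- matrix(4L, 100, 100)
  labels[40:60, 40:60] <- 2L
  m <- region_mask(labels)
  expect_equal(exclude_border(m, 0)$labels, m$labels)
  m2 <- exclude_border(m, 0.02)
  expect_true(all(m2$labels[1:2, ] == 0L) && all(m2$labels[, 99:100] == 0L))
  expect_equal(m2$labels[3:98, 3:98], m$labels[3:98, 3:98])
  # 10x10 at 0.49: only the central 2x2 survives
  m10 <- region_mask(matrix(4L, 10, 10))
  m10b <- exclude_border(m10, 0.49)
  expect_equal(sum(m10b$labels != 0L), 4)
  expect_true(all(m10b$labels[5:6, 5:6] == 4L))
})

test_that("exclude_border is idempotent and conserves pixel counts", {
  sc <- make_scene(scene_spec(size = c(64, 64), egg_n = 1,
                              egg_axes_px = c(7, 5), seed = 2))
  m1 <- exclude_border(sc$mask, 0.05)
  m2 <- exclude_border(m1, 0.05)
  expect_equal(m1$labels, m2$labels)
  expect_equal(sum(table(m1$labels)), 64 * 64)
  edge_egg <- matrix(0L, 10, 10)
  edge_egg[1, 5] <- 1L
  expect_warning(exclude_border(region_mask(edge_egg), 0.2), "emptied")
})

test_that("Lab conversion maps the gray standard to its reference lightness", {
  px <- array(0.18, c(8, 8, 3))
  px[1, 1, ] <- 0  # one black pixel
  lab <- rgb_to_lab(rgb_scene(px, 1), gray_standard(0.18))
  expect_equal(lab$L[2, 2], 116 * 0.18^(1 / 3) - 16, tolerance = 1e-3)
  expect_equal(lab$a[2, 2], 0, tolerance = 1e-6)
  expect_equal(lab$b[2, 2], 0, tolerance = 1e-6)
  expect_equal(lab$L[1, 1], 0, tolerance = 1e-6)
})

test_that("Lab conversion is invariant to global exposure scaling", {
  set.seed(3)
  px <- array(runif(8 * 8 * 3, 0.05, 0.4), c(8, 8, 3))
  lab1 <- rgb_to_lab(rgb_scene(px, 1), gray_standard(0.2))
  lab2 <- rgb_to_lab(rgb_scene(px * 2, 1), gray_standard(0.4))
  expect_equal(lab1$L, lab2$L, tolerance = 1e-6)
  expect_equal(lab1$a, lab2$a, tolerance = 1e-6)
  expect_equal(lab1$b, lab2$b, tolerance = 1e-6)
})

test_that("overexposure raises a clipping warning", {
  px <- array(0.9, c(10, 10, 3))  # 10x brighter than the standard: clips
  expect_warning(rgb_to_lab(rgb_scene(px, 1), gray_standard(0.09)), "clipped")
})

test_that("region reflectance is measured against the gray standard", {
  labels <- matrix(4L, 10, 10)
  labels[1:5, ] <- 2L
  mask <- region_mask(labels)
  px <- array(0, c(10, 10, 3))
  for (k in 1:3) px[, , k] <- ifelse(labels == 2L, 0.18, 0.36)
  sc <- rgb_scene(px, 1)
  std <- gray_standard(0.18)
  expect_equal(reflectance_of_region(sc, std, mask, "nest"), 0.18)
  expect_equal(reflectance_of_region(sc, std, mask, "external"), 0.36)
  expect_error(reflectance_of_region(sc, std, mask, "egg"), "empty")
})

test_that("generated material reflectance is recovered from the rendered scene", {
  # external region rendered at a known reflectance via its L* preset
  refl_target <- 0.55
  L_target <- 116 * refl_target^(1 / 3) - 16
  sc <- make_scene(scene_spec(size = c(64, 64), egg_n = 0,
                              region_L = c(egg = 30, nest = 30, internal = 30,
                                           external = L_target),
                              region_contrast = c(egg = 0, nest = 0,
                                                  internal = 0, external = 0),
                              seed = 9))
  got <- reflectance_of_region(sc$scene, gray_standard(0.18), sc$mask, "external")
  expect_equal(got, refl_target, tolerance = 0.01)
})
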
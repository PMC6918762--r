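# Shared fixtures: all synthetic, generated in code. Synthetic scenes are
# rendered at reduced size relative to multi-megapixel field photographs, so
# the analysis bank uses correspondingly reduced scales (grain sizes of a few
# pixels vs the field protocol's 16-48).

STD <- gray_standard(0.18)

small_bank <- function(scales = c(3, 6), n_orientations = 3) {
  build_bank(scales = scales, n_orientations = n_orientations)
}

# scene with two textured regions (nest+internal vs external) differing in
# lightness and speckle grain; no eggs
two_texture_spec <- function(size = 256, seed = 42,
                             nest_L = 33, ext_L = 25,
                             nest_grain = 5, ext_grain = 1.5, contrast = 8) {
  scene_spec(size = c(size, size), egg_n = 0,
             region_L = c(egg = ext_L, nest = nest_L,
                          internal = nest_L, external = ext_L),
             region_grain = c(egg = ext_grain, nest = nest_grain,
                              internal = nest_grain, external = ext_grain),
             region_contrast = c(egg = contrast, nest = contrast,
                                 internal = contrast, external = contrast),
             seed = seed)
}

# flat (zero-contrast) scene: every region the same constant lightness
flat_spec <- function(size = 96, seed = 11, L = 28) {
  scene_spec(size = c(size, size), egg_n = 1, egg_axes_px = c(10, 7),
             region_L = c(egg = L, nest = L, internal = L, external = L),
             region_grain = c(egg = 2, nest = 2, internal = 2, external = 2),
             region_contrast = c(egg = 0, nest = 0, internal = 0, external = 0),
             seed = seed)
}

prepare_lab <- function(sc, margin = 0.02) {
  mask <- exclude_border(sc$mask, margin)
  rgb_to_lab(sc$scene, STD, mask = mask)
}

# best two-way pixel agreement between a k=2 label map and a logical truth
binary_agreement <- function(labels, truth, sel) {
  pred <- (labels == 1)[sel]
  tr <- truth[sel]
  max(mean(pred == tr), mean(pred != tr))
}

# hand-built texture map from a given label matrix (no clustering involved)
manual_texture_map <- function(labels, n_clusters = max(labels, na.rm = TRUE)) {
  structure(list(labels = labels, n_clusters = n_clusters,
                 boundaries = nestcamo:::texture_boundaries(labels),
                 tot_withinss = NA_real_),
            class = "texture_map")
}

# square-egg mask: filled square of side `side` with top-left corner (r0, c0)
# inside an image of dims `dims`; everything else nest (code 2)
square_egg_mask <- function(dims = c(48, 48), r0 = 16, c0 = 16, side = 11) {
  labels <- matrix(2L, dims[1], dims[2])
  labels[r0:(r0 + side - 1), c0:(c0 + side - 1)] <- 1L
  region_mask(labels)
}
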
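# Seeded synthetic nest scenes and heating curves. The generator emulates the
# statistical structure the analyses assume — three nested regions (eggs in a
# nest bowl in a microhabitat) differing in mean lightness and texture grain,
# plus exponential egg-heating curves — not photorealistic renderings.
#
# Default region lightnesses are the field means observed in unmanipulated
# nests (egg L* = 25.31, nest L* = 32.28, microhabitat L* = 28.42).

#' Synthetic scene specification
#'
#' @param size c(H, W) in pixels.
#' @param pixel_scale mm per pixel.
#' @param egg_n number of eggs (Kentish plover clutches have up to 3).
#' @param egg_axes_px semi-axes c(a, b) of each egg ellipse, px.
#' @param region_L named vector of mean lightness (L* units) for egg, nest,
#'   internal, external.
#' @param region_grain named vector of texture grain (blur sigma, px).
#' @param region_contrast named vector of speckle lightness contrast (L*).
#' @param treatment `"O"` (original), `"T"` (material added: nest retextured
#'   with `material_L` lightness), or `"W"` (one week later: material patches
#'   retained over `retained_fraction` of the nest).
#' @param material_L lightness of the experimental material (T/W only).
#' @param retained_fraction fraction of nest area still covered in W scenes,
#'   default 0.15 (the field estimate of material left after one week).
#' @param nest_radius_frac nest disc radius as a fraction of min(H, W).
#' @param internal_ring_px width of the internal buffer ring, px.
#' @param std_value linear value of the rendered gray-standard patch.
#' @param seed integer seed.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(size = c(128, 128), pixel_scale = 0.5,
                       egg_n = 2, egg_axes_px = c(12, 8),
                       region_L = c(egg = 25.31, nest = 32.28,
                                    internal = 30, external = 28.42),
                       region_grain = c(egg = 1.5, nest = 3,
                                        internal = 3, external = 2.5),
                       region_contrast = c(egg = 6, nest = 8,
                                           internal = 8, external = 7),
                       treatment = c("O", "T", "W"),
                       material_L = 60, retained_fraction = 0.15,
                       nest_radius_frac = 0.3, internal_ring_px = 3,
                       std_value = 0.18, seed = 1L) {
  treatment <- match.arg(treatment)
  stopifnot(length(size) == 2, all(size >= 32), pixel_scale > 0,
            egg_n >= 0, all(egg_axes_px > 0),
            retained_fraction >= 0, retained_fraction <= 1,
            internal_ring_px >= 1)
  nest_r <- nest_radius_frac * min(size)
  if (egg_n > 0 && max(egg_axes_px) * 2.2 > nest_r)
    stop("egg geometry infeasible: eggs do not fit inside the nest disc")
  structure(as.list(environment()), class = "scene_spec")
}

#' Render a synthetic nest scene
#'
#' Produces a neutral (a* = b* = 0) linear-RGB scene in reflectance units:
#' per-region speckle textures are seeded Gaussian noise, low-pass filtered
#' at the region grain, thresholded at the median into two-level patches at
#' `region_L ± contrast/2`, then mapped from L* to linear reflectance. A
#' gray-standard patch of known value is rendered in the top-left corner and
#' excluded (code 0) from the mask.
#'
#' @param spec a `scene_spec`.
#' @return list with `scene` (`rgb_scene`), `mask` (`region_mask`) and
#'   `truth` (generation ground truth: region lightnesses actually used,
#'   egg geometry, treatment fields, standard value, seed).
#' @export
make_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$size[1]; w <- spec$size[2]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(spec$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  labels <- region_layout(spec)
  region_L <- spec$region_L
  eff_nest_L <- region_L[["nest"]]
  Lmap <- matrix(0, h, w)
  material_mask <- matrix(FALSE, h, w)
  for (r in c("egg", "nest", "internal", "external")) {
    sel <- labels == REGION_CODES[[r]]
    if (!any(sel)) next
    field <- speckle_field(h, w, spec$region_grain[[r]])
    patt <- region_L[[r]] + spec$region_contrast[[r]] *
      (field > stats::median(field[sel])) - spec$region_contrast[[r]] / 2
    if (r == "nest" && spec$treatment != "O") {
      mat_field <- speckle_field(h, w, spec$region_grain[[r]] * 1.5)
      frac <- if (spec$treatment == "T") 1 else spec$retained_fraction
      thr <- stats::quantile(mat_field[sel], 1 - frac)
      mat <- sel & (mat_field >= thr)
      patt[mat] <- spec$material_L + spec$region_contrast[[r]] *
        ((field > stats::median(field[sel])) - 0.5)[mat]
      material_mask <- material_mask | mat
      eff_nest_L <- (1 - frac) * region_L[["nest"]] + frac * spec$material_L
    }
    Lmap[sel] <- patt[sel]
  }
  refl <- lab_L_to_Y(pmin(pmax(Lmap, 0), 100))
  # gray-standard patch, excluded from analysis
  ps <- max(4L, round(min(h, w) / 16))
  refl[seq_len(ps), seq_len(ps)] <- spec$std_value
  labels[seq_len(ps), seq_len(ps)] <- 0L
  material_mask[seq_len(ps), seq_len(ps)] <- FALSE
  px <- array(pmin(pmax(refl, 0), 1), c(h, w, 3))
  eggs <- attr(labels, "eggs")
  attr(labels, "eggs") <- NULL
  mask <- region_mask(labels)
  truth <- list(schema = "nestcamo-scene-truth/1",
                region_L = as.list(region_L),
                effective_nest_L = eff_nest_L,
                treatment = spec$treatment, material_L = spec$material_L,
                retained_fraction = spec$retained_fraction,
                egg_major_axes_px = if (length(eggs)) vapply(eggs, function(e) 2 * max(e$axes), numeric(1)) else numeric(0),
                std_value = spec$std_value, pixel_scale = spec$pixel_scale,
                seed = spec$seed)
  list(scene = rgb_scene(px, spec$pixel_scale,
                         meta = list(generator = "nestcamo synthetic")),
       mask = mask, material_mask = material_mask, truth = truth)
}

# Nested layout: external field, nest disc at center, internal ring between
# them, elliptical eggs placed on a ring inside the nest.
region_layout <- function(spec) {
  h <- spec$size[1]; w <- spec$size[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(rep(seq_len(h), w), h)
  xx <- matrix(rep(seq_len(w), each = h), h)
  rr <- sqrt((yy - cy)^2 + (xx - cx)^2)
  nest_r <- spec$nest_radius_frac * min(h, w)
  labels <- matrix(REGION_CODES[["external"]], h, w)
  labels[rr <= nest_r + spec$internal_ring_px] <- REGION_CODES[["internal"]]
  labels[rr <= nest_r] <- REGION_CODES[["nest"]]
  eggs <- list()
  if (spec$egg_n > 0) {
    a <- spec$egg_axes_px[1]; b <- spec$egg_axes_px[2]
    ring <- 0
    if (spec$egg_n > 1) {
      # adjacent egg centers must clear one major axis plus a 2 px gap
      ring_min <- (2 * max(a, b) + 2) / (2 * sin(pi / spec$egg_n))
      ring_max <- nest_r - max(a, b) - 2
      if (ring_min > ring_max)
        stop("egg geometry infeasible: ", spec$egg_n,
             " eggs of this size cannot be placed without overlap")
      ring <- min(max(ring_min, 0.55 * ring_max), ring_max)
    }
    for (i in seq_len(spec$egg_n)) {
      ang <- 2 * pi * (i - 1) / spec$egg_n + pi / 7
      ey <- cy + ring * sin(ang); ex <- cx + ring * cos(ang)
      orient <- ang + pi / 2
      u <- (xx - ex) * cos(orient) + (yy - ey) * sin(orient)
      v <- -(xx - ex) * sin(orient) + (yy - ey) * cos(orient)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      labels[inside] <- REGION_CODES[["egg"]]
      eggs[[i]] <- list(center = c(ey, ex), axes = c(a, b), angle = orient)
    }
  }
  attr(labels, "eggs") <- eggs
  labels
}

# Low-pass-filtered seeded Gaussian noise; grain = blur sigma in px.
speckle_field <- function(h, w, grain) {
  z <- matrix(stats::rnorm(h * w), h, w)
  if (grain <= 0) return(z)
  as.matrix(EBImage::gblur(z, sigma = grain))
}

# CIE inverse lightness: L* (0-100) -> relative luminance Y (0-1).
lab_L_to_Y <- function(L) {
  fy <- (L + 16) / 116
  ifelse(fy^3 > 216 / 24389, fy^3, (116 * fy - 16) * 27 / 24389)
}

#' Write a synthetic scene to disk
#'
#' Saves the image as 16-bit TIFF, the label mask as 8-bit PNG, and the
#' ground truth as JSON, for round-tripping through [load_scene()].
#'
#' @param sc result of [make_scene()].
#' @param dir output directory.
#' @param id basename for the three files.
#' @return invisibly, the three paths.
#' @export
write_scene <- function(sc, dir, id = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img <- file.path(dir, paste0(id, ".tif"))
  msk <- file.path(dir, paste0(id, "_mask.png"))
  tru <- file.path(dir, paste0(id, "_truth.json"))
  tiff::writeTIFF(sc$scene$pixels, img, bits.per.sample = 16L)
  png::writePNG(sc$mask$labels / 255, msk)
  jsonlite::write_json(sc$truth, tru, auto_unbox = TRUE, digits = NA)
  invisible(c(image = img, mask = msk, truth = tru))
}

#' Synthetic heating-curve specification
#'
#' Defaults follow the laboratory protocol: records every 15 s for 60 min.
#'
#' @param T_i,T_f initial and final temperature, degrees C.
#' @param Tc characteristic heating time, s.
#' @param interval sampling interval, s.
#' @param duration total duration, s.
#' @param noise_sd Gaussian measurement noise, degrees C.
#' @param seed integer seed.
#' @export
curve_spec <- function(T_i = 25, T_f = 45, Tc = 300, interval = 15,
                       duration = 3600, noise_sd = 0.2, seed = 1L) {
  stopifnot(Tc > 0, interval > 0, duration >= 5 * interval, noise_sd >= 0)
  structure(list(T_i = T_i, T_f = T_f, Tc = Tc, interval = interval,
                 duration = duration, noise_sd = noise_sd, seed = seed),
            class = "curve_spec")
}

#' Generate a synthetic heating series
#'
#' `T(t) = T_f + (T_i - T_f) * exp(-t/Tc)` plus seeded Gaussian noise.
#'
#' @param spec a `curve_spec`.
#' @param material,replicate labels attached to the series.
#' @return list with `series` (a `heating_series`) and `truth` (the spec).
#' @export
make_heating_curve <- function(spec, material = NA_character_, replicate = NA) {
  stopifnot(inherits(spec, "curve_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(spec$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  t <- seq(0, spec$duration, by = spec$interval)
  temp <- spec$T_f + (spec$T_i - spec$T_f) * exp(-t / spec$Tc) +
    stats::rnorm(length(t), sd = spec$noise_sd)
  list(series = heating_series(t, temp, material = material,
                               replicate = replicate),
       truth = unclass(spec))
}
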
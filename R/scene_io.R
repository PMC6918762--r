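#' @importFrom stats kmeans cor cor.test coef fitted lm approx rnorm runif sd setNames
#' @importFrom utils write.csv read.csv
NULL

REGION_CODES <- c(excluded = 0L, egg = 1L, nest = 2L, internal = 3L, external = 4L)

#' Calibrated linear-RGB nest scene
#'
#' Container for a linear RGB raster (values in \[0, 1\]) together with its
#' pixel-scale calibration. Pixel values are expected to be linear in scene
#' radiance (16-bit TIFF/PNG exports of RAW data, not gamma-encoded JPEGs);
#' RAW decoding itself is out of scope.
#'
#' @param pixels numeric H x W x 3 array, linear RGB in \[0, 1\].
#' @param pixel_scale mm per pixel, > 0.
#' @param meta optional named list of free-form provenance strings.
#' @return an object of class `rgb_scene`.
#' @export
rgb_scene <- function(pixels, pixel_scale, meta = list()) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (!all(is.finite(pixels))) stop("pixel values must be finite")
  if (min(pixels) < 0 || max(pixels) > 1) stop("pixel values must lie in [0, 1]")
  if (!is.numeric(pixel_scale) || length(pixel_scale) != 1L || pixel_scale <= 0)
    stop("pixel_scale must be a single positive number (mm per pixel)")
  structure(list(pixels = pixels, pixel_scale = pixel_scale, meta = meta),
            class = "rgb_scene")
}

#' Region-of-interest label mask
#'
#' Codes: 0 = excluded margin, 1 = egg, 2 = nest, 3 = internal buffer ring
#' (clustered but excluded from camouflage scores), 4 = external
#' (microhabitat). Egg instances are labelled connected components of the egg
#' region; each egg's length is the major-axis length of its best-fit ellipse,
#' in pixels.
#'
#' @param labels integer H x W matrix of region codes 0..4.
#' @param egg_instances optional integer H x W matrix of per-egg labels
#'   (0 outside eggs). Derived from 8-connected components when `NULL`.
#' @param egg_lengths_px optional numeric vector of per-egg major-axis lengths
#'   in pixels. Computed from image moments when `NULL`.
#' @return an object of class `region_mask`.
#' @export
region_mask <- function(labels, egg_instances = NULL, egg_lengths_px = NULL) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), unname(REGION_CODES))
  if (length(bad)) stop("unknown region code: ", paste(bad, collapse = ", "))
  egg <- labels == REGION_CODES[["egg"]]
  if (is.null(egg_instances)) {
    egg_instances <- if (any(egg)) {
      ei <- EBImage::bwlabel(matrix(as.numeric(egg), nrow(labels)))
      matrix(as.integer(ei), nrow(labels))
    } else matrix(0L, nrow(labels), ncol(labels))
  }
  if (is.null(egg_lengths_px) && any(egg)) {
    egg_lengths_px <- vapply(seq_len(max(egg_instances)), function(i) {
      ellipse_major_axis(egg_instances == i)
    }, numeric(1))
  }
  structure(list(labels = labels, egg_instances = egg_instances,
                 egg_lengths_px = egg_lengths_px),
            class = "region_mask")
}

# Major-axis length (px) of the best-fit ellipse of a binary blob: 4 sd of the
# pixel coordinates along the principal axis (equals the major axis for an
# ideal filled ellipse).
ellipse_major_axis <- function(bin) {
  idx <- which(bin, arr.ind = TRUE)
  if (nrow(idx) < 2L) return(1)
  v <- eigen(stats::cov(idx), symmetric = TRUE, only.values = TRUE)$values[1]
  4 * sqrt(max(v, 0))
}

#' Gray reference standard
#'
#' A patch of known diffuse reflectance (the field protocol uses an 18%
#' card) photographed in the scene; used to normalise linear pixel values to
#' reflectance units and to set the adapted white point of the Lab conversion.
#'
#' @param measured_value mean linear pixel value of the standard patch (> 0).
#' @param nominal_reflectance known reflectance fraction, default 0.18.
#' @export
gray_standard <- function(measured_value, nominal_reflectance = 0.18) {
  stopifnot(measured_value > 0,
            nominal_reflectance > 0, nominal_reflectance < 1)
  structure(list(measured_value = measured_value,
                 nominal_reflectance = nominal_reflectance),
            class = "gray_standard")
}

#' Load a scene raster and its region mask
#'
#' Reads a linear-RGB image (PNG or TIFF) and a paired ROI mask. Masks may be
#' a label raster (PNG/TIFF whose gray levels encode codes 0-4) or a polygon
#' JSON file (a list of `{code, xy}` polygons in 0-based row/col pixel
#' coordinates, rasterised by the even-odd rule at pixel centers).
#'
#' @param image_path path to a PNG/TIFF image.
#' @param mask_path path to a label raster or polygon JSON.
#' @param pixel_scale mm per pixel.
#' @return list with elements `scene` (`rgb_scene`) and `mask` (`region_mask`).
#' @export
load_scene <- function(image_path, mask_path, pixel_scale) {
  stopifnot(file.exists(image_path), file.exists(mask_path))
  px <- read_raster(image_path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  if (grepl("\\.json$", mask_path, ignore.case = TRUE)) {
    labels <- rasterize_polygon_mask(mask_path, dim(px)[1:2])
  } else {
    m <- read_raster(mask_path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    # gray levels encode small integer codes; 8-bit rasters store code/255
    labels <- round(m * if (max(m) <= 0.5) 255 else 1)
  }
  if (!all(dim(labels) == dim(px)[1:2]))
    stop("mask dimensions (", paste(dim(labels), collapse = "x"),
         ") do not match image (", paste(dim(px)[1:2], collapse = "x"), ")")
  list(scene = rgb_scene(px, pixel_scale, meta = list(image = image_path)),
       mask = region_mask(labels))
}

read_raster <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
  else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) tiff::readTIFF(path)
  else stop("unsupported raster format: ", path)
}

# Polygon JSON mask: [{"code": 2, "xy": [[r0,c0],[r1,c1],...]}, ...] with
# 0-based row/col vertices; later polygons overwrite earlier ones. Even-odd
# crossing test evaluated at pixel centers.
rasterize_polygon_mask <- function(path, dims) {
  polys <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  labels <- matrix(0L, dims[1], dims[2])
  centers_r <- rep(seq_len(dims[1]) - 1, times = dims[2])
  centers_c <- rep(seq_len(dims[2]) - 1, each = dims[1])
  for (p in polys) {
    xy <- if (is.matrix(p$xy)) p$xy else do.call(rbind, p$xy)
    inside <- point_in_polygon_evenodd(centers_r, centers_c, xy[, 1], xy[, 2])
    labels[inside] <- as.integer(p$code)
  }
  labels
}

point_in_polygon_evenodd <- function(pr, pc, vr, vc) {
  n <- length(vr)
  inside <- logical(length(pr))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vc[i] > pc) != (vc[j] > pc)) &
      (pr < (vr[j] - vr[i]) * (pc - vc[i]) / (vc[j] - vc[i]) + vr[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Exclude a margin around the picture border
#'
#' Outer pixels of nest photographs can be distorted (vignetting, demosaicing
#' edge effects), so a thin frame is recoded to the excluded code 0 before
#' analysis.
#'
#' @param mask a `region_mask`.
#' @param margin_fraction fraction of `min(H, W)` to strip from each edge,
#'   in \[0, 0.5); default 0.02.
#' @return a `region_mask` with the margin recoded to 0.
#' @export
exclude_border <- function(mask, margin_fraction = 0.02) {
  stopifnot(inherits(mask, "region_mask"),
            margin_fraction >= 0, margin_fraction < 0.5)
  labels <- mask$labels
  m <- floor(margin_fraction * min(dim(labels)))
  if (m > 0) {
    h <- nrow(labels); w <- ncol(labels)
    keep_r <- seq.int(m + 1L, h - m)
    keep_c <- seq.int(m + 1L, w - m)
    new <- matrix(0L, h, w)
    new[keep_r, keep_c] <- labels[keep_r, keep_c]
    emptied <- setdiff(intersect(unique(as.vector(labels)), 1:4),
                       unique(as.vector(new)))
    if (length(emptied))
      warning("margin exclusion emptied region(s): ",
              paste(names(REGION_CODES)[match(emptied, REGION_CODES)],
                    collapse = ", "))
    labels <- new
  }
  region_mask(labels, egg_instances = {
    ei <- mask$egg_instances
    ei[labels != REGION_CODES[["egg"]]] <- 0L
    ei
  }, egg_lengths_px = mask$egg_lengths_px)
}

# Reference white of the Lab conversion, taken from grDevices itself so that
# neutral (R=G=B) pixels map exactly to a*=b*=0.
lab_reference_white <- function() {
  as.numeric(grDevices::convertColor(matrix(c(100, 0, 0), 1),
                                     from = "Lab", to = "XYZ"))
}

# sRGB primaries (linear) -> XYZ, columns rescaled so the neutral axis maps to
# the Lab reference white: the gray-standard adaptation makes the camera
# neutral the white point.
rgb_to_xyz_matrix <- function() {
  m <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  white <- lab_reference_white()
  diag(white / as.numeric(m %*% rep(1, 3))) %*% m
}

#' Convert a normalised scene to CIE L*a*b*
#'
#' Linear pixel values are first scaled so the gray standard maps to its
#' nominal reflectance, then converted to L*a*b* with the adapted white point
#' (scene neutral axis = reference white). Values are clipped to \[0, 1\]
#' before conversion; a warning is raised when more than 1% of pixels clip,
#' which in the field protocol flags overexposed photographs.
#'
#' @param scene an `rgb_scene`.
#' @param std a `gray_standard`.
#' @param mask optional `region_mask` carried along for downstream steps.
#' @return an object of class `lab_scene` with matrices `L` (0-100), `a`, `b`,
#'   plus `pixel_scale`, `mask` and the clip count.
#' @export
rgb_to_lab <- function(scene, std, mask = NULL) {
  stopifnot(inherits(scene, "rgb_scene"), inherits(std, "gray_standard"))
  d <- dim(scene$pixels)
  lin <- scene$pixels * (std$nominal_reflectance / std$measured_value)
  n_clip <- sum(lin > 1)
  if (n_clip > 0.01 * prod(d[1:2]))
    warning(sprintf("%.1f%% of pixels clipped after normalisation; possible overexposure",
                    100 * n_clip / prod(d[1:2])))
  lin[lin > 1] <- 1
  rgbm <- cbind(as.vector(lin[, , 1]), as.vector(lin[, , 2]), as.vector(lin[, , 3]))
  xyz <- rgbm %*% t(rgb_to_xyz_matrix())
  lab <- grDevices::convertColor(xyz, from = "XYZ", to = "Lab", clip = NA)
  structure(list(L = matrix(lab[, 1], d[1], d[2]),
                 a = matrix(lab[, 2], d[1], d[2]),
                 b = matrix(lab[, 3], d[1], d[2]),
                 pixel_scale = scene$pixel_scale,
                 mask = mask, n_clipped = n_clip),
            class = "lab_scene")
}

#' Mean reflectance of a masked region
#'
#' Mean linear pixel value of the region (averaged over RGB) divided by the
#' standard's measured value, times its nominal reflectance.
#'
#' @inheritParams rgb_to_lab
#' @param mask a `region_mask`.
#' @param region region code (1-4) or name ("egg", "nest", "internal",
#'   "external").
#' @return reflectance fraction.
#' @export
reflectance_of_region <- function(scene, std, mask, region) {
  code <- region_code(region)
  sel <- mask$labels == code
  if (!any(sel)) stop("region ", region, " is empty")
  vals <- c(scene$pixels[, , 1][sel], scene$pixels[, , 2][sel],
            scene$pixels[, , 3][sel])
  mean(vals) / std$measured_value * std$nominal_reflectance
}

region_code <- function(region) {
  if (is.character(region)) {
    if (!region %in% names(REGION_CODES)) stop("unknown region name: ", region)
    REGION_CODES[[region]]
  } else {
    if (!region %in% REGION_CODES) stop("unknown region code: ", region)
    as.integer(region)
  }
}
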
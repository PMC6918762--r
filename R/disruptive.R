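# Disruptive-camouflage score: the fraction of the egg outline that the
# texture analysis "sees". An egg whose outline coincides with texture
# frontiers is easy to detect (high score); a disrupted/hidden outline gives
# a low score.

#' One-pixel-wide egg border image
#'
#' Inner border of each egg instance: egg pixels with a 4-neighbour outside
#' that instance (or on the image edge).
#'
#' @param mask a `region_mask` with at least one egg instance.
#' @return logical H x W matrix.
#' @export
egg_border_image <- function(mask) {
  ei <- mask$egg_instances
  if (is.null(ei) || !any(ei > 0)) stop("mask has no egg pixels")
  h <- nrow(ei); w <- ncol(ei)
  up <- rbind(ei[-1, , drop = FALSE], rep(-1L, w))
  dn <- rbind(rep(-1L, w), ei[-h, , drop = FALSE])
  lf <- cbind(ei[, -1, drop = FALSE], rep(-1L, h))
  rt <- cbind(rep(-1L, h), ei[, -w, drop = FALSE])
  ei > 0 & (ei != up | ei != dn | ei != lf | ei != rt)
}

#' Dilate an egg-border image with a cross structuring element
#'
#' Radius is 1% of the arithmetic mean egg length (best-fit-ellipse major
#' axis, px), rounded, with a floor of 1 px.
#'
#' @param border logical matrix.
#' @param egg_lengths_px per-egg lengths in pixels.
#' @return logical matrix (superset of `border`).
#' @export
dilate_border <- function(border, egg_lengths_px) {
  stopifnot(all(egg_lengths_px > 0))
  r <- cross_radius(egg_lengths_px)
  k <- cross_kernel(r)
  EBImage::dilate(matrix(as.numeric(border), nrow(border)), k) > 0.5
}

cross_radius <- function(egg_lengths_px) max(1L, round(0.01 * mean(egg_lengths_px)))

cross_kernel <- function(r) {
  k <- matrix(0, 2 * r + 1, 2 * r + 1)
  k[r + 1, ] <- 1
  k[, r + 1] <- 1
  k
}

#' Morphological thinning to unit-width curves
#'
#' Zhang-Suen thinning; reduces a binary image to 8-connected single-pixel
#' curves.
#'
#' @param bin logical matrix.
#' @return logical matrix.
#' @export
thin_binary <- function(bin) {
  img <- matrix(as.integer(bin), nrow(bin))
  pad <- function(m) cbind(0L, rbind(0L, m, 0L), 0L)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- pad(img)
      h <- nrow(img); w <- ncol(img)
      ctr <- p[2:(h + 1), 2:(w + 1)]
      p2 <- p[1:h, 2:(w + 1)]; p3 <- p[1:h, 3:(w + 2)]
      p4 <- p[2:(h + 1), 3:(w + 2)]; p5 <- p[3:(h + 2), 3:(w + 2)]
      p6 <- p[3:(h + 2), 2:(w + 1)]; p7 <- p[3:(h + 2), 1:w]
      p8 <- p[2:(h + 1), 1:w]; p9 <- p[1:h, 1:w]
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seq9 <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- Reduce(`+`, lapply(1:8, function(i) (seq9[[i]] == 0) & (seq9[[i + 1]] == 1)))
      cond <- ctr == 1 & bsum >= 2 & bsum <= 6 & a == 1
      if (step == 1) cond <- cond & (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      else           cond <- cond & (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      if (any(cond)) { img[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  img == 1L
}

#' Disruptive camouflage score
#'
#' Intersects the dilated egg-border image with the texture-frontier image,
#' thins the intersection back to unit width, and reports the percentage of
#' egg-border pixels detected: a border pixel counts as detected when a
#' thinned frontier pixel lies within the dilation radius (Euclidean). Lower
#' values indicate better-disrupted (better camouflaged) outlines.
#'
#' @param tex a `texture_map`.
#' @param mask a `region_mask` with egg instances.
#' @return an object of class `disruptive_score`: list with `per_egg`
#'   (percent per egg instance) and `scene_value` (pooled over all border
#'   pixels).
#' @export
disruptive_score <- function(tex, mask) {
  border <- egg_border_image(mask)
  if (!any(border)) stop("egg border is empty")
  r <- cross_radius(mask$egg_lengths_px)
  dil <- dilate_border(border, mask$egg_lengths_px)
  inter <- dil & tex$boundaries
  thinned <- thin_binary(inter)
  if (!any(thinned)) {
    per <- rep(0, max(mask$egg_instances))
    return(structure(list(per_egg = per, scene_value = 0),
                     class = "disruptive_score"))
  }
  # distance from every pixel to the nearest thinned frontier pixel
  dist <- EBImage::distmap(matrix(as.numeric(!thinned), nrow(thinned)))
  detected <- border & (dist <= r + 1e-9)
  n_eggs <- max(mask$egg_instances)
  per <- vapply(seq_len(n_eggs), function(i) {
    bi <- border & mask$egg_instances == i
    if (!any(bi)) return(NA_real_)
    100 * sum(detected & bi) / sum(bi)
  }, numeric(1))
  structure(list(per_egg = per,
                 scene_value = 100 * sum(detected) / sum(border)),
            class = "disruptive_score")
}
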
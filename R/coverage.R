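#' Nest-material coverage via a digital grid
#'
#' Embeds a square grid (2 x 2 mm by default) in the nest region of a
#' close-up photograph and reports the percentage of grid squares in which
#' the experimental material dominates (covers more than half of the
#' square's in-nest area) — the measure of how much added material the birds
#' accepted.
#'
#' The grid is anchored at the corner of the nest-region bounding box.
#' Squares with at least 50% of their area inside the nest are counted;
#' a square is dominated when material pixels exceed 50% of its in-nest area.
#'
#' @param material_mask logical matrix: pixels covered by experimental
#'   material.
#' @param nest_mask logical matrix of the nest region; same shape.
#' @param pixel_scale mm per pixel (> 0).
#' @param square_mm grid square side in mm, default 2.
#' @return an object of class `coverage_result`: list with `n_squares`,
#'   `n_dominated`, `percent`.
#' @export
coverage_percent <- function(material_mask, nest_mask, pixel_scale,
                             square_mm = 2) {
  stopifnot(all(dim(material_mask) == dim(nest_mask)),
            pixel_scale > 0, square_mm > 0)
  if (!any(nest_mask)) stop("nest mask is empty")
  side <- square_mm / pixel_scale
  if (side < 1) stop("grid square smaller than one pixel at this scale")
  side <- round(side)
  idx <- which(nest_mask, arr.ind = TRUE)
  r0 <- min(idx[, 1]); c0 <- min(idx[, 2])
  h <- nrow(nest_mask); w <- ncol(nest_mask)
  n_squares <- 0L; n_dominated <- 0L
  for (gr in seq(r0, h, by = side)) {
    for (gc in seq(c0, w, by = side)) {
      rr <- gr:min(gr + side - 1L, h)
      cc <- gc:min(gc + side - 1L, w)
      in_nest <- nest_mask[rr, cc, drop = FALSE]
      if (sum(in_nest) < 0.5 * side^2) next
      n_squares <- n_squares + 1L
      mat <- material_mask[rr, cc, drop = FALSE] & in_nest
      if (sum(mat) > 0.5 * sum(in_nest)) n_dominated <- n_dominated + 1L
    }
  }
  if (n_squares == 0L) stop("no grid square lies (>=50%) inside the nest")
  structure(list(n_squares = n_squares, n_dominated = n_dominated,
                 percent = 100 * n_dominated / n_squares),
            class = "coverage_result")
}
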
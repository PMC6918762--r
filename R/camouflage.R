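# Texture clustering and camouflage scoring. All analysed pixels of ONE image
# (region codes 1-4) are clustered jointly; signatures are only ever compared
# within an image, so cluster identities need not align across scenes.

#' Cluster per-pixel features into texture classes
#'
#' K-means over the feature vectors of every analysed pixel (regions 1-4;
#' the excluded margin, code 0, is ignored). Initialisation is k-means++
#' with `restarts` independent seedings; Lloyd iterations via
#' [stats::kmeans()]. Deterministic given `seed`.
#'
#' @param stack a `feature_stack`.
#' @param mask a `region_mask`.
#' @param n_clusters number of texture classes (field default 14).
#' @param seed integer RNG seed.
#' @param restarts independent k-means++ restarts, default 10.
#' @param standardize scale each feature to unit variance before clustering
#'   (default `FALSE`).
#' @return an object of class `texture_map`: `labels` (H x W integer matrix,
#'   NA outside the analysed area), `n_clusters`, `boundaries` (logical
#'   matrix of texture frontiers), `tot_withinss`.
#' @export
cluster_textures <- function(stack, mask, n_clusters = 14, seed = 1L,
                             restarts = 10, standardize = FALSE) {
  stopifnot(inherits(stack, "feature_stack"), inherits(mask, "region_mask"))
  if (n_clusters < 2) stop("n_clusters must be >= 2")
  d <- dim(stack$features)
  sel <- which(mask$labels != 0L)
  if (length(sel) < n_clusters) stop("fewer analysed pixels than clusters")
  x <- matrix(stack$features, d[1] * d[2], d[3])[sel, , drop = FALSE]
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    x <- sweep(x, 2, pmax(sds, .Machine$double.eps), "/")
  }
  n_distinct <- nrow(unique(x))
  if (n_distinct < n_clusters) {
    warning("only ", n_distinct, " distinct feature vectors; reducing clusters")
    n_clusters <- max(1L, n_distinct)
  }
  km <- if (n_clusters == 1L) {
    list(cluster = rep(1L, nrow(x)), tot.withinss = 0)
  } else {
    run_kmeans_pp(x, n_clusters, seed, restarts)
  }
  labels <- matrix(NA_integer_, d[1], d[2])
  labels[sel] <- km$cluster
  structure(list(labels = labels, n_clusters = n_clusters,
                 boundaries = texture_boundaries(labels),
                 tot_withinss = km$tot.withinss),
            class = "texture_map")
}

# k-means++ seeding + Lloyd iterations, best of `restarts` by total
# within-cluster sum of squares.
run_kmeans_pp <- function(x, k, seed, restarts) {
  best <- NULL
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (r in seq_len(restarts)) {
    centers <- kmeanspp_centers(x, k)
    km <- suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = 100, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}

kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[idx[1], ], "-")^2)
  for (i in seq_len(k - 1L)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx[i + 1L] <- sample.int(n, 1, prob = p)
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[i + 1L], ], "-")^2))
  }
  # jitter-free: duplicated seeds impossible while d2[center]=0
  x[idx, , drop = FALSE]
}

# Texture frontiers: a labelled pixel is a boundary pixel when a 4-neighbour
# carries a different (non-NA) label and its own label is the smaller of the
# two, giving a one-pixel-thick frontier on the lower-label side.
texture_boundaries <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  b <- matrix(FALSE, h, w)
  cmp <- function(a, bb) !is.na(a) & !is.na(bb) & a < bb
  b[-h, ] <- b[-h, ] | cmp(labels[-h, ], labels[-1, ])
  b[-1, ] <- b[-1, ] | cmp(labels[-1, ], labels[-h, ])
  b[, -w] <- b[, -w] | cmp(labels[, -w], labels[, -1])
  b[, -1] <- b[, -1] | cmp(labels[, -1], labels[, -w])
  b
}

#' Clustering signature of a region
#'
#' Relative presence (%) of each texture cluster among the region's pixels; a
#' normalised histogram summing to 100.
#'
#' @param tex a `texture_map`.
#' @param mask a `region_mask`.
#' @param region region code (1-4) or name.
#' @return an object of class `cluster_signature`: numeric vector of length
#'   `n_clusters` with attributes `region`.
#' @export
clustering_signature <- function(tex, mask, region) {
  code <- region_code(region)
  sel <- mask$labels == code & !is.na(tex$labels)
  if (!any(sel)) stop("region ", region, " has no analysed pixels")
  counts <- tabulate(tex$labels[sel], nbins = tex$n_clusters)
  structure(100 * counts / sum(counts), region = region,
            class = "cluster_signature")
}

#' Chi-squared distance between two texture signatures
#'
#' For normalised signatures g and h (each summing to 100), the score is
#' `0.5 * sum((g_i - h_i)^2 / (g_i + h_i))` over bins with `g_i + h_i > 0`.
#' It ranges from 0 (identical texture composition — perfect
#' background/pattern match) to 100 (disjoint support); lower values mean
#' better camouflage. Not a metric: the triangle inequality can fail.
#'
#' @param g,h numeric signatures of equal length, each summing to 100.
#' @param half apply the 1/2 factor (default `TRUE`).
#' @return the distance (numeric scalar).
#' @export
chi2_distance <- function(g, h, half = TRUE) {
  g <- as.numeric(g); h <- as.numeric(h)
  if (length(g) != length(h)) stop("signatures differ in length")
  if (abs(sum(g) - 100) > 1e-6 || abs(sum(h) - 100) > 1e-6)
    stop("signatures must be normalised to sum to 100")
  s <- g + h
  keep <- s > 0
  d <- sum((g[keep] - h[keep])^2 / s[keep])
  if (half) d / 2 else d
}

#' Select the number of texture clusters
#'
#' Runs the clustering pipeline on each scene for every candidate cluster
#' count and computes the correlation between the egg and external
#' (microhabitat) signatures, averaged over scenes. The chosen count is the
#' smallest candidate after which the mean correlation stops decreasing by
#' more than `tol` (the elbow of the saturation curve).
#'
#' @param scenes list of `lab_scene` objects, each carrying its mask.
#' @param bank a `filter_bank`.
#' @param candidates candidate cluster counts, ascending; default the
#'   protocol's `c(6, 8, 10, 12, 14, 16, 20)`.
#' @param seed integer seed.
#' @param tol minimum meaningful decrease in mean correlation, default 0.02.
#' @param method correlation type, `"pearson"` (default) or `"spearman"`.
#' @return list with `n_clusters` (the choice) and `curve` (data frame of
#'   candidate, mean correlation).
#' @export
select_n_clusters <- function(scenes, bank, candidates = c(6, 8, 10, 12, 14, 16, 20),
                              seed = 1L, tol = 0.02, method = "pearson") {
  if (!length(candidates)) stop("candidate list is empty")
  if (is.unsorted(candidates)) stop("candidates must be ascending")
  stacks <- lapply(scenes, apply_bank, bank = bank)
  means <- vapply(candidates, function(k) {
    cors <- mapply(function(st, sc) {
      tex <- cluster_textures(st, sc$mask, n_clusters = k, seed = seed)
      stats::cor(as.numeric(clustering_signature(tex, sc$mask, "egg")),
                 as.numeric(clustering_signature(tex, sc$mask, "external")),
                 method = method)
    }, stacks, scenes)
    mean(cors)
  }, numeric(1))
  choice <- candidates[length(candidates)]
  if (length(candidates) > 1) {
    dec <- -diff(means)
    below <- which(dec < tol)
    if (length(below)) choice <- candidates[below[1]]
  } else choice <- candidates[1]
  list(n_clusters = choice,
       curve = data.frame(n_clusters = candidates, mean_correlation = means))
}

#' Full per-scene camouflage report row
#'
#' Runs features, clustering, signatures and the disruptive score for one
#' scene and returns the one-row data frame written to the scene CSV:
#' image id, the four 14-element signatures (egg, nest, internal, external),
#' the egg-border percentage, and the chi-squared scores Egg-Nest,
#' Egg-External and Nest-External.
#'
#' @param lab a `lab_scene` carrying its mask.
#' @param bank a `filter_bank`.
#' @param n_clusters cluster count, default 14.
#' @param seed integer seed.
#' @param id image identifier string.
#' @return a one-row data frame; also attaches the `texture_map` as
#'   attribute `"texture_map"`.
#' @export
scene_report <- function(lab, bank, n_clusters = 14, seed = 1L, id = "scene") {
  stack <- apply_bank(lab, bank)
  tex <- cluster_textures(stack, lab$mask, n_clusters = n_clusters, seed = seed)
  regs <- c("egg", "nest", "internal", "external")
  sigs <- lapply(regs, function(r) clustering_signature(tex, lab$mask, r))
  names(sigs) <- regs
  disr <- disruptive_score(tex, lab$mask)
  row <- data.frame(id = id)
  for (r in regs) {
    m <- matrix(as.numeric(sigs[[r]]), nrow = 1)
    colnames(m) <- paste0(r, "_sig", seq_len(tex$n_clusters))
    row <- cbind(row, m)
  }
  row$egg_border_pct <- disr$scene_value
  row$score_egg_nest <- chi2_distance(sigs$egg, sigs$nest)
  row$score_egg_external <- chi2_distance(sigs$egg, sigs$external)
  row$score_nest_external <- chi2_distance(sigs$nest, sigs$external)
  attr(row, "texture_map") <- tex
  row
}
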
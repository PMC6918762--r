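# End-to-end orchestration: scenes -> per-image CSV rows (signatures,
# chi-squared scores, disruptive %), heating CSV -> per-replicate fits and
# per-material summaries. Thin glue over the module functions; all runs are
# deterministic under the configured seed.

#' Run configuration
#'
#' Bundles every tunable of the scene pipeline. Serialisable to/from YAML.
#'
#' @param margin_fraction border exclusion fraction, default 0.02.
#' @param scales filter-bank scales, px.
#' @param n_orientations oriented kernels per symmetry class.
#' @param n_clusters K-means cluster count, default 14.
#' @param seed integer seed used for every stochastic step.
#' @param restarts K-means restarts.
#' @param square_mm coverage grid square side, mm.
#' @param nominal_reflectance gray-standard reflectance.
#' @return an object of class `run_config` (a named list).
#' @export
run_config <- function(margin_fraction = 0.02, scales = c(16, 24, 32, 48),
                       n_orientations = 5, n_clusters = 14, seed = 1L,
                       restarts = 10, square_mm = 2,
                       nominal_reflectance = 0.18) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Run the scene camouflage pipeline
#'
#' For each input scene: exclude the border margin, normalise against the
#' gray standard and convert to Lab, extract texture features, cluster,
#' compute the four region signatures, chi-squared camouflage scores and the
#' disruptive egg-border percentage. Failures in one scene are logged and
#' flagged; the run continues.
#'
#' @param scenes named list; each element is a list with `scene`
#'   (`rgb_scene`) and `mask` (`region_mask`), as produced by [make_scene()]
#'   or [load_scene()].
#' @param std a `gray_standard` (one per run; per-scene standards may be
#'   supplied as an element `std` of each scene).
#' @param config a `run_config`.
#' @param out_csv optional path; the report table is written there.
#' @param texture_dir optional directory; texture-label and boundary images
#'   are saved there as PNGs.
#' @return data frame with one row per scene (invisibly also written to
#'   `out_csv` if given); failed scenes yield a row with `error` set.
#' @export
run_scene_pipeline <- function(scenes, std, config = run_config(),
                               out_csv = NULL, texture_dir = NULL) {
  bank <- build_bank(config$scales, config$n_orientations)
  rows <- vector("list", length(scenes))
  ids <- names(scenes)
  if (is.null(ids)) ids <- sprintf("scene%03d", seq_along(scenes))
  for (i in seq_along(scenes)) {
    rows[[i]] <- tryCatch({
      sc <- scenes[[i]]
      sstd <- if (!is.null(sc$std)) sc$std else std
      mask <- exclude_border(sc$mask, config$margin_fraction)
      lab <- rgb_to_lab(sc$scene, sstd, mask = mask)
      row <- scene_report(lab, bank, n_clusters = config$n_clusters,
                          seed = config$seed, id = ids[i])
      if (!is.null(texture_dir)) save_texture_images(
        attr(row, "texture_map"), texture_dir, ids[i])
      attr(row, "texture_map") <- NULL
      row$error <- NA_character_
      row
    }, error = function(e) {
      message("scene ", ids[i], " failed: ", conditionMessage(e))
      data.frame(id = ids[i], error = conditionMessage(e))
    })
  }
  out <- do.call(rbind_fill, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

save_texture_images <- function(tex, dir, id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab <- tex$labels
  lab[is.na(lab)] <- 0L
  png::writePNG(lab / max(1L, tex$n_clusters),
                file.path(dir, paste0(id, "_textures.png")))
  png::writePNG(matrix(as.numeric(tex$boundaries), nrow(lab)),
                file.path(dir, paste0(id, "_boundaries.png")))
}

rbind_fill <- function(...) {
  rows <- list(...)
  if (!length(rows)) return(data.frame())
  cols <- unique(unlist(lapply(rows, names)))
  filled <- lapply(rows, function(r) {
    for (c in setdiff(cols, names(r))) r[[c]] <- NA
    r[cols]
  })
  do.call(rbind, filled)
}

#' Run the heating-analysis pipeline
#'
#' Fits the Newtonian heating model to every (material, replicate) series of
#' a long-format table and summarises per material: mean and standard error
#' of the characteristic heating time Tc, mean fit r-squared, and the mean
#' final temperature.
#'
#' @param records data frame with columns `time_s`, `temp_C`, `material`,
#'   `replicate` (the heating CSV dialect).
#' @param k_final trailing records averaged for the final temperature.
#' @param out_csv optional path for the per-material summary CSV.
#' @return list with `fits` (per-replicate data frame) and `summary`
#'   (per-material data frame).
#' @export
run_heating_pipeline <- function(records, k_final = 5, out_csv = NULL) {
  need <- c("time_s", "temp_C", "material", "replicate")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  keys <- unique(records[, c("material", "replicate")])
  fits <- list(); skipped <- 0L
  for (j in seq_len(nrow(keys))) {
    sel <- records$material == keys$material[j] &
      records$replicate == keys$replicate[j]
    f <- tryCatch({
      ser <- heating_series(records$time_s[sel], records$temp_C[sel],
                            material = keys$material[j],
                            replicate = keys$replicate[j])
      ft <- fit_heating(ser)
      data.frame(material = keys$material[j], replicate = keys$replicate[j],
                 T_i = ft$T_i, T_f = ft$T_f, a = ft$a, b = ft$b,
                 Tc = ft$Tc, r2 = ft$r2,
                 T_final = summarize_final_temperature(ser, k_final))
    }, error = function(e) {
      warning("series (", keys$material[j], ", ", keys$replicate[j],
              ") skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(f)) skipped <- skipped + 1L else fits[[length(fits) + 1L]] <- f
  }
  fits <- do.call(rbind, fits)
  if (is.null(fits)) stop("no series could be fitted")
  se <- function(x) stats::sd(x) / sqrt(length(x))
  mats <- split(fits, fits$material)
  summary <- do.call(rbind, lapply(mats, function(d) data.frame(
    material = d$material[1], n_replicates = nrow(d),
    Tc_mean = mean(d$Tc), Tc_se = se(d$Tc),
    r2_mean = mean(d$r2), T_final_mean = mean(d$T_final))))
  rownames(summary) <- NULL
  if (!is.null(out_csv)) utils::write.csv(summary, out_csv, row.names = FALSE)
  list(fits = fits, summary = summary, n_skipped = skipped)
}
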
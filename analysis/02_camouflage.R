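#!/usr/bin/env Rscript
# Scores camouflage for every simulated O/T/W scene: per-region clustering
# signatures, chi-squared background/pattern-matching scores and the
# disruptive egg-border percentage, then summarises how the treatment (T)
# and the week-later removal (W) move the Nest-Microhabitat contrast.
#
# Requires: analysis/01_simulate.R
# Outputs:  results/camouflage_scores.csv, results/camouflage_by_treatment.csv

library(nestcamo)

scene_dir <- "results/sim/scenes"
stopifnot(dir.exists(scene_dir))
imgs <- list.files(scene_dir, pattern = "\\.tif$", full.names = TRUE)

scenes <- lapply(imgs, function(f) {
  load_scene(f, sub("\\.tif$", "_mask.png", f), pixel_scale = 0.5)
})
names(scenes) <- sub("\\.tif$", "", basename(imgs))

# bank scales follow the speckle grain of the 128 px synthetic scenes (the
# field protocol's 16-48 px scales correspond to multi-megapixel frames)
cfg <- run_config(scales = c(2, 4), n_orientations = 3, n_clusters = 6,
                  seed = 1L)
out <- run_scene_pipeline(scenes, gray_standard(0.18), cfg,
                          out_csv = "results/camouflage_scores.csv")

out$treatment <- sub(".*_", "", out$id)
agg <- aggregate(out[, c("score_egg_nest", "score_nest_external",
                         "egg_border_pct")],
                 by = list(treatment = out$treatment), FUN = mean)
write.csv(agg, "results/camouflage_by_treatment.csv", row.names = FALSE)
print(agg, digits = 3)

t_vs_o <- agg$score_nest_external[agg$treatment == "T"] -
  agg$score_nest_external[agg$treatment == "O"]
w_vs_o <- agg$score_nest_external[agg$treatment == "W"] -
  agg$score_nest_external[agg$treatment == "O"]
cat(sprintf(paste0(
  "Adding pale material raises the Nest-Microhabitat contrast by %.1f ",
  "chi-squared units;\nafter 85%% removal the residual shift is %.1f ",
  "(near the original state).\n"), t_vs_o, w_vs_o))
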
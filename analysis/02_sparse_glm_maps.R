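#!/usr/bin/env Rscript
## Stage 2 -- sparse-design GLM and feature maps.
##
## For each hemisphere and stimulus dimension: smooth (2 mm FWHM), apply
## global scaling, fit the voxel-wise GLM with 300 s discrete-cosine
## high-pass, mask at omnibus p < 0.001 (uncorrected), and derive the
## high-minus-low contrast map and the best-condition map. Projected
## vertex maps are written to scratch/, mask sizes to results/.

library(audtopo)

indir <- "scratch/study"
if (!dir.exists(indir)) stop("run analysis/01_simulate_study.R first")
config <- read_config("results/study_config.yaml")

summary_rows <- list()
for (hemi in config$hemispheres) {
  tag <- substr(hemi, 1, 1)
  mesh <- read_mesh(file.path(indir, sprintf("sheet_%s.surf.gii", tag)))
  for (feature in c("rate", "frequency")) {
    ser <- read_volume(file.path(indir, sprintf("bold_%s_%s.nii.gz", feature, tag)),
                       TA_s = 1)
    sched_df <- read_table(file.path(indir, sprintf("schedule_%s_%s.tsv", feature, tag)))
    conds <- if (feature == "rate") rate_conditions() else frequency_conditions()
    sched <- structure(data.frame(volume = sched_df$volume,
                                  condition = as.character(sched_df$condition),
                                  stringsAsFactors = FALSE),
                       TR_s = 10, TA_s = 1, conditions = conds$label,
                       class = c("stimulus_schedule", "data.frame"))

    ser <- global_scale(smooth_volumes(ser, config$sparse$fwhm_mm))
    sm <- fit_glm(ser, build_design(sched, config$sparse$highpass_cutoff_s))
    mask <- omnibus_mask(sm, config$sparse$alpha, config$sparse$correction)
    sets <- if (feature == "rate") list(low = c("0.5", "2"), high = c("128", "512"))
            else list(low = "0.5-1k", high = "8-16k")
    cm <- contrast_map(sm, sets$low, sets$high, mask = mask)
    bm <- best_map(sm, conds$value_hz, mask = mask)

    vv <- project_scalar(unclass(cm), mesh, config$projection$radius_mm, mask)
    bv <- project_label(unclass(bm), mesh, config$projection$radius_mm, mask)
    write_vertex_values(as.numeric(vv),
                        file.path(indir, sprintf("contrast_%s_%s.func.gii", feature, tag)))
    write_vertex_values(as.integer(bv),
                        file.path(indir, sprintf("best_%s_%s.label.gii", feature, tag)),
                        label_names = conds$label)
    summary_rows[[length(summary_rows) + 1]] <- data.frame(
      hemisphere = hemi, feature = feature,
      mask_voxels = sum(mask), total_voxels = length(mask),
      vertices_with_data = sum(!is.na(vv)))
    message(sprintf("%s / %s: %d voxels in the p<%g mask, %d vertices covered",
                    hemi, feature, sum(mask), config$sparse$alpha, sum(!is.na(vv))))
  }
}
write_table(do.call(rbind, summary_rows), "results/glm_mask_summary.tsv")
message("feature maps written; mask summary in results/glm_mask_summary.tsv")
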
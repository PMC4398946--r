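#!/usr/bin/env Rscript
## Stage 1 -- generate the synthetic study.
##
## Builds the cortical sheets (one animal, both hemispheres), plants the
## ground-truth maps (concentric iso-rate bands; per-field tonotopic axes
## with reversals; A1 frequency/rate gradient directions 165/53 deg), and
## simulates one sparse AM-rate session (540 volumes, 6 rates) and one
## sparse frequency session (720 volumes, 3 bands) per hemisphere.
## Volumes and meshes are written under scratch/ (they are large and
## regenerable); the run configuration under results/.

library(audtopo)

outdir <- "scratch/study"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)

config <- default_config()
yaml::write_yaml(unclass(config), "results/study_config.yaml")

for (hemi in config$hemispheres) {
  surf <- make_surface(do.call(sheet_spec, c(config$sheet,
                                             list(hemisphere = hemi))))
  truth <- make_ground_truth(surf$mesh, surf$parcellation,
                             do.call(topo_params, config$topo))
  tag <- substr(hemi, 1, 1)
  write_mesh(surf$mesh, file.path(outdir, sprintf("sheet_%s.surf.gii", tag)))
  write_vertex_values(as.integer(surf$parcellation),
                      file.path(outdir, sprintf("fields_%s.label.gii", tag)),
                      label_names = field_levels())
  write_vertex_values(truth$rate_hz,
                      file.path(outdir, sprintf("truth_rate_%s.func.gii", tag)))
  write_vertex_values(truth$freq_hz,
                      file.path(outdir, sprintf("truth_freq_%s.func.gii", tag)))

  for (feature in c("rate", "frequency")) {
    conds <- if (feature == "rate") rate_conditions() else frequency_conditions()
    nv <- if (feature == "rate") config$sparse$rate_volumes else config$sparse$freq_volumes
    sched <- make_schedule(nv, conds$label,
                           seed = audtopo:::derive_seed(config$seed, "M1", hemi,
                                                        feature, "sched"))
    noise <- noise_params(sd = config$noise$sd,
                          seed = audtopo:::derive_seed(config$seed, "M1", hemi,
                                                       feature, "noise"))
    ser <- simulate_sparse_experiment(truth, surf$mesh, sched, conds, noise)
    write_volume(ser, file.path(outdir, sprintf("bold_%s_%s.nii.gz", feature, tag)))
    write_table(sched, file.path(outdir, sprintf("schedule_%s_%s.tsv", feature, tag)))
    message(sprintf("%s hemisphere, %s experiment: %d volumes simulated",
                    hemi, feature, nv))
  }
}
message("synthetic study written to ", outdir)
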
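#!/usr/bin/env Rscript
## Stage 3 -- per-field gradient directions and relative angles.
##
## Flattens each analysed field (A1, R, CL), fits the 2D regression
## gradients of the projected frequency- and rate-contrast maps, computes
## the relative angle alpha between them, and writes the summary table
## (member rows + Average / Std-dev rows) in the published layout.
## Also re-aggregates the published per-hemisphere values themselves as an
## arithmetic cross-check of the summary machinery.

library(audtopo)

indir <- "scratch/study"
if (!dir.exists(indir)) stop("run stages 01 and 02 first")
config <- read_config("results/study_config.yaml")

datasets <- list()
for (hemi in config$hemispheres) {
  tag <- substr(hemi, 1, 1)
  mesh <- read_mesh(file.path(indir, sprintf("sheet_%s.surf.gii", tag)))
  parc_raw <- read_vertex_values(file.path(indir, sprintf("fields_%s.label.gii", tag)))
  parc <- structure(factor(field_levels()[as.integer(parc_raw)],
                           levels = field_levels()),
                    class = c("field_parcellation", "factor"))
  datasets[[length(datasets) + 1]] <- list(
    animal = "M1", hemisphere = toupper(tag), mesh = mesh, parcellation = parc,
    rate_values = as.numeric(read_vertex_values(
      file.path(indir, sprintf("contrast_rate_%s.func.gii", tag)))),
    freq_values = as.numeric(read_vertex_values(
      file.path(indir, sprintf("contrast_frequency_%s.func.gii", tag)))))
}

tbl <- field_gradient_table(datasets, fields = config$gradients$fields)
write_gradient_table(tbl, "results/gradient_table.tsv")
print(tbl[, c("animal", "hemisphere", "field", "alpha_deg",
              "freq_dir_deg", "rate_dir_deg", "n_vertices")], digits = 4)

## cross-check: aggregate the published rows with the same machinery
pub <- published_gradient_table()
rows <- list()
for (f in unique(pub$field)) {
  sub <- pub[pub$field == f, ]
  rows[[f]] <- data.frame(
    field = f,
    alpha_mean = round(summarize_field_stats(sub$alpha_deg)$average, 1),
    alpha_sd = round(summarize_field_stats(sub$alpha_deg)$std_dev, 1),
    freq_dir_mean = round(summarize_field_stats(sub$freq_dir_deg)$average, 1),
    rate_dir_mean = round(summarize_field_stats(sub$rate_dir_deg)$average, 1))
}
pub_summary <- do.call(rbind, rows)
write_table(pub_summary, "results/published_table_summary.tsv")
message("gradient table in results/gradient_table.tsv; ",
        "published-row aggregation in results/published_table_summary.tsv")
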
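#!/usr/bin/env Rscript
# Generate the synthetic study inputs: one ground-truthed SEM-style
# micrograph per formulation, triplicate bench-assay replicates drawn at
# the published means/SDs, and chromatographic peaks on the published
# calibration line. Everything downstream (02-04) consumes these files.

suppressMessages(library(capmetrics))

seed <- 7
out <- "results/synthetic"
dir.create(file.path(out, "micrographs"), showWarnings = FALSE,
           recursive = TRUE)

forms <- study_table("recipes")$formulation

message("Simulating micrographs (1024 x 1024 content + 65 px databar, ",
        "20 um / 229 px) ...")
truths <- list()
for (i in seq_along(forms)) {
  ms <- simulate_micrograph(micrograph_sim_params(
    n_particles = 120, allow_border = TRUE, seed = seed + i))
  write_micrograph(ms$image,
                   file.path(out, "micrographs", paste0(forms[i], ".tif")))
  write_ground_truth(ms$truth,
                     file.path(out, "micrographs", paste0(forms[i], "_truth.csv")))
  truths[[forms[i]]] <- ms$truth
}
message("  ", length(forms), " micrographs, ",
        sum(vapply(truths, nrow, integer(1))), " particles rendered")

message("Simulating triplicate bench assays at the published levels ...")
t1 <- study_table("moisture_solubility")
t3 <- study_table("density_flow")
moisture <- simulate_assay_replicates(
  data.frame(formulation = t1$formulation, true_mean = t1$moisture_mean,
             replicate_sd = t1$moisture_sd), seed = seed + 50)
density_b <- simulate_assay_replicates(
  data.frame(formulation = t3$formulation, true_mean = t3$bulk_density_mean,
             replicate_sd = t3$bulk_density_sd), seed = seed + 51)
density_t <- simulate_assay_replicates(
  data.frame(formulation = t3$formulation, true_mean = t3$tapped_density_mean,
             replicate_sd = t3$tapped_density_sd), seed = seed + 52)
write.csv(moisture, file.path(out, "moisture_replicates.csv"), row.names = FALSE)
write.csv(density_b, file.path(out, "bulk_density_replicates.csv"), row.names = FALSE)
write.csv(density_t, file.path(out, "tapped_density_replicates.csv"), row.names = FALSE)

message("Simulating calibration levels and sample peaks ...")
curve <- calibration_curve(6379.25, 2232.78)
cal <- data.frame(amount = c(2.45, 12.25, 61.25, 122.5))
cal$area <- simulate_peak_areas(cal$amount, curve, noise_sd = 0,
                                seed = seed)$area
prep <- sample_prep()
t6 <- study_table("lutein")
amounts <- t6$powder_conc_mean * prep$injection_volume * prep$sample_mass /
  prep$reconstitution_volume
pk <- simulate_peak_areas(amounts, curve, noise_sd = 50, seed = seed + 60)
peaks <- data.frame(formulation = t6$formulation,
                    retention_time = pk$retention_time, area = pk$area)
write.csv(cal, file.path(out, "calibration_levels.csv"), row.names = FALSE)
write.csv(peaks, file.path(out, "sample_peaks.csv"), row.names = FALSE)

message("Done: inputs under ", out)
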
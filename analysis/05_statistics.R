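#!/usr/bin/env Rscript
# One-way ANOVA + Tukey HSD + compact letter display on the published
# per-formulation summaries (mean, SD, n = 3), reproducing the
# homogeneous-group superscripts of the characterization tables.

suppressMessages(library(capmetrics))

out <- "results"
dir.create(out, showWarnings = FALSE)

metrics <- list(
  moisture = c("moisture_solubility", "moisture_mean", "moisture_sd"),
  solubility = c("moisture_solubility", "solubility_mean", "solubility_sd"),
  encapsulation_efficiency = c("oil_ee", "ee_mean", "ee_sd"),
  carr_index = c("density_flow", "ci_mean", "ci_sd"),
  hausner_ratio = c("density_flow", "hr_mean", "hr_sd"),
  powder_lutein = c("lutein", "powder_conc_mean", "powder_conc_sd")
)

rows <- list()
for (m in names(metrics)) {
  spec <- metrics[[m]]
  tb <- study_table(spec[1])
  gd <- group_data(data.frame(label = tb$formulation, mean = tb[[spec[2]]],
                              sd = tb[[spec[3]]], n = tb$n))
  hg <- homogeneous_groups(gd)
  lt <- hg$letters
  message(sprintf("%-26s F = %8.2f, p = %.3g, %d homogeneous groups",
                  m, hg$anova$f, hg$anova$p, length(unique(lt))))
  rows[[m]] <- data.frame(
    metric = m, formulation = tb$formulation,
    value = format_mean_sd(tb[[spec[2]]], tb[[spec[3]]],
                           unname(lt[tb$formulation])))
}
letters_tab <- do.call(rbind, rows)
rownames(letters_tab) <- NULL
write.csv(letters_tab, file.path(out, "tukey_letters.csv"), row.names = FALSE)
message("Wrote ", file.path(out, "tukey_letters.csv"))
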
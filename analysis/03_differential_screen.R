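#!/usr/bin/env Rscript

# Per-drug differential sensitivity between the perturbed and reference
# lines: log2 ratio of control-relative AUC, Bonferroni-corrected p-values,
# volcano annotation. The effect threshold (|log2| >= 0.15) matches a
# moderate selective effect; the hit rule also requires adjusted P < 0.05.

library(cinsynergy)

lines <- list(aneuploidy = "Ts12Ts5", cin = "Mad2cKD")

for (screen_name in names(lines)) {
  metrics <- readr::read_csv(sprintf("scratch/metrics_%s.csv", screen_name),
                             comment = "#", show_col_types = FALSE)
  diff_tbl <- differential_screen(metrics, line_a = lines[[screen_name]],
                                  line_b = "RPE1")
  volcano <- build_volcano_table(diff_tbl, effect_min = 0.15, alpha = 0.05)
  write_stage_csv(volcano, sprintf("results/differential_%s.csv", screen_name),
                  "differential")
  hits <- volcano[volcano$hit, ]
  message(sprintf("%s screen: %d/%d drugs flagged after Bonferroni",
                  screen_name, nrow(hits), nrow(volcano)))
  print(as.data.frame(hits[c("drug", "effect", "p_raw", "p_bonferroni")]),
        row.names = FALSE)

  p <- plot_volcano(volcano)
  dir.create("scratch", showWarnings = FALSE)
  ggplot2::ggsave(sprintf("scratch/volcano_%s.png", screen_name), p,
                  width = 6, height = 4, dpi = 150)
}
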
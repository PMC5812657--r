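#!/usr/bin/env Rscript
## Stage 1 — karyotype morphometrics on the packaged Cophomantini records:
## per-species 2n, x, ploidy, FN and a validation report.
## Writes results/karyotype_summary.csv and results/validation_report.txt.

suppressPackageStartupMessages(library(karyevo))
dir.create("results", showWarnings = FALSE)

d <- load_cophomantini()

summary_rows <- lapply(names(d$karyotypes), function(nm) {
  k <- d$karyotypes[[nm]]
  morph <- table(vapply(k$pairs, function(p) p$morphology, ""))
  data.frame(species = nm, group = k$group, ploidy = k$ploidy,
             x = k$basic_number_x, two_n = k$diploid_number_2n,
             fn = fundamental_number(k),
             n_metacentric = sum(morph["metacentric"], na.rm = TRUE),
             n_submetacentric = sum(morph["submetacentric"], na.rm = TRUE),
             n_subtelocentric = sum(morph["subtelocentric"], na.rm = TRUE),
             n_telocentric = sum(morph["telocentric"], na.rm = TRUE),
             n_b_chromosomes = length(k$b_chromosomes),
             sex_system = k$sex_system)
})
summary_df <- do.call(rbind, summary_rows)
write.csv(summary_df, "results/karyotype_summary.csv", row.names = FALSE,
          na = "")

violations <- unlist(lapply(names(d$karyotypes), function(nm) {
  v <- validate_karyotype(d$karyotypes[[nm]])
  if (length(v)) paste0(nm, ": ", v) else character(0)
}))
writeLines(c(sprintf("karyotypes validated: %d", length(d$karyotypes)),
             sprintf("violations: %d", length(violations)), violations),
           "results/validation_report.txt")

cat("Classified", nrow(summary_df), "karyotypes;",
    length(violations), "invariant violations.\n")
cat("Fundamental numbers of the three Hyloscirtus karyotypes:",
    summary_df$fn[summary_df$species == "Hyloscirtus_alytolylax"],
    summary_df$fn[summary_df$species == "Hyloscirtus_larinopygion"],
    summary_df$fn[summary_df$species == "Hyloscirtus_palmeri"], "\n")
cat("Diploid numbers observed:",
    paste(sort(unique(summary_df$two_n)), collapse = ", "), "\n")
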
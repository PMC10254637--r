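#!/usr/bin/env Rscript

# Stage 5: mutation candidates.
#
# Filters the stage-2 scan down to charged residues with ddE < -1 kcal/mol
# that are not mechanistically required, suggests charge-cancelling
# substitutions, and annotates solvent exposure and hydrogen-bond freedom.

suppressPackageStartupMessages(library(dipolescan))

scan <- read_scan_tsv("results/scan.tsv")
structure_R <- read_pqr("results/fixture/R.pqr")

catalytic <- c("A:107:TYR", "A:109:GLU", "A:121:LYS", "A:140:ASP")
report <- build_report(scan, structure_R,
                       advisor_config(threshold = 1.0,
                                      excluded_residues = catalytic))
write_report_tsv(report, "results/report.tsv")
print(report)

cat(sprintf("\n%d candidates written to results/report.tsv\n",
            nrow(report$candidates)))
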
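#!/usr/bin/env Rscript

# Stage 4: geometry stability of the modelled system.
#
# Superposition RMSD of the jittered trajectory against its reference, and
# distance monitors for the two catalytic contacts: the carboxylate-oxygen
# pair (asymmetric: one oxygen stays nearer the transferring proton) and a
# fixed donor-acceptor distance.

suppressPackageStartupMessages(library(dipolescan))

traj <- read_multimodel("results/fixture/traj.pdb")
cat(sprintf("Trajectory: %d frames, %d atoms\n", length(traj),
            nrow(traj[[1]])))

ser <- rmsd_series(traj, label = "all-atom")
cat(sprintf("Mean RMSD vs frame 1: %.2f A\n", attr(ser, "mean")))
dir.create("results/geometry", showWarnings = FALSE, recursive = TRUE)
utils::write.table(ser, "results/geometry/rmsd.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

mons <- monitor(traj, list(
  monitor_spec("acceptor_carboxylate", "A:500:OX",
               c("A:109:OE1", "A:109:CD")),
  monitor_spec("donor_acceptor", "A:500:OX", "A:109:OE1")))
write_monitor_tsv(mons, "results/geometry")
for (m in mons) print(m)
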
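#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study system.
#
# Emits the toy reactant/transition-state pair with per-atom charges, the
# QM-region definition, closed-form ground truth, a jittered trajectory for
# the geometry analyses, and a synthetic deletion energy table. Everything
# downstream reads these files, so the whole workflow is reproducible from
# this seed alone.

suppressPackageStartupMessages(library(dipolescan))

seed <- 42L
out <- "results/fixture"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

fx <- make_toy_enzyme(toy_ncs_spec(seed = seed), out_dir = out)
cat(sprintf("Toy enzyme: %d atoms, %d environment residues (seed %d)\n",
            nrow(fx$pair$reactant), nrow(fx$truth), seed))
cat(sprintf("Planted anticatalytic residues: %s\n",
            paste(with(subset(fx$truth, planted & ddE < -1),
                       paste0(resname, resid)), collapse = ", ")))

make_trajectory(fx$pair$reactant, n_frames = 500, jitter_sigma = 0.25,
                seed = seed, path = file.path(out, "traj.pdb"))
cat("Trajectory: 500 frames, sigma 0.25 A -> results/fixture/traj.pdb\n")

tab <- make_energy_table(
  12, wt_barrier = 10.6,
  planted_effects = c("64" = -1.7, "71" = -2.0, "105" = -1.8,
                      "110" = -2.6, "117" = -2.4, "163" = -1.9),
  noise_sigma = 0, seed = seed,
  path = file.path(out, "energies.csv"))
cat("Energy table: 12 deletions, 6 planted shifts -> results/fixture/energies.csv\n")
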
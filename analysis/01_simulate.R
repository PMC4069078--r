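#!/usr/bin/env Rscript
# Build the synthetic two-state study: a thermostable beta-barrel-like
# protein observed free and ligand-bound at 58 C, with 15N relaxation
# decay series at 600 and 800 MHz, hetNOE intensity pairs, H/D exchange
# build-up series, a sequence table, unit N-H bond vectors, a synthetic
# structure ensemble and an RDC splitting table. Everything downstream
# (02-07) reads this workspace.

library(nmrdyn)

seed <- 20260
ws_dir <- file.path("results", "workspace")

ws <- demo_workspace(seed = seed, dir = ws_dir,
                     n_strand = 16, n_loop = 8, n_rigidified = 4)

cat("Synthetic study written to", ws_dir, "\n")
cat(sprintf("  %d residues (%d strand, %d loop), ids %d-%d\n",
            nrow(ws$truths$free$residues), 16, 8,
            min(ws$truths$free$residues$residue),
            max(ws$truths$free$residues$residue)))
cat(sprintf("  overall tumbling: tau_c = %.1f ns (both states)\n",
            ws$truths$free$tensor$tau_c * 1e9))
cat(sprintf("  seeded rigidification on binding (+0.15 in S2): residues %s\n",
            paste(sort(ws$rigidified), collapse = ", ")))
cat(sprintf("  free-form exchange rates offset +0.28e-3 s^-1 vs bound\n"))
cat("  config: ", file.path(ws_dir, "config.yaml"), "\n")
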
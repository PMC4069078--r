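#!/usr/bin/env Rscript
# H/D exchange kinetics: build-up fits, censored bounds for fast
# exchangers, intrinsic rates, protection factors and the plotting
# categories; free-vs-bound protection comparison.

library(nmrdyn)

cfg <- read_config(file.path("results", "workspace", "config.yaml"))
cfg$stages <- "hdx"
run_pipeline(cfg)

hdx <- lapply(c(free = "free", bound = "bound"), function(st)
  read.delim(file.path(cfg$outdir, sprintf("%s_hdx_protection.tsv", st)),
             sep = "\t", comment.char = "#"))

cat(sprintf("fast-exchange lower bound at t1 = 900 s: %.1e s^-1\n",
            censor_bound(900)))
cat(sprintf("second-group bound at t2 = %.0f s:        %.1e s^-1\n",
            default_hdx_grid()[2], censor_bound(default_hdx_grid()[2])))
for (st in names(hdx)) {
  tab <- hdx[[st]]
  cat(sprintf("%-5s: categories %s\n", st,
              paste(sprintf("%s=%d", names(table(tab$category)),
                            table(tab$category)), collapse = ", ")))
}
# rate offset on residues measured in both states (matched pairs)
both <- intersect(hdx$free$residue[hdx$free$category == "measured"],
                  hdx$bound$residue[hdx$bound$category == "measured"])
kf <- hdx$free$k_ex[match(both, hdx$free$residue)]
kb <- hdx$bound$k_ex[match(both, hdx$bound$residue)]
cat(sprintf(
  "matched residues (n = %d): mean k_ex free %.2e, bound %.2e, offset %.2e s^-1\n",
  length(both), mean(kf), mean(kb), mean(kf - kb)))
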
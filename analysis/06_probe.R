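#!/usr/bin/env Rscript
# Stage 6: virtual screw-pathway probing and run report.
#
# Probes the averaged density model along a central pathway (long axis) and
# a peripheral pathway running just beneath the dorsal surface, each with a
# 3 mm diameter disk-sampled cylinder, then renders the run report.

library(carposhape)

cfg <- pipeline_config("analysis/config.yaml")
cfg$stages <- list(synth = FALSE, preprocess = FALSE, correspond = FALSE,
                   shape = FALSE, density = FALSE, probe = TRUE)
manifest <- run_pipeline(cfg)

ps <- read.csv(file.path(cfg$out_dir, "probes", "probe_summary.csv"))
print(ps, row.names = FALSE)
cat(sprintf("\nperipheral / central path-mean vBMD ratio: %.2f\n",
            ps$mean[ps$pathway == "peripheral"] /
            ps$mean[ps$pathway == "central"]))
pipeline_report(manifest)
cat("\nreport written to", file.path(cfg$out_dir, "report", "report.txt"), "\n")
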
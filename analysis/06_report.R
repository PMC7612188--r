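#!/usr/bin/env Rscript
# Report-layer arithmetic: census percentages, plus-end densities, and the
# summary of the earlier stages' outputs.
library(axonmt)
dir.create("results", showWarnings = FALSE)
pc <- pf_census(c("12" = 134, "13" = 101, "ND" = 21))
print(pc)
d <- densities(11, 75, 0.3)
cat(sprintf("plus ends: %.2g/um, %.2g/um^2 (ratio to 0.065/um^2: %.1f)\n",
            d$report["per_um"], d$report["per_um2"], d$per_um2 / 0.065))
rows <- list(c("census_12_pct", pc$percent[pc$class == "12"]),
             c("census_13_pct", pc$percent[pc$class == "13"]),
             c("plus_ends_per_um", d$report["per_um"]),
             c("plus_ends_per_um2", d$report["per_um2"]))
write.table(do.call(rbind, rows), "results/report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = c("key", "value"))
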
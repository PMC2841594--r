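#!/usr/bin/env Rscript
# Scan ICR and control regions for the H3K4me3/H3K9me3/H4K20me3 tri-mark
# signature (regions evaluated as their own intervals, pluripotent cell
# type). Run analysis/01_simulate.R first.

suppressPackageStartupMessages(library(imprintmarks))

paths <- bundle_paths("scratch/bundle", cell_types = c("ESC", "NPC", "MEF"))
bundle <- read_bundle(list(paths = paths))
sig <- Filter(function(cs) cs$mark %in% c("H3K4me3", "H3K9me3", "H4K20me3"),
              bundle$callsets$ESC)
k27 <- Filter(function(cs) cs$mark == "H3K27me3", bundle$callsets$ESC)[[1]]

scan <- scan_icr_signature(bundle$regions, sig, k27_callset = k27)
dir.create("results", showWarnings = FALSE)
write.table(scan$reports, "results/04_icr_scan.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(scan$summary, "results/04_icr_scan_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

print(scan)
icr <- scan$summary[scan$summary$class %in% c("promoter ICR", "intergenic ICR"), ]
message(sprintf("tri-mark signature at %d/%d ICR regions",
                sum(icr$n_signature), sum(icr$n)))
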
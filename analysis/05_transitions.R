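#!/usr/bin/env Rscript
# Bivalency-resolution dynamics: for imprinted genes bivalent in the
# pluripotent state, classify what the H3K4me3/H3K27me3 profile resolves to
# in each differentiated cell type, together with the expression outcome.
# Run analysis/01_simulate.R first.

suppressPackageStartupMessages(library(imprintmarks))

paths <- bundle_paths("scratch/bundle", cell_types = c("ESC", "NPC", "MEF"))
bundle <- read_bundle(list(paths = paths))
res <- resolve_gene_records(bundle$query, bundle$genes)
imp <- bundle$genes[match(res$matched, bundle$genes$gene_id), ]

st <- build_state_table(imp, bundle$callsets,
                        expression = bundle$expression[, c("gene_id", "cell_type", "status")])
tt <- rbind(transition_table(st, "ESC", "NPC"),
            transition_table(st, "ESC", "MEF"))
dir.create("results", showWarnings = FALSE)
write.table(tt, "results/05_transitions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

xt <- table(tt$transition_class, tt$expression_outcome)
message(nrow(tt), " transitions out of the bivalent state:")
print(xt)
write.table(as.data.frame(xt), "results/05_transition_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
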
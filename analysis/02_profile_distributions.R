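#!/usr/bin/env Rscript
# Combinatorial H3K4me3/H3K27me3/H3K9me3 profile distributions at imprinted
# versus all gene TSSs (pluripotent cell type), plus the two-mark bivalency
# distributions per cell type. Run analysis/01_simulate.R first.

suppressPackageStartupMessages(library(imprintmarks))

paths <- bundle_paths("scratch/bundle", cell_types = c("ESC", "NPC", "MEF"))
bundle <- read_bundle(list(paths = paths))
res <- resolve_gene_records(bundle$query, bundle$genes)
message(length(res$matched), " imprinted genes resolved; ",
        length(res$not_present), " not present in the annotation")

imp <- bundle$genes[match(res$matched, bundle$genes$gene_id), ]
tax3 <- taxonomy_preset("three_mark")
tax2 <- taxonomy_preset("bivalency")
pick <- function(ct, marks) {
  Filter(function(cs) cs$mark %in% marks, bundle$callsets[[ct]])
}

rows <- list()
for (set in list(list("imprinted", imp), list("all_genes", bundle$genes))) {
  d <- profile_distribution(set[[2]], pick("ESC", tax3$marks), tax3)
  rows[[length(rows) + 1]] <- data.frame(
    gene_set = set[[1]], cell_type = "ESC", taxonomy = "three_mark",
    label = d$labels, count = d$counts, n = d$n,
    percent = round(d$percentages, 1), row.names = NULL)
}
for (ct in c("ESC", "NPC", "MEF")) {
  d <- profile_distribution(imp, pick(ct, tax2$marks), tax2)
  rows[[length(rows) + 1]] <- data.frame(
    gene_set = "imprinted", cell_type = ct, taxonomy = "bivalency",
    label = d$labels, count = d$counts, n = d$n,
    percent = round(d$percentages, 1), row.names = NULL)
}
out <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.table(out, "results/02_profile_distributions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

biv <- out[out$taxonomy == "three_mark" & out$label == "H3K4me3+H3K27me3", ]
message(sprintf("H3K4me3+H3K27me3 co-enrichment: %.0f%% of imprinted vs %.0f%% of all genes",
                biv$percent[biv$gene_set == "imprinted"],
                biv$percent[biv$gene_set == "all_genes"]))
print(out, row.names = FALSE)
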
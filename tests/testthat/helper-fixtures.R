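# Fixtures built in code; no files needed.

make_callset <- function(triples, mark = "H3K4me3", cell_type = "ESC",
                         method = "WI") {
  if (!length(triples)) {
    return(callset(mark = mark, cell_type = cell_type, method = method))
  }
  m <- do.call(rbind, triples)
  callset(as.character(m[, 1]), as.integer(m[, 2]), as.integer(m[, 3]),
          mark = mark, cell_type = cell_type, method = method)
}

make_genes <- function(n, chrom = "chr1", spacing = 10000L, start = 5000L) {
  gene_table(data.frame(
    gene_id = sprintf("g%03d", seq_len(n)),
    aliases = sprintf("Sym%03d", seq_len(n)),
    chrom = chrom,
    tss = start + (seq_len(n) - 1L) * spacing,
    strand = rep(c("+", "-"), length.out = n),
    species = "mouse",
    stringsAsFactors = FALSE))
}

# independent O(n*m) overlap oracle on 0-based half-open intervals
brute_force_overlap <- function(w_start, w_end, w_chrom, ivs) {
  any(ivs$chrom == w_chrom & ivs$start < w_end & w_start < ivs$end)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 50000L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(2000L, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# direct textbook chi-square recomputation, kept independent of the package
oracle_chisq <- function(m, yates = FALSE) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  d <- abs(m - e)
  if (yates) d <- pmax(d - 0.5, 0)
  stat <- sum(d^2 / e)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(stat = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

# the nine printed bivalency-resolution examples (ESC -> differentiated),
# encoded from the published dynamics table
table1_fixture <- function() {
  rows <- list(
    list("Gatm",    "NPC", "repressed", "expressed", "K4_only",  "resolved_to_K4",    "activated"),
    list("Gatm",    "MEF", "repressed", "expressed", "bivalent", "retained_bivalent", "activated"),
    list("Peg12",   "NPC", "repressed", "expressed", "K4_only",  "resolved_to_K4",    "activated"),
    list("Tfpi2",   "MEF", "repressed", "expressed", "neither",  "resolved_to_none",  "activated"),
    list("Ascl2",   "NPC", "repressed", "repressed", "bivalent", "retained_bivalent", "still_repressed"),
    list("Calcr",   "NPC", "repressed", "repressed", "K27_only", "resolved_to_K27",   "still_repressed"),
    list("Kcnq1",   "NPC", "repressed", "repressed", "K27_only", "resolved_to_K27",   "still_repressed"),
    list("Rasgrf",  "NPC", "repressed", "repressed", "bivalent", "retained_bivalent", "still_repressed"),
    list("Slc22a3", "NPC", "repressed", "repressed", "K27_only", "resolved_to_K27",   "still_repressed"),
    list("Tfpi2",   "NPC", "repressed", "repressed", "neither",  "resolved_to_none",  "still_repressed"))
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gene = r[[1]], to_cell = r[[2]], from_expr = r[[3]],
               to_expr = r[[4]], to_state = r[[5]],
               expected_class = r[[6]], expected_outcome = r[[7]],
               stringsAsFactors = FALSE)
  }))
}

small_config <- function(...) {
  synthetic_config(n_genes = 400, n_imprinted = 40,
                   n_icr_intergenic = 3, n_other_regions = 3, ...)
}
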
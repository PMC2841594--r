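region_fix <- list(region_id = "r1", chrom = "chr1", start = 1000, end = 2000,
                   class = "promoter ICR")

sig_callsets <- function(k4, k9, k20, ct = "ESC") {
  iv <- list(c("chr1", 1200, 1400))
  list(make_callset(if (k4) iv else list(), mark = "H3K4me3", cell_type = ct),
       make_callset(if (k9) iv else list(), mark = "H3K9me3", cell_type = ct),
       make_callset(if (k20) iv else list(), mark = "H4K20me3", cell_type = ct,
                    method = "HMM"))
}

test_that("tri-mark signature is the conjunction over all 8 combinations", {
  for (k4 in c(FALSE, TRUE)) for (k9 in c(FALSE, TRUE)) for (k20 in c(FALSE, TRUE)) {
    rep <- detect_tri_mark(region_fix, sig_callsets(k4, k9, k20))
    expect_equal(rep$signature, k4 && k9 && k20)
    expect_equal(unname(rep$marks), c(k4, k9, k20))
  }
  # wrong mark set is an error
  bad <- sig_callsets(TRUE, TRUE, TRUE)
  bad[[2]] <- make_callset(list(), mark = "H3K27me3")
  expect_error(detect_tri_mark(region_fix, bad), "signature marks")
})

test_that("K27 is excluded from the signature but reported as annotation", {
  k27 <- make_callset(list(c("chr1", 1200, 1400)), mark = "H3K27me3")
  rep <- detect_tri_mark(region_fix, sig_callsets(TRUE, TRUE, TRUE),
                         k27_callset = k27)
  expect_true(rep$signature)
  expect_true(rep$k27)
  rep2 <- detect_tri_mark(region_fix, sig_callsets(TRUE, TRUE, TRUE))
  expect_true(is.na(rep2$k27))
})

test_that("ICR scan summarises signature fractions by region class", {
  regions <- data.frame(
    region_id = c("icr1", "icr2", "gdmr", "ctrl"),
    chrom = "chr1",
    start = c(1000, 5000, 9000, 13000),
    end = c(2000, 6000, 10000, 14000),
    class = c("promoter ICR", "intergenic ICR", "non-ICR germline DMR", "other"),
    stringsAsFactors = FALSE)
  iv <- function(s) c("chr1", s + 100, s + 300)
  cs <- list(
    make_callset(list(iv(1000), iv(5000), iv(9000)), mark = "H3K4me3"),
    make_callset(list(iv(1000), iv(5000)), mark = "H3K9me3"),
    make_callset(list(iv(1000), iv(5000)), mark = "H4K20me3", method = "HMM"))
  scan <- scan_icr_signature(regions, cs)
  sm <- scan$summary
  expect_equal(sm$fraction[sm$class == "promoter ICR"], 1)
  expect_equal(sm$fraction[sm$class == "intergenic ICR"], 1)
  # the germline DMR that is not an ICR has activating mark only: no signature
  expect_equal(sm$fraction[sm$class == "non-ICR germline DMR"], 0)
  expect_length(scan$non_icr_with_signature, 0)
  expect_error(scan_icr_signature(regions[0, ], cs), "empty")
})

test_that("bivalency state is the 4-way H3K4me3/H3K27me3 mapping", {
  expect_equal(bivalency_state(TRUE, TRUE), "bivalent")
  expect_equal(bivalency_state(TRUE, FALSE), "K4_only")
  expect_equal(bivalency_state(FALSE, TRUE), "K27_only")
  expect_equal(bivalency_state(FALSE, FALSE), "neither")
  expect_equal(bivalency_state(c(H3K4me3 = TRUE, H3K27me3 = TRUE)), "bivalent")
  expect_error(bivalency_state(NA, TRUE), "missing")
})

test_that("transition classification is total and deterministic over all state pairs", {
  states <- c("K4_only", "K27_only", "bivalent", "neither")
  exprs <- c("expressed", "repressed", "unknown")
  for (fs in states) for (ts in states) for (fe in exprs) for (te in exprs) {
    rec <- classify_transition("g", "ESC", "NPC", fs, ts, fe, te)
    expect_equal(nrow(rec), 1)
    expect_true(rec$transition_class %in%
                  c("resolved_to_K4", "resolved_to_K27", "resolved_to_none",
                    "retained_bivalent", "gained_marks", "not_applicable"))
    expect_true(rec$expression_outcome %in%
                  c("activated", "still_repressed", "still_expressed",
                    "silenced", "unknown"))
    if (fs == "bivalent") expect_false(rec$transition_class %in%
                                         c("gained_marks", "not_applicable"))
  }
  expect_equal(classify_transition("g", "ESC", "NPC", "neither", "bivalent")$transition_class,
               "gained_marks")
  expect_equal(classify_transition("g", "ESC", "NPC", "K4_only", "K27_only")$transition_class,
               "not_applicable")
  expect_error(classify_transition("g", "ESC", "ESC", "bivalent", "bivalent"),
               "distinct cell types")
})

test_that("the published bivalency-dynamics rows classify to their expected classes", {
  fx <- table1_fixture()
  for (i in seq_len(nrow(fx))) {
    rec <- classify_transition(fx$gene[i], "ESC", fx$to_cell[i],
                               "bivalent", fx$to_state[i],
                               fx$from_expr[i], fx$to_expr[i])
    expect_equal(rec$transition_class, fx$expected_class[i],
                 label = paste(fx$gene[i], fx$to_cell[i]))
    expect_equal(rec$expression_outcome, fx$expected_outcome[i],
                 label = paste(fx$gene[i], fx$to_cell[i]))
  }
})

test_that("transition tables derive states from an integrated state table", {
  genes <- make_genes(3, spacing = 5000L)
  peaks <- function(i) list(c("chr1", genes$tss[i] - 100L, genes$tss[i] + 100L))
  callsets <- list(
    ESC = list(make_callset(c(peaks(1), peaks(2)), mark = "H3K4me3"),
               make_callset(c(peaks(1), peaks(2)), mark = "H3K27me3")),
    NPC = list(make_callset(peaks(1), mark = "H3K4me3", cell_type = "NPC"),
               make_callset(list(), mark = "H3K27me3", cell_type = "NPC")))
  st <- build_state_table(genes, callsets)
  tt <- transition_table(st, "ESC", "NPC")
  expect_equal(nrow(tt), 2)  # only the two ESC-bivalent genes
  expect_equal(tt$transition_class[tt$gene_id == "g001"], "resolved_to_K4")
  expect_equal(tt$transition_class[tt$gene_id == "g002"], "resolved_to_none")
  full <- transition_table(st, "ESC", "NPC", bivalent_only = FALSE)
  expect_equal(nrow(full), 3)
})
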
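test_that("identical (config, seed) yields byte-identical bundles", {
  cfg <- small_config(seed = 101)
  d1 <- tempfile("b1"); d2 <- tempfile("b2")
  b1 <- generate_bundle(cfg, d1)
  b2 <- generate_bundle(cfg, d2)
  files1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(files1, sort(list.files(d2, recursive = TRUE)))
  for (f in setdiff(files1, "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_identical(b1$truth$genes, b2$truth$genes)
  expect_identical(b1$truth$states, b2$truth$states)
  # a different seed changes the realization
  b3 <- generate_bundle(small_config(seed = 102), tempfile())
  expect_false(identical(b1$truth$states$H3K4me3, b3$truth$states$H3K4me3))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(synthetic_config(p_signature_icr = 1.5), "probabilities")
  expect_error(synthetic_config(dmr_split = c(germline = 0.5, somatic = 0.2,
                                              none = 0.2)), "sum to 1")
  expect_error(synthetic_config(n_genes = 10, n_imprinted = 20), "exceeds")
  expect_error(synthetic_config(p_k4_given_expressed = 0.9,
                                p_k27_given_expressed = 0.3), "exceed 1")
})

test_that("generated bundles parse cleanly through the readers", {
  set.seed(400)
  for (seed in c(7, 8)) {
    cfg <- small_config(seed = seed,
                        missingness = c(annotation = runif(1, 0, 0.1),
                                        expression = runif(1, 0, 0.1),
                                        dmr = runif(1, 0, 0.2)))
    b <- generate_bundle(cfg, tempfile())
    bundle <- read_bundle(b)
    expect_s3_class(bundle$genes, "gene_table")
    expect_true(all(vapply(unlist(bundle$callsets, recursive = FALSE),
                           inherits, NA, "callset")))
    expect_equal(sort(names(bundle$callsets)), sort(cfg$cell_types))
    # expression statuses recover the latent state exactly where present
    ts <- b$truth$states
    key <- paste(bundle$expression$gene_id, bundle$expression$cell_type)
    tkey <- paste(ts$gene_id, ts$cell_type)
    want <- ifelse(ts$expressed[match(key, tkey)], "expressed", "repressed")
    expect_equal(bundle$expression$status, want)
    # dropped genes really are absent from their layers but not the queries
    expect_false(any(b$truth$dropped$annotation %in% bundle$genes$gene_id))
    expect_true(all(b$truth$dropped$dmr %in% b$truth$genes$gene_id))
  }
})

test_that("TSS enrichment recovers the latent mark states exactly", {
  cfg <- small_config(seed = 31)
  b <- generate_bundle(cfg, tempfile())
  bundle <- read_bundle(b)
  st <- build_state_table(bundle$genes, bundle$callsets, flank = cfg$flank)
  ts <- b$truth$states
  key <- paste(st$gene_id, st$cell_type)
  tkey <- paste(ts$gene_id, ts$cell_type)
  idx <- match(key, tkey)
  for (mk in c("H3K27me3", "H3K9me3", "H4K20me3")) {
    expect_equal(unname(st[[mk]]), ts[[mk]][idx], label = mk)
  }
  # H3K4me3 true states are all recovered; region peaks sit outside TSS flanks
  expect_equal(unname(st$H3K4me3), ts$H3K4me3[idx])
})

test_that("degenerate probabilities force the corresponding outputs", {
  cfg <- small_config(seed = 5, p_k9k20_given_no_dmr = 0,
                      p_signature_icr = 1)
  b <- generate_bundle(cfg, tempfile())
  bundle <- read_bundle(b)
  # no K9/K20 pair outside germline-DMR genes, by construction
  tg <- b$truth$genes
  expect_true(all(!tg$k9k20[is.na(tg$promoter_dmr) | tg$promoter_dmr != "germline"]))
  scan <- scan_icr_signature(
    bundle$regions,
    Filter(function(cs) cs$mark %in% c("H3K4me3", "H3K9me3", "H4K20me3"),
           bundle$callsets$ESC))
  sm <- scan$summary
  expect_equal(sm$fraction[sm$class == "promoter ICR"], 1)
  expect_equal(sm$fraction[sm$class == "intergenic ICR"], 1)
  expect_length(scan$non_icr_with_signature, 0)

  cfg0 <- small_config(seed = 6, p_signature_icr = 0)
  b0 <- generate_bundle(cfg0, tempfile())
  bundle0 <- read_bundle(b0)
  scan0 <- scan_icr_signature(
    bundle0$regions,
    Filter(function(cs) cs$mark %in% c("H3K4me3", "H3K9me3", "H4K20me3"),
           bundle0$callsets$ESC))
  expect_true(all(scan0$summary$fraction == 0))
})

test_that("mid-range signature probability matches the realized truth count", {
  cfg <- synthetic_config(n_genes = 400, n_imprinted = 40, seed = 91,
                          p_signature_icr = 0.8, n_icr_intergenic = 20,
                          n_other_regions = 3)
  b <- generate_bundle(cfg, tempfile())
  bundle <- read_bundle(b)
  scan <- scan_icr_signature(
    bundle$regions,
    Filter(function(cs) cs$mark %in% c("H3K4me3", "H3K9me3", "H4K20me3"),
           bundle$callsets$ESC))
  truth_icr <- b$truth$regions[b$truth$regions$class %in%
                                 c("promoter ICR", "intergenic ICR"), ]
  got <- scan$reports[scan$reports$class %in% c("promoter ICR", "intergenic ICR"), ]
  expect_equal(sum(got$signature), sum(truth_icr$signature))
  expect_equal(got$signature[match(truth_icr$region_id, got$region_id)],
               truth_icr$signature)
})

test_that("parameter recovery stays within 3 binomial SE at moderate scale", {
  cfg <- synthetic_config(
    n_genes = 5000, n_imprinted = 1600,
    dmr_split = c(germline = 0.4, somatic = 0.15, none = 0.45),
    p_bivalent_given_repressed = c(ESC = 0.5, NPC = 0.18, MEF = 0.33),
    missingness = c(annotation = 0, expression = 0, dmr = 0),
    n_icr_intergenic = 50, seed = 2024)
  b <- generate_bundle(cfg, tempfile())
  bundle <- read_bundle(b)
  st <- build_state_table(
    bundle$genes, bundle$callsets,
    expression = bundle$expression[, c("gene_id", "cell_type", "status")],
    dmr = bundle$dmr, flank = cfg$flank)
  scan <- scan_icr_signature(
    bundle$regions,
    Filter(function(cs) cs$mark %in% c("H3K4me3", "H3K9me3", "H4K20me3"),
           bundle$callsets$ESC))
  rec <- recover_parameters(st, b$truth, cfg, scan = scan)
  expect_gte(min(rec$n[grepl("bivalent|k9k20|expressed", rec$parameter)]), 200)
  expect_true(all(rec$within_3se),
              info = paste(capture.output(print(rec[!rec$within_3se, ])),
                           collapse = "\n"))
  # exact recovery at the boundaries
  expect_equal(rec$estimate[rec$parameter == "p_k9k20_given_no_dmr"], 0)
  expect_equal(rec$estimate[rec$parameter == "p_signature_icr"], 1)
  # mismatched truth is refused
  b2 <- generate_bundle(small_config(seed = 1), tempfile())
  expect_error(recover_parameters(st, b2$truth, cfg), "unknown to the truth")
})
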
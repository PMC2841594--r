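#' Run the full profiling pipeline
#'
#' Orchestrates every stage end-to-end: input reading (or synthetic-bundle
#' generation), gene resolution, profile distributions, DMR- and
#' expression-stratified comparisons, the tri-mark ICR scan, the
#' bivalency-transition table, the calling-method concordance report and all
#' condition-checked chi-square tests. Every analysis-affecting parameter is
#' echoed into the provenance header, and identical configurations (including
#' the seed) produce identical report bundles.
#'
#' @param config list with elements:
#'   * `synthetic` — a [synthetic_config()] (synthetic mode), or
#'   * `paths` — a named list of input files shaped like
#'     `generate_bundle()$paths` (real-data mode);
#'   * `flank` TSS flank in bp (default 1000);
#'   * `out_dir` optional directory for TSV/JSON reports.
#' @return A `pipeline_report` list: `provenance`, `resolution`,
#'   `distributions`, `stratified`, `icr_scan`, `transitions`, `concordance`,
#'   `tests`, `state_table`, and (synthetic mode) `truth`, `recovery`.
#' @export
run_pipeline <- function(config) {
  flank <- if (!is.null(config$flank)) config$flank else 1000
  stopifnot(flank > 0)
  synthetic <- !is.null(config$synthetic)
  if (synthetic) {
    stopifnot(inherits(config$synthetic, "synthetic_config"))
    gen <- generate_bundle(config$synthetic,
                           dir = if (!is.null(config$bundle_dir)) config$bundle_dir
                                 else tempfile("bundle"))
    paths <- gen$paths
  } else {
    if (is.null(config$paths)) stop("config needs either $synthetic or $paths")
    paths <- config$paths
    gen <- NULL
  }
  bundle <- read_bundle(list(paths = paths))
  cts <- names(bundle$callsets)
  ref_ct <- cts[1L]

  provenance <- list(
    package = "imprintmarks",
    version = as.character(utils::packageVersion("imprintmarks")),
    mode = if (synthetic) "synthetic" else "real",
    flank = flank,
    cell_types = cts,
    seed = if (synthetic) config$synthetic$seed else NA,
    caveats = callset_caveats(unlist(bundle$callsets, recursive = FALSE)))

  # gene resolution: imprinted queries against the annotation
  resolution <- resolve_gene_records(bundle$query, bundle$genes)
  imp_genes <- bundle$genes[match(resolution$matched, bundle$genes$gene_id), ,
                            drop = FALSE]
  imp_genes$imprinted <- TRUE
  all_genes <- bundle$genes
  all_genes$imprinted <- all_genes$gene_id %in% imp_genes$gene_id

  tax3 <- taxonomy_preset("three_mark")
  tax2 <- taxonomy_preset("bivalency")
  pick <- function(ct, marks) {
    cs <- bundle$callsets[[ct]]
    cs[vapply(cs, `[[`, "", "mark") %in% marks]
  }

  # combinatorial profile distributions
  distributions <- list(
    imprinted_three_mark = profile_distribution(
      imp_genes, pick(ref_ct, tax3$marks), tax3, flank),
    all_genes_three_mark = profile_distribution(
      all_genes, pick(ref_ct, tax3$marks), tax3, flank))
  for (ct in cts) {
    distributions[[paste0("imprinted_bivalency_", ct)]] <-
      profile_distribution(imp_genes, pick(ct, tax2$marks), tax2, flank)
  }

  # integrated state table
  expression <- bundle$expression[, c("gene_id", "cell_type", "status")]
  state_table <- build_state_table(all_genes, bundle$callsets,
                                   expression = expression, dmr = bundle$dmr,
                                   taxonomy = tax3, flank = flank)
  imp_states <- state_table[state_table$gene_id %in% imp_genes$gene_id, ,
                            drop = FALSE]
  class(imp_states) <- class(state_table)

  # stratifications (pluripotent cell type)
  strat_dmr <- stratify(imp_states, "promoter_dmr", cell_type = ref_ct)
  strat_expr <- lapply(stats::setNames(cts, cts), function(ct) {
    stratify(imp_states, "expression", cell_type = ct)
  })
  marks4 <- attr(state_table, "marks")
  mark_counts_by <- function(groups) {
    t(vapply(groups, function(g) {
      vapply(marks4, function(mk) sum(g[[mk]]), 0L)
    }, stats::setNames(integer(length(marks4)), marks4)))
  }
  stratified <- list(
    by_promoter_dmr = list(
      n = vapply(strat_dmr$groups, nrow, 0L),
      n_unknown = nrow(strat_dmr$unknown),
      mark_counts = mark_counts_by(strat_dmr$groups)),
    by_expression = lapply(strat_expr, function(s) {
      states <- lapply(s$groups, function(g) {
        table(factor(mapply(bivalency_state, g$H3K4me3, g$H3K27me3),
                     levels = BIVALENCY_STATES))
      })
      list(n = vapply(s$groups, nrow, 0L), n_unknown = nrow(s$unknown),
           bivalency_counts = do.call(rbind, states))
    }))

  # tri-mark ICR signature scan (pluripotent cell type; regions as regions)
  sig_cs <- pick(ref_ct, SIGNATURE_MARKS)
  k27_cs <- pick(ref_ct, "H3K27me3")
  icr_scan <- scan_icr_signature(bundle$regions, sig_cs,
                                 k27_callset = if (length(k27_cs)) k27_cs[[1]])

  # bivalency-resolution transitions out of the pluripotent state
  transitions <- do.call(rbind, lapply(setdiff(cts, ref_ct), function(ct) {
    transition_table(imp_states, ref_ct, ct)
  }))

  # calling-method concordance on the imprinted set
  concordance <- lapply(bundle$hmm_callsets, function(hmm) {
    wi <- pick(hmm$cell_type, hmm$mark)
    wi <- wi[vapply(wi, `[[`, "", "method") == "WI"]
    if (!length(wi)) return(NULL)
    method_concordance(wi[[1]], hmm, imp_genes, flank)
  })
  concordance <- Filter(Negate(is.null), concordance)

  # condition-checked chi-square comparisons
  with_profile <- function(dist, label) dist$counts[[label]]
  n_imp <- distributions$imprinted_three_mark$n
  n_all <- distributions$all_genes_three_mark$n
  tests <- list()
  for (lab in c("H3K4me3+H3K27me3", "H3K4me3+H3K9me3")) {
    tab <- matrix(c(with_profile(distributions$imprinted_three_mark, lab),
                    n_imp - with_profile(distributions$imprinted_three_mark, lab),
                    with_profile(distributions$all_genes_three_mark, lab),
                    n_all - with_profile(distributions$all_genes_three_mark, lab)),
                  2, byrow = TRUE,
                  dimnames = list(c("imprinted", "all_genes"), c("with", "without")))
    tests[[paste0("imprinted_vs_all_", lab)]] <- yates_chi2_2x2(tab)
  }
  biv_counts <- vapply(cts, function(ct) {
    distributions[[paste0("imprinted_bivalency_", ct)]]$counts
  }, distributions[[paste0("imprinted_bivalency_", ref_ct)]]$counts)
  keep <- rowSums(biv_counts) > 0
  if (sum(keep) >= 2 && ncol(biv_counts) >= 2) {
    tests$profiles_across_cell_types <- contingency_chi2(t(biv_counts[keep, ])
    )
  }
  if (all(c("dmr", "no_dmr") %in% names(strat_dmr$groups))) {
    mc <- stratified$by_promoter_dmr$mark_counts
    mc <- mc[, colSums(mc) > 0, drop = FALSE]
    if (ncol(mc) >= 2) tests$dmr_vs_no_dmr_marks <- contingency_chi2(mc)
  }
  for (ct in cts) {
    bc <- stratified$by_expression[[ct]]$bivalency_counts
    if (!is.null(bc) && nrow(bc) == 2) {
      bc <- bc[, colSums(bc) > 0, drop = FALSE]
      if (ncol(bc) >= 2) {
        tests[[paste0("expressed_vs_repressed_", ct)]] <- contingency_chi2(bc)
      }
    }
  }

  report <- list(provenance = provenance, resolution = resolution,
                 distributions = distributions, stratified = stratified,
                 icr_scan = icr_scan, transitions = transitions,
                 concordance = concordance, tests = tests,
                 state_table = state_table)
  if (synthetic) {
    report$truth <- gen$truth
    report$recovery <- recover_parameters(state_table, gen$truth,
                                          config$synthetic, scan = icr_scan,
                                          concordance = concordance)
  }
  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a pipeline report bundle to disk
#'
#' Tab-separated tables plus one JSON summary, with the provenance header
#' echoed into every file set.
#'
#' @param report a `pipeline_report`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wt <- function(df, name) {
    f <- file.path(out_dir, name)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, f)
  }
  dist_df <- do.call(rbind, lapply(names(report$distributions), function(nm) {
    d <- report$distributions[[nm]]
    data.frame(analysis = nm, cell_type = d$cell_type, label = d$labels,
               count = d$counts, n = d$n,
               percent = round(d$percentages, 2), row.names = NULL)
  }))
  wt(dist_df, "profile_distributions.tsv")
  wt(report$icr_scan$reports, "icr_scan.tsv")
  wt(report$icr_scan$summary, "icr_scan_summary.tsv")
  if (NROW(report$transitions)) wt(report$transitions, "transitions.tsv")
  if (length(report$concordance)) {
    conc <- do.call(rbind, lapply(report$concordance, function(cr) {
      data.frame(mark = cr$mark, cell_type = cr$cell_type,
                 method_a = cr$methods[1], method_b = cr$methods[2],
                 n = cr$n, n_discordant = cr$n_discordant,
                 fraction_discordant = cr$fraction_discordant)
    }))
    wt(conc, "concordance.tsv")
  }
  tests_df <- do.call(rbind, lapply(names(report$tests), function(nm) {
    tt <- report$tests[[nm]]
    data.frame(test = nm, statistic = tt$statistic, df = tt$df,
               p_value = tt$p_value, yates = tt$yates_applied,
               validity = tt$validity, validity_reason = tt$validity_reason)
  }))
  if (!is.null(tests_df)) wt(tests_df, "tests.tsv")
  wt(as.data.frame(report$state_table), "state_table.tsv")
  if (!is.null(report$recovery)) wt(report$recovery, "parameter_recovery.tsv")
  summary <- list(
    provenance = report$provenance,
    resolution = list(matched = length(report$resolution$matched),
                      not_present = report$resolution$not_present,
                      ambiguous = report$resolution$ambiguous),
    icr_summary = report$icr_scan$summary,
    non_icr_with_signature = report$icr_scan$non_icr_with_signature,
    tests = lapply(report$tests, function(tt) {
      list(statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
           yates = tt$yates_applied, validity = tt$validity)
    }))
  f <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, f)
  invisible(paths)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  mode %s, flank %d bp, cell types: %s\n", x$provenance$mode,
              x$provenance$flank, paste(x$provenance$cell_types, collapse = ", ")))
  cat(sprintf("  %d genes resolved (%d not present, %d ambiguous)\n",
              length(x$resolution$matched), length(x$resolution$not_present),
              length(x$resolution$ambiguous)))
  cat(sprintf("  %d distributions, %d tests, %d transition rows\n",
              length(x$distributions), length(x$tests), NROW(x$transitions)))
  invisible(x)
}
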
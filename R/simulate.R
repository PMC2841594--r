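#' Synthetic-bundle configuration
#'
#' Parameters of the generative model used to emulate mined genome-wide
#' histone-enrichment, expression and methylation data. Defaults echo the
#' scale of the mouse analyses this package targets: 17,761 annotated genes of
#' which 54 are imprinted, roughly half of those carrying a promoter DMR
#' (mostly germline), the 25-unit microarray repression threshold, and
#' conditional mark probabilities shaped like the observed stratified
#' distributions. See the methods vignette for the full generative story.
#'
#' @param n_genes total gene count.
#' @param n_imprinted imprinted subset size.
#' @param dmr_split probabilities over (germline, somatic, none) promoter-DMR
#'   classes for imprinted genes; must sum to 1. Class sizes are fixed at
#'   `round(p * n_imprinted)` so conditional groups have deterministic sizes.
#' @param n_icr_intergenic number of intergenic ICR regions.
#' @param n_other_regions number of unannotated control regions.
#' @param p_signature_icr probability an ICR region carries the
#'   H3K4me3/H3K9me3/H4K20me3 tri-mark.
#' @param p_k9k20_given_germline_dmr,p_k9k20_given_no_dmr probability an
#'   imprinted gene's TSS carries the H3K9me3+H4K20me3 pair (with H3K4me3,
#'   ESC only), conditional on promoter-DMR class ("no" covers somatic and
#'   absent DMRs).
#' @param p_expressed_dmr,p_expressed_no_dmr,p_expressed_background
#'   expression probabilities for imprinted genes with / without a promoter
#'   DMR and for non-imprinted genes.
#' @param p_bivalent_given_repressed,p_bivalent_given_expressed named per-cell
#'   vectors: probability of H3K4me3+H3K27me3 co-enrichment conditional on
#'   expression status (imprinted genes not already resolved from an ESC
#'   bivalent state).
#' @param p_k4_given_expressed,p_k4_given_repressed,p_k27_given_expressed,
#'   p_k27_given_repressed probabilities of the exclusive solo states
#'   `K4_only` / `K27_only` given the gene is not bivalent; their per-status
#'   sum must not exceed 1 (the remainder is `neither`).
#' @param p_resolution named probabilities over
#'   (resolved_to_K4, resolved_to_K27, resolved_to_none, retained_bivalent)
#'   governing the differentiated-cell state of genes bivalent in ESC.
#' @param background_rates named per-mark enrichment rates for non-imprinted
#'   genes.
#' @param p_method_discordance per-gene probability that the HMM call set
#'   (ESC) disagrees with the WI call set for a mark.
#' @param missingness named rates at which genes are absent from the
#'   annotation, expression and DMR layers.
#' @param cell_types cell-type labels; the first is the pluripotent reference.
#' @param peak_width,jitter enrichment-peak geometry (bp).
#' @param tss_spacing,n_chrom gene layout.
#' @param expression_threshold microarray repression threshold.
#' @param flank TSS flank the bundle is designed for.
#' @param seed random seed (integer).
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_genes = 17761,
    n_imprinted = 54,
    dmr_split = c(germline = 18 / 54, somatic = 8 / 54, none = 28 / 54),
    n_icr_intergenic = 4,
    n_other_regions = 5,
    p_signature_icr = 1.0,
    p_k9k20_given_germline_dmr = 0.67,
    p_k9k20_given_no_dmr = 0,
    p_expressed_dmr = 0.71,
    p_expressed_no_dmr = 0.48,
    p_expressed_background = 0.6,
    p_bivalent_given_repressed = c(ESC = 0.53, NPC = 0.18, MEF = 0.33),
    p_bivalent_given_expressed = c(ESC = 0.25, NPC = 0.0, MEF = 0.20),
    p_k4_given_expressed = 0.85,
    p_k4_given_repressed = 0.33,
    p_k27_given_expressed = 0.05,
    p_k27_given_repressed = 0.35,
    p_resolution = c(resolved_to_K4 = 0.2, resolved_to_K27 = 0.3,
                     resolved_to_none = 0.2, retained_bivalent = 0.3),
    background_rates = c(H3K4me3 = 0.6, H3K27me3 = 0.25,
                         H3K9me3 = 0.002, H4K20me3 = 0.01),
    p_method_discordance = 0.019,
    missingness = c(annotation = 0.02, expression = 0.05, dmr = 0.11),
    cell_types = c("ESC", "NPC", "MEF"),
    peak_width = 2000,
    jitter = 400,
    tss_spacing = 20000,
    n_chrom = 19,
    expression_threshold = 25,
    flank = 1000,
    seed = 20100115) {
  cfg <- as.list(environment())
  probs <- c(cfg$p_signature_icr, cfg$p_k9k20_given_germline_dmr,
             cfg$p_k9k20_given_no_dmr, cfg$p_expressed_dmr,
             cfg$p_expressed_no_dmr, cfg$p_expressed_background,
             cfg$p_bivalent_given_repressed, cfg$p_bivalent_given_expressed,
             cfg$p_k4_given_expressed, cfg$p_k4_given_repressed,
             cfg$p_k27_given_expressed, cfg$p_k27_given_repressed,
             cfg$p_resolution, cfg$background_rates, cfg$p_method_discordance,
             cfg$missingness)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (abs(sum(cfg$dmr_split) - 1) > 1e-8) stop("dmr_split must sum to 1")
  if (cfg$p_k4_given_expressed + cfg$p_k27_given_expressed > 1 ||
      cfg$p_k4_given_repressed + cfg$p_k27_given_repressed > 1) {
    stop("solo-state probabilities p_k4 + p_k27 must not exceed 1 per status")
  }
  if (abs(sum(cfg$p_resolution) - 1) > 1e-8) stop("p_resolution must sum to 1")
  if (cfg$n_imprinted > cfg$n_genes) stop("n_imprinted exceeds n_genes")
  stopifnot(length(cfg$cell_types) >= 1,
            all(cfg$cell_types %in% names(cfg$p_bivalent_given_repressed)),
            all(cfg$cell_types %in% names(cfg$p_bivalent_given_expressed)),
            cfg$jitter < cfg$flank, cfg$peak_width >= 2 * cfg$flank,
            cfg$tss_spacing > 2 * (cfg$flank + cfg$peak_width))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "synthetic_config")
}

rbern <- function(n, p) stats::runif(n) < p

#' Generate a complete synthetic input bundle
#'
#' Realizes the generative model of [synthetic_config()] into the on-disk
#' input formats the readers expect (gene annotation TSV, per-cell-type
#' expression TSVs, DMR table, region list, BED call sets per
#' mark/cell-type/method, and a query gene list), together with the retained
#' ground truth. Generation is deterministic given `(config, seed)`: the same
#' configuration always yields byte-identical files.
#'
#' Model sketch: imprinted genes get a promoter-DMR class; the
#' H3K9me3+H4K20me3 pair (with H3K4me3) is drawn conditional on that class
#' and realized in the pluripotent cell type only; H3K4me3/H3K27me3 states
#' are drawn conditional on expression status, with differentiated-cell
#' states of ESC-bivalent genes drawn from the resolution distribution; ICR
#' regions are separate intervals, placed outside every TSS flank, carrying
#' the tri-mark with probability `p_signature_icr`; the one germline DMR that
#' does not act as an ICR never carries it. True mark states are realized as
#' enrichment peaks guaranteed to overlap the TSS window (|jitter| < flank),
#' so the pipeline can in principle recover every latent state exactly.
#'
#' @param config a `synthetic_config`.
#' @param dir output directory (created if needed).
#' @return List with `dir`, `paths` (named list of emitted files), `truth`
#'   (latent assignments: `genes`, `states`, `regions`, `discordant`) and
#'   `config`.
#' @export
generate_bundle <- function(config, dir = tempfile("bundle")) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "callsets"), showWarnings = FALSE)
  set.seed(cfg$seed)

  n <- cfg$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))
  symbol <- sprintf("Sym%05d", seq_len(n))
  chrom <- paste0("chr", ((seq_len(n) - 1L) %% cfg$n_chrom) + 1L)
  tss <- 10000L + ((seq_len(n) - 1L) %/% cfg$n_chrom) * as.integer(cfg$tss_spacing)
  strand <- ifelse(seq_len(n) %% 2L == 0L, "-", "+")

  imp_idx <- sort(sample.int(n, cfg$n_imprinted))
  imprinted <- seq_len(n) %in% imp_idx

  # promoter-DMR classes with deterministic sizes
  n_germ <- round(cfg$dmr_split[["germline"]] * cfg$n_imprinted)
  n_som <- round(cfg$dmr_split[["somatic"]] * cfg$n_imprinted)
  n_som <- min(n_som, cfg$n_imprinted - n_germ)
  dmr_class <- rep(NA_character_, n)
  cls <- sample(c(rep("germline", n_germ), rep("somatic", n_som),
                  rep("none", cfg$n_imprinted - n_germ - n_som)))
  dmr_class[imp_idx] <- cls

  # all germline promoter DMRs are confirmed ICRs except one
  icr <- rep(FALSE, n)
  non_icr_flag <- rep(FALSE, n)
  germ_idx <- which(!is.na(dmr_class) & dmr_class == "germline")
  if (length(germ_idx) >= 2L) {
    odd_one_out <- germ_idx[length(germ_idx)]
    icr[setdiff(germ_idx, odd_one_out)] <- TRUE
    non_icr_flag[odd_one_out] <- TRUE
  } else if (length(germ_idx) == 1L) {
    icr[germ_idx] <- TRUE
  }

  # gene-level repressive pair (realized in the pluripotent cell type only)
  p_pair <- ifelse(is.na(dmr_class), 0,
                   ifelse(dmr_class == "germline",
                          cfg$p_k9k20_given_germline_dmr,
                          cfg$p_k9k20_given_no_dmr))
  k9k20 <- rbern(n, p_pair)

  truth_genes <- data.frame(
    gene_id = gene_id, imprinted = imprinted, promoter_dmr = dmr_class,
    icr = icr, non_icr_germline_flag = non_icr_flag, k9k20 = k9k20,
    stringsAsFactors = FALSE)

  # per-gene per-cell-type latent states
  cts <- cfg$cell_types
  ref_ct <- cts[1L]
  p_expr <- ifelse(!imprinted, cfg$p_expressed_background,
                   ifelse(dmr_class == "none",
                          cfg$p_expressed_no_dmr, cfg$p_expressed_dmr))
  states <- list()
  esc_biv <- rep(NA, n)
  res_class <- matrix(NA_character_, n, length(cts), dimnames = list(NULL, cts))
  for (ct in cts) {
    expressed <- rbern(n, p_expr)
    k4 <- k27 <- k9 <- k20 <- rep(FALSE, n)
    bg <- !imprinted
    k4[bg] <- rbern(sum(bg), cfg$background_rates[["H3K4me3"]])
    k27[bg] <- rbern(sum(bg), cfg$background_rates[["H3K27me3"]])
    k9[bg] <- rbern(sum(bg), cfg$background_rates[["H3K9me3"]])
    k20[bg] <- rbern(sum(bg), cfg$background_rates[["H4K20me3"]])
    im <- which(imprinted)
    p_biv <- ifelse(expressed[im],
                    cfg$p_bivalent_given_expressed[[ct]],
                    cfg$p_bivalent_given_repressed[[ct]])
    biv <- rbern(length(im), p_biv)
    # non-bivalent genes take exactly one of K4_only / K27_only / neither, so
    # K4&K27 co-occurrence happens only through the bivalency draw
    p_k4 <- ifelse(expressed[im], cfg$p_k4_given_expressed, cfg$p_k4_given_repressed)
    p_k27 <- ifelse(expressed[im], cfg$p_k27_given_expressed, cfg$p_k27_given_repressed)
    u <- stats::runif(length(im))
    solo_k4 <- u < p_k4
    solo_k27 <- !solo_k4 & u < p_k4 + p_k27
    k4[im] <- ifelse(biv, TRUE, solo_k4)
    k27[im] <- ifelse(biv, TRUE, solo_k27)
    if (ct == ref_ct) {
      esc_biv <- rep(FALSE, n)
      esc_biv[im] <- biv
      # repressive pair overlays the pluripotent state; requires H3K4me3
      k9[im] <- k9k20[im]
      k20[im] <- k9k20[im]
      k4[im] <- k4[im] | k9k20[im]
    } else {
      # ESC-bivalent genes follow the resolution distribution instead
      res_i <- which(imprinted & esc_biv)
      if (length(res_i)) {
        draw <- sample(names(cfg$p_resolution), length(res_i),
                       replace = TRUE, prob = cfg$p_resolution)
        res_class[res_i, ct] <- draw
        k4[res_i] <- draw %in% c("resolved_to_K4", "retained_bivalent")
        k27[res_i] <- draw %in% c("resolved_to_K27", "retained_bivalent")
      }
    }
    states[[ct]] <- data.frame(
      gene_id = gene_id, cell_type = ct, expressed = expressed,
      H3K4me3 = k4, H3K27me3 = k27, H3K9me3 = k9, H4K20me3 = k20,
      esc_bivalent = esc_biv, resolution_class = res_class[, ct],
      stringsAsFactors = FALSE)
  }
  truth_states <- do.call(rbind, states)
  rownames(truth_states) <- NULL

  # ICR / control regions: placed outside every TSS flank
  regions <- data.frame(region_id = character(), class = character(),
                        chrom = character(), start = integer(), end = integer(),
                        stringsAsFactors = FALSE)
  prom_icr <- which(icr)
  if (length(prom_icr)) {
    regions <- rbind(regions, data.frame(
      region_id = paste0("ICRp_", gene_id[prom_icr]), class = "promoter ICR",
      chrom = chrom[prom_icr], start = tss[prom_icr] + 3000L,
      end = tss[prom_icr] + 5500L, stringsAsFactors = FALSE))
  }
  if (cfg$n_icr_intergenic > 0) {
    k <- seq_len(cfg$n_icr_intergenic)
    base <- 10000L + ((n - 1L) %/% cfg$n_chrom + 2L) * as.integer(cfg$tss_spacing)
    regions <- rbind(regions, data.frame(
      region_id = sprintf("ICRi_%02d", k), class = "intergenic ICR",
      chrom = paste0("chr", ((k - 1L) %% cfg$n_chrom) + 1L),
      start = base + k * 50000L, end = base + k * 50000L + 2500L,
      stringsAsFactors = FALSE))
  }
  flagged <- which(non_icr_flag)
  if (length(flagged)) {
    regions <- rbind(regions, data.frame(
      region_id = paste0("gDMR_", gene_id[flagged]), class = "non-ICR germline DMR",
      chrom = chrom[flagged], start = tss[flagged] + 3000L,
      end = tss[flagged] + 5500L, stringsAsFactors = FALSE))
  }
  if (cfg$n_other_regions > 0) {
    k <- seq_len(cfg$n_other_regions)
    base <- 10000L + ((n - 1L) %/% cfg$n_chrom + 2L) * as.integer(cfg$tss_spacing)
    regions <- rbind(regions, data.frame(
      region_id = sprintf("CTRL_%02d", k), class = "other",
      chrom = paste0("chr", ((k - 1L) %% cfg$n_chrom) + 1L),
      start = base + 1000000L + k * 50000L, end = base + 1000000L + k * 50000L + 2500L,
      stringsAsFactors = FALSE))
  }
  is_icr_region <- regions$class %in% c("promoter ICR", "intergenic ICR")
  regions$signature <- FALSE
  regions$signature[is_icr_region] <- rbern(sum(is_icr_region), cfg$p_signature_icr)
  # the germline DMR that is not an ICR gets activating mark only, never the
  # repressive pair; unannotated control regions carry nothing
  truth_regions <- regions

  # realize mark states as enrichment peaks around each TSS
  half <- as.integer(cfg$peak_width) %/% 2L
  peaks_for <- function(idx) {
    if (!length(idx)) {
      return(data.frame(chrom = character(), start = integer(), end = integer()))
    }
    centre <- tss[idx] + as.integer(round(stats::runif(length(idx),
                                                       -cfg$jitter, cfg$jitter)))
    start <- pmax(centre - half, 0L)
    data.frame(chrom = chrom[idx], start = start,
               end = start + as.integer(cfg$peak_width),
               stringsAsFactors = FALSE)
  }
  marks <- c("H3K4me3", "H3K27me3", "H3K9me3", "H4K20me3")
  mark_method <- c(H3K4me3 = "WI", H3K27me3 = "WI", H3K9me3 = "WI",
                   H4K20me3 = "HMM")
  region_peaks <- function(mark) {
    sel <- if (mark %in% SIGNATURE_MARKS) {
      regions$signature | (regions$class == "non-ICR germline DMR" & mark == "H3K4me3")
    } else rep(FALSE, nrow(regions))
    data.frame(chrom = regions$chrom[sel], start = regions$start[sel],
               end = regions$end[sel], stringsAsFactors = FALSE)
  }
  write_bed <- function(df, path) {
    df <- df[order(df$chrom, df$start, method = "radix"), , drop = FALSE]
    writeLines(sprintf("%s\t%d\t%d", df$chrom, df$start, df$end), path)
  }
  paths <- list(callsets = list())
  for (ct in cts) {
    st <- states[[ct]]
    for (mk in marks) {
      df <- peaks_for(which(st[[mk]]))
      if (ct == ref_ct) df <- rbind(df, region_peaks(mk))
      f <- file.path(dir, "callsets", sprintf("%s_%s_%s.bed", mk, ct, mark_method[[mk]]))
      write_bed(df, f)
      paths$callsets[[sprintf("%s_%s_%s", mk, ct, mark_method[[mk]])]] <- f
    }
  }
  # second calling method in the pluripotent cell type, with per-gene flips
  discordant <- list()
  for (mk in c("H3K4me3", "H3K27me3", "H3K9me3")) {
    st <- states[[ref_ct]]
    flip <- rbern(n, cfg$p_method_discordance)
    calls <- xor(st[[mk]], flip)
    discordant[[mk]] <- gene_id[flip]
    df <- rbind(peaks_for(which(calls)), region_peaks(mk))
    f <- file.path(dir, "callsets", sprintf("%s_%s_HMM.bed", mk, ref_ct))
    write_bed(df, f)
    paths$callsets[[sprintf("%s_%s_HMM", mk, ref_ct)]] <- f
  }

  # annotation layer (with per-layer missingness; queries keep dropped genes)
  drop_ann <- imprinted & rbern(n, cfg$missingness[["annotation"]])
  extra_alias <- ifelse(imprinted, paste0("|Imp_", symbol), "")
  ann <- data.frame(gene_id = gene_id,
                    aliases = paste0(symbol, extra_alias),
                    chrom = chrom, tss = tss, strand = strand,
                    species = "mouse", stringsAsFactors = FALSE)
  ann <- ann[!drop_ann, , drop = FALSE]
  paths$genes <- file.path(dir, "genes.tsv")
  utils::write.table(ann, paths$genes, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # imprinted-gene query list: mixture of ids and aliases
  use_alias <- rbern(cfg$n_imprinted, 0.5)
  query <- ifelse(use_alias, symbol[imp_idx], gene_id[imp_idx])
  paths$query <- file.path(dir, "imprinted_genes.txt")
  writeLines(query, paths$query)

  # expression layer: intensities consistent with the latent status
  drop_expr <- rbern(n, cfg$missingness[["expression"]])
  paths$expression <- list()
  for (ct in cts) {
    expressed <- states[[ct]]$expressed
    lo <- stats::runif(n, 0, cfg$expression_threshold - 0.1)
    hi <- stats::runif(n, cfg$expression_threshold, 40 * cfg$expression_threshold)
    intensity <- round(ifelse(expressed, hi, lo), 1)
    df <- data.frame(gene_id = gene_id, intensity = sprintf("%.1f", intensity),
                     stringsAsFactors = FALSE)[!drop_expr, , drop = FALSE]
    f <- file.path(dir, sprintf("expression_%s.tsv", ct))
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$expression[[ct]] <- f
  }

  # DMR / imprinting annotation layer (imprinted genes only)
  drop_dmr <- rbern(cfg$n_imprinted, cfg$missingness[["dmr"]])
  dmr <- data.frame(
    gene_id = gene_id[imp_idx],
    promoter_dmr = dmr_class[imp_idx],
    icr = icr[imp_idx],
    icr_location = ifelse(icr[imp_idx], "promoter", "n/a"),
    non_icr_germline_flag = non_icr_flag[imp_idx],
    stringsAsFactors = FALSE)[!drop_dmr, , drop = FALSE]
  paths$dmr <- file.path(dir, "dmr.tsv")
  utils::write.table(dmr, paths$dmr, sep = "\t", quote = FALSE, row.names = FALSE)

  paths$regions <- file.path(dir, "regions.tsv")
  utils::write.table(regions[, c("region_id", "class", "chrom", "start", "end")],
                     paths$regions, sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- list(genes = truth_genes, states = truth_states,
                regions = truth_regions, discordant = discordant,
                dropped = list(annotation = gene_id[drop_ann],
                               expression = gene_id[drop_expr],
                               dmr = gene_id[imp_idx][drop_dmr]),
                seed = cfg$seed)
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, paths$truth, dataframe = "columns", digits = NA)
  list(dir = dir, paths = paths, truth = truth, config = cfg)
}

#' Reconstruct the paths list for an on-disk bundle
#'
#' Rebuilds the `paths` structure [read_bundle()] expects from a directory
#' previously written by [generate_bundle()] (or laid out the same way by
#' hand). Cell types are ordered alphabetically unless given; the first is
#' treated as the pluripotent reference by [run_pipeline()].
#'
#' @param dir bundle directory.
#' @param cell_types optional explicit cell-type ordering.
#' @return Named list of file paths.
#' @export
bundle_paths <- function(dir, cell_types = NULL) {
  cs_files <- sort(list.files(file.path(dir, "callsets"), pattern = "\\.bed$",
                              full.names = TRUE))
  if (!length(cs_files)) stop("no call sets under ", file.path(dir, "callsets"))
  cs <- as.list(cs_files)
  names(cs) <- sub("\\.bed$", "", basename(cs_files))
  expr_files <- sort(list.files(dir, pattern = "^expression_.*\\.tsv$",
                                full.names = TRUE))
  cts <- sub("^expression_(.*)\\.tsv$", "\\1", basename(expr_files))
  if (!is.null(cell_types)) {
    ord <- match(cell_types, cts)
    expr_files <- expr_files[ord]; cts <- cts[ord]
    cs_ct <- vapply(strsplit(names(cs), "_", fixed = TRUE), `[[`, "", 2L)
    cs <- cs[order(match(cs_ct, cell_types))]
  }
  expr <- as.list(expr_files)
  names(expr) <- cts
  list(genes = file.path(dir, "genes.tsv"),
       query = file.path(dir, "imprinted_genes.txt"),
       callsets = cs, expression = expr,
       dmr = file.path(dir, "dmr.tsv"),
       regions = file.path(dir, "regions.tsv"))
}

#' Read a synthetic (or equivalently formatted real) bundle
#'
#' Parses every emitted layer back through the package readers.
#'
#' @param bundle result of [generate_bundle()], or a list with the same
#'   `paths` structure pointing at real data.
#' @return List with `genes` (`gene_table`), `query` (character),
#'   `callsets` (cell type -> list of `callset`, WI/primary method),
#'   `hmm_callsets` (pluripotent second-method call sets), `expression`
#'   (long data frame with `status`), `dmr`, `regions`.
#' @export
read_bundle <- function(bundle) {
  paths <- bundle$paths
  genes <- read_gene_annotation(paths$genes)
  query <- readLines(paths$query)
  cs_names <- names(paths$callsets)
  parse_one <- function(nm) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    parse_enrichment_intervals(paths$callsets[[nm]], mark = parts[1],
                               cell_type = parts[2], method = parts[3])
  }
  all_cs <- lapply(cs_names, parse_one)
  names(all_cs) <- cs_names
  cts <- unique(vapply(all_cs, `[[`, "", "cell_type"))
  primary <- lapply(cts, function(ct) {
    keep <- vapply(all_cs, function(cs) {
      cs$cell_type == ct &&
        (cs$method == "WI" || (cs$mark == "H4K20me3" && cs$method == "HMM"))
    }, NA)
    unname(all_cs[keep])
  })
  names(primary) <- cts
  hmm <- all_cs[vapply(all_cs, function(cs) {
    cs$method == "HMM" && cs$mark != "H4K20me3"
  }, NA)]
  expr <- do.call(rbind, lapply(names(paths$expression), function(ct) {
    df <- utils::read.delim(paths$expression[[ct]], colClasses = "character")
    data.frame(gene_id = df$gene_id, cell_type = ct,
               intensity = as.numeric(df$intensity),
               status = call_expression_from_intensity(as.numeric(df$intensity)),
               stringsAsFactors = FALSE)
  }))
  dmr <- utils::read.delim(paths$dmr, colClasses = c(
    gene_id = "character", promoter_dmr = "character", icr = "logical",
    icr_location = "character", non_icr_germline_flag = "logical"))
  regions <- utils::read.delim(paths$regions, colClasses = c(
    region_id = "character", class = "character", chrom = "character",
    start = "integer", end = "integer"))
  list(genes = genes, query = query, callsets = primary, hmm_callsets = hmm,
       expression = expr, dmr = dmr, regions = regions)
}

se_binom <- function(p, m) sqrt(p * (1 - p) / m)

#' Recover generator parameters from an analysed bundle
#'
#' Compares empirical conditional frequencies computed from the pipeline's
#' integrated state table against the configured generating probabilities,
#' with binomial standard errors. Conditioning groups use the retained truth
#' (latent DMR class, latent ESC bivalency) so each estimate targets exactly
#' one configured parameter.
#'
#' @param state_table `gene_state_table` from [build_state_table()] run on the
#'   bundle.
#' @param truth,config from [generate_bundle()].
#' @param scan optional [scan_icr_signature()] result for region-level
#'   parameters.
#' @param concordance optional [method_concordance()] report (or list of them)
#'   for the method-discordance rate.
#' @return Data frame with one row per recoverable parameter: `parameter`,
#'   `configured`, `estimate`, `n`, `se`, `abs_error`, `within_3se`.
#' @export
recover_parameters <- function(state_table, truth, config, scan = NULL,
                               concordance = NULL) {
  if (!all(state_table$gene_id %in% truth$genes$gene_id)) {
    stop("state table contains genes unknown to the truth record (seed mismatch?)")
  }
  cfg <- config
  ref_ct <- cfg$cell_types[1L]
  df <- as.data.frame(state_table)
  tg <- truth$genes
  df$t_dmr <- tg$promoter_dmr[match(df$gene_id, tg$gene_id)]
  df$t_imprinted <- tg$imprinted[match(df$gene_id, tg$gene_id)]
  df$t_k9k20 <- tg$k9k20[match(df$gene_id, tg$gene_id)]
  ts <- truth$states
  key <- paste(df$gene_id, df$cell_type)
  tkey <- paste(ts$gene_id, ts$cell_type)
  df$t_esc_biv <- ts$esc_bivalent[match(key, tkey)]

  rows <- list()
  add <- function(parameter, configured, x) {
    m <- length(x)
    est <- if (m) mean(x) else NA_real_
    se <- se_binom(configured, max(m, 1L))
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = parameter, configured = configured, estimate = est, n = m,
      se = se, abs_error = abs(est - configured),
      within_3se = isTRUE(abs(est - configured) <= 3 * se + 1e-12),
      stringsAsFactors = FALSE)
  }

  esc <- df[df$cell_type == ref_ct, , drop = FALSE]
  germ <- esc[!is.na(esc$t_dmr) & esc$t_dmr == "germline", ]
  nong <- esc[!is.na(esc$t_dmr) & esc$t_dmr != "germline", ]
  add("p_k9k20_given_germline_dmr", cfg$p_k9k20_given_germline_dmr,
      germ$H3K9me3 & germ$H4K20me3)
  add("p_k9k20_given_no_dmr", cfg$p_k9k20_given_no_dmr,
      nong$H3K9me3 & nong$H4K20me3)

  known_expr <- df$expression != "unknown"
  impr <- df[known_expr & df$t_imprinted, , drop = FALSE]
  withd <- impr[impr$cell_type == ref_ct & !is.na(impr$t_dmr) & impr$t_dmr != "none", ]
  nod <- impr[impr$cell_type == ref_ct & !is.na(impr$t_dmr) & impr$t_dmr == "none", ]
  add("p_expressed_dmr", cfg$p_expressed_dmr, withd$expression == "expressed")
  add("p_expressed_no_dmr", cfg$p_expressed_no_dmr, nod$expression == "expressed")

  for (ct in cfg$cell_types) {
    sub <- impr[impr$cell_type == ct & !impr$t_k9k20, , drop = FALSE]
    if (ct != ref_ct) sub <- sub[!sub$t_esc_biv, , drop = FALSE]
    for (status in c("repressed", "expressed")) {
      p <- if (status == "repressed") cfg$p_bivalent_given_repressed[[ct]]
           else cfg$p_bivalent_given_expressed[[ct]]
      g <- sub[sub$expression == status, , drop = FALSE]
      add(sprintf("p_bivalent_given_%s[%s]", status, ct), p,
          g$H3K4me3 & g$H3K27me3)
    }
  }

  # resolution distribution, pooled over differentiated cell types
  diffs <- setdiff(cfg$cell_types, ref_ct)
  if (length(diffs)) {
    resolved <- df[df$cell_type %in% diffs & df$t_imprinted & df$t_esc_biv, ]
    if (nrow(resolved)) {
      cls <- mapply(function(k4, k27) {
        s <- bivalency_state(k4, k27)
        switch(s, bivalent = "retained_bivalent", K4_only = "resolved_to_K4",
               K27_only = "resolved_to_K27", neither = "resolved_to_none")
      }, resolved$H3K4me3, resolved$H3K27me3)
      for (nm in names(cfg$p_resolution)) {
        add(sprintf("p_resolution[%s]", nm), cfg$p_resolution[[nm]], cls == nm)
      }
    }
  }

  if (!is.null(scan)) {
    icr <- scan$reports[scan$reports$class %in% c("promoter ICR", "intergenic ICR"), ]
    add("p_signature_icr", cfg$p_signature_icr, icr$signature)
  }
  if (!is.null(concordance)) {
    if (inherits(concordance, "concordance_report")) concordance <- list(concordance)
    disc <- unlist(lapply(concordance, function(cr) {
      c(rep(TRUE, cr$n_discordant), rep(FALSE, cr$n - cr$n_discordant))
    }))
    add("p_method_discordance", cfg$p_method_discordance, disc)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
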
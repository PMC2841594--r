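#' TSS window for a gene
#'
#' Builds the symmetric assessment window around a gene's transcription start
#' site: `[tss - flank, tss + flank)` in 0-based half-open coordinates,
#' clamped at coordinate 0. The annotation table stores the strand-aware TSS
#' directly, so the window itself is strand-symmetric. `flank = 0` degenerates
#' to the 1-bp window `[tss, tss + 1)` covering the TSS base itself.
#'
#' @param gene one-row `gene_table` slice (or list with `gene_id`, `chrom`,
#'   `tss`).
#' @param flank non-negative flank in bp on each side (default 1000).
#' @return List with `gene_id`, `chrom`, `start`, `end` (0-based half-open).
#' @export
tss_window <- function(gene, flank = 1000) {
  stopifnot(flank >= 0)
  tss <- as.integer(gene$tss)
  if (flank == 0) {
    start <- tss; end <- tss + 1L
  } else {
    start <- max(tss - as.integer(flank), 0L)
    end <- tss + as.integer(flank)
  }
  list(gene_id = gene$gene_id, chrom = as.character(gene$chrom),
       start = start, end = end)
}

window_gr <- function(w) {
  GenomicRanges::GRanges(w$chrom, IRanges::IRanges(w$start + 1L, w$end))
}

#' Is a window enriched in a call set?
#'
#' `TRUE` iff some called interval overlaps the window by at least 1 bp under
#' half-open semantics. A chromosome absent from the call set simply yields
#' `FALSE`.
#'
#' @param window list with `chrom`, `start`, `end` (0-based half-open), as
#'   returned by [tss_window()], or any interval in that form.
#' @param callset a `callset`.
#' @return Logical scalar.
#' @export
is_enriched_at <- function(window, callset) {
  stopifnot(inherits(callset, "callset"))
  if (!length(callset$gr)) return(FALSE)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(window_gr(window), callset$gr))
  length(hits) > 0L
}

#' Per-gene mark enrichment vector
#'
#' Evaluates each supplied call set (one per mark, all from one cell type)
#' against the gene's TSS window.
#'
#' @param gene one-row `gene_table` slice.
#' @param callsets list of `callset` objects sharing one `cell_type`.
#' @param flank TSS flank in bp.
#' @return Named logical vector (one entry per mark) with attributes
#'   `gene_id`, `cell_type`, `method`.
#' @export
mark_vector <- function(gene, callsets, flank = 1000) {
  ct <- unique(vapply(callsets, `[[`, "", "cell_type"))
  if (length(ct) != 1L) {
    stop("call sets span multiple cell types: ", paste(ct, collapse = ", "))
  }
  w <- tss_window(gene, flank)
  calls <- vapply(callsets, function(cs) is_enriched_at(w, cs), NA)
  names(calls) <- vapply(callsets, `[[`, "", "mark")
  if (anyDuplicated(names(calls))) stop("duplicate mark among call sets")
  structure(calls, gene_id = gene$gene_id, cell_type = ct,
            method = paste(unique(vapply(callsets, `[[`, "", "method")),
                           collapse = "+"))
}

#' Mark-enrichment matrix for many genes
#'
#' Vectorized overlap of all genes' TSS windows against each mark's call set
#' (one [GenomicRanges::findOverlaps] per mark).
#'
#' @param genes `gene_table` (rows = genes to assess).
#' @param callsets list of `callset` objects, one per mark, one cell type.
#' @param flank TSS flank in bp.
#' @return Logical matrix, rows = `genes$gene_id`, columns = marks; attribute
#'   `cell_type`.
#' @export
mark_matrix <- function(genes, callsets, flank = 1000) {
  ct <- unique(vapply(callsets, `[[`, "", "cell_type"))
  if (length(ct) != 1L) {
    stop("call sets span multiple cell types: ", paste(ct, collapse = ", "))
  }
  marks <- vapply(callsets, `[[`, "", "mark")
  if (anyDuplicated(marks)) stop("duplicate mark among call sets")
  tss <- as.integer(genes$tss)
  fl <- as.integer(flank)
  if (fl == 0) {
    s0 <- tss; e0 <- tss + 1L
  } else {
    s0 <- pmax(tss - fl, 0L); e0 <- tss + fl
  }
  wins <- GenomicRanges::GRanges(as.character(genes$chrom),
                                 IRanges::IRanges(s0 + 1L, e0))
  m <- matrix(FALSE, nrow = nrow(genes), ncol = length(marks),
              dimnames = list(genes$gene_id, marks))
  for (j in seq_along(callsets)) {
    gr <- callsets[[j]]$gr
    if (!length(gr)) next
    hits <- suppressWarnings(GenomicRanges::findOverlaps(wins, gr))
    m[unique(S4Vectors::queryHits(hits)), j] <- TRUE
  }
  structure(m, cell_type = ct)
}
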
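EXPR_LEVELS <- c("expressed", "repressed", "unknown")

#' Expression status from microarray signal intensity
#'
#' A gene is called repressed when its signal intensity is strictly below the
#' threshold (default 25), expressed when at or above it, and unknown when the
#' intensity is missing. Vectorized.
#'
#' @param intensity numeric vector of signal intensities (`NA` = missing).
#' @param threshold repression threshold (default 25).
#' @return Character vector in `{expressed, repressed, unknown}`.
#' @export
call_expression_from_intensity <- function(intensity, threshold = 25) {
  stopifnot(threshold > 0)
  if (any(intensity < 0, na.rm = TRUE)) stop("negative signal intensity")
  out <- ifelse(is.na(intensity), "unknown",
                ifelse(intensity < threshold, "repressed", "expressed"))
  as.character(out)
}

#' Consolidate binary expression calls from multiple assays
#'
#' Pooled calls from different platforms (e.g. microarray and massively
#' parallel signature sequencing) are accepted only when consistent: if all
#' assays agree the shared status is returned, any disagreement yields
#' `"unknown"`.
#'
#' @param calls character vector of per-assay calls, each `"expressed"` or
#'   `"repressed"` (entries of `"unknown"`/`NA` are ignored as non-evidence).
#' @return A single status string.
#' @export
consolidate_expression_calls <- function(calls) {
  if (!length(calls)) stop("no expression calls to consolidate")
  calls <- calls[!is.na(calls) & calls != "unknown"]
  if (!length(calls)) return("unknown")
  bad <- setdiff(calls, c("expressed", "repressed"))
  if (length(bad)) stop("unrecognised call(s): ", paste(bad, collapse = ", "))
  u <- unique(calls)
  if (length(u) == 1L) u else "unknown"
}

#' Validate a DMR/imprinting annotation table
#'
#' @param df data frame with columns `gene_id`, `promoter_dmr` (`none`,
#'   `somatic`, `germline`), `icr` (logical: region experimentally confirmed
#'   as an imprinting control region), `icr_location` (`promoter`,
#'   `intergenic`, `n/a`) and `non_icr_germline_flag` (logical: germline DMR
#'   known not to act as an ICR).
#' @return The validated data frame.
#' @export
dmr_annotation <- function(df) {
  need <- c("gene_id", "promoter_dmr", "icr", "icr_location", "non_icr_germline_flag")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("DMR table missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in DMR table")
  if (any(!df$promoter_dmr %in% c("none", "somatic", "germline"))) {
    stop("promoter_dmr must be one of none/somatic/germline")
  }
  df$icr <- as.logical(df$icr)
  df$non_icr_germline_flag <- as.logical(df$non_icr_germline_flag)
  if (any(!df$icr_location %in% c("promoter", "intergenic", "n/a"))) {
    stop("icr_location must be promoter/intergenic/n/a")
  }
  bad <- df$icr & !(df$promoter_dmr == "germline" | df$icr_location == "intergenic")
  if (any(bad)) {
    stop("ICR without germline promoter DMR or intergenic location: ",
         paste(df$gene_id[bad], collapse = ", "))
  }
  if (any(df$non_icr_germline_flag & df$icr)) {
    stop("non_icr_germline_flag set on a confirmed ICR")
  }
  df
}

#' Build the integrated per-gene state table
#'
#' Joins, per gene and cell type: the mark-enrichment vector (from TSS-window
#' overlap), the combinatorial profile label, the expression status and the
#' DMR/imprinting annotation. Genes missing from a layer get `unknown` (or
#' `NA` annotation) for that layer and are retained, never dropped silently;
#' the `exclusions` attribute records which genes lacked which layer.
#'
#' @param genes `gene_table` rows (the resolved gene set).
#' @param callsets_by_celltype named list (cell type -> list of `callset`).
#' @param expression data frame `gene_id`, `cell_type`, `status`; one row per
#'   gene per cell type.
#' @param dmr [dmr_annotation()] table (or `NULL`).
#' @param taxonomy `profile_taxonomy` used for the profile label.
#' @param flank TSS flank in bp.
#' @return A `gene_state_table` data frame keyed by (`gene_id`, `cell_type`)
#'   with one logical column per mark, plus `profile`, `expression`,
#'   `promoter_dmr`, `icr`, `icr_location`, `non_icr_germline_flag`,
#'   `imprinted`.
#' @export
build_state_table <- function(genes, callsets_by_celltype, expression = NULL,
                              dmr = NULL, taxonomy = NULL, flank = 1000) {
  stopifnot(is.list(callsets_by_celltype), length(callsets_by_celltype) >= 1,
            !is.null(names(callsets_by_celltype)))
  if (!is.null(expression)) {
    if (anyDuplicated(expression[, c("gene_id", "cell_type")])) {
      stop("duplicate (gene_id, cell_type) rows in expression input")
    }
  }
  if (!is.null(dmr)) dmr <- dmr_annotation(dmr)
  exclusions <- list()
  rows <- lapply(names(callsets_by_celltype), function(ct) {
    m <- mark_matrix(genes, callsets_by_celltype[[ct]], flank = flank)
    df <- data.frame(gene_id = rownames(m), cell_type = ct,
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(m))
    if (!is.null(taxonomy)) {
      df$profile <- classify_matrix(m, taxonomy)
    }
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$expression <- "unknown"
  if (!is.null(expression)) {
    key_out <- paste(out$gene_id, out$cell_type, sep = "\r")
    key_in <- paste(expression$gene_id, expression$cell_type, sep = "\r")
    idx <- match(key_out, key_in)
    out$expression[!is.na(idx)] <- expression$status[idx[!is.na(idx)]]
    miss <- unique(out$gene_id[is.na(idx)])
    if (length(miss)) exclusions$expression <- miss
  }
  if (!is.null(dmr)) {
    idx <- match(out$gene_id, dmr$gene_id)
    out$promoter_dmr <- dmr$promoter_dmr[idx]
    out$icr <- dmr$icr[idx]
    out$icr_location <- dmr$icr_location[idx]
    out$non_icr_germline_flag <- dmr$non_icr_germline_flag[idx]
    miss <- unique(out$gene_id[is.na(idx)])
    if (length(miss)) exclusions$dmr <- miss
  } else {
    out$promoter_dmr <- NA_character_
    out$icr <- NA
    out$icr_location <- NA_character_
    out$non_icr_germline_flag <- NA
  }
  out$imprinted <- if (!is.null(genes$imprinted)) {
    genes$imprinted[match(out$gene_id, genes$gene_id)]
  } else NA
  attr(out, "exclusions") <- exclusions
  attr(out, "marks") <- vapply(callsets_by_celltype[[1]], `[[`, "", "mark")
  class(out) <- c("gene_state_table", "data.frame")
  out
}

#' Stratify a state table
#'
#' Splits the rows of one cell type into named groups by a stratifier. Rows
#' with unknown/missing values for the stratifier are excluded from the groups
#' but returned separately, so every row is accounted for.
#'
#' @param table a `gene_state_table`.
#' @param by one of `"promoter_dmr"`, `"expression"`, `"imprint_status"`.
#' @param cell_type cell type to stratify (default: all rows).
#' @return List with `groups` (named list of data frames), `unknown` (data
#'   frame of excluded rows) and `by`.
#' @export
stratify <- function(table, by = c("promoter_dmr", "expression", "imprint_status"),
                     cell_type = NULL) {
  by <- match.arg(by)
  df <- as.data.frame(table)
  if (!is.null(cell_type)) df <- df[df$cell_type == cell_type, , drop = FALSE]
  val <- switch(by,
    promoter_dmr = ifelse(is.na(df$promoter_dmr), NA_character_,
                          ifelse(df$promoter_dmr == "none", "no_dmr", "dmr")),
    expression = ifelse(df$expression == "unknown", NA_character_, df$expression),
    imprint_status = ifelse(is.na(df$imprinted), NA_character_,
                            ifelse(df$imprinted, "imprinted", "not_imprinted")))
  known <- !is.na(val)
  groups <- split(df[known, , drop = FALSE], val[known])
  list(groups = groups, unknown = df[!known, , drop = FALSE], by = by)
}
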
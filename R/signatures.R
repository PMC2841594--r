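SIGNATURE_MARKS <- c("H3K4me3", "H3K9me3", "H4K20me3")

#' Tri-mark signature at one region
#'
#' Tests a region (evaluated as its own interval, not a TSS window — imprinting
#' control regions may be intergenic) for joint enrichment of H3K4me3, H3K9me3
#' and H4K20me3. The signature is the conjunction of the three per-mark
#' overlaps. H3K27me3 is deliberately not part of the signature (it is not
#' found at all known ICRs); pass `k27_callset` to annotate its presence.
#'
#' @param region list with `chrom`, `start`, `end` (0-based half-open) and
#'   optionally `region_id`, `class`.
#' @param callsets list of `callset` objects for exactly the three signature
#'   marks, one cell type.
#' @param k27_callset optional H3K27me3 `callset`; reported as an annotation
#'   column only.
#' @return A `tri_mark_report`: list with `region_id`, per-mark logicals
#'   (`marks`), `signature`, `region_class`, and `k27` (logical or `NA`).
#' @export
detect_tri_mark <- function(region, callsets, k27_callset = NULL) {
  marks <- vapply(callsets, `[[`, "", "mark")
  if (!setequal(marks, SIGNATURE_MARKS) || length(marks) != 3L) {
    stop("need exactly the three signature marks: ",
         paste(SIGNATURE_MARKS, collapse = ", "))
  }
  ct <- unique(vapply(callsets, `[[`, "", "cell_type"))
  if (length(ct) != 1L) stop("call sets span multiple cell types")
  calls <- vapply(callsets, function(cs) is_enriched_at(region, cs), NA)
  names(calls) <- marks
  calls <- calls[SIGNATURE_MARKS]
  structure(list(region_id = if (!is.null(region$region_id)) region$region_id else NA_character_,
                 marks = calls,
                 signature = all(calls),
                 region_class = if (!is.null(region$class)) region$class else "other",
                 k27 = if (is.null(k27_callset)) NA else is_enriched_at(region, k27_callset),
                 cell_type = ct),
            class = "tri_mark_report")
}

#' Scan a region list for the ICR tri-mark signature
#'
#' Applies [detect_tri_mark()] to every annotated region and summarises the
#' signature fraction per region class. Any non-ICR region carrying the
#' signature is flagged: the signature is only an ICR signature if it never
#' appears elsewhere.
#'
#' @param regions data frame with columns `region_id`, `chrom`, `start`,
#'   `end`, `class` (one of `"promoter ICR"`, `"intergenic ICR"`,
#'   `"non-ICR germline DMR"`, `"other"`).
#' @param callsets list of `callset` for the three signature marks.
#' @param k27_callset optional H3K27me3 annotation call set.
#' @return An `icr_scan`: list with `reports` (data frame, one row per region),
#'   `summary` (per-class n / n_signature / fraction) and
#'   `non_icr_with_signature` (region ids).
#' @export
scan_icr_signature <- function(regions, callsets, k27_callset = NULL) {
  if (NROW(regions) == 0L) stop("empty region list")
  reps <- lapply(seq_len(nrow(regions)), function(i) {
    detect_tri_mark(as.list(regions[i, , drop = FALSE]), callsets, k27_callset)
  })
  df <- data.frame(
    region_id = vapply(reps, `[[`, "", "region_id"),
    class = vapply(reps, `[[`, "", "region_class"),
    H3K4me3 = vapply(reps, function(r) r$marks[["H3K4me3"]], NA),
    H3K9me3 = vapply(reps, function(r) r$marks[["H3K9me3"]], NA),
    H4K20me3 = vapply(reps, function(r) r$marks[["H4K20me3"]], NA),
    signature = vapply(reps, `[[`, NA, "signature"),
    H3K27me3 = vapply(reps, `[[`, NA, "k27"),
    stringsAsFactors = FALSE)
  agg <- lapply(split(df, df$class), function(g) {
    data.frame(class = g$class[1], n = nrow(g), n_signature = sum(g$signature),
               fraction = sum(g$signature) / nrow(g), stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, agg)
  rownames(summary) <- NULL
  icr_classes <- c("promoter ICR", "intergenic ICR")
  structure(list(reports = df, summary = summary,
                 non_icr_with_signature =
                   df$region_id[df$signature & !df$class %in% icr_classes]),
            class = "icr_scan")
}

#' @export
print.icr_scan <- function(x, ...) {
  cat("<icr_scan>\n")
  print(x$summary)
  if (length(x$non_icr_with_signature)) {
    cat("non-ICR regions carrying the signature:",
        paste(x$non_icr_with_signature, collapse = ", "), "\n")
  } else {
    cat("no non-ICR region carries the signature\n")
  }
  invisible(x)
}

BIVALENCY_STATES <- c("K4_only", "K27_only", "bivalent", "neither")

#' Bivalency state from H3K4me3/H3K27me3 booleans
#'
#' @param k4,k27 logicals (or a single named logical vector in `k4` with
#'   entries `H3K4me3` and `H3K27me3`).
#' @return One of `"bivalent"`, `"K4_only"`, `"K27_only"`, `"neither"`.
#' @export
bivalency_state <- function(k4, k27 = NULL) {
  if (is.null(k27)) {
    v <- k4
    if (!all(c("H3K4me3", "H3K27me3") %in% names(v))) {
      stop("need both H3K4me3 and H3K27me3 calls")
    }
    k4 <- v[["H3K4me3"]]; k27 <- v[["H3K27me3"]]
  }
  if (is.na(k4) || is.na(k27)) stop("missing mark call")
  if (k4 && k27) "bivalent" else if (k4) "K4_only" else if (k27) "K27_only" else "neither"
}

state_marks <- function(state) {
  switch(state,
         bivalent = c("H3K4me3", "H3K27me3"),
         K4_only = "H3K4me3",
         K27_only = "H3K27me3",
         neither = character())
}

expression_outcome <- function(from_expr, to_expr) {
  if (from_expr == "unknown" || to_expr == "unknown") return("unknown")
  if (from_expr == "repressed" && to_expr == "expressed") return("activated")
  if (from_expr == "repressed" && to_expr == "repressed") return("still_repressed")
  if (from_expr == "expressed" && to_expr == "expressed") return("still_expressed")
  "silenced"
}

#' Classify a bivalency-resolution transition between two cell types
#'
#' Tracks what happens to a gene's H3K4me3/H3K27me3 state upon differentiation.
#' For genes bivalent in the starting cell type, resolution classes record
#' which mark (if either) remains; genes not bivalent at the start are
#' `not_applicable`, except that a strict gain of marks (e.g. neither to
#' bivalent) is classed `gained_marks` so the classifier is total. The
#' expression outcome (activated / still_repressed / still_expressed /
#' silenced / unknown) is tracked alongside.
#'
#' @param gene_id gene identifier.
#' @param from_cell_type,to_cell_type distinct cell-type labels.
#' @param from_state,to_state bivalency states (see [bivalency_state()]).
#' @param from_expression,to_expression statuses in
#'   `{expressed, repressed, unknown}`.
#' @return A `transition_record`: one-row data frame with `transition_class`
#'   and `expression_outcome` among its columns.
#' @export
classify_transition <- function(gene_id, from_cell_type, to_cell_type,
                                from_state, to_state,
                                from_expression = "unknown",
                                to_expression = "unknown") {
  if (identical(from_cell_type, to_cell_type)) {
    stop("transition requires two distinct cell types")
  }
  stopifnot(from_state %in% BIVALENCY_STATES, to_state %in% BIVALENCY_STATES)
  cls <- if (from_state == "bivalent") {
    switch(to_state,
           bivalent = "retained_bivalent",
           K4_only = "resolved_to_K4",
           K27_only = "resolved_to_K27",
           neither = "resolved_to_none")
  } else {
    fm <- state_marks(from_state); tm <- state_marks(to_state)
    if (all(fm %in% tm) && length(tm) > length(fm)) "gained_marks" else "not_applicable"
  }
  out <- data.frame(gene_id = gene_id,
                    from_cell_type = from_cell_type, to_cell_type = to_cell_type,
                    from_state = from_state, to_state = to_state,
                    from_expression = from_expression, to_expression = to_expression,
                    transition_class = cls,
                    expression_outcome = expression_outcome(from_expression, to_expression),
                    stringsAsFactors = FALSE)
  class(out) <- c("transition_record", "data.frame")
  out
}

#' Bivalency-transition table from an integrated state table
#'
#' For every gene present in both cell types, derives the bivalency state in
#' each and classifies the transition.
#'
#' @param table a `gene_state_table` containing H3K4me3 and H3K27me3 columns.
#' @param from_cell_type,to_cell_type cell types to compare.
#' @param bivalent_only keep only genes bivalent in the starting cell type
#'   (default `TRUE`, the resolution question).
#' @return Data frame of transition records.
#' @export
transition_table <- function(table, from_cell_type, to_cell_type,
                             bivalent_only = TRUE) {
  df <- as.data.frame(table)
  a <- df[df$cell_type == from_cell_type, , drop = FALSE]
  b <- df[df$cell_type == to_cell_type, , drop = FALSE]
  common <- intersect(a$gene_id, b$gene_id)
  a <- a[match(common, a$gene_id), , drop = FALSE]
  b <- b[match(common, b$gene_id), , drop = FALSE]
  recs <- lapply(seq_along(common), function(i) {
    classify_transition(
      common[i], from_cell_type, to_cell_type,
      bivalency_state(a$H3K4me3[i], a$H3K27me3[i]),
      bivalency_state(b$H3K4me3[i], b$H3K27me3[i]),
      a$expression[i], b$expression[i])
  })
  out <- do.call(rbind, recs)
  if (bivalent_only && NROW(out)) {
    out <- out[out$from_state == "bivalent", , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
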
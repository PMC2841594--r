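#' Combinatorial profile taxonomy
#'
#' A taxonomy maps every possible subset of an ordered mark list to exactly one
#' label: named categories are exact subset matches; any unnamed non-empty
#' subset falls back to `"Other"` and the empty subset to `"None"`.
#'
#' @param marks ordered character vector of mark names.
#' @param categories named list; each element is the exact mark subset
#'   (character vector) carrying that label.
#' @return A `profile_taxonomy`.
#' @export
profile_taxonomy <- function(marks, categories) {
  stopifnot(length(marks) >= 1, !anyDuplicated(marks))
  if (is.null(names(categories)) || any(!nzchar(names(categories)))) {
    stop("categories must be a fully named list")
  }
  keys <- vapply(categories, function(s) {
    if (!all(s %in% marks)) stop("category uses mark(s) outside the taxonomy")
    if (!length(s)) stop("named categories must be non-empty subsets")
    paste(sort(s), collapse = "+")
  }, "")
  if (anyDuplicated(keys)) stop("two categories name the same mark subset")
  if (any(names(categories) %in% c("Other", "None"))) {
    stop("'Other' and 'None' are reserved fallback labels")
  }
  structure(list(marks = marks, categories = categories, keys = keys),
            class = "profile_taxonomy")
}

#' Built-in profile taxonomies
#'
#' * `"three_mark"` — H3K4me3/H3K27me3/H3K9me3 with named categories
#'   "H3K4me3 only", "H3K27me3 only", "H3K4me3+H3K27me3", "H3K4me3+H3K9me3"
#'   (used for comparing imprinted genes against the genome-wide background in
#'   ESCs).
#' * `"bivalency"` — H3K4me3/H3K27me3 with "H3K4me3 only", "H3K27me3 only"
#'   and the bivalent "H3K4me3+H3K27me3" category (used for cross-cell-type
#'   and expression-stratified comparisons).
#'
#' @param name preset name.
#' @return A `profile_taxonomy`.
#' @export
taxonomy_preset <- function(name = c("three_mark", "bivalency")) {
  name <- match.arg(name)
  switch(name,
    three_mark = profile_taxonomy(
      marks = c("H3K4me3", "H3K27me3", "H3K9me3"),
      categories = list(
        "H3K4me3 only" = "H3K4me3",
        "H3K27me3 only" = "H3K27me3",
        "H3K4me3+H3K27me3" = c("H3K4me3", "H3K27me3"),
        "H3K4me3+H3K9me3" = c("H3K4me3", "H3K9me3"))),
    bivalency = profile_taxonomy(
      marks = c("H3K4me3", "H3K27me3"),
      categories = list(
        "H3K4me3 only" = "H3K4me3",
        "H3K27me3 only" = "H3K27me3",
        "H3K4me3+H3K27me3" = c("H3K4me3", "H3K27me3"))))
}

#' All labels a taxonomy can emit
#' @param taxonomy a `profile_taxonomy`.
#' @export
taxonomy_labels <- function(taxonomy) {
  c(names(taxonomy$categories), "Other", "None")
}

#' Classify one mark vector under a taxonomy
#'
#' @param vector named logical vector covering exactly the taxonomy's marks
#'   (a [mark_vector()] result, or any named logical).
#' @param taxonomy a `profile_taxonomy`.
#' @return The category label (exact subset match), `"Other"` (unnamed
#'   non-empty subset) or `"None"` (no mark enriched).
#' @export
classify_profile <- function(vector, taxonomy) {
  stopifnot(inherits(taxonomy, "profile_taxonomy"))
  if (!setequal(names(vector), taxonomy$marks)) {
    stop("mark vector covers [", paste(names(vector), collapse = ","),
         "] but taxonomy expects [", paste(taxonomy$marks, collapse = ","), "]")
  }
  present <- names(vector)[as.logical(vector)]
  if (!length(present)) return("None")
  key <- paste(sort(present), collapse = "+")
  hit <- which(taxonomy$keys == key)
  if (length(hit)) names(taxonomy$categories)[hit] else "Other"
}

classify_matrix <- function(m, taxonomy) {
  m <- m[, taxonomy$marks, drop = FALSE]
  apply(m, 1L, function(row) classify_profile(row, taxonomy))
}

#' Profile distribution over a gene set
#'
#' Assesses every gene's TSS window against each mark's call set, classifies
#' the resulting mark vectors, and tabulates counts and percentages per label.
#' Genes absent from the annotation must be filtered upstream (via
#' [resolve_gene_records()]); every gene passed in is assessed.
#'
#' @param genes `gene_table` rows to assess.
#' @param callsets list of `callset` objects, one cell type, covering (at
#'   least) the taxonomy's marks.
#' @param taxonomy a `profile_taxonomy`.
#' @param flank TSS flank in bp (default 1000).
#' @return A `profile_distribution`: list with `cell_type`, `labels`, `counts`
#'   (named integer, all labels), `n`, `percentages`, `profiles` (per-gene
#'   label vector) and `caveats` (e.g. for HMM-called H4K20me3 sets).
#' @export
profile_distribution <- function(genes, callsets, taxonomy, flank = 1000) {
  if (NROW(genes) == 0L) stop("empty gene list")
  m <- mark_matrix(genes, callsets, flank = flank)
  labels <- classify_matrix(m, taxonomy)
  lv <- taxonomy_labels(taxonomy)
  counts <- table(factor(labels, levels = lv))
  counts <- stats::setNames(as.integer(counts), lv)
  n <- nrow(m)
  structure(list(cell_type = attr(m, "cell_type"),
                 labels = lv,
                 counts = counts,
                 n = n,
                 percentages = 100 * counts / n,
                 profiles = labels,
                 caveats = callset_caveats(callsets)),
            class = "profile_distribution")
}

callset_caveats <- function(callsets) {
  unlist(lapply(callsets, function(cs) {
    if (identical(cs$mark, "H4K20me3") && identical(cs$method, "HMM")) {
      sprintf("%s (%s) called by the more stringent HMM method and may be slightly underrepresented relative to WI-called marks",
              cs$mark, cs$cell_type)
    } else character()
  }))
}

#' @export
print.profile_distribution <- function(x, ...) {
  cat(sprintf("<profile_distribution> %s, n = %d genes\n", x$cell_type, x$n))
  df <- data.frame(label = x$labels, count = x$counts,
                   percent = round(x$percentages, 1), row.names = NULL)
  print(df)
  for (cv in x$caveats) cat("caveat:", cv, "\n")
  invisible(x)
}

#' Enrichment-call concordance between two calling methods
#'
#' Compares, gene by gene, the TSS enrichment boolean produced by two call
#' sets for the same mark and cell type but different calling methods (e.g.
#' window-interval vs hidden-Markov-model calls). A gene is discordant when
#' the two booleans differ.
#'
#' @param callset_a,callset_b `callset` objects: same mark, same cell type,
#'   methods may differ.
#' @param genes `gene_table` rows to compare.
#' @param flank TSS flank in bp.
#' @return A `concordance_report`: list with `mark`, `cell_type`, `methods`,
#'   `n`, `n_discordant`, `fraction_discordant`, `discordant_genes`.
#' @export
method_concordance <- function(callset_a, callset_b, genes, flank = 1000) {
  if (!identical(callset_a$mark, callset_b$mark)) {
    stop("call sets are for different marks")
  }
  if (!identical(callset_a$cell_type, callset_b$cell_type)) {
    stop("call sets are for different cell types")
  }
  wa <- mark_matrix(genes, list(callset_a), flank = flank)[, 1L]
  wb <- mark_matrix(genes, list(callset_b), flank = flank)[, 1L]
  disc <- xor(wa, wb)
  structure(list(mark = callset_a$mark, cell_type = callset_a$cell_type,
                 methods = c(callset_a$method, callset_b$method),
                 n = NROW(genes), n_discordant = sum(disc),
                 fraction_discordant = sum(disc) / NROW(genes),
                 discordant_genes = genes$gene_id[disc]),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %s in %s, %s vs %s: %d/%d discordant (%.1f%%)\n",
              x$mark, x$cell_type, x$methods[1], x$methods[2],
              x$n_discordant, x$n, 100 * x$fraction_discordant))
  invisible(x)
}
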
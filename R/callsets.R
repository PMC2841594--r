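#' @importFrom GenomicRanges GRanges reduce sort findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom GenomeInfoDb seqnames
NULL

KNOWN_METHODS <- c("WI", "HMM", "other")

#' Construct an enrichment call set
#'
#' An enrichment call set holds the genomic regions called enriched for one
#' histone mark in one cell type by one calling method. Intervals are stored
#' 0-based half-open (BED convention) and are always kept merged (union of
#' overlapping or book-ended intervals) and sorted per chromosome.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; 0-based half-open coordinates.
#' @param mark histone mark name, e.g. `"H3K4me3"`.
#' @param cell_type cell-type label, e.g. `"ESC"`.
#' @param method calling method: `"WI"`, `"HMM"` or `"other"`.
#' @return An object of class `callset` with fields `mark`, `cell_type`,
#'   `method` and `gr` (a merged, sorted [GenomicRanges::GRanges]).
#' @export
callset <- function(chrom = character(), start = integer(), end = integer(),
                    mark, cell_type, method = "other") {
  method <- match.arg(method, KNOWN_METHODS)
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (length(start)) {
    bad <- which(end <= start | start < 0 | is.na(start) | is.na(end))
    if (length(bad)) {
      stop("invalid interval(s) at position(s) ", paste(bad, collapse = ", "),
           ": need 0 <= start < end")
    }
  }
  # internal representation is 1-based closed; half-open [s, e) -> [s+1, e]
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))  # merges book-ended runs
  structure(list(mark = mark, cell_type = cell_type, method = method, gr = gr),
            class = "callset")
}

#' @export
print.callset <- function(x, ...) {
  cat(sprintf("<callset> %s in %s [%s]: %d merged interval(s)\n",
              x$mark, x$cell_type, x$method, length(x$gr)))
  invisible(x)
}

#' Number of merged intervals in a call set
#' @param x a `callset`.
#' @export
n_intervals <- function(x) length(x$gr)

#' Parse enrichment intervals from BED-like text
#'
#' Reads tab-delimited lines with at least three columns (chrom, start, end;
#' extra columns ignored) into a merged, sorted call set. Accepts a file path
#' (plain or gzip-compressed) or a character vector of lines. Input interval
#' order is irrelevant; overlapping and book-ended intervals are unioned.
#'
#' @param x file path or character vector of tab-delimited lines.
#' @param mark,cell_type,method metadata recorded on the call set.
#' @param one_based set `TRUE` if the source uses 1-based inclusive starts;
#'   coordinates are converted to the package's 0-based half-open convention.
#' @return A `callset`.
#' @export
parse_enrichment_intervals <- function(x, mark, cell_type, method = "other",
                                       one_based = FALSE) {
  lines <- if (length(x) == 1L && file.exists(x)) {
    con <- gzfile(x, "rt")  # gzfile reads plain text transparently
    on.exit(close(con))
    readLines(con)
  } else {
    as.character(x)
  }
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (!length(lines)) {
    return(callset(mark = mark, cell_type = cell_type, method = method))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed line ", which(nf < 3L)[1L], ": fewer than 3 tab-delimited columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | !nzchar(chrom))
  if (length(bad)) stop("malformed line ", bad[1L], ": non-integer coordinates")
  if (one_based) start <- start - 1L
  bad <- which(start < 0L | end <= start)
  if (length(bad)) {
    stop("invalid interval on line ", bad[1L], ": need 0 <= start < end")
  }
  callset(chrom, start, end, mark = mark, cell_type = cell_type, method = method)
}

#' Serialize a call set as BED3 text
#'
#' Writes the merged intervals back out as 0-based half-open BED3 lines.
#' Re-parsing the output reproduces the interval collection exactly.
#'
#' @param x a `callset`.
#' @param path optional file path; if `NULL` the lines are returned.
#' @return Character vector of BED3 lines (invisibly when `path` is given).
#' @export
write_callset <- function(x, path = NULL) {
  stopifnot(inherits(x, "callset"))
  lines <- if (length(x$gr)) {
    sprintf("%s\t%d\t%d",
            as.character(GenomeInfoDb::seqnames(x$gr)),
            GenomicRanges::start(x$gr) - 1L,
            GenomicRanges::end(x$gr))
  } else character()
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Assemble a gene reference table
#'
#' Validates a data frame of gene records: canonical identifier, pipe-separated
#' aliases (official symbols, accession numbers, alias names), chromosome,
#' strand-aware TSS coordinate, strand and species. The canonical identifier is
#' always included among a record's aliases.
#'
#' @param df data frame with columns `gene_id`, `aliases` (pipe-separated
#'   string, may be empty), `chrom`, `tss`, `strand` (`+`/`-`), `species`.
#' @return A validated `gene_table` data frame with an added logical column
#'   `manual` (provenance flag, `FALSE` for table-sourced records).
#' @export
gene_table <- function(df) {
  need <- c("gene_id", "aliases", "chrom", "tss", "strand", "species")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene table missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id in reference: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  }
  if (any(!nzchar(df$gene_id))) stop("empty gene_id")
  if (any(!df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df$tss <- as.integer(df$tss)
  if (any(is.na(df$tss) | df$tss < 0L)) stop("tss must be a non-negative integer")
  # gene_id is itself a resolvable alias
  df$aliases <- vapply(seq_len(nrow(df)), function(i) {
    al <- strsplit(df$aliases[i], "|", fixed = TRUE)[[1]]
    al <- unique(c(df$gene_id[i], al[nzchar(al)]))
    paste(al, collapse = "|")
  }, "")
  if (is.null(df$manual)) df$manual <- FALSE
  rownames(df) <- NULL
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Read a gene annotation table from a TSV file
#'
#' Tab-delimited with a header line: `gene_id`, `aliases` (pipe-separated),
#' `chrom`, `tss`, `strand`, `species`. Plain or gzip-compressed.
#'
#' @param path file path.
#' @return A `gene_table`.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  df$aliases[is.na(df$aliases)] <- ""
  gene_table(df)
}

alias_map <- function(reference, case_sensitive) {
  al <- strsplit(reference$aliases, "|", fixed = TRUE)
  name <- unlist(al, use.names = FALSE)
  id <- rep(reference$gene_id, lengths(al))
  if (!case_sensitive) name <- tolower(name)
  unique(data.frame(name = name, gene_id = id, stringsAsFactors = FALSE))
}

#' Resolve query gene names against a reference table
#'
#' Each query is matched by exact lookup (case-insensitive by default) against
#' canonical identifiers and aliases; no substring matching is ever performed.
#' Queries with no match are reported as not present; queries matching more
#' than one distinct record are reported as ambiguous and never silently
#' assigned. The three outcomes partition the query set.
#'
#' @param query_names character vector of gene names.
#' @param reference a `gene_table`.
#' @param case_sensitive match aliases respecting case? Default `FALSE`.
#' @return A `resolution_report`: list with `matched` (named character vector,
#'   query name -> gene_id), `not_present` and `ambiguous` (character vectors).
#' @export
resolve_gene_records <- function(query_names, reference, case_sensitive = FALSE) {
  stopifnot(inherits(reference, "gene_table"))
  query_names <- as.character(query_names)
  if (any(!nzchar(query_names))) stop("empty query name")
  map <- alias_map(reference, case_sensitive)
  key <- if (case_sensitive) query_names else tolower(query_names)
  hits <- lapply(key, function(k) unique(map$gene_id[map$name == k]))
  n <- lengths(hits)
  matched <- vapply(hits[n == 1L], `[[`, "", 1L)
  names(matched) <- query_names[n == 1L]
  structure(list(matched = matched,
                 not_present = query_names[n == 0L],
                 ambiguous = query_names[n > 1L]),
            class = "resolution_report")
}

#' @export
print.resolution_report <- function(x, ...) {
  cat(sprintf("<resolution_report> %d matched, %d not present, %d ambiguous\n",
              length(x$matched), length(x$not_present), length(x$ambiguous)))
  if (length(x$not_present)) {
    cat("  Gene not present:", paste(x$not_present, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Add manually curated records to a reference table
#'
#' Genes absent from every mined source (typically non-coding RNAs such as
#' imprinted macro-ncRNAs) can be appended by hand. Added records carry a
#' `manual = TRUE` provenance flag. Duplicate identifiers are an error.
#'
#' @param reference a `gene_table`.
#' @param records data frame of new records with the `gene_table` columns.
#' @return The extended `gene_table`.
#' @export
add_manual_records <- function(reference, records) {
  stopifnot(inherits(reference, "gene_table"))
  if (NROW(records) == 0L) return(reference)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records$manual <- TRUE
  dup <- intersect(records$gene_id, reference$gene_id)
  if (length(dup)) stop("gene_id already present: ", paste(dup, collapse = ", "))
  gene_table(rbind(as.data.frame(reference),
                   records[, names(reference), drop = FALSE]))
}
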
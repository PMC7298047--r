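#' Normalize gene symbols
#'
#' Lexical normalization only: leading/trailing whitespace is stripped and
#' letters are uppercased. No alias or synonym resolution is attempted, so
#' `"Cdkn2b-As1"` and `"CDKN2B-AS1"` collapse but historic aliases do not.
#' All-whitespace input yields `NA_character_`, the empty marker; callers
#' decide how to treat it.
#'
#' @param raw Character vector of raw gene symbols.
#' @return Character vector of the same length; `NA` where nothing remains
#'   after normalization.
#' @examples
#' normalize_symbol(c(" myoc ", "Cdkn2b-As1", "   "))
#' @export
normalize_symbol <- function(raw) {
  out <- toupper(trimws(as.character(raw)))
  out[is.na(out) | !nzchar(out)] <- NA_character_
  out
}

#' Construct a gene set
#'
#' A `gene_set` is a deduplicated, lexicographically ordered collection of
#' normalized gene symbols, each carrying the set of evidence-source labels
#' that contributed it. Ordering is deterministic (C-locale sort) so that
#' every downstream table derived from a gene set is byte-reproducible.
#'
#' @param symbols Character vector of raw symbols (normalized internally).
#' @param sources Either a single label applied to all symbols, or a list of
#'   character vectors parallel to `symbols`.
#' @param label Free-text name for the set.
#' @return An object of class `gene_set` with elements `symbol` (sorted
#'   character vector), `sources` (list of character vectors, parallel to
#'   `symbol`) and `label`.
#' @export
gene_set <- function(symbols, sources = "unspecified", label = "gene_set") {
  sym <- normalize_symbol(symbols)
  keep <- !is.na(sym)
  sym <- sym[keep]
  if (is.list(sources)) {
    stopifnot(length(sources) == length(symbols))
    src <- sources[keep]
  } else {
    src <- rep(list(as.character(sources)), length(sym))
  }
  ord <- order_c(sym)
  sym <- sym[ord]
  src <- src[ord]
  # collapse duplicate symbols, unioning their sources
  first <- !duplicated(sym)
  idx <- cumsum(first)
  merged <- vector("list", sum(first))
  for (i in seq_along(sym)) {
    j <- idx[i]
    merged[[j]] <- union(merged[[j]], src[[i]])
  }
  merged <- lapply(merged, function(s) sort(s, method = "radix"))
  structure(
    list(symbol = sym[first], sources = merged, label = label),
    class = "gene_set"
  )
}

# locale-independent lexicographic order
order_c <- function(x) order(x, method = "radix")

#' @export
length.gene_set <- function(x) length(x$symbol)

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d symbols\n", x$label, length(x)))
  show <- utils::head(x$symbol, 6L)
  cat(" ", paste(show, collapse = ", "),
      if (length(x) > 6L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.gene_set <- function(x, ...) {
  data.frame(
    symbol = x$symbol,
    sources = vapply(x$sources, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Gene symbols of a set
#' @param x A `gene_set`.
#' @return Sorted character vector of symbols.
#' @export
gene_symbols <- function(x) {
  if (inherits(x, "gene_set")) x$symbol else unique(normalize_symbol(x))
}

#' Merge gene lists from several evidence sources
#'
#' Takes per-source raw symbol lists (e.g. a Mendelian-disease catalog, a
#' GWAS catalog export, phenotype-prioritized genes, differential-expression
#' lists) and returns their union as a single `gene_set`, recording for each
#' symbol every source that contributed it. Empty and duplicate raw entries
#' collapse; the result is never larger than the sum of the input lengths.
#'
#' @param sources Named list; each element a character vector of raw symbols.
#'   Names are the source labels and must be unique.
#' @param label Label for the merged set.
#' @return A `gene_set`.
#' @examples
#' merge_gene_sources(list(OMIM = c("MYOC", "OPTN"), GWAS = c("optn", "SIX6")))
#' @export
merge_gene_sources <- function(sources, label = "merged") {
  if (!is.list(sources) || length(sources) == 0L)
    stop("'sources' must be a nonempty named list")
  labs <- names(sources)
  if (is.null(labs) || any(!nzchar(labs)) || anyDuplicated(labs))
    stop("source labels must be present and unique")
  sym <- unlist(lapply(sources, as.character), use.names = FALSE)
  lab <- rep(labs, times = vapply(sources, length, integer(1)))
  gs <- gene_set(sym, sources = as.list(lab), label = label)
  if (length(gs) == 0L) stop("no genes after normalization")
  gs
}

#' Overlap between two gene sets
#'
#' @param a,b `gene_set` objects (or character vectors of symbols).
#' @return Named integer vector `c(intersection, a_only, b_only)`.
#' @export
set_overlap <- function(a, b) {
  sa <- gene_symbols(a)
  sb <- gene_symbols(b)
  inter <- length(intersect(sa, sb))
  c(intersection = inter, a_only = length(sa) - inter, b_only = length(sb) - inter)
}

#' Read a one-symbol-per-line gene list
#'
#' Lines starting with `#` and blank lines are ignored.
#'
#' @param path File path.
#' @return Character vector of raw symbols.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Read a two-column symbol/source TSV into a gene_set
#'
#' Expects columns `symbol` and `source` (header required).
#'
#' @param path File path.
#' @param label Label for the resulting set.
#' @return A `gene_set`.
#' @export
read_gene_tsv <- function(path, label = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("symbol", "source") %in% names(df)))
    stop("expected columns 'symbol' and 'source' in ", path)
  gene_set(df$symbol, sources = as.list(df$source), label = label)
}

#' Write a gene_set as a two-column TSV
#'
#' Columns `symbol` and comma-joined `sources`, in the set's deterministic
#' lexicographic order.
#'
#' @param x A `gene_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
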
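#' Disease-category breakdown for a gene set
#'
#' Collects the distinct diseases linked to any query gene (a PheWAS-style
#' gene-disease table) and tabulates them by category. Diseases reached via
#' several query genes count once; diseases missing from the category map
#' fall into `"other"`. The category vocabulary is whatever the map
#' supplies — nothing is hard-coded.
#'
#' @param gene_disease data.frame with columns `gene_symbol`, `disease_id`.
#' @param disease_category data.frame with columns `disease_id`, `category`
#'   (or a named character vector keyed by disease id).
#' @param query A `gene_set` or character vector of symbols.
#' @return List of class `disease_breakdown` with `total_diseases` and
#'   `per_category` (data.frame category, count, proportion; proportions
#'   sum to 1 when the total is positive).
#' @export
disease_breakdown <- function(gene_disease, disease_category, query) {
  if (!all(c("gene_symbol", "disease_id") %in% names(gene_disease)))
    stop("gene-disease table needs columns 'gene_symbol' and 'disease_id'")
  if (is.data.frame(disease_category)) {
    if (!all(c("disease_id", "category") %in% names(disease_category)))
      stop("category map needs columns 'disease_id' and 'category'")
    cat_map <- stats::setNames(as.character(disease_category$category),
                               disease_category$disease_id)
  } else {
    cat_map <- disease_category
  }
  q <- gene_symbols(query)
  if (length(q) == 0L) stop("empty query")
  sym <- normalize_symbol(gene_disease$gene_symbol)
  dis <- sort(unique(gene_disease$disease_id[!is.na(sym) & sym %in% q]),
              method = "radix")
  if (length(dis) == 0L) {
    per <- data.frame(category = character(), count = integer(),
                      proportion = numeric(), stringsAsFactors = FALSE)
    return(structure(list(total_diseases = 0L, per_category = per),
                     class = "disease_breakdown"))
  }
  cats <- unname(cat_map[dis])
  cats[is.na(cats)] <- "other"
  tab <- table(cats)
  per <- data.frame(category = names(tab), count = as.integer(tab),
                    proportion = as.numeric(tab) / length(dis),
                    stringsAsFactors = FALSE)
  per <- per[order(-per$count, per$category, method = "radix"), , drop = FALSE]
  rownames(per) <- NULL
  structure(list(total_diseases = length(dis), per_category = per),
            class = "disease_breakdown")
}

#' @export
print.disease_breakdown <- function(x, ...) {
  cat(sprintf("%d diseases linked to the query gene set\n", x$total_diseases))
  if (nrow(x$per_category)) {
    p <- x$per_category
    p$proportion <- sprintf("%.1f%%", 100 * p$proportion)
    print(p, row.names = FALSE)
  }
  invisible(x)
}

#' Read a gene-disease association TSV
#' @param path TSV with header `gene_symbol  disease_id`.
#' @return data.frame.
#' @export
read_gene_disease <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_symbol", "disease_id") %in% names(df)))
    stop("expected columns 'gene_symbol' and 'disease_id' in ", path)
  df
}

#' Read a disease-category TSV
#' @param path TSV with header `disease_id  category`.
#' @return data.frame.
#' @export
read_disease_categories <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("disease_id", "category") %in% names(df)))
    stop("expected columns 'disease_id' and 'category' in ", path)
  df
}
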
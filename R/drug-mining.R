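#' Read a drug-gene interaction table
#'
#' TSV with header `drug_id  drug_name  gene_symbol  source` (DGIdb-export
#' style; `drug_name` and `source` optional). Gene symbols are normalized
#' and duplicate (drug_id, gene_symbol, source) triples dropped.
#'
#' @param path File path.
#' @return data.frame with columns drug_id, drug_name, gene_symbol, source.
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_interactions(df)
}

as_interactions <- function(df) {
  if (!all(c("drug_id", "gene_symbol") %in% names(df)))
    stop("interaction table needs columns 'drug_id' and 'gene_symbol'")
  if (is.null(df$drug_name)) df$drug_name <- df$drug_id
  if (is.null(df$source)) df$source <- "unspecified"
  df$gene_symbol <- normalize_symbol(df$gene_symbol)
  df <- df[!is.na(df$gene_symbol), , drop = FALSE]
  if (nrow(df) == 0L) stop("interaction table is empty after normalization")
  key <- paste(df$drug_id, df$gene_symbol, df$source, sep = "\r")
  df <- df[!duplicated(key), c("drug_id", "drug_name", "gene_symbol", "source")]
  rownames(df) <- NULL
  df
}

#' Per-drug target overrepresentation in a disease gene set
#'
#' For every drug in the interaction table, forms the 2x2 table of universe
#' genes cross-classified by membership in the query set and the drug's
#' target set, tests for association, and adjusts across drugs by
#' Benjamini-Hochberg. The gene universe defaults to all distinct genes in
#' the interaction table (`"auto"`); p-values depend on this choice, so it
#' can be overridden with any gene set. The query is intersected with the
#' universe before testing.
#'
#' The default test is chi-squared with Yates continuity correction, falling
#' back per drug to the one-sided Fisher exact test whenever any expected
#' cell is below `min_expected` (the chi-square approximation is unreliable
#' at the tiny counts real target sets produce). `method = "fisher"` forces
#' the exact test (one-sided, overrepresentation) everywhere.
#'
#' @param interactions data.frame as from [read_interactions()].
#' @param query A `gene_set` (or character vector) of disease genes.
#' @param universe `"auto"`, a `gene_set`, or a character vector.
#' @param method `"chi2_yates"`, `"chi2"`, or `"fisher"`.
#' @param alpha FDR threshold for flagging candidates.
#' @param min_expected Expected-cell threshold for the Fisher fallback.
#' @return data.frame sorted by ascending p then drug_id with columns
#'   drug_id, drug_name, k (targets in query), K (targets in universe),
#'   n (query genes in universe), N (universe size), statistic, p_value,
#'   q_value, rank (1-based, ties share the minimum), method, candidate.
#' @export
enrich_drugs <- function(interactions, query, universe = "auto",
                         method = c("chi2_yates", "chi2", "fisher"),
                         alpha = 0.05, min_expected = 5) {
  method <- match.arg(method)
  interactions <- as_interactions(interactions)
  uni <- if (identical(universe, "auto"))
    sort(unique(interactions$gene_symbol), method = "radix")
  else gene_symbols(universe)
  N <- length(uni)
  q_sym <- intersect(gene_symbols(query), uni)
  if (length(q_sym) == 0L) stop("query disjoint from universe")
  n <- length(q_sym)

  targets <- split(interactions$gene_symbol, interactions$drug_id)
  names_by_id <- interactions$drug_name[!duplicated(interactions$drug_id)]
  names(names_by_id) <- interactions$drug_id[!duplicated(interactions$drug_id)]

  rows <- lapply(names(targets), function(id) {
    tg <- intersect(unique(targets[[id]]), uni)
    K <- length(tg)
    if (K == 0L) {
      warning("drug '", id, "' has no targets in the universe; skipped")
      return(NULL)
    }
    k <- length(intersect(tg, q_sym))
    tab <- c(k, n - k, K - k, N - n - K + k)
    use <- method
    if (method != "fisher") {
      margins <- c(tab[1] + tab[2], tab[3] + tab[4], tab[1] + tab[3], tab[2] + tab[4])
      expected <- outer(margins[1:2], margins[3:4]) / N
      if (any(margins == 0) || any(expected < min_expected)) use <- "fisher"
    }
    res <- if (use == "fisher")
      fisher_exact(tab, alternative = "greater")
    else
      chi_squared(tab, correct = (use == "chi2_yates"))
    data.frame(drug_id = id, drug_name = unname(names_by_id[id]),
               k = k, K = K, n = n, N = N,
               statistic = res$statistic, p_value = res$p.value,
               method = res$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no drug had targets in the universe")
  out$q_value <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$drug_id, method = "radix"), , drop = FALSE]
  out$rank <- rank(out$p_value, ties.method = "min")
  out$candidate <- out$q_value <= alpha
  rownames(out) <- NULL
  out[, c("drug_id", "drug_name", "k", "K", "n", "N", "statistic",
          "p_value", "q_value", "rank", "method", "candidate")]
}

#' Read a disease-drug / drug-gene bridge map
#'
#' Two TSVs: `disease  drug_id` and `drug_id  gene_symbol` (headers
#' required), e.g. exported from a curated drug database.
#'
#' @param disease_drugs_path,drug_genes_path File paths.
#' @return List with `disease_to_drugs` and `drug_to_genes`, each a named
#'   list of character vectors.
#' @export
read_bridge_map <- function(disease_drugs_path, drug_genes_path) {
  dd <- utils::read.delim(disease_drugs_path, stringsAsFactors = FALSE)
  dg <- utils::read.delim(drug_genes_path, stringsAsFactors = FALSE)
  if (!all(c("disease", "drug_id") %in% names(dd)))
    stop("disease-drug map needs columns 'disease' and 'drug_id'")
  if (!all(c("drug_id", "gene_symbol") %in% names(dg)))
    stop("drug-gene map needs columns 'drug_id' and 'gene_symbol'")
  list(
    disease_to_drugs = lapply(split(dd$drug_id, dd$disease), unique),
    drug_to_genes = lapply(split(normalize_symbol(dg$gene_symbol), dg$drug_id),
                           function(g) unique(g[!is.na(g)]))
  )
}

#' Expand a disease through drugs to an indirect target gene set
#'
#' Looks up the drugs recorded for a disease, then unions their target
#' genes. The returned gene set can seed [enrich_drugs()] as its query —
#' the indirect route used when a disease's approved drugs are known but a
#' direct gene list is not.
#'
#' @param bridge List as from [read_bridge_map()].
#' @param disease Disease token.
#' @return List with `drugs` (character vector) and `genes` (a `gene_set`).
#' @export
bridge_expand <- function(bridge, disease) {
  known <- names(bridge$disease_to_drugs)
  if (!disease %in% known)
    stop("unknown disease '", disease, "'; known: ", paste(known, collapse = ", "))
  drugs <- sort(bridge$disease_to_drugs[[disease]], method = "radix")
  have <- drugs %in% names(bridge$drug_to_genes)
  if (any(!have))
    warning("no target genes recorded for: ", paste(drugs[!have], collapse = ", "))
  genes <- unique(unlist(bridge$drug_to_genes[drugs[have]], use.names = FALSE))
  list(drugs = drugs,
       genes = gene_set(genes, sources = paste0("bridge:", disease),
                        label = paste0(disease, "_drug_targets")))
}

#' Consensus ranking of candidate drugs across evidence sources
#'
#' Merges per-source enrichment result tables: a drug survives if it passes
#' `q <= alpha` in at least one source, and survivors are ordered by
#' descending number of supporting sources, then ascending minimum p across
#' supporting sources, then drug_id. The first `k` survivors are returned.
#' All sources carry equal weight.
#'
#' @param result_lists Named list of data.frames from [enrich_drugs()].
#' @param alpha Per-source FDR threshold for support.
#' @param k Maximum number of drugs returned.
#' @return data.frame with columns drug_id, n_sources, sources
#'   (comma-joined), best_p, best_q; possibly empty.
#' @export
consensus_rank <- function(result_lists, alpha = 0.05, k = 40) {
  stopifnot(is.list(result_lists), length(result_lists) >= 1L, k >= 1)
  if (is.null(names(result_lists)) || any(!nzchar(names(result_lists))))
    stop("result_lists must be named by source label")
  sup <- do.call(rbind, lapply(names(result_lists), function(lab) {
    df <- result_lists[[lab]]
    pass <- df$q_value <= alpha
    if (!any(pass)) return(NULL)
    data.frame(drug_id = df$drug_id[pass], source = lab,
               p = df$p_value[pass], q = df$q_value[pass],
               stringsAsFactors = FALSE)
  }))
  empty <- data.frame(drug_id = character(), n_sources = integer(),
                      sources = character(), best_p = numeric(),
                      best_q = numeric(), stringsAsFactors = FALSE)
  if (is.null(sup)) return(empty)
  by_drug <- split(sup, sup$drug_id)
  out <- do.call(rbind, lapply(by_drug, function(d) {
    data.frame(drug_id = d$drug_id[1], n_sources = nrow(d),
               sources = paste(sort(d$source, method = "radix"), collapse = ","),
               best_p = min(d$p), best_q = min(d$q), stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$n_sources, out$best_p, out$drug_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, k)
}

#' Write an enrichment or consensus result table as TSV
#' @param x data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
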
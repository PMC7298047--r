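#' Run the repurposing pipeline end to end
#'
#' Config-driven orchestration of the package's stages in dependency order:
#' gene-list merging, per-source target enrichment, disease-drug-gene
#' bridging, consensus ranking, the EMR prevalence screen, and the
#' disease-category breakdown. Any stage is skipped when its inputs are
#' omitted from the config. All outputs are written as TSV into
#' `out_dir`, plus a JSON run manifest with the config echo and per-stage
#' row counts. Reruns with the same config are byte-identical.
#'
#' The config (a list, or path to a YAML file) has optional blocks:
#' \describe{
#'   \item{genes}{named map label -> gene-list file (one symbol per line).}
#'   \item{interactions}{named map label -> interaction TSV; each is
#'     enriched against the merged (or bridged) gene set.}
#'   \item{universe}{optional gene-list file overriding the auto universe.}
#'   \item{bridge}{`disease_drugs`, `drug_genes` (TSV paths) and `disease`;
#'     the bridged target set is enriched like another source (label
#'     `bridge`).}
#'   \item{emr}{`path` (CSV) and `drugs` (file with one drug per line, or a
#'     vector).}
#'   \item{spectrum}{`gene_disease` and `categories` TSV paths.}
#'   \item{params}{`method`, `alpha`, `k`, `correct`,
#'     `background_prevalence`, `background_size`, `age_cutoff`; defaults
#'     chi2_yates / 0.05 / 40 / TRUE / 0.01 / 1000 / 40.}
#'   \item{out_dir}{output directory (created).}
#' }
#'
#' @param config List or path to a YAML file.
#' @param quiet Suppress progress messages.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config must name an out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  p <- config$params
  params <- list(
    method = p$method %||% "chi2_yates",
    alpha = p$alpha %||% 0.05,
    k = p$k %||% 40,
    correct = p$correct %||% TRUE,
    background_prevalence = p$background_prevalence %||% 0.01,
    background_size = p$background_size %||% 1000,
    age_cutoff = p$age_cutoff %||% 40)
  if (params$alpha <= 0 || params$alpha >= 1) stop("alpha must lie in (0,1)")
  if (params$k < 1) stop("k must be >= 1")

  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  counts <- list()
  warnings <- character()
  run_stage <- function(stage, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      warnings <<- c(warnings, sprintf("%s: %s", stage, conditionMessage(w)))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  genes <- NULL
  if (!is.null(config$genes)) {
    genes <- run_stage("merge-genes", {
      lists <- lapply(config$genes, read_gene_list)
      gs <- merge_gene_sources(lists, label = "merged_genes")
      write_gene_set(gs, file.path(out_dir, "genes.tsv"))
      gs
    })
    counts$genes <- length(genes)
    say("merge-genes", "%d genes from %d sources", length(genes),
        length(config$genes))
  }

  bridged <- NULL
  if (!is.null(config$bridge)) {
    bridged <- run_stage("bridge", {
      bm <- read_bridge_map(config$bridge$disease_drugs,
                            config$bridge$drug_genes)
      bx <- bridge_expand(bm, config$bridge$disease)
      write_gene_set(bx$genes, file.path(out_dir, "bridge_genes.tsv"))
      bx
    })
    counts$bridge_drugs <- length(bridged$drugs)
    counts$bridge_genes <- length(bridged$genes)
    say("bridge", "%d drugs -> %d indirect target genes",
        length(bridged$drugs), length(bridged$genes))
  }

  enrichments <- list()
  if (!is.null(config$interactions)) {
    universe <- if (!is.null(config$universe))
      gene_set(read_gene_list(config$universe), label = "universe")
    else "auto"
    queries <- list()
    if (!is.null(genes)) queries <- c(queries, list(genes))
    if (!is.null(bridged)) queries[["bridge"]] <- bridged$genes
    if (length(queries) == 0L) stop("interactions given but no gene stage")
    query <- if (!is.null(genes)) genes else bridged$genes
    for (lab in names(config$interactions)) {
      enrichments[[lab]] <- run_stage(paste0("enrich:", lab), {
        res <- enrich_drugs(read_interactions(config$interactions[[lab]]),
                            query, universe = universe,
                            method = params$method, alpha = params$alpha)
        write_result_tsv(res, file.path(out_dir,
                                        sprintf("enrichment_%s.tsv", lab)))
        res
      })
      counts[[paste0("enrichment_", lab)]] <- nrow(enrichments[[lab]])
      say("enrich", "%s: %d drugs tested, %d candidates", lab,
          nrow(enrichments[[lab]]), sum(enrichments[[lab]]$candidate))
    }
    if (length(enrichments) >= 1L) {
      consensus <- run_stage("consensus", {
        cs <- consensus_rank(enrichments, alpha = params$alpha, k = params$k)
        write_result_tsv(cs, file.path(out_dir, "consensus.tsv"))
        cs
      })
      counts$consensus <- nrow(consensus)
      say("consensus", "%d consensus candidates", nrow(consensus))
    }
  }

  if (!is.null(config$emr)) {
    screen <- run_stage("emr-screen", {
      records <- read_emr(config$emr$path)
      drugs <- config$emr$drugs
      if (is.character(drugs) && length(drugs) == 1L && file.exists(drugs))
        drugs <- read_gene_list(drugs)
      bg <- background_model(params$background_prevalence,
                             params$background_size)
      res <- screen_all(records, drugs, background = bg,
                        correct = params$correct,
                        age_cutoff = params$age_cutoff)
      write_result_tsv(res, file.path(out_dir, "emr_screen.tsv"))
      res
    })
    counts$emr_screen <- nrow(screen)
    say("emr-screen", "%d drugs screened", nrow(screen))
  }

  if (!is.null(config$spectrum)) {
    if (is.null(genes)) stop("spectrum stage needs a genes stage")
    spec_res <- run_stage("spectrum", {
      bd <- disease_breakdown(read_gene_disease(config$spectrum$gene_disease),
                              read_disease_categories(config$spectrum$categories),
                              genes)
      write_result_tsv(bd$per_category, file.path(out_dir, "spectrum.tsv"))
      bd
    })
    counts$spectrum_categories <- nrow(spec_res$per_category)
    counts$spectrum_diseases <- spec_res$total_diseases
    say("spectrum", "%d diseases in %d categories", spec_res$total_diseases,
        nrow(spec_res$per_category))
  }

  manifest <- list(
    config = config,
    counts = counts,
    version = as.character(utils::packageVersion("repurpose")),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    warnings = warnings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
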
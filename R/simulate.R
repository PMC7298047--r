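# Seeded generators for every input the pipeline consumes. Each generator
# seeds its own RNG stream from the config seed (plus a fixed per-generator
# offset) and restores the caller's RNG state on exit, so adding a generator
# or reordering calls never perturbs existing fixtures.

with_stream <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) + offset) %% .Machine$integer.max)
  force(code)
}

#' Configuration for a synthetic drug-gene interaction table
#'
#' Defaults match the package's standard recovery-study conditions: a 2000
#' gene universe, 200 drugs with 20 targets each, a 200-gene query set, and
#' 10 planted drugs whose targets favour the query at enrichment factor 10
#' (relative odds that a planted drug's target lies in the query set).
#'
#' @param n_genes Universe size.
#' @param n_drugs Number of drugs.
#' @param targets_per_drug Distinct targets drawn per drug.
#' @param query_size Size of the query gene set.
#' @param planted_drugs Number of drugs with enriched targets.
#' @param enrichment_factor Relative odds (>= 1) of a planted target lying
#'   in the query; 1 reduces planted drugs to background.
#' @param seed Integer seed.
#' @return List of validated settings.
#' @export
enrichment_sim_config <- function(n_genes = 2000, n_drugs = 200,
                                  targets_per_drug = 20, query_size = 200,
                                  planted_drugs = 10, enrichment_factor = 10,
                                  seed = 1) {
  stopifnot(query_size <= n_genes, planted_drugs <= n_drugs,
            enrichment_factor >= 1, n_genes >= 1, n_drugs >= 1)
  if (targets_per_drug > n_genes)
    stop("infeasible config: targets_per_drug exceeds n_genes")
  as.list(environment())
}

#' Simulate a drug-gene interaction table with planted enriched drugs
#'
#' Background drugs draw their targets uniformly without replacement from
#' the gene universe. Planted drugs draw each target from the query set
#' with probability `q*f / (q*f + 1 - q)` where `q = query_size/n_genes`
#' and `f` is the enrichment factor (so `f = 1` is exactly background), the
#' remainder uniformly from non-query genes. Deterministic for a fixed
#' seed.
#'
#' @param config From [enrichment_sim_config()].
#' @return List with `interactions` (data.frame drug_id, drug_name,
#'   gene_symbol, source), `query` (a `gene_set`), and `truth` (data.frame
#'   drug_id, planted, enrichment_factor).
#' @export
simulate_interactions <- function(config = enrichment_sim_config()) {
  with_stream(config$seed, 0L, {
    genes <- sprintf("G%05d", seq_len(config$n_genes))
    drugs <- sprintf("D%04d", seq_len(config$n_drugs))
    query <- sort(sample(genes, config$query_size), method = "radix")
    nonquery <- setdiff(genes, query)
    planted <- sort(sample(drugs, config$planted_drugs), method = "radix")
    qfrac <- config$query_size / config$n_genes
    f <- config$enrichment_factor
    p_in <- qfrac * f / (qfrac * f + 1 - qfrac)
    t <- config$targets_per_drug
    target_list <- lapply(drugs, function(d) {
      if (d %in% planted) {
        k_in <- stats::rbinom(1L, t, p_in)
        k_in <- min(k_in, length(query))
        k_out <- min(t - k_in, length(nonquery))
        c(sample(query, k_in), sample(nonquery, k_out))
      } else {
        sample(genes, t)
      }
    })
    interactions <- data.frame(
      drug_id = rep(drugs, times = lengths(target_list)),
      drug_name = rep(drugs, times = lengths(target_list)),
      gene_symbol = unlist(target_list, use.names = FALSE),
      source = "synthetic", stringsAsFactors = FALSE)
    truth <- data.frame(drug_id = drugs, planted = drugs %in% planted,
                        enrichment_factor = ifelse(drugs %in% planted, f, 1),
                        stringsAsFactors = FALSE)
    list(interactions = interactions,
         query = gene_set(query, sources = "simulated", label = "sim_query"),
         truth = truth)
  })
}

#' Configuration for a synthetic EMR cohort
#'
#' Defaults encode the package's standard odds-ratio recovery study: 20,000
#' patients over age 40, 1% baseline glaucoma prevalence, and one drug with
#' exposure probability 0.5 and true odds ratio 0.25.
#'
#' @param n_patients Number of patients.
#' @param age_range Integer (min, max); ages drawn uniformly.
#' @param baseline_prevalence Glaucoma probability for unexposed patients.
#' @param drug_specs data.frame with columns `drug`,
#'   `exposure_probability`, `true_odds_ratio`.
#' @param seed Integer seed.
#' @return List of validated settings.
#' @export
emr_sim_config <- function(n_patients = 20000, age_range = c(41, 90),
                           baseline_prevalence = 0.01,
                           drug_specs = data.frame(
                             drug = "drug_a", exposure_probability = 0.5,
                             true_odds_ratio = 0.25,
                             stringsAsFactors = FALSE),
                           seed = 1) {
  stopifnot(n_patients >= 1, length(age_range) == 2, age_range[1] >= 0,
            age_range[1] <= age_range[2],
            baseline_prevalence > 0, baseline_prevalence < 1,
            all(drug_specs$exposure_probability > 0),
            all(drug_specs$exposure_probability < 1),
            all(drug_specs$true_odds_ratio > 0))
  as.list(environment())
}

#' Simulate EMR records with planted per-drug odds ratios
#'
#' Ages are uniform integers on `age_range`; drug exposures are independent
#' Bernoulli draws per drug; each patient's glaucoma outcome is Bernoulli
#' with odds equal to the baseline odds times the product of the true odds
#' ratios of the drugs they are exposed to (a multiplicative odds model, so
#' a single exposed drug with OR 0.25 quarters the glaucoma odds).
#'
#' @param config From [emr_sim_config()].
#' @return List with `records` (long-format data.frame patient_id, age,
#'   drug, glaucoma — exposed rows only), `patients` (one row per patient,
#'   with the glaucoma flag, for calibration checks), and `truth` (the
#'   drug_specs).
#' @export
simulate_emr <- function(config = emr_sim_config()) {
  with_stream(config$seed, 1L, {
    n <- config$n_patients
    specs <- config$drug_specs
    ages <- sample(seq(config$age_range[1], config$age_range[2]), n,
                   replace = TRUE)
    expo <- vapply(specs$exposure_probability,
                   function(p) stats::rbinom(n, 1L, p) == 1L,
                   logical(n))
    expo <- matrix(expo, nrow = n)
    base_odds <- config$baseline_prevalence / (1 - config$baseline_prevalence)
    log_or <- log(specs$true_odds_ratio)
    odds <- base_odds * exp(as.vector(expo %*% log_or))
    if (any(!is.finite(odds))) stop("odds model out of range")
    prob <- odds / (1 + odds)
    glaucoma <- stats::rbinom(n, 1L, prob)
    ids <- sprintf("P%06d", seq_len(n))
    rows <- lapply(seq_len(nrow(specs)), function(j) {
      i <- which(expo[, j])
      data.frame(patient_id = ids[i], age = ages[i], drug = specs$drug[j],
                 glaucoma = glaucoma[i], stringsAsFactors = FALSE)
    })
    list(records = do.call(rbind, rows),
         patients = data.frame(patient_id = ids, age = ages,
                               glaucoma = glaucoma, stringsAsFactors = FALSE),
         truth = specs)
  })
}

#' Deterministic EMR fixture reproducing the published nine-drug screen
#'
#' Emits one record per patient per drug so that [summarize_cohorts()]
#' recovers, for each of the nine candidate drugs, exactly the published
#' cohort counts (total exposed, exposed with glaucoma, and the same pair
#' in the over-40 stratum). Patients in the over-40 stratum are assigned
#' age 41 and the rest age 30; only the four counts matter downstream.
#'
#' @return data.frame of EMR records (patient_id, age, drug, glaucoma).
#' @export
nine_drug_cohort_fixture <- function() {
  counts <- data.frame(
    drug = c("cytarabine", "caffeine", "dipyridamole", "paclitaxel",
             "dasatinib", "celecoxib", "theophylline", "aspirin",
             "nicardipine"),
    n_total = c(435L, 3L, 46L, 634L, 6L, 1719L, 4594L, 5358L, 588L),
    g_total = c(0L, 0L, 0L, 0L, 0L, 1L, 5L, 16L, 2L),
    n_over40 = c(242L, 0L, 15L, 573L, 2L, 1488L, 4397L, 5197L, 564L),
    g_over40 = c(0L, 0L, 0L, 0L, 0L, 1L, 5L, 13L, 2L),
    stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    with(counts[i, ], {
      n_young <- n_total - n_over40
      g_young <- g_total - g_over40
      age <- c(rep(41L, n_over40), rep(30L, n_young))
      glaucoma <- c(rep(1L, g_over40), rep(0L, n_over40 - g_over40),
                    rep(1L, g_young), rep(0L, n_young - g_young))
      data.frame(patient_id = sprintf("%s_%05d", drug, seq_len(n_total)),
                 age = age, drug = drug, glaucoma = glaucoma,
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}
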
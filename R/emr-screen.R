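#' Read a long-format EMR table
#'
#' CSV with header `patient_id,age,drug,glaucoma`; one drug exposure per
#' row, patients repeating across rows, `glaucoma` in \{0, 1\} and
#' consistent across a patient's rows.
#'
#' @param path File path.
#' @return data.frame with those four columns.
#' @export
read_emr <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_emr(df)
}

validate_emr <- function(df) {
  need <- c("patient_id", "age", "drug", "glaucoma")
  if (!all(need %in% names(df)))
    stop("EMR table needs columns ", paste(need, collapse = ", "))
  if (any(df$age < 0, na.rm = TRUE)) stop("negative age in EMR table")
  if (!all(df$glaucoma %in% c(0, 1))) stop("glaucoma flag must be 0 or 1")
  flags <- tapply(df$glaucoma, df$patient_id, function(g) length(unique(g)))
  bad <- names(flags)[flags > 1L]
  if (length(bad))
    stop("inconsistent glaucoma flag for patient(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  df
}

#' Per-drug exposure cohorts from EMR records
#'
#' One cohort per requested drug: total exposed patients, exposed patients
#' with glaucoma, and the same pair restricted to age strictly greater than
#' `age_cutoff`. A patient counts once per drug regardless of row
#' multiplicity; a patient on several drugs counts in each cohort.
#'
#' @param records data.frame as from [read_emr()].
#' @param drugs Character vector of drug tokens (zero-count cohorts are
#'   returned for drugs absent from the records).
#' @param age_cutoff Strict lower age bound for the older stratum
#'   (default 40).
#' @return data.frame with columns drug, n_total, g_total, n_over40,
#'   g_over40.
#' @export
summarize_cohorts <- function(records, drugs, age_cutoff = 40) {
  records <- validate_emr(records)
  key <- paste(records$patient_id, records$drug, sep = "\r")
  records <- records[!duplicated(key), , drop = FALSE]
  out <- lapply(drugs, function(d) {
    r <- records[records$drug == d, , drop = FALSE]
    old <- r$age > age_cutoff
    data.frame(drug = d,
               n_total = nrow(r), g_total = sum(r$glaucoma),
               n_over40 = sum(old), g_over40 = sum(r$glaucoma[old]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Proportion of events
#' @param g Event count.
#' @param n Cohort size.
#' @return `g/n`, or 0 when `n` is 0.
#' @export
prevalence <- function(g, n) {
  if (any(g > n)) stop("event count exceeds cohort size")
  ifelse(n > 0, g / n, 0)
}

#' Background comparison model for the EMR screen
#'
#' The screen compares each exposed cohort not to an observed control group
#' but to a fixed background: a pseudo-cohort of `cohort_size` reference
#' individuals with event probability `prevalence`. The defaults (1%
#' glaucoma prevalence in people over 40, reference cohort of 1000) give
#' background cells (10, 990).
#'
#' @param prevalence Background event probability, in (0, 1).
#' @param cohort_size Reference pseudo-cohort size.
#' @return List with `prevalence` and `cohort_size`.
#' @export
background_model <- function(prevalence = 0.01, cohort_size = 1000) {
  stopifnot(prevalence > 0, prevalence < 1, cohort_size > 0)
  list(prevalence = prevalence, cohort_size = cohort_size)
}

#' Rescale a small cohort to the assumed comparison size
#'
#' Cohorts smaller than the background cohort size are rescaled for the
#' chi-squared comparison: the cohort is assumed to have `cohort_size`
#' participants and the event count is scaled proportionally
#' (`g * cohort_size / n`, real-valued). Cohorts at or above `cohort_size`
#' pass through unchanged. An empty cohort scales to zero events.
#'
#' @param n_over40,g_over40 Observed cohort size and event count.
#' @param background A [background_model()].
#' @return List with `adjusted_n`, `adjusted_g`, `scaled` (logical),
#'   `zero_event` (logical).
#' @export
adjust_cohort <- function(n_over40, g_over40, background = background_model()) {
  stopifnot(g_over40 >= 0, g_over40 <= n_over40 || n_over40 == 0)
  if (n_over40 >= background$cohort_size)
    return(list(adjusted_n = n_over40, adjusted_g = g_over40,
                scaled = FALSE, zero_event = g_over40 == 0))
  g <- if (n_over40 > 0) g_over40 * background$cohort_size / n_over40 else 0
  list(adjusted_n = background$cohort_size, adjusted_g = g,
       scaled = TRUE, zero_event = g == 0)
}

#' Screen one exposure cohort against the background prevalence
#'
#' Computes cohort prevalences, the chi-squared P of the (possibly
#' rescaled) cohort against the background pseudo-cohort, and the odds
#' ratio of glaucoma in the cohort versus the background odds. The odds
#' ratio always uses the RAW over-cutoff counts
#' (`(g/(n-g)) / (prev/(1-prev))`); the rescaling affects only the
#' chi-squared comparison. OR is 0 when no exposed patient has the event,
#' and undefined (NA, flagged) when all do.
#'
#' @param cohort One row from [summarize_cohorts()] (or an equivalent list
#'   with drug, n_total, g_total, n_over40, g_over40).
#' @param background A [background_model()].
#' @param correct Yates continuity correction for the chi-squared
#'   (default `TRUE`).
#' @return One-row data.frame with columns drug, n_total, g_total,
#'   prevalence, n_over40, g_over40, prevalence_over40, adjusted_n,
#'   adjusted_g, p_value, odds_ratio, flags (comma-joined labels among
#'   "scaled", "zero_event", "or_undefined").
#' @export
screen_drug <- function(cohort, background = background_model(), correct = TRUE) {
  n <- cohort$n_over40
  g <- cohort$g_over40
  adj <- adjust_cohort(n, g, background)
  bg_g <- background$prevalence * background$cohort_size
  bg_n <- background$cohort_size
  p <- chi_squared(c(adj$adjusted_g, adj$adjusted_n - adj$adjusted_g,
                     bg_g, bg_n - bg_g), correct = correct)$p.value
  bg_odds <- background$prevalence / (1 - background$prevalence)
  flags <- character()
  if (adj$scaled) flags <- c(flags, "scaled")
  if (n == 0 || g == 0) {
    or <- 0
    if (adj$zero_event) flags <- c(flags, "zero_event")
  } else if (g == n) {
    or <- NA_real_
    flags <- c(flags, "or_undefined")
  } else {
    or <- (g / (n - g)) / bg_odds
  }
  data.frame(drug = cohort$drug,
             n_total = cohort$n_total, g_total = cohort$g_total,
             prevalence = prevalence(cohort$g_total, cohort$n_total),
             n_over40 = n, g_over40 = g,
             prevalence_over40 = prevalence(g, n),
             adjusted_n = adj$adjusted_n, adjusted_g = adj$adjusted_g,
             p_value = p, odds_ratio = or,
             flags = paste(flags, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Screen a list of drugs against EMR records
#'
#' Composition of [summarize_cohorts()] and [screen_drug()]; results are
#' sorted by ascending p-value, then drug.
#'
#' @inheritParams summarize_cohorts
#' @inheritParams screen_drug
#' @return data.frame, one row per drug (empty for an empty drug list).
#' @export
screen_all <- function(records, drugs, background = background_model(),
                       correct = TRUE, age_cutoff = 40) {
  if (length(drugs) == 0L)
    return(screen_drug(list(drug = "x", n_total = 0, g_total = 0,
                            n_over40 = 0, g_over40 = 0), background,
                       correct)[0, , drop = FALSE])
  cohorts <- summarize_cohorts(records, drugs, age_cutoff)
  out <- do.call(rbind, lapply(seq_len(nrow(cohorts)), function(i)
    screen_drug(cohorts[i, , drop = FALSE], background, correct)))
  out <- out[order(out$p_value, out$drug, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
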
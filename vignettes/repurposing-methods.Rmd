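---
title: "Methods: target-set enrichment and the EMR prevalence screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: target-set enrichment and the EMR prevalence screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repurpose)
```

## The study design this package implements

A repurposing screen of this kind has two halves. The *in silico* half
starts from a disease gene set and asks, for every drug in a drug–gene
interaction database, whether the drug's targets overlap the disease set
more than chance would allow; candidates surviving FDR control in one or
more databases are merged into a consensus list. The *pharmaco-epidemiology*
half then looks the candidates up in hospital EMR data and compares the
disease prevalence among exposed patients to a fixed population background.
Glaucoma supplies the defaults throughout — a 1% background prevalence in
people older than 40 — but nothing glaucoma-specific is hard-coded.

## Gene catalog

Evidence sources (Mendelian catalogs, GWAS hits, phenotype-prioritized
genes, differential-expression lists) arrive as plain symbol lists.
`merge_gene_sources()` unions them after purely *lexical* normalization
(trim, uppercase). We deliberately do no alias or synonym resolution: that
would require an external nomenclature database and would make results
depend on its version. The consequence is that a symbol and its historic
alias count as two genes; users who need alias folding should apply it
upstream. Output order is always lexicographic (C locale), so every
downstream table is byte-reproducible.

## The contingency machinery

All association tests reduce to a 2×2 table. Three numerical choices
matter.

**Yates clamp.** The corrected statistic is
`n(max(|ad−bc| − n/2, 0))² / ((a+b)(c+d)(a+c)(b+d))`; when
`|ad−bc| ≤ n/2` it is exactly 0 and p = 1. Without the clamp, tiny cohorts
can produce spuriously large corrected statistics. The shortcut form is
algebraically identical to `Σ(O−E)²/E` with the per-cell correction, which
the test suite verifies to 1e-10 relative on random tables.

**Real-valued cells.** The EMR screen's rescaling rule (below) produces
non-integer event counts, so the chi-squared accepts real cells. The
Fisher exact test, being a count-conditional test, rejects them.

**Continuity correction default.** The correction is ON by default in both
halves of the pipeline. For the EMR screen this choice is forced by
reproduction: the reference nine-drug screen's printed P values (1.74E-03
for the single-event 1488-patient cohort, 4.30E-03 for the zero-event
cohorts) are recovered with the correction and not without it (9.9E-04 and
1.5E-03 respectively). For enrichment the correction guards against the
anti-conservatism of small expected cells; it is an explicit flag
everywhere.

**Fisher's test and sidedness.** `fisher_exact()` defaults to the
two-sided convention of `stats::fisher.test` (sum all tables with the
observed margins whose probability does not exceed the observed table's).
`enrich_drugs()`, however, asks a directional question — are the drug's
targets *over*represented in the query? — and therefore uses the one-sided
upper tail, both when Fisher is requested and when it is the small-count
fallback. A two-sided test would award significance to drugs whose targets
avoid the disease set, which is not the screening question. P-values are
never reported as exactly 0; underflow is floored at the smallest positive
double and noted.

**BH-FDR.** `bh_fdr()` delegates to `stats::p.adjust(method = "BH")`; the
test suite pins it against a literal step-up implementation.

## Enrichment: the universe question

The p-value of every drug depends on the gene universe N. There is no
canonical choice; ours is the set of all distinct genes in the interaction
table being tested (`universe = "auto"`), because it is self-contained,
reproducible, and matches the population from which target sets are drawn.
A curated universe (e.g. all protein-coding genes) can be supplied instead
and will generally *shrink* p-values by inflating the d cell, so universes
must be held fixed when comparing runs. The query is always intersected
with the universe before testing.

Consensus ranking across source databases weights all sources equally:
drugs are ordered by the number of sources in which they pass `q ≤ α`,
then by minimum p across supporting sources, then lexicographically by
drug id. The aggregation rule is stated here because "rank by P and FDR"
admits several readings; ties are resolved deterministically so the
top-k list is stable.

## EMR screen

For each drug we count exposed patients and disease cases, overall and in
the over-40 stratum (strictly greater than the cutoff). The comparison is
not exposed-vs-unexposed but exposed-vs-background: a pseudo-cohort of
`cohort_size` (default 1000) reference individuals at `prevalence`
(default 0.01), i.e. cells (10, 990).

Two rules need care, and both were fixed by reproducing the reference
nine-drug screen exactly:

* **Assumed-1000 rescaling.** Cohorts smaller than 1000 are treated as if
  they had 1000 participants, events scaled proportionally (real-valued),
  *for the chi-squared only*. An empty over-40 cohort scales to (0, 1000)
  and is flagged `zero_event`.
* **Odds ratio from raw counts.** OR = `(g/(n−g)) / (p/(1−p))` always uses
  the unscaled over-40 counts. This is the only combination consistent
  with the reference table: its 564-patient cohort's OR (0.35) matches raw
  counts while its P matches only the scaled comparison. OR is 0 when no
  exposed patient has the disease and undefined (flagged) when all do.

Two printed P values in the reference screen recompute ≈2–3% away
(7.73E-06 vs 7.60E-06; 1.01E-03 vs 9.80E-04), consistent with intermediate
rounding in the original; the package documents them as near-misses and
its tests require 5% relative agreement there rather than printed-digit
equality.

Patients on several candidate drugs count in each drug's cohort; the
screen makes no attempt at confounder adjustment, time-to-event modeling,
or visit deduplication beyond collapsing duplicate (patient, drug) rows.

## Synthetic data: what it emulates and what it does not

`simulate_interactions()` draws background drugs' targets uniformly from
the universe and planted drugs' targets from the query set with
probability `q·f/(q·f + 1 − q)` (`q` the query fraction, `f` the
enrichment factor), so `f = 1` is exactly the null. `simulate_emr()` draws
ages uniformly, exposures as independent Bernoullis, and the disease as a
Bernoulli whose odds are the baseline odds times the product of the true
odds ratios of the patient's exposures. Each generator seeds its own RNG
stream from the config seed and restores the caller's stream, so adding
generators never perturbs existing fixtures.

The defaults are the package's standard study conditions: 2000 genes, 200
drugs, 20 targets per drug, a 200-gene query, 10 planted drugs at
enrichment factor 10; and 20,000 patients over 40 at 1% baseline with one
drug at exposure probability 0.5 and true OR 0.25. The exposure
probability is set at 0.5 because the odds-ratio recovery study needs
roughly 25 expected events in the exposed arm for the OR estimate to land
in [0.15, 0.40] at least 95% of the time; at half the exposure the
binomial tail alone caps the success rate near 91%, which no correct
implementation could beat. Under these conditions the per-drug probability
that a planted drug survives `q ≤ 0.05` is analytically ≈0.91 (the
overlap must reach 8 of 20 targets), so the ≥90% recovery property is
real but tight, and the test suite estimates it over 100 seeded
replicates.

What the generators do *not* emulate: gene–gene correlation, target-set
size heterogeneity, ICD coding noise, visit structure, age-dependent
exposure, or confounding. Passing recovery tests therefore demonstrates
correctness of the statistics on clean data, not robustness to the
messiness of real EMR extracts.

A deterministic fixture, `nine_drug_cohort_fixture()`, reconstructs the reference
nine-drug hospital screen at the patient level (over-40 patients get age
41, the rest 30; only the four cohort counts matter downstream), which is
what the reproduction tests and the acceptance script run on.

## Problem sizes and determinism

The test suite uses the study conditions above directly: the exhaustive
Fisher-vs-enumeration sweep covers all ~136,000 tables with n ≤ 40; null
calibration uses 5000 tables of n = 2000; enrichment recovery uses 100
simulated tables (1000 planted drugs); OR recovery uses 200 cohorts of
20,000 patients. All stochastic checks run under fixed seeds and are
exactly reproducible; `run_pipeline()` reruns are byte-identical for a
fixed config.

## Known limitations

* Lexical symbol matching only; alias-sensitive inputs need upstream
  normalization.
* The enrichment p-value is universe-dependent by construction; the
  package reports the universe size alongside every result.
* The EMR screen's background is a point prevalence, not a matched
  control group; estimates inherit whatever selection bias the hospital
  population carries.
* Consensus ranking treats sources as exchangeable; a source with an
  inflated database (many tiny target sets) contributes support as easily
  as a curated one.
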
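# repurpose

Computational drug repurposing from disease gene sets, with an electronic
medical record (EMR) prevalence screen for candidate drugs.

The package targets a common study design in ophthalmic genetics and
beyond: collect the genes implicated in a disease (Mendelian catalogs, GWAS
hits, phenotype-prioritized genes, differential-expression lists), ask
which drugs' target genes are overrepresented in that set, merge the
evidence across several drug–gene databases into a consensus candidate
list, and then check in hospital EMR data whether patients exposed to a
candidate drug develop the disease more or less often than a fixed
background prevalence. Glaucoma — baseline prevalence about 1% in people
over 40 — is the motivating application and supplies the defaults, but
every prevalence, cutoff and vocabulary is a parameter.

## The statistics

**Target overrepresentation.** For each drug, universe genes are
cross-classified by membership in the disease query set and in the drug's
target set, giving a 2×2 table with cells
(k, n−k, K−k, N−n−K+k) for a universe of N genes, query of n, target set
of K, overlap k. Association is tested with the chi-squared statistic in
shortcut form, with optional Yates continuity correction,

    X² = n_tot · ( max(|ad − bc| − n_tot/2, 0) )² / ((a+b)(c+d)(a+c)(b+d)),

falling back to the one-sided Fisher exact test whenever an expected cell
drops below 5. P-values are adjusted across drugs by Benjamini–Hochberg;
drugs with q ≤ α (default 0.05) are candidates. Consensus across source
databases ranks drugs by number of supporting sources, then minimum p.

**EMR screen.** For each drug, the exposed cohort older than 40 is
compared against a reference pseudo-cohort of 1000 individuals at 1%
prevalence, i.e. background cells (10, 990). Cohorts smaller than 1000 are
rescaled to an assumed 1000 participants (events scaled proportionally,
real-valued) before the Yates-corrected chi-squared; the odds ratio always
uses the raw counts: OR = (g/(n−g)) / (0.01/0.99).

## Worked example

The built-in fixture `nine_drug_cohort_fixture()` encodes a published nine-drug
hospital screen (per-drug exposure cohorts and glaucoma cases):

```r
library(repurpose)
emr <- nine_drug_cohort_fixture()
res <- screen_all(emr, sort(unique(emr$drug)))
res[, c("drug", "n_over40", "g_over40", "p_value", "odds_ratio")]
#>           drug n_over40 g_over40      p_value odds_ratio
#> 1 theophylline     4397        5 7.732654e-06 0.11270492
#> 2      aspirin     5197       13 1.012146e-03 0.24826389
#> 3    celecoxib     1488        1 1.746792e-03 0.06657700
#> 4     caffeine        0        0 4.328249e-03 0.00000000
#> 5   cytarabine      242        0 4.328249e-03 0.00000000
#> 6    dasatinib        2        0 4.328249e-03 0.00000000
#> 7 dipyridamole       15        0 4.328249e-03 0.00000000
#> 8   paclitaxel      573        0 4.328249e-03 0.00000000
#> 9  nicardipine      564        2 1.370468e-01 0.35231317
```

Reading the celecoxib row: 1 of 1488 exposed patients over 40 had
glaucoma, odds ratio 0.067 against the 1% background — a 15-fold lower
odds — with P ≈ 1.7×10⁻³ from the Yates-corrected comparison with the
(10, 990) reference cohort. The zero-event cohorts share
P ≈ 4.3×10⁻³: after rescaling to an assumed 1000 participants they are
all the same (0, 1000) vs (10, 990) comparison, and their odds ratio
is 0.

Enrichment on a synthetic interaction table with planted enriched drugs:

```r
sim <- simulate_interactions(enrichment_sim_config(seed = 1))
res <- enrich_drugs(sim$interactions, sim$query)
head(res[res$candidate, c("drug_id", "k", "K", "p_value", "q_value")], 3)
#>   drug_id  k  K      p_value      q_value
#> 1   D0147 14 20 2.040600e-10 4.081201e-08
#> 2   D0009 13 20 3.869910e-09 3.869910e-07
#> 3   D0075 12 20 5.934901e-08 2.373961e-06
```

An end-to-end run (gene merge → enrichment → consensus → EMR screen →
disease-category breakdown) is driven by a YAML config through
`run_pipeline()`; see `?run_pipeline` and the methods vignette
(`vignettes/repurposing-methods.Rmd`).

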
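test_that("drug enrichment builds the documented 2x2 table and exact p", {
  inter <- make_interactions(list(X = c("g1", "g2", "g3")))
  universe <- paste0("g", 1:10)
  query <- gene_set(paste0("g", 1:5))
  res <- enrich_drugs(inter, query, universe = universe, method = "fisher")
  expect_equal(res$k, 3L)
  expect_equal(res$K, 3L)
  expect_equal(res$n, 5L)
  expect_equal(res$N, 10L)
  # one-sided hypergeometric tail: C(5,3)C(5,0)/C(10,3) = 1/12
  expect_equal(res$p_value, 1 / 12, tolerance = 1e-12)
  expect_equal(res$q_value, res$p_value)
})

test_that("a drug covering the whole query scores smallest p in the table", {
  set.seed(5)
  universe <- sprintf("u%03d", 1:40)
  query <- gene_set(universe[1:20])
  targets <- c(list(best = universe[1:20]),
               lapply(stats::setNames(1:6, paste0("bg", 1:6)),
                      function(i) sample(universe, 10)))
  res <- enrich_drugs(make_interactions(targets), query, universe = universe,
                      method = "fisher")
  expect_equal(res$drug_id[1], "best")
  expect_true(all(res$p_value[1] <= res$p_value))
})

test_that("zero overlap is never more significant than positive overlap at equal K", {
  universe <- paste0("g", 1:30)
  query <- gene_set(universe[1:10])
  inter <- make_interactions(list(
    none = universe[21:25],          # K = 5, k = 0
    some = c(universe[1:2], universe[21:23])))  # K = 5, k = 2
  res <- enrich_drugs(inter, query, universe = universe, method = "fisher")
  expect_gte(res$p_value[res$drug_id == "none"],
             res$p_value[res$drug_id == "some"])
})

test_that("enrichment results conserve the universe and rank deterministically", {
  set.seed(9)
  sim <- simulate_interactions(enrichment_sim_config(
    n_genes = 300, n_drugs = 40, targets_per_drug = 8, query_size = 60,
    planted_drugs = 5, enrichment_factor = 8, seed = 3))
  res <- enrich_drugs(sim$interactions, sim$query)
  # cell conservation: k + (n-k) + (K-k) + (N-n-K+k) = N
  expect_true(all(res$k + (res$n - res$k) + (res$K - res$k) +
                    (res$N - res$n - res$K + res$k) == res$N))
  expect_true(all(res$k <= pmin(res$K, res$n)))
  expect_true(all(res$q_value >= res$p_value - 1e-15))
  expect_false(is.unsorted(res$p_value))
  expect_equal(res$rank, rank(res$p_value, ties.method = "min"))
  # adding an unrelated drug changes no other drug's p-value
  extra <- rbind(sim$interactions,
                 make_interactions(list(ZZZ = sim$interactions$gene_symbol[1:5])))
  res2 <- enrich_drugs(extra, sim$query)
  shared <- match(res$drug_id, res2$drug_id)
  expect_equal(res$p_value, res2$p_value[shared])
})

test_that("query disjoint from universe and empty-target drugs are handled", {
  inter <- make_interactions(list(X = c("g1", "g2")))
  expect_error(enrich_drugs(inter, gene_set("zz")), "disjoint")
  inter2 <- make_interactions(list(X = c("g1", "g2"), Y = "g9"))
  expect_warning(
    res <- enrich_drugs(inter2, gene_set("g1"), universe = c("g1", "g2")),
    "no targets in the universe")
  expect_equal(res$drug_id, "X")
})

test_that("bridge expansion unions drug target genes for a disease", {
  bridge <- list(
    disease_to_drugs = list(glaucoma = c("d1", "d2"), other = "d3"),
    drug_to_genes = list(d1 = c("GA", "GB"), d2 = c("GB", "GC"), d3 = "GZ"))
  bx <- bridge_expand(bridge, "glaucoma")
  expect_equal(bx$drugs, c("d1", "d2"))
  expect_equal(bx$genes$symbol, c("GA", "GB", "GC"))
  expect_error(bridge_expand(bridge, "unknown"), "glaucoma")
  # partial map: missing drug drops out with a warning
  bridge$drug_to_genes$d2 <- NULL
  expect_warning(bx2 <- bridge_expand(bridge, "glaucoma"), "d2")
  expect_equal(bx2$genes$symbol, c("GA", "GB"))
  # singleton
  expect_equal(length(bridge_expand(bridge, "other")$genes), 1L)
})

test_that("consensus ranking favours source support, then minimum p, then id", {
  mk <- function(ids, p, q) data.frame(drug_id = ids, p_value = p, q_value = q,
                                       stringsAsFactors = FALSE)
  res <- consensus_rank(list(
    s1 = mk(c("X", "Y"), c(1e-6, 1e-8), c(1e-5, 0.2)),
    s2 = mk(c("X", "Y"), c(1e-4, 1e-8), c(1e-3, 1e-7))), alpha = 0.05, k = 40)
  # X passes in both sources, Y only in s2 (despite its smaller p)
  expect_equal(res$drug_id, c("X", "Y"))
  expect_equal(res$n_sources, c(2L, 1L))
  expect_equal(res$best_p[1], 1e-6)

  # drugs failing everywhere are dropped; k truncates
  res2 <- consensus_rank(list(s1 = mk(c("A", "B", "C"),
                                      c(1e-6, 1e-5, 0.9),
                                      c(1e-4, 1e-4, 0.9))), k = 1)
  expect_equal(res2$drug_id, "A")
  # ties on support and p break lexicographically
  res3 <- consensus_rank(list(s1 = mk(c("B", "A"), c(1e-4, 1e-4), c(1e-3, 1e-3))))
  expect_equal(res3$drug_id, c("A", "B"))
  # empty output is legal
  res4 <- consensus_rank(list(s1 = mk("A", 0.9, 0.9)))
  expect_equal(nrow(res4), 0L)
})

test_that("interaction table reader normalizes and deduplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("drug_id\tdrug_name\tgene_symbol\tsource",
               "d1\tDrug One\tmyoc\tdgidb",
               "d1\tDrug One\tMYOC\tdgidb",
               "d1\tDrug One\toptn\tdgidb"), f)
  tab <- read_interactions(f)
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$gene_symbol, c("MYOC", "OPTN"))
})
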
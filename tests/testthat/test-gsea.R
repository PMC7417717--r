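ranked_fixture <- function(n = 50, seed = 6) {
  set.seed(seed)
  m <- sort(rnorm(n, 0, 1), decreasing = TRUE)
  data.frame(gene = sprintf("g%03d", seq_len(n)), metric = m,
             stringsAsFactors = FALSE)
}

test_that("filter_collection applies size, overlap and exclusion rules", {
  universe <- paste0("u", 1:100)
  coll <- gene_set_collection(list(
    A = universe[1:20],
    B = c(universe[1:9], universe[31]),      # overlap 9/10 = 0.9 with A
    C = universe[41:60],
    small = universe[1:4],
    big = universe,                           # fails max_size below
    out = universe[61:80]))
  filt <- filter_collection(coll, universe, min_size = 5, max_size = 50,
                            overlap_cut = 0.8, exclude = "out")
  expect_setequal(names(filt$sets$sets), c("A", "C"))
  expect_setequal(filt$dropped$name, c("out", "small", "big", "B"))
  expect_match(filt$dropped$reason[filt$dropped$name == "B"], "overlap")
  # genes outside the universe are trimmed
  coll2 <- gene_set_collection(list(D = c(universe[1:6], "alien")))
  filt2 <- filter_collection(coll2, universe)
  expect_false("alien" %in% filt2$sets$sets$D)
  # disjoint legal sets all kept; idempotence
  again <- filter_collection(filt$sets, universe, min_size = 5, max_size = 50,
                             overlap_cut = 0.8)
  expect_equal(again$sets$sets, filt$sets$sets)
  expect_equal(nrow(again$dropped), 0)
})

test_that("sample_metric is the sample-minus-control-mean contrast", {
  ds <- toy_dataset()
  r <- sample_metric(ds, "d1")
  # independent recomputation by explicit loop
  ctl <- c("c1", "c2")
  for (g in rownames(ds$matrix)) {
    expected <- ds$matrix[g, "d1"] - mean(ds$matrix[g, ctl])
    expect_equal(r$metric[r$gene == g], unname(expected), tolerance = 1e-12)
  }
  expect_true(all(diff(r$metric) <= 0))
  # degenerate sample identical to control mean warns
  mat <- ds$matrix
  mat[, "d1"] <- rowMeans(mat[, ctl])
  ds2 <- expression_dataset("T2", "LV", mat, ds$samples)
  expect_warning(sample_metric(ds2, "d1"), "meaningless")
  expect_error(sample_metric(ds, "zz"), "unknown sample")
})

test_that("enrichment_score matches the hand-walked toy cases", {
  ranked <- data.frame(gene = c("a", "b", "c"), metric = c(3, 2, 1))
  expect_equal(enrichment_score(ranked, "a"), 1)
  expect_equal(enrichment_score(ranked, "c"), -1)
  expect_error(enrichment_score(ranked, c("a", "b", "c")), "whole")
  expect_error(enrichment_score(ranked, "zz"), "does not intersect")
  # zero member weights fall back to equal increments, with warning
  flat <- data.frame(gene = c("a", "b", "c", "d"), metric = c(1, 0, 0, -1))
  expect_warning(es0 <- enrichment_score(flat, c("b", "c")), "equal hit")
  expect_equal(es0, es_oracle(flat, c("b", "c")))
})

test_that("enrichment_score equals the cumulative-sum oracle on random cases", {
  for (i in 1:100) {
    ranked <- ranked_fixture(50, seed = i)
    gs <- sample(ranked$gene, 8)
    expect_equal(enrichment_score(ranked, gs), es_oracle(ranked, gs),
                 tolerance = 1e-12)
  }
  # antisymmetry: negating metrics negates the score
  ranked <- ranked_fixture(60, seed = 123)
  neg <- data.frame(gene = rev(ranked$gene), metric = rev(-ranked$metric))
  for (i in 1:10) {
    gs <- sample(ranked$gene, 10)
    expect_equal(enrichment_score(neg, gs), -enrichment_score(ranked, gs),
                 tolerance = 1e-12)
  }
})

test_that("null ES is mean-zero and gene_permutation_p behaves at the edges", {
  ranked <- ranked_fixture(100, seed = 9)
  nulls <- null_es_distribution(ranked, 10, n_perm = 1000, seed = 2)
  expect_lt(abs(mean(nulls)), 3 * sd(nulls) / sqrt(1000))
  expect_equal(gene_permutation_p(ranked, 10, 0, null_es = nulls), 1)
  # observed far beyond every null: p at the add-one floor
  p_floor <- gene_permutation_p(ranked, 10, 0.999, null_es = nulls)
  expect_equal(p_floor, 1 / (1 + sum(nulls > 0)))
  # p = 1 when no same-signed nulls exist
  expect_equal(gene_permutation_p(ranked, 2, -0.5, null_es = abs(nulls) + 0.01), 1)
  # top-gene steep-metric case: near the add-one floor at n_perm = 50
  steep <- data.frame(gene = paste0("g", 1:20),
                      metric = c(10, rep(0.01, 19)))
  es <- enrichment_score(steep, "g1")
  p <- gene_permutation_p(steep, 1, es, n_perm = 50, seed = 3)
  nv <- null_es_distribution(steep, 1, 50, seed = 3)
  expect_equal(p, (1 + sum(nv > 0 & nv >= es)) / (1 + sum(nv > 0)))
})

test_that("per-sample enrichment recovers planted pathways and flags direction", {
  gen <- .small_gen()
  comp <- gen$compendium
  universe <- sort(unique(unlist(lapply(comp$datasets,
                                        function(d) rownames(d$matrix)))))
  filt <- filter_collection(gen$collection, universe)
  # a single comparison keeps this test quick
  one <- comp
  one$datasets <- comp$datasets[2]
  one$comparisons <- comp$comparisons[comp$comparisons$dataset_id == "DS02" &
                                      comp$comparisons$condition == "DCM", ]
  enr <- sample_enrichment(one, filt, n_perm = 100, seed = 11)
  cond <- "DCM"
  planted <- gen$truth$active_pathways[[cond]]
  hit_rate <- vapply(planted, function(pw) {
    e <- enr[enr$pathway == pw, ]
    mean(e$significant)
  }, numeric(1))
  expect_gt(mean(hit_rate > 0.5), 0.8)   # most planted pathways hit in most samples
  # direction matches the planted sign for significant calls
  sig <- enr[enr$significant & enr$pathway %in% planted, ]
  dirs <- gen$truth$pathway_direction[[cond]][sig$pathway]
  expect_gt(mean((sig$es > 0) == (dirs > 0)), 0.9)
})
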
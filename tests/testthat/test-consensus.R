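# minimal DEResult builder for consensus-tier tests
fake_de <- function(id, genes, calls, rp_up = NULL, rp_down = NULL) {
  n <- length(genes)
  de <- data.frame(gene = genes,
                   rp_up = rp_up %||% rep(10, n),
                   rp_down = rp_down %||% rep(10, n),
                   p_up = 0.5, p_down = 0.5, pfp_up = 1, pfp_down = 1,
                   call = calls, stringsAsFactors = FALSE)
  attr(de, "comparison_id") <- id
  de
}
`%||%` <- function(a, b) if (is.null(a)) b else a

make_calls <- function(gene, n_up, n_down, n_total = 25) {
  lapply(seq_len(n_total), function(i)
    fake_de(paste0("cmp", i), gene,
            if (i <= n_up) "up" else if (i <= n_up + n_down) "down" else "none"))
}

test_that("gene_consensus tallies calls and applies the 60% boundary", {
  # 17 up / 6 down of 25 -> FDEG, direction up
  gc <- gene_consensus(make_calls("NPPB", 17, 6))
  expect_equal(gc$n_up, 17); expect_equal(gc$n_down, 6)
  expect_true(gc$fdeg); expect_equal(gc$direction, "up")
  # 0 up / 25 down -> FDEG, direction down
  gc2 <- gene_consensus(make_calls("SERPINA3", 0, 25))
  expect_true(gc2$fdeg); expect_equal(gc2$direction, "down")
  # boundary: 15 of 25 qualifies, 14 does not
  expect_true(gene_consensus(make_calls("g", 15, 0))$fdeg)
  expect_false(gene_consensus(make_calls("g", 14, 0))$fdeg)
  expect_error(gene_consensus(c(make_calls("g", 1, 0, 1), make_calls("g", 1, 0, 1))),
               "duplicate comparison ids")
})

test_that("direction ties break by summed rank evidence and fdeg_min is monotone", {
  des <- make_calls("g", 8, 8, 16)
  # rank evidence favouring down: rp_up > rp_down in every comparison
  des <- lapply(des, function(d) { d$rp_up <- 40; d$rp_down <- 2; d })
  expect_message(gc <- gene_consensus(des, fdeg_min = 10), "tie")
  expect_equal(gc$direction, "down")
  # raising fdeg_min can only shrink the FDEG set
  gen_calls <- c(make_calls("a", 20, 0), lapply(make_calls("b", 12, 0),
    function(d) { attr(d, "comparison_id") <-
      paste0(attr(d, "comparison_id"), "x"); d }))
  # combine into comparison-indexed list of two-gene tables
  f1 <- gene_consensus(make_calls("a", 20, 0), fdeg_min = 12)
  f2 <- gene_consensus(make_calls("a", 20, 0), fdeg_min = 21)
  expect_true(f1$fdeg); expect_false(f2$fdeg)
})

test_that("consensus counts are invariant to comparison order", {
  gen <- .small_gen()
  set.seed(20)
  des <- lapply(1:6, function(i)
    fake_de(paste0("c", i), paste0("g", 1:10),
            sample(c("up", "down", "none"), 10, replace = TRUE)))
  a <- gene_consensus(des, fdeg_min = 3)
  b <- gene_consensus(rev(des), fdeg_min = 3)
  expect_equal(a, b)
})

test_that("sharing_profile reproduces printed-ratio arithmetic", {
  set.seed(21)
  n_de <- c(rep(1, 4000), rep(5, 2443), rep(13, 150), rep(20, 92))
  gc <- data.frame(gene = paste0("g", seq_along(n_de)),
                   n_up = n_de, n_down = 0, n_de = n_de,
                   fdeg = FALSE, direction = NA_character_)
  prof <- sharing_profile(gc)
  expect_equal(prof$n_degs, 6685)
  expect_equal(sum(prof$histogram$n_genes), 6685)
  expect_equal(prof$frac_gt(12), 242 / 6685)
  expect_equal(round(100 * prof$frac_gt(12), 1), 3.6)
})

enr_fixture <- function(n_samples, sig_per_pathway, conds = NULL) {
  # one pathway "P"; sig_per_pathway samples significant (up)
  sid <- sprintf("s%03d", seq_len(n_samples))
  data.frame(sample_id = sid,
             condition = conds %||% rep("A", n_samples),
             dataset_id = "D", pathway = "P",
             es = ifelse(seq_len(n_samples) <= sig_per_pathway, 0.5, 0.01),
             p = ifelse(seq_len(n_samples) <= sig_per_pathway, 0.01, 0.5),
             significant = seq_len(n_samples) <= sig_per_pathway,
             direction = "up", stringsAsFactors = FALSE)
}

test_that("condition_dysregulation requires a strict majority", {
  expect_true(condition_dysregulation(enr_fixture(5, 3))$dysregulated)
  expect_false(condition_dysregulation(enr_fixture(4, 2))$dysregulated)
})

test_that("frequent_pathways applies the strict 60% boundary", {
  expect_true(frequent_pathways(enr_fixture(414, 249))$frequent)   # 249 > 248.4
  expect_false(frequent_pathways(enr_fixture(414, 248))$frequent)  # 248 < 248.4
  pc <- frequent_pathways(enr_fixture(10, 10))
  expect_equal(pc$n_up, 10); expect_equal(pc$n_down, 0)
  # conservation: n_significant recomputable from the raw enrichment rows
  gen <- .small_gen()
  set.seed(22)
  enr <- do.call(rbind, lapply(1:8, function(i) {
    e <- enr_fixture(1, rbinom(1, 1, 0.5))
    e$sample_id <- paste0("s", i); e$pathway <- "Q"; e
  }))
  pc2 <- frequent_pathways(enr, frac = 0.6)
  expect_equal(pc2$n_significant, sum(enr$p < 0.05))
  expect_equal(pc2$n_up + pc2$n_down, pc2$n_significant)
})

test_that("figure5_coords satisfies x >= |y| and the corner cases", {
  pc <- data.frame(pathway = c("none", "allup"),
                   n_significant = c(0, 10), n_up = c(0, 10), n_down = c(0, 0),
                   frequent = c(FALSE, TRUE))
  xy <- figure5_coords(pc, n_samples = 10)
  expect_equal(xy$x, c(0, 1)); expect_equal(xy$y, c(0, 1))
  set.seed(23)
  for (i in 1:50) {
    n <- 20
    up <- sample(0:n, 1); dn <- sample(0:(n - up), 1)
    pc <- data.frame(pathway = "p", n_significant = up + dn,
                     n_up = up, n_down = dn, frequent = FALSE)
    xy <- figure5_coords(pc, n_samples = n)
    expect_gte(xy$x, abs(xy$y) - 1e-12)
  }
})

test_that("list_enrichment and ora_annotate agree with the Fisher primitive", {
  universe <- paste0("u", 1:40)
  q <- universe[1:10]; ref <- universe[6:20]
  le <- list_enrichment(q, ref, universe)
  expect_equal(le$overlap, 5)
  expect_equal(le$p, fisher_greater(5, 10, 5, 20))
  # disjoint query/reference: p = 1
  expect_equal(list_enrichment(universe[1:5], universe[30:40], universe)$p, 1)
  # relabelling invariance
  perm <- setNames(sample(universe), universe)
  le2 <- list_enrichment(unname(perm[q]), unname(perm[ref]), universe)
  expect_equal(le2$p, le$p)
  # the 4-gene enumeration case
  expect_equal(list_enrichment(c("a", "b"), c("a", "b"), c("a", "b", "c", "d"))$p,
               1 / 6, tolerance = 1e-12)
  # ora matches per-term list_enrichment; extreme containment is significant
  ann <- gene_set_collection(list(T1 = universe[1:10], T2 = universe[25:34]))
  tab <- ora_annotate(q, ann, universe)
  for (i in seq_len(nrow(tab)))
    expect_equal(tab$p[i],
                 list_enrichment(q, ann$sets[[tab$term[i]]], universe)$p)
  expect_true(tab$significant[tab$term == "T1"])
  expect_false(tab$significant[tab$term == "T2"])
  expect_error(list_enrichment(q, ref, character(0)), "empty universe")
})
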
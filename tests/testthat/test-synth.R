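test_that("generator is deterministic and honours its config", {
  cfg <- small_config(seed = 99L)
  g1 <- generate_compendium(cfg)
  g2 <- generate_compendium(cfg)
  expect_identical(g1$compendium$datasets[[3]]$matrix,
                   g2$compendium$datasets[[3]]$matrix)
  expect_identical(g1$truth, g2$truth)
  expect_identical(g1$network$edges, g2$network$edges)
  g3 <- generate_compendium(small_config(seed = 100L))
  expect_false(identical(g1$compendium$datasets[[3]]$matrix,
                         g3$compendium$datasets[[3]]$matrix))
  expect_equal(nrow(g1$compendium$comparisons), 25)
  expect_equal(length(g1$truth$fdeg_genes), cfg$n_fdeg)
  expect_equal(length(g1$collection$sets), cfg$n_pathways)
  # manifest references existing objects
  expect_true(all(g1$truth$fdeg_genes %in%
                    unlist(lapply(g1$compendium$datasets,
                                  function(d) rownames(d$matrix)))))
  expect_true(all(unlist(g1$truth$active_pathways) %in% names(g1$collection$sets)))
  expect_true(all(g1$truth$tf_pathway_links$pathway %in% g1$truth$core_pathways))
})

test_that("config validation rejects infeasible settings", {
  expect_error(generator_config(n_genes = 40, pathway_size_range = c(10, 50)),
               "exceeds gene count")
  expect_error(generator_config(fdeg_condition_prob = 1.5), "\\[0, 1\\]")
  expect_error(generator_config(n_fdeg = 0), "positive")
  expect_error(generator_config(n_core_pathways = 20,
                                n_active_pathways_per_condition = 15),
               "core pathways")
})

test_that("planted effects have the configured magnitude", {
  gen <- .small_gen()
  cfg <- gen$config
  comp <- gen$compendium
  # pick an up-regulated planted gene and a condition where it is active
  up <- names(gen$truth$fdeg_direction)[gen$truth$fdeg_direction > 0]
  checked <- 0
  for (i in seq_len(nrow(comp$comparisons))) {
    row <- comp$comparisons[i, ]
    ds <- comparison_dataset(comp, row$comparison_id)
    g <- intersect(up, rownames(ds$matrix))
    g <- g[gen$truth$fdeg_active[g, row$condition]]
    # exclude genes also carrying a pathway shift in this condition
    in_active_pw <- unique(unlist(gen$collection$sets[
      gen$truth$active_pathways[[row$condition]]]))
    g <- setdiff(g, in_active_pw)
    if (!length(g)) next
    diff <- rowMeans(ds$matrix[g, row$disease_ids[[1]], drop = FALSE]) -
      rowMeans(ds$matrix[g, row$control_ids[[1]], drop = FALSE])
    nd <- length(row$disease_ids[[1]]); nc <- length(row$control_ids[[1]])
    se <- cfg$noise_sd * sqrt(1 / nd + 1 / nc)
    expect_true(all(abs(diff - cfg$fdeg_effect) < 3.5 * se))
    checked <- checked + length(g)
  }
  expect_gt(checked, 10)
})

test_that("null comparison generator is shape-correct, seeded and centred", {
  ds <- generate_null_comparison(100, 5, 5, seed = 1)
  expect_equal(dim(ds$matrix), c(100, 10))
  expect_equal(sum(ds$samples$group == "disease"), 5)
  ds2 <- generate_null_comparison(100, 5, 5, seed = 2)
  expect_false(identical(ds$matrix, ds2$matrix))
  # Monte-Carlo: per-gene disease-control mean difference averages ~0
  diffs <- vapply(1:30, function(s) {
    d <- generate_null_comparison(50, 4, 4, seed = s)
    mean(rowMeans(d$matrix[, 1:4]) - rowMeans(d$matrix[, 5:8]))
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * 0.5 / sqrt(30 * 50 * 2))
})

test_that("compendium round-trips through write_compendium / pipeline loader", {
  gen <- .small_gen()
  tmp <- withr::local_tempdir()
  write_compendium(gen, tmp)
  ds1 <- gen$compendium$datasets[[1]]
  stem <- gsub("|", "_", names(gen$compendium$datasets)[1], fixed = TRUE)
  back <- read_expression(file.path(tmp, paste0(stem, ".matrix.tsv")),
                          file.path(tmp, paste0(stem, ".samples.tsv")))
  expect_equal(back$matrix, ds1$matrix, tolerance = 1e-12)
  net <- read_network(file.path(tmp, "network.tsv"))
  expect_equal(net$tf_index, gen$network$tf_index)
})
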
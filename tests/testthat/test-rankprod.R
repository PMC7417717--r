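test_that("pairwise_log_ratios enumerates all disease/control pairs", {
  ds <- toy_dataset()
  r <- pairwise_log_ratios(ds, c("d1", "d2"), c("c1", "c2"))
  expect_equal(ncol(r), 4)
  expect_equal(r["g1", "d1/c1"], 8 - 7.9)
  r1 <- pairwise_log_ratios(ds, "d1", "c1")
  expect_equal(ncol(r1), 1)
  expect_equal(unname(r1["g2", 1]), 5 - 6.9)
  # identical disease and control values give all-zero ratios
  mat <- matrix(5, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  same <- expression_dataset("X", "t", mat,
    data.frame(sample_id = colnames(mat),
               group = rep(c("disease", "control"), each = 2),
               condition = rep(c("A", "control"), each = 2)))
  expect_true(all(pairwise_log_ratios(same, c("s1", "s2"), c("s3", "s4")) == 0))
  expect_error(pairwise_log_ratios(ds, "nope", "c1"), "missing sample")
})

test_that("rank_product equals the brute-force product of ranks", {
  # gene always ranked 1 -> rp 1; ranks (2, 8) -> geometric mean 4
  rt <- matrix(c(10, 5, 1, 9, 3, 2), nrow = 3,
               dimnames = list(c("a", "b", "c"), NULL))
  rp <- rank_product(rt)
  expect_equal(unname(rp$rp_up["a"]), 1)
  # ranks (2, 8) over K = 2 -> geometric mean 4
  rt2 <- cbind(9:1, 1:9)
  rownames(rt2) <- paste0("g", 1:9)
  expect_equal(unname(rank_product(rt2)$rp_up["g2"]), sqrt(2 * 8))
  set.seed(4)
  for (i in 1:100) {
    tab <- matrix(rnorm(15), nrow = 5,
                  dimnames = list(paste0("g", 1:5), NULL))
    rp <- rank_product(tab)
    # oracle: direct product of per-column descending ranks, K-th root
    up_oracle <- apply(apply(tab, 2, function(v) rank(-v)), 1, prod)^(1 / 3)
    dn_oracle <- apply(apply(tab, 2, rank), 1, prod)^(1 / 3)
    expect_equal(rp$rp_up, up_oracle, tolerance = 1e-12)
    expect_equal(rp$rp_down, dn_oracle, tolerance = 1e-12)
    # direction symmetry: up on negated table equals down
    expect_equal(rank_product(-tab)$rp_up, rp$rp_down, tolerance = 1e-12)
  }
})

test_that("permutation p is monotone in rp and exhaustively correct at G=2", {
  # G = 2, K = 1: every permutation of two ranks contributes null rank
  # products {1, 2}, so the top gene has c = n_perm of 2*n_perm null values
  # <= 1: p = 1/2 exactly (half of random orderings put it first)
  rt <- matrix(c(2, 1), nrow = 2, dimnames = list(c("hi", "lo"), NULL))
  res <- permutation_null(rt, n_perm = 50, seed = 5)
  expect_equal(res$p_up[1], 0.5)
  expect_equal(res$p_up[2], 1)
  # pfp of the best-ranked gene = expected false positives / 1
  expect_equal(res$pfp_up[1], res$p_up[1] * 2 / 1)
  # monotone: p non-decreasing in rp within a direction
  ds <- generate_null_comparison(200, 3, 3, seed = 8)
  de <- rankprod_de(ds, ds$samples$sample_id[1:3], ds$samples$sample_id[4:6],
                    n_perm = 50, seed = 9)
  o <- order(de$rp_up)
  expect_true(all(diff(de$p_up[o]) >= 0))
  expect_true(all(de$p_up > 0 & de$p_up <= 1))
})

test_that("call_degs applies the pfp threshold and direction rule", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   pfp_up = c(0.01, 0.9, 0.5, 0.02),
                   pfp_down = c(0.9, 0.01, 0.5, 0.02))
  expect_message(out <- call_degs(de), "tied pfp")
  expect_equal(out$call, c("up", "down", "none", "none"))
})

test_that("planted up-regulated genes are recovered in active conditions", {
  gen <- .small_gen()
  comp <- gen$compendium
  row <- comp$comparisons[2, ]  # a DCM comparison in the default design
  ds <- comparison_dataset(comp, row$comparison_id)
  de <- rankprod_de(ds, row$disease_ids[[1]], row$control_ids[[1]],
                    n_perm = 60, seed = 10)
  planted <- intersect(gen$truth$fdeg_genes, de$gene)
  active <- planted[gen$truth$fdeg_active[planted, row$condition]]
  calls <- de$call[match(active, de$gene)]
  expect_gt(mean(calls != "none"), 0.9)
  dirs <- ifelse(gen$truth$fdeg_direction[active] > 0, "up", "down")
  agree <- calls == dirs
  expect_gt(mean(agree[calls != "none"]), 0.95)
})
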
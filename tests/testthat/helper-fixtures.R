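# Shared fixtures, built in code. The small compendium keeps the full
# 25-comparison design but shrinks genes/groups/permutations so module tests
# stay fast; expensive end-to-end recoveries live in test-acceptance.R.

small_config <- function(seed = 7L) {
  generator_config(n_genes = 300,
                   disease_range = c(4L, 6L), control_range = c(4L, 5L),
                   n_fdeg = 20, n_pathways = 20,
                   pathway_size_range = c(8L, 15L),
                   n_active_pathways_per_condition = 6, n_core_pathways = 4,
                   n_tfs = 10, tf_random_targets = 10,
                   # the small world needs denser coverage for Fisher power;
                   # the default-scale coverage of 0.3 is exercised in
                   # test-acceptance.R
                   tf_pathway_coverage = 0.5,
                   seed = seed)
}

# memoised: generating once is enough for read-only tests
.small_gen <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_compendium(small_config())
    cache
  }
})

toy_dataset <- function() {
  # 6 genes x 5 samples (3 disease / 2 control), fixed values
  mat <- matrix(c(8, 9, 8.5, 7.9, 8.2,
                  5, 5.2, 5.1, 6.9, 7.1,
                  10, 10.4, 10.2, 10.1, 9.9,
                  3, 3.3, 3.1, 3.2, 2.9,
                  6.5, 6.4, 6.6, 6.5, 6.4,
                  9.1, 9.0, 9.2, 7.0, 7.2),
                nrow = 6, byrow = TRUE,
                dimnames = list(paste0("g", 1:6),
                                c("d1", "d2", "d3", "c1", "c2")))
  expression_dataset("TOY", "LV", mat,
                     data.frame(sample_id = colnames(mat),
                                group = rep(c("disease", "control"), c(3, 2)),
                                condition = rep(c("DCM", "control"), c(3, 2)),
                                stringsAsFactors = FALSE))
}

# independent O(N) running-sum oracle for the enrichment score
es_oracle <- function(ranked, gene_set, w = 1) {
  hit <- ranked$gene %in% gene_set
  N <- nrow(ranked); NH <- sum(hit)
  wts <- abs(ranked$metric)^w
  inc <- ifelse(hit, wts / sum(wts[hit]), 0)
  if (sum(wts[hit]) == 0) inc <- ifelse(hit, 1 / NH, 0)
  dec <- ifelse(hit, 0, 1 / (N - NH))
  rs <- cumsum(inc - dec)
  # package convention: a +/- magnitude tie resolves to the positive extremum
  if (max(rs) >= -min(rs)) max(rs) else min(rs)
}

# brute-force hypergeometric upper tail by pmf summation
fisher_oracle <- function(a, b, c, d) {
  if (a + b == 0 || a + c == 0) return(1)
  k <- a:min(a + b, a + c)
  sum(stats::dhyper(k, a + b, c + d, a + c))
}
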
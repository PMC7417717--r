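# Tier 1: rank-product differential expression.
#
# For one comparison, every disease/control sample pair yields a vector of
# log2 ratios; genes are ranked within each pair (descending for the
# up-regulated direction, ascending for down) and the rank product is the
# geometric mean of a gene's ranks across pairs. Significance comes from a
# permutation null in which each pair's ranks are replaced by an independent
# uniform random permutation.

#' Pairwise log-ratios for one comparison
#'
#' All n_d x n_c disease/control sample pairs; the entry for gene g in pair
#' (i, j) is x\[g, disease_i\] - x\[g, control_j\] (log2 scale, so a
#' difference is a log fold change).
#'
#' @param ds An `ExpressionDataset`.
#' @param disease_ids,control_ids Sample ids of the comparison.
#' @return Numeric genes x K matrix of log2 ratios (K = n_d * n_c).
#' @export
pairwise_log_ratios <- function(ds, disease_ids, control_ids) {
  stopifnot(inherits(ds, "ExpressionDataset"),
            length(disease_ids) >= 1, length(control_ids) >= 1)
  missing <- setdiff(c(disease_ids, control_ids), colnames(ds$matrix))
  if (length(missing)) stop("missing sample: ", paste(missing, collapse = ", "))
  dis <- ds$matrix[, disease_ids, drop = FALSE]
  ctl <- ds$matrix[, control_ids, drop = FALSE]
  out <- matrix(0, nrow(ds$matrix), length(disease_ids) * length(control_ids))
  rownames(out) <- rownames(ds$matrix)
  k <- 0L
  pair_names <- character(ncol(out))
  for (i in seq_along(disease_ids)) for (j in seq_along(control_ids)) {
    k <- k + 1L
    out[, k] <- dis[, i] - ctl[, j]
    pair_names[k] <- paste(disease_ids[i], control_ids[j], sep = "/")
  }
  colnames(out) <- pair_names
  out
}

#' Rank products over a ratio table
#'
#' Per pair, genes are ranked by ratio descending (up) and ascending (down)
#' with average ties; the rank product is the geometric mean of the ranks
#' across the K pairs, so values live in \[1, G\] whatever K is. The ordering
#' of genes is identical to the raw product of ranks.
#'
#' @param ratio_table Genes x K numeric matrix from [pairwise_log_ratios()].
#' @return List with numeric vectors `rp_up` and `rp_down` (named by gene).
#' @export
rank_product <- function(ratio_table) {
  stopifnot(is.matrix(ratio_table), ncol(ratio_table) >= 1)
  if (anyNA(ratio_table)) stop("NaN ratios")
  up_ranks <- apply(ratio_table, 2, function(v) rank(-v, ties.method = "average"))
  G <- nrow(ratio_table)
  list(rp_up = exp(rowMeans(log(up_ranks))),
       rp_down = exp(rowMeans(log(G + 1 - up_ranks))))
}

#' Permutation null, p-values and pfp for rank products
#'
#' Each of `n_perm` permutations builds an independent permuted copy of the
#' expression data — gene labels are shuffled independently within every
#' sample — and recomputes all G null rank products from the resulting pair
#' ratios. Shuffling at the sample level (rather than independently per
#' pair) preserves the correlation among ratio vectors that share a sample,
#' which the all-pairs design induces; under a global null the permuted data
#' have exactly the joint distribution of the observed data, so p-values are
#' calibrated. When only a ratio table is available (no `samples`), the
#' lighter pair-independent rank permutation is used instead; it is
#' anticonservative under shared-sample designs and a warning says so.
#'
#' For an observed gene with rank product rho at ascending-sort position s:
#' c = number of null rank products <= rho pooled over permutations;
#' p = c / (n_perm * G); pfp = (c / n_perm) / s (the expected count of false
#' calls at position s, divided by s). Both directions are handled
#' identically. p (and hence pfp) is floored at c = 1 so p-values stay
#' strictly positive.
#'
#' @param ratio_table Genes x K ratio matrix.
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed.
#' @param samples Optional list with numeric matrices `disease` and
#'   `control` (genes x samples, same genes as `ratio_table`): the data the
#'   ratio table was computed from, enabling the sample-level permutation
#'   null.
#' @return data.frame with gene, rp_up, rp_down, p_up, p_down, pfp_up,
#'   pfp_down.
#' @export
permutation_null <- function(ratio_table, n_perm = 100, seed = 1L,
                             samples = NULL) {
  stopifnot(n_perm >= 1)
  G <- nrow(ratio_table); K <- ncol(ratio_table)
  if (G * n_perm == 0) stop("empty null")
  rp <- rank_product(ratio_table)
  set.seed(seed)
  null_up <- numeric(n_perm * G)
  null_dn <- numeric(n_perm * G)
  if (!is.null(samples)) {
    dis <- samples$disease; ctl <- samples$control
    stopifnot(is.matrix(dis), is.matrix(ctl), nrow(dis) == G, nrow(ctl) == G,
              ncol(dis) * ncol(ctl) == K)
    di <- rep(seq_len(ncol(dis)), each = ncol(ctl))
    ci <- rep(seq_len(ncol(ctl)), times = ncol(dis))
    for (b in seq_len(n_perm)) {
      pdis <- apply(dis, 2, function(x) x[sample.int(G)])
      pctl <- apply(ctl, 2, function(x) x[sample.int(G)])
      r <- apply(pdis[, di, drop = FALSE] - pctl[, ci, drop = FALSE], 2,
                 function(v) rank(-v, ties.method = "average"))
      idx <- ((b - 1L) * G + 1L):(b * G)
      null_up[idx] <- exp(rowMeans(log(r)))
      null_dn[idx] <- exp(rowMeans(log(G + 1 - r)))
    }
  } else {
    if (K > 1)
      warning("pair-independent rank permutation null; anticonservative when ",
              "ratio columns share samples - pass `samples` for a calibrated null")
    for (b in seq_len(n_perm)) {
      acc_up <- numeric(G); acc_dn <- numeric(G)
      for (k in seq_len(K)) {
        r <- sample.int(G)
        acc_up <- acc_up + log(r)
        acc_dn <- acc_dn + log(G + 1 - r)
      }
      idx <- ((b - 1L) * G + 1L):(b * G)
      null_up[idx] <- exp(acc_up / K)
      null_dn[idx] <- exp(acc_dn / K)
    }
  }
  count_le <- function(obs, null) findInterval(obs, sort(null))
  tally <- function(obs, null) {
    c_obs <- pmax(count_le(obs, null), 1L)
    s <- rank(obs, ties.method = "average")
    p <- c_obs / (n_perm * G)
    list(p = p, pfp = (c_obs / n_perm) / s)
  }
  up <- tally(rp$rp_up, null_up)
  dn <- tally(rp$rp_down, null_dn)
  data.frame(gene = rownames(ratio_table),
             rp_up = unname(rp$rp_up), rp_down = unname(rp$rp_down),
             p_up = up$p, p_down = dn$p,
             pfp_up = up$pfp, pfp_down = dn$pfp,
             stringsAsFactors = FALSE)
}

#' Call differentially expressed genes from pfp values
#'
#' A gene is called up if pfp_up < `pfp_threshold` and pfp_up <= pfp_down
#' (symmetrically for down); an exact tie with both below threshold resolves
#' to none (and is messaged). The result gains a `call` column.
#'
#' @param de data.frame from [permutation_null()].
#' @param pfp_threshold pfp cutoff (default 0.05).
#' @return `de` with a `call` column in \{"up", "down", "none"\}.
#' @export
call_degs <- function(de, pfp_threshold = 0.05) {
  up <- de$pfp_up < pfp_threshold & de$pfp_up < de$pfp_down
  dn <- de$pfp_down < pfp_threshold & de$pfp_down < de$pfp_up
  tie <- de$pfp_up < pfp_threshold & de$pfp_down < pfp_threshold &
    de$pfp_up == de$pfp_down
  if (any(tie))
    message(sum(tie), " gene(s) significant in both directions with tied pfp; called none")
  de$call <- ifelse(up, "up", ifelse(dn, "down", "none"))
  de
}

#' Rank-product differential expression for one comparison
#'
#' Convenience driver: ratios, rank products, permutation null, calls.
#'
#' @param ds An `ExpressionDataset`.
#' @param disease_ids,control_ids Sample ids.
#' @param comparison_id Label attached to the result.
#' @param n_perm,seed,pfp_threshold Passed through.
#' @return A `DEResult` data.frame (attribute `comparison_id`).
#' @export
rankprod_de <- function(ds, disease_ids, control_ids,
                        comparison_id = "comparison",
                        n_perm = 100, seed = 1L, pfp_threshold = 0.05) {
  ratios <- pairwise_log_ratios(ds, disease_ids, control_ids)
  samples <- list(disease = ds$matrix[, disease_ids, drop = FALSE],
                  control = ds$matrix[, control_ids, drop = FALSE])
  de <- call_degs(permutation_null(ratios, n_perm = n_perm, seed = seed,
                                   samples = samples),
                  pfp_threshold = pfp_threshold)
  attr(de, "comparison_id") <- comparison_id
  class(de) <- c("DEResult", class(de))
  de
}

#' Rank-product differential expression across a compendium
#'
#' Runs [rankprod_de()] for every comparison; per-comparison seeds are
#' `seed + comparison index` so single comparisons can be reproduced in
#' isolation.
#'
#' @param comp An `ExpressionCompendium`.
#' @param n_perm,seed,pfp_threshold Passed through.
#' @return Named list of `DEResult` objects, one per comparison.
#' @export
rankprod_compendium <- function(comp, n_perm = 100, seed = 1L, pfp_threshold = 0.05) {
  stopifnot(inherits(comp, "ExpressionCompendium"))
  out <- list()
  for (i in seq_len(nrow(comp$comparisons))) {
    row <- comp$comparisons[i, ]
    ds <- comparison_dataset(comp, row$comparison_id)
    out[[row$comparison_id]] <- rankprod_de(
      ds, row$disease_ids[[1]], row$control_ids[[1]],
      comparison_id = row$comparison_id,
      n_perm = n_perm, seed = seed + i, pfp_threshold = pfp_threshold)
  }
  out
}
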
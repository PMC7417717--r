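# Tier 2: per-sample pre-ranked gene set enrichment.
#
# Each disease sample is contrasted against its dataset's control mean to
# give a per-gene ranking metric; the weighted Kolmogorov-Smirnov running-sum
# enrichment score (weight exponent 1, the classic "weighted" scheme) is
# computed for every pathway surviving the size/overlap filter, and nominal
# p-values come from gene permutation (random same-size sets). The null ES
# distribution depends only on the ranked metrics and the set size, so nulls
# are shared across same-size pathways within a sample.

#' Filter a gene set collection for analysis
#'
#' Sets named in `exclude` are dropped first; every set is intersected with
#' the analysis universe; sets outside \[`min_size`, `max_size`\] are dropped;
#' finally, scanning sets in descending-size order, any set whose overlap
#' coefficient |A∩B| / min(|A|, |B|) with an already-kept set exceeds
#' `overlap_cut` is dropped (the larger set wins, maximizing retained gene
#' coverage).
#'
#' @param coll A `GeneSetCollection`.
#' @param universe Character vector of measured genes.
#' @param min_size,max_size Size window after universe intersection.
#' @param overlap_cut Overlap-coefficient cutoff.
#' @param exclude Optional character vector of set names dropped a priori.
#' @return A `FilteredCollection`: list with `sets` (a `GeneSetCollection`
#'   whose sets are universe-intersected) and `dropped` (data.frame name,
#'   reason).
#' @export
filter_collection <- function(coll, universe, min_size = 5, max_size = 300,
                              overlap_cut = 0.8, exclude = NULL) {
  stopifnot(inherits(coll, "GeneSetCollection"), length(coll$sets) >= 1)
  dropped <- list()
  note <- function(name, reason)
    dropped[[length(dropped) + 1L]] <<- data.frame(name = name, reason = reason,
                                                   stringsAsFactors = FALSE)
  sets <- coll$sets
  for (nm in intersect(exclude, names(sets))) note(nm, "excluded")
  sets <- sets[setdiff(names(sets), exclude)]
  sets <- lapply(sets, intersect, universe)
  sz <- lengths(sets)
  for (nm in names(sets)[sz < min_size]) note(nm, "too small")
  for (nm in names(sets)[sz > max_size]) note(nm, "too large")
  sets <- sets[sz >= min_size & sz <= max_size]
  kept <- list()
  for (nm in names(sets)[order(lengths(sets), decreasing = TRUE)]) {
    s <- sets[[nm]]
    clash <- FALSE
    for (knm in names(kept)) {
      k <- kept[[knm]]
      if (length(intersect(s, k)) / min(length(s), length(k)) > overlap_cut) {
        note(nm, paste0("overlap>", overlap_cut, " with ", knm))
        clash <- TRUE
        break
      }
    }
    if (!clash) kept[[nm]] <- s
  }
  kept <- kept[intersect(names(sets), names(kept))]  # restore input order
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(name = character(0), reason = character(0))
  structure(list(sets = gene_set_collection(kept, provenance = coll$provenance),
                 dropped = dropped),
            class = "FilteredCollection")
}

#' @export
print.FilteredCollection <- function(x, ...) {
  cat(sprintf("FilteredCollection: %d kept, %d dropped\n",
              length(x$sets$sets), nrow(x$dropped)))
  invisible(x)
}

#' Per-sample ranking metric
#'
#' The metric for gene g is x\[g, sample\] minus the mean of x\[g, \] over the
#' dataset's control samples (a per-sample log2 fold change). Genes are
#' returned sorted by metric descending; exact metric ties break by gene
#' name so the ordering is reproducible.
#'
#' @param ds An `ExpressionDataset` with at least one control.
#' @param disease_sample A disease sample id in `ds`.
#' @return data.frame (gene, metric) sorted descending by metric.
#' @export
sample_metric <- function(ds, disease_sample) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  ctl <- ds$samples$sample_id[ds$samples$group == "control"]
  if (!length(ctl)) stop("no controls")
  if (!disease_sample %in% colnames(ds$matrix))
    stop("unknown sample: ", disease_sample)
  m <- ds$matrix[, disease_sample] - rowMeans(ds$matrix[, ctl, drop = FALSE])
  if (all(m == 0))
    warning("all metrics are zero for sample ", disease_sample,
            "; enrichment p-values will be meaningless")
  o <- order(-m, rownames(ds$matrix))
  data.frame(gene = rownames(ds$matrix)[o], metric = unname(m[o]),
             stringsAsFactors = FALSE)
}

# Enrichment score from hit positions only. Running sum rises by
# |m|^w / N_R at member genes and falls by 1/(N - N_H) elsewhere; between
# hits the sum decays linearly, so its extrema occur immediately after a hit
# or immediately before the next one — O(N_H) instead of O(N).
.es_from_positions <- function(abs_w, positions, N) {
  NH <- length(positions)
  o <- order(positions)
  pos <- positions[o]
  w <- abs_w[o]
  NR <- sum(w)
  if (NR == 0) {
    w <- rep(1, NH)           # all member metrics zero: equal hit increments
    NR <- NH
  }
  miss <- 1 / (N - NH)
  hitcum <- cumsum(w) / NR
  i <- seq_len(NH)
  after <- hitcum - (pos - i) * miss          # running sum at j = pos_i
  before <- c(0, hitcum[-NH]) - (pos - i) * miss  # at j = pos_i - 1
  lo <- min(before); hi <- max(after)
  if (hi >= -lo) hi else lo
}

#' Weighted KS enrichment score
#'
#' Walking the ranked list, members of the set increment the running sum by
#' |metric|^`weight_exponent` / N_R (N_R = total member weight) and
#' non-members decrement it by 1 / (N - N_H); the enrichment score is the
#' running-sum value of maximal absolute magnitude, signed (positive score =
#' set concentrated at the top). If every member metric is zero, equal hit
#' increments 1/N_H are used (with a warning).
#'
#' @param ranked data.frame from [sample_metric()] (gene, metric), sorted.
#' @param gene_set Character vector of member genes.
#' @param weight_exponent Metric weight exponent (default 1).
#' @return The enrichment score in \[-1, 1\].
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  N <- nrow(ranked)
  hit <- ranked$gene %in% gene_set
  NH <- sum(hit)
  if (NH == 0) stop("gene set does not intersect the ranked list")
  if (NH == N) stop("gene set covers the whole ranked list")
  pos <- which(hit)
  w <- abs(ranked$metric[pos])^weight_exponent
  if (sum(w) == 0)
    warning("all member metrics are zero; using equal hit increments")
  .es_from_positions(w, pos, N)
}

#' Gene-permutation nominal p-value for an enrichment score
#'
#' Draws `n_perm` random gene sets of the same size (without replacement)
#' from the ranked universe, computes their enrichment scores, and returns
#' the add-one-smoothed one-tailed p among same-signed nulls:
#' p = (1 + #\{same sign, |null| >= |observed|\}) / (1 + #\{same sign\}).
#' p = 1 when the observed score is 0 or no same-signed null exists.
#'
#' @param ranked data.frame from [sample_metric()].
#' @param gene_set_size Size of the observed set.
#' @param observed_es Observed enrichment score.
#' @param n_perm Number of random sets (default 1000).
#' @param seed Integer seed.
#' @param null_es Optional pre-computed null scores (overrides generation;
#'   used by the per-sample driver to share nulls across same-size sets).
#' @param weight_exponent Metric weight exponent (default 1).
#' @return Nominal p-value in (0, 1].
#' @export
gene_permutation_p <- function(ranked, gene_set_size, observed_es,
                               n_perm = 1000, seed = 1L, null_es = NULL,
                               weight_exponent = 1) {
  if (is.null(null_es)) {
    stopifnot(n_perm >= 1)
    null_es <- null_es_distribution(ranked, gene_set_size, n_perm, seed,
                                    weight_exponent)
  }
  if (observed_es == 0) return(1)
  same <- if (observed_es > 0) null_es > 0 else null_es < 0
  if (!any(same)) return(1)
  (1 + sum(abs(null_es[same]) >= abs(observed_es))) / (1 + sum(same))
}

#' Null enrichment-score distribution for a given set size
#'
#' @param ranked data.frame from [sample_metric()].
#' @param size Set size.
#' @param n_perm Number of random sets.
#' @param seed Integer seed.
#' @param weight_exponent Metric weight exponent.
#' @return Numeric vector of `n_perm` null scores.
#' @export
null_es_distribution <- function(ranked, size, n_perm, seed = 1L,
                                 weight_exponent = 1) {
  N <- nrow(ranked)
  stopifnot(size >= 1, size < N)
  absm <- abs(ranked$metric)^weight_exponent
  set.seed(seed)
  vapply(seq_len(n_perm), function(b) {
    pos <- sample.int(N, size)
    .es_from_positions(absm[pos], pos, N)
  }, numeric(1))
}

#' Per-sample enrichment over a filtered collection
#'
#' Computes the enrichment score and gene-permutation p for every pathway in
#' every disease sample of the compendium. Null distributions are shared
#' across same-size pathways within a sample (the null depends only on the
#' ranked metrics and the set size).
#'
#' @param comp An `ExpressionCompendium`.
#' @param filtered A `FilteredCollection` (or `GeneSetCollection`, taken
#'   as-is).
#' @param n_perm Gene permutations per (sample, set size) (default 1000).
#' @param seed Integer seed; per-sample seeds derive from it.
#' @param alpha Nominal significance level for the `significant` flag
#'   (default 0.05).
#' @return A `SampleEnrichment` data.frame: sample_id, condition, dataset_id,
#'   pathway, es, p, significant, direction.
#' @export
sample_enrichment <- function(comp, filtered, n_perm = 1000, seed = 1L,
                              alpha = 0.05) {
  stopifnot(inherits(comp, "ExpressionCompendium"))
  sets <- if (inherits(filtered, "FilteredCollection")) filtered$sets$sets
          else filtered$sets
  out <- list()
  sample_counter <- 0L
  for (i in seq_len(nrow(comp$comparisons))) {
    row <- comp$comparisons[i, ]
    ds <- comparison_dataset(comp, row$comparison_id)
    universe <- rownames(ds$matrix)
    local_sets <- lapply(sets, intersect, universe)
    local_sets <- local_sets[lengths(local_sets) >= 1 &
                             lengths(local_sets) < length(universe)]
    for (sid in row$disease_ids[[1]]) {
      sample_counter <- sample_counter + 1L
      ranked <- sample_metric(ds, sid)
      sizes <- sort(unique(lengths(local_sets)))
      nulls <- lapply(stats::setNames(sizes, sizes), function(s)
        null_es_distribution(ranked, s, n_perm, seed = seed + sample_counter))
      es <- vapply(local_sets, function(g) enrichment_score(ranked, g), numeric(1))
      p <- vapply(seq_along(local_sets), function(j)
        gene_permutation_p(ranked, length(local_sets[[j]]), es[j],
                           null_es = nulls[[as.character(length(local_sets[[j]]))]]),
        numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sid, condition = row$condition, dataset_id = row$dataset_id,
        pathway = names(local_sets), es = unname(es), p = p,
        significant = p < alpha,
        direction = ifelse(es > 0, "up", ifelse(es < 0, "down", "none")),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("SampleEnrichment", class(res))
  res
}
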
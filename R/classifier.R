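# Signature evaluation: pool every sample of every dataset into one feature
# matrix over a candidate gene list, run stratified 10-fold cross-validation
# with a random-forest classifier, and score the pooled out-of-fold
# predictions with ROC AUC. A random-gene baseline repeats the procedure on
# size-matched random signatures to show the consensus signature carries
# information beyond its size. Samples are pooled across datasets without
# batch correction, so absolute AUCs are optimistic under dataset
# confounding; the paired comparison against the size-matched baseline is
# the meaningful readout.

#' Build a pooled feature matrix for a gene signature
#'
#' Rows are all samples of all datasets; columns are the requested genes.
#' Genes absent from any dataset are dropped (and reported), mirroring the
#' requirement that a classifier feature be measured in every sample.
#'
#' @param comp An `ExpressionCompendium`.
#' @param genes Candidate gene list.
#' @return List: `features` (samples x genes matrix), `labels` (logical,
#'   TRUE = disease), `sample_ids`, `dropped` (genes not detected
#'   everywhere).
#' @export
build_feature_matrix <- function(comp, genes) {
  stopifnot(inherits(comp, "ExpressionCompendium"), length(genes) >= 1)
  common <- Reduce(intersect, lapply(comp$datasets, function(d) rownames(d$matrix)))
  keep <- intersect(genes, common)
  dropped <- setdiff(genes, keep)
  if (length(dropped))
    message(length(dropped), " gene(s) not detected in all datasets; dropped")
  if (!length(keep)) stop("no gene survives the detected-everywhere filter")
  blocks <- lapply(comp$datasets, function(d) t(d$matrix[keep, , drop = FALSE]))
  features <- do.call(rbind, blocks)
  labels <- unlist(lapply(comp$datasets, function(d) d$samples$group == "disease"),
                   use.names = FALSE)
  list(features = features, labels = labels,
       sample_ids = rownames(features), dropped = dropped)
}

#' Genes detected in every dataset of a compendium
#' @param comp An `ExpressionCompendium`.
#' @return Character vector of genes present in all dataset matrices.
#' @export
detected_everywhere <- function(comp) {
  sort(Reduce(intersect, lapply(comp$datasets, function(d) rownames(d$matrix))))
}

#' Cross-validated random-forest AUC
#'
#' Stratified random partition into `n_folds` parts (fold sizes within each
#' class differ by at most one); each part is scored by a forest trained on
#' the rest; the pooled out-of-fold scores give a single ROC AUC.
#'
#' @param features Samples x genes numeric matrix.
#' @param labels Logical vector (TRUE = disease) or "disease"/"control".
#' @param n_folds Number of folds (default 10).
#' @param n_trees Trees per forest (default 500).
#' @param mtry Features per split; default `floor(sqrt(ncol(features)))`.
#' @param min_node Minimum node size (default 1: grow to purity).
#' @param seed Integer seed (folds, bootstraps and splits all derive from it).
#' @return List: `auc`, `scores` (pooled out-of-fold, input order), `folds`
#'   (per-sample fold id).
#' @export
cv_auc <- function(features, labels, n_folds = 10, n_trees = 500,
                   mtry = NULL, min_node = 1, seed = 1L) {
  if (is.character(labels)) labels <- labels == "disease"
  n <- nrow(features)
  stopifnot(n == length(labels))
  if (n < n_folds) stop("fewer samples than folds")
  if (min(sum(labels), sum(!labels)) < n_folds)
    stop("a class has fewer samples than folds; stratification infeasible")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(features))))
  set.seed(seed)
  folds <- integer(n)
  for (cls in c(TRUE, FALSE)) {
    i <- which(labels == cls)
    folds[i] <- sample(rep_len(seq_len(n_folds), length(i)))
  }
  scores <- numeric(n)
  for (f in seq_len(n_folds)) {
    test <- folds == f
    scores[test] <- .rf_fit_predict(features[!test, , drop = FALSE],
                                    as.integer(labels[!test]),
                                    features[test, , drop = FALSE],
                                    as.integer(n_trees), as.integer(mtry),
                                    as.integer(min_node))
  }
  list(auc = roc_auc(scores, labels), scores = scores, folds = folds)
}

#' Random-gene baseline for a signature AUC
#'
#' Repeats [cv_auc()] on `n_repeats` random signatures of `k` genes drawn
#' without replacement from the genes detected in every dataset, and tests
#' (one-sample t) whether the null AUC distribution sits below the observed
#' signature AUC.
#'
#' @param comp An `ExpressionCompendium`.
#' @param k Signature size to match.
#' @param observed_auc AUC of the signature under evaluation.
#' @param n_repeats Number of random signatures (default 1000; >= 3 for the
#'   t-test).
#' @param n_folds,n_trees,seed Passed to [cv_auc()]; repeat r uses
#'   `seed + r`.
#' @return List: `null_aucs`, `mean`, `t_p` (NA with a message when
#'   `n_repeats` < 3).
#' @export
random_gene_baseline <- function(comp, k, observed_auc, n_repeats = 1000,
                                 n_folds = 10, n_trees = 500, seed = 1L) {
  pool <- detected_everywhere(comp)
  if (k > length(pool)) stop("k exceeds the candidate gene pool")
  set.seed(seed)
  draws <- replicate(n_repeats, sample(pool, k), simplify = FALSE)
  null_aucs <- vapply(seq_len(n_repeats), function(r) {
    fm <- build_feature_matrix(comp, draws[[r]])
    cv_auc(fm$features, fm$labels, n_folds = n_folds, n_trees = n_trees,
           seed = seed + r)$auc
  }, numeric(1))
  t_p <- if (n_repeats >= 3) {
    tryCatch(one_sample_t(null_aucs, observed_auc), error = function(e) {
      message("baseline t-test undefined (", conditionMessage(e), "); returning NA")
      NA_real_
    })
  } else {
    message("t-test needs >= 3 repeats; returning NA")
    NA_real_
  }
  list(null_aucs = null_aucs, mean = mean(null_aucs), t_p = t_p)
}
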
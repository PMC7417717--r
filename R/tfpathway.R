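# Tier 3: regulatory screening. Every (TF, frequent pathway) pair is tested
# for over-representation of the TF's targets among the pathway's genes with
# a one-sided Fisher's exact test; Benjamini-Hochberg correction is applied
# once across the whole grid of pairs, and an edge passes when the adjusted
# p is below q and the TF covers more than `ratio_cut` of the pathway.

#' Fisher enrichment of TF targets in one pathway
#'
#' The universe-restricted 2x2 table has a = |targets ∩ pathway| (within the
#' universe); the ratio is pathway coverage a / |pathway ∩ universe| — the
#' fraction of the pathway's (measured) genes the TF targets.
#'
#' @param tf_targets Character vector of the TF's target genes.
#' @param pathway_genes Character vector of pathway members.
#' @param universe Background gene universe.
#' @return List: `overlap`, `ratio`, `p`, `pathway_size` (within universe),
#'   `n_targets` (within universe).
#' @export
tf_pathway_test <- function(tf_targets, pathway_genes, universe) {
  pw <- intersect(pathway_genes, universe)
  if (!length(pw)) stop("pathway has no genes in the universe")
  tg <- intersect(tf_targets, universe)
  a <- length(intersect(tg, pw))
  b <- length(pw) - a
  c_ <- length(tg) - a
  d <- length(universe) - a - b - c_
  list(overlap = a, ratio = a / length(pw),
       p = fisher_greater(a, b, c_, d),
       pathway_size = length(pw), n_targets = length(tg))
}

#' Screen all TF x frequent-pathway pairs
#'
#' Tests every TF in the network against every frequent pathway, adjusts
#' p-values by Benjamini-Hochberg across the full grid jointly, and flags
#' passing edges (p_adj < `q` and ratio > `ratio_cut`). The default universe
#' is the union of all network target genes and all genes of the filtered
#' collection, so both table margins are drawn from the same population.
#'
#' @param net A `RegulatoryNetwork`.
#' @param frequent A `PathwayConsensus` (only rows with `frequent = TRUE`
#'   are screened) or a character vector of pathway names.
#' @param coll A `FilteredCollection` or `GeneSetCollection` providing
#'   pathway membership.
#' @param q Adjusted-p threshold (default 0.05).
#' @param ratio_cut Coverage-ratio threshold (default 0.2).
#' @param universe Optional explicit background universe.
#' @return A `TFPathwayScreen` data.frame: tf, pathway, overlap,
#'   pathway_size, n_targets, ratio, p, p_adj, pass. Attributes
#'   `mean_tfs_per_pathway` and `mean_pathways_per_tf` summarize passing
#'   edges (denominators: pathways/TFs with at least one passing edge).
#' @export
tf_pathway_screen <- function(net, frequent, coll, q = 0.05, ratio_cut = 0.2,
                              universe = NULL) {
  stopifnot(inherits(net, "RegulatoryNetwork"))
  if (!length(net$tf_index)) stop("empty network")
  sets <- if (inherits(coll, "FilteredCollection")) coll$sets$sets else coll$sets
  pw_names <- if (is.character(frequent)) frequent else
    frequent$pathway[frequent$frequent]
  pw_names <- intersect(pw_names, names(sets))
  if (!length(pw_names)) stop("no frequent pathway present in the collection")
  if (is.null(universe))
    universe <- union(unique(net$edges$target), unique(unlist(sets)))
  rows <- list()
  for (tf in names(net$tf_index)) {
    tg <- net$tf_index[[tf]]
    for (pw in pw_names) {
      t <- tf_pathway_test(tg, sets[[pw]], universe)
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, pathway = pw, overlap = t$overlap,
        pathway_size = t$pathway_size, n_targets = t$n_targets,
        ratio = t$ratio, p = t$p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p)
  res$pass <- res$p_adj < q & res$ratio > ratio_cut
  edges <- res[res$pass, ]
  attr(res, "mean_tfs_per_pathway") <-
    if (nrow(edges)) nrow(edges) / length(unique(edges$pathway)) else 0
  attr(res, "mean_pathways_per_tf") <-
    if (nrow(edges)) nrow(edges) / length(unique(edges$tf)) else 0
  class(res) <- c("TFPathwayScreen", class(res))
  res
}
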
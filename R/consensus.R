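# Consensus across comparisons and samples: frequently-DE genes (with
# majority direction), the DEG sharing profile, per-condition and
# compendium-wide pathway dysregulation frequencies, scatter coordinates for
# the up/down consensus plot, and flat-list enrichment helpers.

#' Gene-level consensus across comparisons
#'
#' Tallies, per gene, the number of comparisons calling it up and down. A
#' gene is a frequently differentially expressed gene (FDEG) when it is
#' called in at least `fdeg_min` comparisons (default: ceiling of 60% of the
#' number of comparisons — "more than 60%" with the conventional boundary
#' included, so 15 of 25 qualifies). FDEG direction is the majority call;
#' ties break by the sign of the gene's summed log-ratio-rank evidence
#' (sum over comparisons of rp_down - rp_up, positive = up), which mirrors
#' classifying a gene by where its ranks generally sit.
#'
#' @param de_results List of `DEResult` data.frames (one per comparison,
#'   unique comparison ids).
#' @param fdeg_min Minimum number of DE calls; default
#'   `ceiling(0.6 * length(de_results))`.
#' @return A `GeneConsensus` data.frame: gene, n_up, n_down, n_de, fdeg,
#'   direction ("up"/"down" for FDEGs, NA otherwise). Attribute
#'   `n_comparisons`.
#' @export
gene_consensus <- function(de_results, fdeg_min = NULL) {
  stopifnot(length(de_results) >= 1)
  ids <- vapply(de_results, function(d) attr(d, "comparison_id") %||% NA_character_, "")
  ids[is.na(ids)] <- names(de_results)[is.na(ids)]
  if (anyDuplicated(ids)) stop("duplicate comparison ids")
  n_comp <- length(de_results)
  if (is.null(fdeg_min)) fdeg_min <- ceiling(0.6 * n_comp)
  if (fdeg_min > n_comp) stop("fdeg_min exceeds the number of comparisons")
  genes <- sort(unique(unlist(lapply(de_results, `[[`, "gene"))))
  n_up <- n_down <- tilt <- stats::setNames(numeric(length(genes)), genes)
  for (d in de_results) {
    g <- d$gene
    n_up[g[d$call == "up"]] <- n_up[g[d$call == "up"]] + 1
    n_down[g[d$call == "down"]] <- n_down[g[d$call == "down"]] + 1
    tilt[g] <- tilt[g] + (d$rp_down - d$rp_up)
  }
  n_de <- n_up + n_down
  fdeg <- n_de >= fdeg_min
  direction <- ifelse(n_up > n_down, "up",
                      ifelse(n_down > n_up, "down",
                             ifelse(tilt >= 0, "up", "down")))
  if (any(fdeg & n_up == n_down))
    message(sum(fdeg & n_up == n_down),
            " FDEG direction tie(s) broken by summed rank evidence")
  res <- data.frame(gene = genes, n_up = unname(n_up), n_down = unname(n_down),
                    n_de = unname(n_de), fdeg = unname(fdeg),
                    direction = ifelse(fdeg, direction, NA_character_),
                    stringsAsFactors = FALSE)
  attr(res, "n_comparisons") <- n_comp
  class(res) <- c("GeneConsensus", class(res))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' DEG sharing profile
#'
#' Histogram of how many comparisons each DEG is shared by, plus the
#' fraction of DEGs shared by strictly more than each count.
#'
#' @param gc A `GeneConsensus`.
#' @return List: `histogram` (data.frame n_de, n_genes over DEGs only),
#'   `n_degs` (number of genes DE at least once), and `frac_gt(k)` — a
#'   function giving the fraction of DEGs with n_de > k.
#' @export
sharing_profile <- function(gc) {
  deg <- gc[gc$n_de > 0, ]
  tab <- table(deg$n_de)
  hist <- data.frame(n_de = as.integer(names(tab)), n_genes = as.integer(tab))
  n_degs <- nrow(deg)
  list(histogram = hist, n_degs = n_degs,
       frac_gt = function(k) sum(deg$n_de > k) / n_degs)
}

#' Per-condition pathway dysregulation
#'
#' A pathway is dysregulated in a condition iff it is significant in
#' strictly more than half of that condition's disease samples (pooled over
#' all of the condition's comparisons).
#'
#' @param enr A `SampleEnrichment` data.frame.
#' @return data.frame: condition, pathway, n_samples, n_significant,
#'   dysregulated.
#' @export
condition_dysregulation <- function(enr) {
  conds <- unique(enr$condition)
  out <- list()
  for (cond in conds) {
    e <- enr[enr$condition == cond, ]
    n_samples <- length(unique(e$sample_id))
    if (n_samples == 0) stop("condition with zero disease samples: ", cond)
    agg <- stats::aggregate(significant ~ pathway, data = e, FUN = sum)
    out[[cond]] <- data.frame(condition = cond, pathway = agg$pathway,
                              n_samples = n_samples,
                              n_significant = agg$significant,
                              dysregulated = agg$significant > n_samples / 2,
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Frequently dysregulated pathways across all disease samples
#'
#' Pools every disease sample; a pathway is frequent iff it is significant
#' in strictly more than `frac` of them. `n_up`/`n_down` count significant
#' samples by enrichment-score sign.
#'
#' @param enr A `SampleEnrichment` data.frame.
#' @param frac Frequency threshold (default 0.6).
#' @return A `PathwayConsensus` data.frame: pathway, n_significant, n_up,
#'   n_down, frequent. Attribute `n_samples`.
#' @export
frequent_pathways <- function(enr, frac = 0.6) {
  n_samples <- length(unique(enr$sample_id))
  stopifnot(n_samples >= 1)
  sig <- enr[enr$significant, ]
  pathways <- sort(unique(enr$pathway))
  n_sig <- n_up <- stats::setNames(integer(length(pathways)), pathways)
  tab <- table(factor(sig$pathway, levels = pathways))
  n_sig[] <- as.integer(tab)
  up_tab <- table(factor(sig$pathway[sig$es > 0], levels = pathways))
  n_up[] <- as.integer(up_tab)
  res <- data.frame(pathway = pathways, n_significant = unname(n_sig),
                    n_up = unname(n_up), n_down = unname(n_sig - n_up),
                    frequent = unname(n_sig > frac * n_samples),
                    stringsAsFactors = FALSE)
  attr(res, "n_samples") <- n_samples
  class(res) <- c("PathwayConsensus", class(res))
  res
}

#' Consensus scatter coordinates
#'
#' For each pathway, with M_up and N_down the proportions of disease samples
#' where it is significantly up- and down-regulated: x = M_up + N_down
#' (how often dysregulated at all) and y = M_up - N_down (direction balance).
#' Always x >= |y|.
#'
#' @param pc A `PathwayConsensus`.
#' @param n_samples Total disease samples; defaults to the attribute set by
#'   [frequent_pathways()].
#' @return data.frame: pathway, x, y, frequent.
#' @export
figure5_coords <- function(pc, n_samples = attr(pc, "n_samples")) {
  stopifnot(!is.null(n_samples), n_samples >= 1)
  m_up <- pc$n_up / n_samples
  n_down <- pc$n_down / n_samples
  data.frame(pathway = pc$pathway, x = m_up + n_down, y = m_up - n_down,
             frequent = pc$frequent, stringsAsFactors = FALSE)
}

#' Enrichment of one gene list in another
#'
#' One-sided Fisher's exact test of the overlap between a query and a
#' reference list within a universe.
#'
#' @param query,reference Gene sets (subsets of `universe`).
#' @param universe The measured gene universe.
#' @return List: `overlap` (count) and `p` (one-sided Fisher p).
#' @export
list_enrichment <- function(query, reference, universe) {
  if (!length(universe)) stop("empty universe")
  query <- intersect(query, universe)
  reference <- intersect(reference, universe)
  a <- length(intersect(query, reference))
  b <- length(setdiff(reference, query))
  c_ <- length(setdiff(query, reference))
  d <- length(universe) - a - b - c_
  list(overlap = a, p = fisher_greater(a, b, c_, d))
}

#' Over-representation analysis against a flat annotation collection
#'
#' Hypergeometric upper-tail test per term with Benjamini-Hochberg
#' adjustment across terms. Terms are flat gene lists; no ontology
#' propagation is performed (pre-propagate upstream if hierarchical
#' semantics are wanted).
#'
#' @param query Gene set of interest.
#' @param annotation A `GeneSetCollection` of terms.
#' @param universe Measured gene universe.
#' @param q Adjusted-p significance threshold (default 0.05).
#' @return data.frame: term, size, overlap, p, p_adj, significant — sorted
#'   by p.
#' @export
ora_annotate <- function(query, annotation, universe, q = 0.05) {
  stopifnot(inherits(annotation, "GeneSetCollection"), length(annotation$sets) >= 1)
  res <- lapply(names(annotation$sets), function(nm) {
    le <- list_enrichment(query, annotation$sets[[nm]], universe)
    data.frame(term = nm,
               size = length(intersect(annotation$sets[[nm]], universe)),
               overlap = le$overlap, p = le$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- bh_adjust(res$p)
  res$significant <- res$p_adj < q
  res[order(res$p), ]
}
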
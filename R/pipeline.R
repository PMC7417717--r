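# End-to-end orchestration: generate (or load) a compendium, then run the
# three tiers and the classifier from one config, writing every stage's
# table plus a run manifest into a single output directory. One global seed
# fans out to per-stage seeds via a fixed offset so any stage can be rerun
# in isolation; stage outputs on disk suffice to recompute downstream
# stages.

#' Pipeline configuration
#'
#' Thresholds default to the pipeline's canonical values: pfp < 0.05 for DE
#' calls, a gene is frequently DE at >= 60% of comparisons, a pathway is
#' dysregulated per condition at > 50% of its disease samples and frequent
#' at > 60% of all disease samples, GSEA nominal p < 0.05 with the
#' \[5, 300\] set-size window and 0.8 overlap pruning, and the TF screen
#' gates at BH-adjusted p < 0.05 with coverage ratio > 0.2.
#'
#' @param generator A `GeneratorConfig` for synthetic input, or NULL when
#'   `input_dir` is given.
#' @param input_dir Directory of on-disk inputs (as written by
#'   [write_compendium()]); overrides `generator`.
#' @param pfp_threshold,fdeg_fraction,condition_fraction,pathway_fraction,
#'   gsea_alpha,min_size,max_size,overlap_cut,tf_q,ratio_cut Thresholds.
#' @param de_n_perm,gsea_n_perm Permutation counts.
#' @param n_folds,n_trees,baseline_repeats Classifier settings.
#' @param run_classifier Whether to run the (comparatively slow) classifier
#'   stage.
#' @param exclude_pathways Optional names dropped before filtering.
#' @param seed Global integer seed.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(generator = generator_config(),
                            input_dir = NULL,
                            pfp_threshold = 0.05,
                            fdeg_fraction = 0.6,
                            condition_fraction = 0.5,
                            pathway_fraction = 0.6,
                            gsea_alpha = 0.05,
                            min_size = 5, max_size = 300, overlap_cut = 0.8,
                            tf_q = 0.05, ratio_cut = 0.2,
                            de_n_perm = 100, gsea_n_perm = 1000,
                            n_folds = 10, n_trees = 500, baseline_repeats = 50,
                            run_classifier = TRUE,
                            exclude_pathways = NULL,
                            seed = 1L) {
  cfg <- as.list(environment())
  fracs <- c(cfg$fdeg_fraction, cfg$condition_fraction, cfg$pathway_fraction)
  if (any(fracs <= 0 | fracs >= 1)) stop("fractions must lie in (0, 1)")
  counts <- c(cfg$de_n_perm, cfg$gsea_n_perm, cfg$n_folds, cfg$n_trees,
              cfg$baseline_repeats)
  if (any(counts <= 0)) stop("counts must be positive")
  if (cfg$pfp_threshold <= 0 || cfg$gsea_alpha <= 0 || cfg$tf_q <= 0)
    stop("significance thresholds must be positive")
  structure(cfg, class = "PipelineConfig")
}

.load_inputs <- function(input_dir) {
  sheet <- utils::read.delim(file.path(input_dir, "samples.tsv"),
                             stringsAsFactors = FALSE)
  keys <- unique(paste(sheet$dataset_id, sheet$tissue, sep = "|"))
  datasets <- lapply(keys, function(k) {
    stem <- gsub("|", "_", k, fixed = TRUE)
    read_expression(file.path(input_dir, paste0(stem, ".matrix.tsv")),
                    file.path(input_dir, paste0(stem, ".samples.tsv")))
  })
  list(compendium = expression_compendium(datasets),
       collection = read_gmt(file.path(input_dir, "pathways.gmt")),
       network = read_network(file.path(input_dir, "network.tsv")),
       truth = NULL)
}

#' Run the full three-tier pipeline
#'
#' @param cfg A `PipelineConfig`.
#' @param outdir Output directory (created; existing files overwritten).
#' @return Invisibly, a list with all in-memory stage results plus
#'   `manifest`; tables and the manifest JSON are written under `outdir`.
#' @export
run_pipeline <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage_seed <- function(i) cfg$seed + 1000L * i
  log_stage <- function(name, ...) message(sprintf("[%s] %s", name, sprintf(...)))
  manifest <- list(config = unclass(cfg), stages = list())

  # stage 1: inputs
  if (!is.null(cfg$input_dir)) {
    inputs <- .load_inputs(cfg$input_dir)
  } else {
    gen_cfg <- cfg$generator
    inputs <- generate_compendium(gen_cfg)
    write_compendium(inputs, file.path(outdir, "inputs"))
  }
  comp <- inputs$compendium
  n_samples_total <- sum(vapply(comp$datasets, function(d) ncol(d$matrix), 0L))
  log_stage("inputs", "%d datasets, %d comparisons, %d samples",
            length(comp$datasets), nrow(comp$comparisons), n_samples_total)
  manifest$stages$inputs <- list(datasets = length(comp$datasets),
                                 comparisons = nrow(comp$comparisons),
                                 samples = n_samples_total)

  # stage 2: rank-product DE per comparison
  de <- rankprod_compendium(comp, n_perm = cfg$de_n_perm,
                            seed = stage_seed(2), pfp_threshold = cfg$pfp_threshold)
  de_tab <- do.call(rbind, lapply(names(de), function(id)
    cbind(comparison_id = id, de[[id]])))
  write_result_table(de_tab, file.path(outdir, "de_results.tsv"))
  n_deg <- length(unique(de_tab$gene[de_tab$call != "none"]))
  log_stage("rankprod", "%d distinct DEGs across %d comparisons", n_deg, length(de))
  manifest$stages$rankprod <- list(degs = n_deg, comparisons = length(de))

  # stage 3: gene consensus
  fdeg_min <- ceiling(cfg$fdeg_fraction * length(de))
  gc <- gene_consensus(de, fdeg_min = fdeg_min)
  write_result_table(gc, file.path(outdir, "gene_consensus.tsv"))
  prof <- sharing_profile(gc)
  write_result_table(prof$histogram, file.path(outdir, "deg_sharing.tsv"))
  log_stage("consensus", "%d FDEGs (threshold %d of %d comparisons)",
            sum(gc$fdeg), fdeg_min, length(de))
  manifest$stages$gene_consensus <- list(fdegs = sum(gc$fdeg), fdeg_min = fdeg_min)

  # stage 4: collection filtering + per-sample enrichment
  universe <- sort(unique(unlist(lapply(comp$datasets,
                                        function(d) rownames(d$matrix)))))
  filt <- filter_collection(inputs$collection, universe,
                            min_size = cfg$min_size, max_size = cfg$max_size,
                            overlap_cut = cfg$overlap_cut,
                            exclude = cfg$exclude_pathways)
  enr <- sample_enrichment(comp, filt, n_perm = cfg$gsea_n_perm,
                           seed = stage_seed(4), alpha = cfg$gsea_alpha)
  write_result_table(enr, file.path(outdir, "sample_enrichment.tsv"))
  log_stage("gsea", "%d pathways kept, %d disease samples scored",
            length(filt$sets$sets), length(unique(enr$sample_id)))
  manifest$stages$gsea <- list(pathways = length(filt$sets$sets),
                               dropped = nrow(filt$dropped),
                               disease_samples = length(unique(enr$sample_id)))

  # stage 5: pathway consensus
  cond_dys <- condition_dysregulation(enr)
  write_result_table(cond_dys, file.path(outdir, "condition_dysregulation.tsv"))
  pc <- frequent_pathways(enr, frac = cfg$pathway_fraction)
  write_result_table(pc, file.path(outdir, "pathway_consensus.tsv"))
  write_result_table(figure5_coords(pc), file.path(outdir, "pathway_coords.tsv"))
  log_stage("pathways", "%d frequently dysregulated pathways", sum(pc$frequent))
  manifest$stages$pathway_consensus <- list(frequent = sum(pc$frequent))

  # stage 6: TF screen
  screen <- NULL
  if (sum(pc$frequent) > 0 && nrow(inputs$network$edges) > 0) {
    screen <- tf_pathway_screen(inputs$network, pc, filt,
                                q = cfg$tf_q, ratio_cut = cfg$ratio_cut)
    write_result_table(screen, file.path(outdir, "tf_pathway_screen.tsv"))
    write_result_table(screen[screen$pass, c("tf", "pathway")],
                       file.path(outdir, "tf_pathway_edges.tsv"))
    log_stage("tfscreen", "%d passing edges (%d TFs, %d pathways)",
              sum(screen$pass), length(unique(screen$tf[screen$pass])),
              length(unique(screen$pathway[screen$pass])))
    manifest$stages$tf_screen <- list(edges = sum(screen$pass))
  } else {
    log_stage("tfscreen", "skipped (no frequent pathway or empty network)")
    manifest$stages$tf_screen <- list(edges = 0L, skipped = TRUE)
  }

  # stage 7: classifier
  clf <- NULL
  if (isTRUE(cfg$run_classifier) && sum(gc$fdeg) > 0) {
    fm <- build_feature_matrix(comp, gc$gene[gc$fdeg])
    cv <- cv_auc(fm$features, fm$labels, n_folds = cfg$n_folds,
                 n_trees = cfg$n_trees, seed = stage_seed(7))
    base <- random_gene_baseline(comp, k = ncol(fm$features),
                                 observed_auc = cv$auc,
                                 n_repeats = cfg$baseline_repeats,
                                 n_folds = cfg$n_folds, n_trees = cfg$n_trees,
                                 seed = stage_seed(7) + 1L)
    clf <- list(features_used = colnames(fm$features), auc = cv$auc,
                null_mean = base$mean, t_p = base$t_p,
                null_aucs = base$null_aucs)
    jsonlite::write_json(clf[c("auc", "null_mean", "t_p")],
                         file.path(outdir, "classifier.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage("classifier", "signature AUC %.3f vs random-gene mean %.3f (t p = %.3g)",
              cv$auc, base$mean, base$t_p)
    manifest$stages$classifier <- clf[c("auc", "null_mean", "t_p")]
  }

  manifest$seed <- cfg$seed
  manifest$package_version <- as.character(utils::packageVersion("tritier"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(inputs = inputs, de = de, gene_consensus = gc,
                 sharing = prof, filtered = filt, enrichment = enr,
                 condition_dysregulation = cond_dys, pathway_consensus = pc,
                 tf_screen = screen, classifier = clf, manifest = manifest))
}

#' Read a pipeline config from JSON
#'
#' The JSON mirrors [pipeline_config()] arguments; a `generator` object, if
#' present, mirrors [generator_config()] arguments.
#'
#' @param path Path to the JSON config.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$generator))
    raw$generator <- do.call(generator_config, as.list(raw$generator))
  do.call(pipeline_config, raw)
}
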
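# Synthetic multi-aetiology compendia with planted structure.
#
# The generator states a world with the structure the analysis assumes:
# 11 aetiologies spread over 12 dataset/tissue strata giving 25 comparisons
# (mirroring the unbalanced public-compendium design the pipeline targets),
# Gaussian log2 intensities, a dedicated set of frequently differentially
# expressed genes, per-condition pathway shifts with a shared "core" of
# pathways active in every condition, and a TF->target network in which half
# the TFs are truly coupled to core pathways and half are decoys.

# default design: dataset, tissue, conditions (strata give 25 comparisons
# over 11 conditions, mimicking an unbalanced multi-study compendium)
.default_design <- function() {
  list(
    list(id = "DS01", tissue = "LV", conditions = "ICM"),
    list(id = "DS02", tissue = "LV", conditions = c("DCM", "ICM")),
    list(id = "DS03", tissue = "LV", conditions = c("DHF", "NDHF")),
    list(id = "DS04", tissue = "LV", conditions = "DCM"),
    list(id = "DS05", tissue = "LV", conditions = c("DCM", "ICM")),
    list(id = "DS06", tissue = "LV", conditions = c("DCM", "ARVC")),
    list(id = "DS06", tissue = "RV", conditions = c("DCM", "ARVC")),
    list(id = "DS07", tissue = "heart", conditions = c("ICM", "NICM")),
    list(id = "DS08", tissue = "heart", conditions = c("ICM", "IDCM")),
    list(id = "DS09", tissue = "LV", conditions = c("DCM", "ICM")),
    list(id = "DS10", tissue = "LV",
         conditions = c("ICM", "IDCM", "VCM", "HCM", "FDCM", "PPCM")),
    list(id = "DS11", tissue = "LV", conditions = "ICM"))
}

#' Configuration for the synthetic compendium generator
#'
#' Defaults describe the stated world used by the recovery benchmarks:
#' 2000 genes at baseline N(8, 2^2) log2 units with N(0, 0.5^2) sample noise;
#' 100 planted frequently-DE genes at +/-1.5 log2 fold change, each active in
#' a condition with probability 0.9; 100 pathways of 10-50 genes of which 15
#' are active per condition (10 shared "core" pathways plus 5
#' condition-specific ones) at a +/-1.0 log2 shift; 50 TFs of which half are
#' coupled to a core pathway (covering 30% of its genes) plus 30 random decoy
#' targets each.
#'
#' @param n_genes Number of genes in the shared universe.
#' @param disease_range,control_range Integer ranges the per-comparison
#'   disease and per-stratum control group sizes are drawn from.
#' @param baseline_mean,baseline_sd Per-gene baseline distribution (log2).
#' @param noise_sd Per-sample measurement noise (log2).
#' @param n_fdeg Number of planted frequently-DE genes.
#' @param fdeg_effect Planted log2 fold change for active FDEGs.
#' @param fdeg_condition_prob Probability a planted FDEG is active in a
#'   condition.
#' @param n_pathways Number of gene sets generated.
#' @param pathway_size_range Min/max genes per set.
#' @param n_active_pathways_per_condition Active pathways per condition
#'   (including the core).
#' @param n_core_pathways Pathways active in every condition; these are the
#'   pathways that can become frequently dysregulated compendium-wide.
#' @param pathway_effect Log2 shift added to members of an active pathway.
#' @param n_tfs Number of TFs; the first half are coupled to core pathways.
#' @param tf_pathway_coverage Fraction of the coupled pathway's genes a
#'   linked TF targets.
#' @param tf_random_targets Random decoy targets per TF.
#' @param missing_frac Fraction of genes missing from each dataset.
#' @param seed Integer seed; the whole compendium is reproducible from it.
#' @return A list of class `GeneratorConfig`.
#' @export
generator_config <- function(n_genes = 2000,
                             disease_range = c(4L, 20L),
                             control_range = c(4L, 16L),
                             baseline_mean = 8, baseline_sd = 2, noise_sd = 0.5,
                             n_fdeg = 100, fdeg_effect = 1.5,
                             fdeg_condition_prob = 0.9,
                             n_pathways = 100, pathway_size_range = c(10L, 50L),
                             n_active_pathways_per_condition = 15,
                             n_core_pathways = 10,
                             pathway_effect = 1.0,
                             n_tfs = 50, tf_pathway_coverage = 0.3,
                             tf_random_targets = 30,
                             missing_frac = 0.05,
                             seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_genes, cfg$n_fdeg, cfg$n_pathways, cfg$n_tfs,
              cfg$n_active_pathways_per_condition, cfg$n_core_pathways)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (cfg$fdeg_condition_prob < 0 || cfg$fdeg_condition_prob > 1 ||
      cfg$tf_pathway_coverage < 0 || cfg$tf_pathway_coverage > 1 ||
      cfg$missing_frac < 0 || cfg$missing_frac >= 1)
    stop("probabilities must be in [0, 1]")
  if (cfg$pathway_size_range[2] > cfg$n_genes)
    stop("pathway size exceeds gene count")
  if (cfg$pathway_size_range[1] < 5 || cfg$pathway_size_range[2] > 300)
    stop("pathway sizes must lie within the (5, 300) analysis window")
  if (cfg$n_core_pathways > cfg$n_active_pathways_per_condition)
    stop("core pathways cannot exceed active pathways per condition")
  structure(cfg, class = "GeneratorConfig")
}

#' Generate a synthetic compendium with ground truth
#'
#' Per gene g, baseline mu_g ~ N(baseline_mean, baseline_sd^2); every sample
#' value adds N(0, noise_sd^2) noise; disease samples of a condition add
#' +/-`fdeg_effect` for planted FDEGs active there (sign fixed per gene) and
#' +/-`pathway_effect` for members of that condition's active pathways (sign
#' fixed per pathway-condition pair). TFs in the first half of the roster
#' target `tf_pathway_coverage` of one core pathway plus random decoys; the
#' remaining TFs are pure decoys. Fully reproducible from `cfg$seed`.
#'
#' @param cfg A `GeneratorConfig`.
#' @return List with elements `compendium` (`ExpressionCompendium`),
#'   `collection` (`GeneSetCollection`), `network` (`RegulatoryNetwork`) and
#'   `truth` (the manifest: `fdeg_genes`, `fdeg_direction`, `fdeg_active`
#'   gene x condition matrix, `active_pathways` / `pathway_direction` per
#'   condition, `core_pathways`, `frequent_de_genes`, `tf_pathway_links`,
#'   `decoy_tfs`).
#' @export
generate_compendium <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  set.seed(cfg$seed)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  design <- .default_design()
  conditions <- unique(unlist(lapply(design, `[[`, "conditions")))

  mu <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  names(mu) <- genes

  # planted frequently-DE genes
  fdeg <- sample(genes, cfg$n_fdeg)
  fdeg_sign <- stats::setNames(sample(c(1, -1), cfg$n_fdeg, replace = TRUE), fdeg)
  fdeg_active <- matrix(stats::runif(cfg$n_fdeg * length(conditions)) < cfg$fdeg_condition_prob,
                        nrow = cfg$n_fdeg, dimnames = list(fdeg, conditions))

  # pathways: core set active everywhere, the rest condition-specific.
  # Members are drawn from the non-FDEG genes so the two planted mechanisms
  # stay orthogonal: an FDEG inside an always-active pathway would carry a
  # net effect different from the one the manifest records.
  sizes <- sample(seq(cfg$pathway_size_range[1], cfg$pathway_size_range[2]),
                  cfg$n_pathways, replace = TRUE)
  pnames <- sprintf("PW%03d", seq_len(cfg$n_pathways))
  non_fdeg <- setdiff(genes, fdeg)
  if (max(sizes) > length(non_fdeg)) stop("pathway size exceeds non-FDEG gene pool")
  sets <- stats::setNames(lapply(sizes, function(s) sample(non_fdeg, s)), pnames)
  core <- pnames[seq_len(cfg$n_core_pathways)]
  n_extra <- cfg$n_active_pathways_per_condition - cfg$n_core_pathways
  active_pathways <- lapply(stats::setNames(conditions, conditions), function(cond)
    c(core, sample(setdiff(pnames, core), n_extra)))
  pathway_direction <- lapply(active_pathways, function(ap)
    stats::setNames(sample(c(1, -1), length(ap), replace = TRUE), ap))

  # per-condition additive shift vector over the gene universe
  shift <- matrix(0, cfg$n_genes, length(conditions), dimnames = list(genes, conditions))
  for (cond in conditions) {
    act <- rownames(fdeg_active)[fdeg_active[, cond]]
    shift[act, cond] <- shift[act, cond] + cfg$fdeg_effect * fdeg_sign[act]
    for (pw in active_pathways[[cond]])
      shift[sets[[pw]], cond] <- shift[sets[[pw]], cond] +
        cfg$pathway_effect * pathway_direction[[cond]][pw]
  }

  datasets <- list()
  for (d in design) {
    present <- sort(sample(genes, round(cfg$n_genes * (1 - cfg$missing_frac))))
    n_ctl <- sample(seq(cfg$control_range[1], cfg$control_range[2]), 1)
    cols <- list(); info <- list()
    for (cond in d$conditions) {
      n_dis <- sample(seq(cfg$disease_range[1], cfg$disease_range[2]), 1)
      vals <- mu[present] + shift[present, cond] +
        matrix(stats::rnorm(length(present) * n_dis, 0, cfg$noise_sd), ncol = n_dis)
      colnames(vals) <- sprintf("%s.%s.%s.d%02d", d$id, d$tissue, cond, seq_len(n_dis))
      cols[[cond]] <- vals
      info[[cond]] <- data.frame(sample_id = colnames(vals), group = "disease",
                                 condition = cond, stringsAsFactors = FALSE)
    }
    ctl <- mu[present] +
      matrix(stats::rnorm(length(present) * n_ctl, 0, cfg$noise_sd), ncol = n_ctl)
    colnames(ctl) <- sprintf("%s.%s.ctl.c%02d", d$id, d$tissue, seq_len(n_ctl))
    mat <- do.call(cbind, c(cols, list(ctl)))
    rownames(mat) <- present
    samples <- rbind(do.call(rbind, info),
                     data.frame(sample_id = colnames(ctl), group = "control",
                                condition = "control", stringsAsFactors = FALSE))
    datasets[[length(datasets) + 1L]] <-
      expression_dataset(d$id, d$tissue, mat, samples)
  }
  comp <- expression_compendium(datasets)

  # regulatory network: linked TFs cover a core pathway, decoys are random
  tfs <- sprintf("TF%03d", seq_len(cfg$n_tfs))
  n_linked <- floor(cfg$n_tfs / 2)
  links <- data.frame(tf = character(0), pathway = character(0), stringsAsFactors = FALSE)
  edge_tf <- character(0); edge_tg <- character(0)
  for (i in seq_along(tfs)) {
    if (i <= n_linked) {
      pw <- core[((i - 1L) %% length(core)) + 1L]
      members <- sets[[pw]]
      planted <- sample(members, ceiling(cfg$tf_pathway_coverage * length(members)))
      decoys <- sample(setdiff(genes, planted), cfg$tf_random_targets)
      targets <- c(planted, decoys)
      links <- rbind(links, data.frame(tf = tfs[i], pathway = pw, stringsAsFactors = FALSE))
    } else {
      targets <- sample(genes, cfg$tf_random_targets)
    }
    edge_tf <- c(edge_tf, rep(tfs[i], length(targets)))
    edge_tg <- c(edge_tg, targets)
  }
  net <- regulatory_network(edge_tf, edge_tg)

  truth <- list(
    fdeg_genes = sort(fdeg),
    fdeg_direction = fdeg_sign,
    fdeg_active = fdeg_active,
    active_pathways = active_pathways,
    pathway_direction = pathway_direction,
    core_pathways = core,
    frequent_de_genes = sort(unique(c(fdeg, unlist(sets[core])))),
    tf_pathway_links = links,
    decoy_tfs = tfs[seq.int(n_linked + 1L, cfg$n_tfs)])

  list(compendium = comp,
       collection = gene_set_collection(sets, provenance = "synthetic"),
       network = net, truth = truth, config = cfg)
}

#' Generate a pure-noise comparison dataset
#'
#' A single dataset under the global null: every value is baseline + noise,
#' no planted effects. Used for calibration tests of the rank-product tier.
#'
#' @param n_genes,n_disease,n_control Positive counts.
#' @param seed Integer seed.
#' @param baseline_mean,baseline_sd,noise_sd As in [generator_config()].
#' @return An `ExpressionDataset` with condition "null".
#' @export
generate_null_comparison <- function(n_genes, n_disease, n_control, seed = 1L,
                                     baseline_mean = 8, baseline_sd = 2,
                                     noise_sd = 0.5) {
  stopifnot(n_genes > 0, n_disease > 0, n_control > 0)
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  mu <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  n <- n_disease + n_control
  mat <- mu + matrix(stats::rnorm(n_genes * n, 0, noise_sd), ncol = n)
  colnames(mat) <- c(sprintf("dis%02d", seq_len(n_disease)),
                     sprintf("ctl%02d", seq_len(n_control)))
  rownames(mat) <- genes
  samples <- data.frame(
    sample_id = colnames(mat),
    group = rep(c("disease", "control"), c(n_disease, n_control)),
    condition = rep(c("null", "control"), c(n_disease, n_control)),
    stringsAsFactors = FALSE)
  expression_dataset("NULLSIM", "none", mat, samples)
}

#' Write a generated compendium to a directory
#'
#' Writes per-dataset matrix TSVs, one pooled sample sheet, the GMT
#' collection, the edge list and the truth manifest (JSON).
#'
#' @param gen Output of [generate_compendium()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, `outdir`.
#' @export
write_compendium <- function(gen, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sheets <- list()
  for (key in names(gen$compendium$datasets)) {
    ds <- gen$compendium$datasets[[key]]
    stem <- gsub("|", "_", key, fixed = TRUE)
    write_expression(ds, file.path(outdir, paste0(stem, ".matrix.tsv")),
                     file.path(outdir, paste0(stem, ".samples.tsv")))
    sh <- ds$samples; sh$tissue <- ds$tissue; sh$dataset_id <- ds$dataset_id
    sheets[[key]] <- sh
  }
  utils::write.table(do.call(rbind, sheets), file.path(outdir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(gen$collection, file.path(outdir, "pathways.gmt"))
  write_network(gen$network, file.path(outdir, "network.tsv"))
  truth <- gen$truth
  truth$fdeg_active <- list(genes = rownames(truth$fdeg_active),
                            conditions = colnames(truth$fdeg_active),
                            active = truth$fdeg_active)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(outdir)
}
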
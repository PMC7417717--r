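#' @useDynLib tritier, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"

# ---- expression datasets -----------------------------------------------

#' Construct an expression dataset
#'
#' A dataset is one study/tissue stratum: a gene x sample matrix of
#' already-normalized log2 intensities plus a per-sample annotation. Values
#' are assumed normalized upstream; no normalization is performed here.
#' Duplicate gene rows are averaged on construction (the convention for
#' replicated probes mapping to the same symbol).
#'
#' @param dataset_id Dataset identifier.
#' @param tissue Tissue label.
#' @param mat Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids), log2 scale.
#' @param samples data.frame with columns `sample_id`, `group`
#'   ("disease"/"control") and `condition` (aetiology; ignored for controls).
#' @return An object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(dataset_id, tissue, mat, samples) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("matrix needs gene rownames and sample colnames")
  if (anyNA(mat) || any(!is.finite(mat))) stop("matrix values must be finite")
  req <- c("sample_id", "group", "condition")
  if (!all(req %in% names(samples))) stop("sample sheet needs columns: ", paste(req, collapse = ", "))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!setequal(samples$sample_id, colnames(mat)))
    stop("sample sheet and matrix columns disagree")
  samples <- samples[match(colnames(mat), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (!all(samples$group %in% c("disease", "control")))
    stop("group must be 'disease' or 'control'")
  if (sum(samples$group == "control") == 0) stop("no control samples")
  if (sum(samples$group == "disease") == 0) stop("no disease samples")
  if (anyDuplicated(rownames(mat))) {
    mat <- rowsum(mat, group = rownames(mat), reorder = FALSE) /
      as.vector(table(rownames(mat))[unique(rownames(mat))])
  }
  structure(list(dataset_id = dataset_id, tissue = tissue,
                 matrix = mat, samples = samples),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset %s [%s]: %d genes x %d samples (%d disease / %d control)\n",
              x$dataset_id, x$tissue, nrow(x$matrix), ncol(x$matrix),
              sum(x$samples$group == "disease"), sum(x$samples$group == "control")))
  invisible(x)
}

#' Read an expression dataset from a matrix TSV and a sample sheet
#'
#' The matrix TSV has a gene-id first column and one column per sample; the
#' sample sheet (TSV) has columns `sample_id`, `group`, `condition`, `tissue`,
#' `dataset_id`. Duplicate gene rows are averaged; row and column order is
#' otherwise preserved.
#'
#' @param matrix_path Path to the expression matrix TSV.
#' @param sample_sheet_path Path to the sample sheet TSV.
#' @return An `ExpressionDataset`.
#' @export
read_expression <- function(matrix_path, sample_sheet_path) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("matrix must have a gene column and >= 1 sample column")
  genes <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric cell in expression matrix")
  rownames(mat) <- genes
  sheet <- utils::read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "condition")
  if (!all(need %in% names(sheet))) stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  unknown <- setdiff(sheet$sample_id, colnames(mat))
  if (length(unknown)) stop("unknown sample id in sheet: ", paste(unknown, collapse = ", "))
  missing <- setdiff(colnames(mat), sheet$sample_id)
  if (length(missing)) stop("matrix sample missing from sheet: ", paste(missing, collapse = ", "))
  expression_dataset(
    dataset_id = if ("dataset_id" %in% names(sheet)) sheet$dataset_id[1] else "dataset",
    tissue = if ("tissue" %in% names(sheet)) sheet$tissue[1] else "tissue",
    mat = mat, samples = sheet[, intersect(c("sample_id", "group", "condition"), names(sheet))])
}

#' Write an expression dataset to a matrix TSV and a sample sheet TSV
#'
#' @param ds An `ExpressionDataset`.
#' @param matrix_path,sample_sheet_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(ds, matrix_path, sample_sheet_path) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  tab <- data.frame(gene = rownames(ds$matrix), ds$matrix,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  sheet <- ds$samples
  sheet$tissue <- ds$tissue
  sheet$dataset_id <- ds$dataset_id
  utils::write.table(sheet, sample_sheet_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, sample_sheet_path))
}

# ---- compendium --------------------------------------------------------

#' Assemble a compendium from expression datasets
#'
#' A compendium is an ordered list of datasets plus the derived comparison
#' table: one comparison per (dataset x condition x tissue) stratum,
#' contrasting that stratum's disease samples against the dataset's controls.
#'
#' @param datasets List of `ExpressionDataset` objects.
#' @return An `ExpressionCompendium` with elements `datasets` and
#'   `comparisons` (data.frame with list-columns `disease_ids`, `control_ids`).
#' @export
expression_compendium <- function(datasets) {
  stopifnot(length(datasets) >= 1, all(vapply(datasets, inherits, TRUE, "ExpressionDataset")))
  ids <- vapply(datasets, function(d) paste(d$dataset_id, d$tissue, sep = "|"), "")
  if (anyDuplicated(ids)) stop("duplicate dataset/tissue strata")
  names(datasets) <- ids
  rows <- list()
  for (d in datasets) {
    ctl <- d$samples$sample_id[d$samples$group == "control"]
    dis <- d$samples[d$samples$group == "disease", , drop = FALSE]
    for (cond in unique(dis$condition)) {
      rows[[length(rows) + 1L]] <- data.frame(
        comparison_id = paste(d$dataset_id, d$tissue, cond, sep = "|"),
        dataset_id = d$dataset_id, condition = cond, tissue = d$tissue,
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$disease_ids <- list(dis$sample_id[dis$condition == cond])
      rows[[length(rows)]]$control_ids <- list(ctl)
    }
  }
  comparisons <- do.call(rbind, rows)
  if (anyDuplicated(comparisons$comparison_id)) stop("duplicate comparison ids")
  structure(list(datasets = datasets, comparisons = comparisons),
            class = "ExpressionCompendium")
}

#' @export
print.ExpressionCompendium <- function(x, ...) {
  ns <- sum(vapply(x$datasets, function(d) ncol(d$matrix), 0L))
  cat(sprintf("ExpressionCompendium: %d datasets, %d comparisons, %d conditions, %d samples\n",
              length(x$datasets), nrow(x$comparisons),
              length(unique(x$comparisons$condition)), ns))
  invisible(x)
}

#' Dataset holding a given comparison
#' @param comp An `ExpressionCompendium`.
#' @param comparison_id One comparison id from `comp$comparisons`.
#' @return The `ExpressionDataset` the comparison lives in.
#' @export
comparison_dataset <- function(comp, comparison_id) {
  i <- match(comparison_id, comp$comparisons$comparison_id)
  if (is.na(i)) stop("unknown comparison id: ", comparison_id)
  row <- comp$comparisons[i, ]
  comp$datasets[[paste(row$dataset_id, row$tissue, sep = "|")]]
}

# ---- GMT gene set collections ------------------------------------------

#' Construct a gene set collection
#' @param sets Named list of character vectors (gene symbols).
#' @param provenance Free-text origin tag.
#' @return A `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, provenance = "unspecified") {
  if (is.null(names(sets)) || any(names(sets) == "")) stop("all sets must be named")
  if (anyDuplicated(names(sets))) stop("duplicate set name")
  sets <- lapply(sets, function(g) {
    g <- unique(as.character(g))
    if (any(is.na(g) | g == "")) stop("genes must be non-empty strings")
    g
  })
  structure(list(sets = sets, provenance = provenance), class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf("GeneSetCollection (%s): %d sets, sizes %d-%d\n",
              x$provenance, length(x$sets), if (length(sz)) min(sz) else 0L,
              if (length(sz)) max(sz) else 0L))
  invisible(x)
}

#' Read a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' name, description, gene, gene, ... Duplicate genes within a line are
#' deduplicated; empty lines are skipped.
#'
#' @param path Path to the GMT file.
#' @return A `GeneSetCollection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) stop("GMT line ", bad[1], " has fewer than 3 fields")
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms)) stop("duplicate set name: ", nms[duplicated(nms)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  gene_set_collection(sets, provenance = path)
}

#' Write a GMT file
#' @param coll A `GeneSetCollection`.
#' @param path Output path.
#' @param descriptions Optional named descriptions; defaults to "na".
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(coll, path, descriptions = NULL) {
  stopifnot(inherits(coll, "GeneSetCollection"))
  nms <- names(coll$sets)
  desc <- if (is.null(descriptions)) rep("na", length(nms)) else descriptions[nms]
  lines <- mapply(function(n, d, g) paste(c(n, d, g), collapse = "\t"),
                  nms, desc, coll$sets)
  writeLines(lines, path)
  invisible(path)
}

# ---- regulatory networks -----------------------------------------------

#' Construct a TF-target regulatory network
#' @param tf,target Parallel character vectors of regulator and target symbols.
#' @return A `RegulatoryNetwork` with a deduplicated `edges` data.frame and a
#'   `tf_index` (named list: TF -> character vector of targets).
#' @export
regulatory_network <- function(tf, target) {
  stopifnot(length(tf) == length(target))
  edges <- unique(data.frame(tf = as.character(tf), target = as.character(target),
                             stringsAsFactors = FALSE))
  rownames(edges) <- NULL
  tf_index <- if (nrow(edges)) split(edges$target, edges$tf) else
    structure(list(), names = character(0))
  structure(list(edges = edges, tf_index = tf_index), class = "RegulatoryNetwork")
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  cat(sprintf("RegulatoryNetwork: %d edges, %d TFs, %d targets\n",
              nrow(x$edges), length(x$tf_index), length(unique(x$edges$target))))
  invisible(x)
}

#' Read a regulatory edge list
#'
#' Two-column TSV (tf, target); extra columns are ignored; a header line
#' named `tf`/`target` (any case) is detected and skipped. Edges are
#' deduplicated.
#'
#' @param path Path to the edge list.
#' @return A `RegulatoryNetwork`.
#' @export
read_network <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(regulatory_network(character(0), character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (tolower(fields[[1]][1]) %in% c("tf", "regulator")) {
    fields <- fields[-1]
    if (!length(fields)) return(regulatory_network(character(0), character(0)))
  }
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) stop("malformed edge on line ", bad[1])
  regulatory_network(vapply(fields, `[[`, "", 1L), vapply(fields, `[[`, "", 2L))
}

#' Write a regulatory edge list
#' @param net A `RegulatoryNetwork`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "RegulatoryNetwork"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result table as TSV
#' @param tab A data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_result_table <- function(tab, path) {
  flat <- tab
  for (j in seq_along(flat)) if (is.list(flat[[j]]))
    flat[[j]] <- vapply(flat[[j]], paste, "", collapse = ",")
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
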
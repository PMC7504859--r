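#' Two-condition expression dataset
#'
#' Bundles a gene-by-sample expression matrix with a two-condition sample
#' design. The design declares which condition label is the baseline
#' (condition 1), so that "decreased" downstream always means a change from
#' baseline to the perturbed condition.
#'
#' @param matrix Numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns (colnames = sample identifiers). Values are assumed
#'   already normalized (e.g. log-scale FPKM); no missing values allowed.
#' @param design Named character vector mapping sample identifier to
#'   condition label; exactly two distinct labels, each with at least 3
#'   samples.
#' @param baseline Condition label treated as condition 1. Defaults to the
#'   label of the first sample in `design`.
#' @param name Free-text dataset name.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `matrix`, `design`, `baseline`, `perturbed`, `name`.
#' @export
expression_dataset <- function(matrix, design, baseline = NULL, name = "dataset") {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("expression must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("expression matrix must carry gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(matrix)))
    stop("format error: duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(colnames(matrix)))
    stop("format error: duplicate sample identifiers", call. = FALSE)
  if (anyNA(matrix))
    stop("format error: missing values in expression matrix", call. = FALSE)
  design <- design[!is.na(design)]
  missing_samples <- setdiff(colnames(matrix), names(design))
  if (length(missing_samples))
    stop("design error: samples absent from design: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  design <- design[colnames(matrix)]
  labels <- unique(design)
  if (length(labels) != 2L)
    stop("design error: exactly two condition labels required, got ",
         length(labels), call. = FALSE)
  counts <- table(design)
  if (any(counts < 3L))
    stop("design error: each condition needs >= 3 samples", call. = FALSE)
  if (is.null(baseline)) baseline <- design[[1L]]
  if (!baseline %in% labels)
    stop("design error: baseline label '", baseline, "' not in design", call. = FALSE)
  structure(
    list(matrix = matrix, design = design, baseline = baseline,
         perturbed = setdiff(labels, baseline), name = name),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset '%s': %d genes x %d samples (%s: %d baseline, %s: %d)\n",
              x$name, nrow(x$matrix), ncol(x$matrix),
              x$baseline, sum(x$design == x$baseline),
              x$perturbed, sum(x$design == x$perturbed)))
  invisible(x)
}

#' Samples belonging to one condition
#'
#' @param dataset An `ExpressionDataset`.
#' @param condition 1 for baseline, 2 for perturbed, or a condition label.
#' @return Sample identifiers.
#' @export
condition_samples <- function(dataset, condition) {
  label <- if (identical(condition, 1) || identical(condition, 1L)) dataset$baseline
           else if (identical(condition, 2) || identical(condition, 2L)) dataset$perturbed
           else condition
  names(dataset$design)[dataset$design == label]
}

#' Read an expression matrix and its sample design
#'
#' The expression file is tab-delimited with a header row of sample
#' identifiers and a first column named `gene`. The design file is a
#' two-column TSV `sample<TAB>condition` whose first line may be a comment
#' `# baseline: <label>` declaring condition 1; without it, the condition of
#' the first listed sample is taken as baseline.
#'
#' @param path Expression TSV path.
#' @param design_path Design TSV path.
#' @param name Dataset name; defaults to the expression file name.
#' @return A validated [expression_dataset()].
#' @export
read_expression <- function(path, design_path, name = basename(path)) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("format error: expression file needs a gene column plus samples", call. = FALSE)
  genes <- as.character(tab[[1L]])
  if (anyDuplicated(genes))
    stop("format error: duplicate gene identifiers in ", path, call. = FALSE)
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes

  lines <- readLines(design_path)
  baseline <- NULL
  header <- grep("^#", lines, value = TRUE)
  m <- regmatches(header, regexec("baseline:\\s*(\\S+)", header))
  hit <- vapply(m, length, 1L) == 2L
  if (any(hit)) baseline <- m[hit][[1L]][2L]
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(vapply(parts, length, 1L) < 2L))
    stop("format error: design file must be sample<TAB>condition", call. = FALSE)
  design <- vapply(parts, `[[`, "", 2L)
  names(design) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(design)))
    stop("format error: duplicate sample identifiers in design", call. = FALSE)
  if (is.null(baseline)) baseline <- design[[1L]]
  expression_dataset(mat, design, baseline = baseline, name = name)
}

#' Write an expression dataset to TSV files
#'
#' Inverse of [read_expression()]: values are written with full precision so
#' a read-write-read round trip is exact.
#'
#' @param dataset An `ExpressionDataset`.
#' @param path Expression TSV path.
#' @param design_path Design TSV path.
#' @export
write_expression <- function(dataset, path, design_path) {
  df <- data.frame(gene = rownames(dataset$matrix),
                   dataset$matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  con <- file(design_path, "w")
  on.exit(close(con))
  writeLines(sprintf("# baseline: %s", dataset$baseline), con)
  utils::write.table(data.frame(sample = names(dataset$design),
                                condition = unname(dataset$design)),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(path, design_path))
}

#' Collapse a transcript-level matrix to gene level by maximum median
#'
#' For each gene, the transcript with the largest cross-sample median
#' expression is retained; median ties are broken by first occurrence in file
#' order.
#'
#' @param matrix Transcript-by-sample numeric matrix.
#' @param mapping Named character vector transcript -> gene for every row.
#' @return Gene-by-sample matrix with one row per gene.
#' @export
collapse_to_genes <- function(matrix, mapping) {
  if (length(mapping) == 0L)
    stop("input error: empty transcript-to-gene mapping", call. = FALSE)
  transcripts <- rownames(matrix)
  if (!all(transcripts %in% names(mapping)))
    stop("input error: transcripts without a gene mapping", call. = FALSE)
  genes <- unname(mapping[transcripts])
  meds <- apply(matrix, 1L, stats::median)
  # which.max returns the first maximum, giving the file-order tie-break
  keep <- vapply(split(seq_along(genes), factor(genes, levels = unique(genes))),
                 function(idx) idx[which.max(meds[idx])], 1L)
  out <- matrix[keep, , drop = FALSE]
  rownames(out) <- unique(genes)
  out
}

#' Preprocessing configuration
#'
#' @param median_percentile_cut Fraction in `[0, 1)`: genes whose cross-sample
#'   median falls strictly below this percentile of all gene medians are
#'   dropped. Conventional values: 0.25 for microarray, 0.50 for RNA-seq.
#' @return A `PreprocessConfig` list.
#' @export
preprocess_config <- function(median_percentile_cut = 0.5) {
  if (median_percentile_cut < 0 || median_percentile_cut >= 1)
    stop("median_percentile_cut must be in [0, 1)", call. = FALSE)
  structure(list(median_percentile_cut = median_percentile_cut,
                 collapse_rule = "max-median"),
            class = "PreprocessConfig")
}

#' Filter genes by cross-sample median expression
#'
#' Removes genes whose cross-sample median falls strictly below the empirical
#' `median_percentile_cut` quantile of all gene medians, so a cut of 0.5
#' performs a median split (genes at or above the interpolated median are
#' kept) and a cut of 0 keeps everything. Raising the cut always keeps a
#' subset of what a lower cut keeps.
#'
#' @param dataset An `ExpressionDataset`.
#' @param cfg A [preprocess_config()].
#' @return The filtered `ExpressionDataset`.
#' @export
filter_by_median <- function(dataset, cfg = preprocess_config()) {
  meds <- apply(dataset$matrix, 1L, stats::median)
  cut <- stats::quantile(meds, cfg$median_percentile_cut, names = FALSE)
  keep <- meds >= cut
  if (!any(keep))
    stop("degenerate output: median filter removed all genes", call. = FALSE)
  expression_dataset(dataset$matrix[keep, , drop = FALSE], dataset$design,
                     baseline = dataset$baseline, name = dataset$name)
}

#' Analysis configuration
#'
#' Central knobs of the differential-coexpression pipeline.
#'
#' @param density Coexpression network density: fraction of all gene pairs
#'   retained as links (per condition, combined by OR). Default 0.1.
#' @param dcl_fraction A-priori fraction of differentially coexpressed links
#'   assumed by the limit-fold-change model. Default 0.1.
#' @param dcg_q_threshold BH-adjusted p cutoff for differentially coexpressed
#'   genes. Default 0.1.
#' @param n_perm_gsnca Label permutations for the pathway rewiring test.
#' @param n_perm_hub Permutations for the hub constancy/retention nulls.
#' @param pathway_p_threshold Per-dataset p cutoff used in the focused-pathway
#'   rule (default 0.01).
#' @param pathway_sig_threshold Looser per-dataset cutoff used for
#'   "significantly rewired" lists and overlap analyses (default 0.05).
#' @param crosstalk_p_threshold Raw p cutoff for crosstalk map edges.
#' @param rng_seed Integer seed used by every randomized operation.
#' @return An `AnalysisConfig` list.
#' @export
analysis_config <- function(density = 0.1, dcl_fraction = 0.1,
                            dcg_q_threshold = 0.1, n_perm_gsnca = 1000L,
                            n_perm_hub = 100L, pathway_p_threshold = 0.01,
                            pathway_sig_threshold = 0.05,
                            crosstalk_p_threshold = 0.05, rng_seed = 1L) {
  fracs <- c(density = density, dcl_fraction = dcl_fraction,
             dcg_q_threshold = dcg_q_threshold,
             pathway_p_threshold = pathway_p_threshold,
             pathway_sig_threshold = pathway_sig_threshold,
             crosstalk_p_threshold = crosstalk_p_threshold)
  bad <- fracs <= 0 | fracs > 1
  # density = 1 (all pairs) is a legitimate degenerate setting used in tests
  if (any(fracs[setdiff(names(fracs), "density")] >= 1) || any(bad))
    stop("config error: fractions must lie in (0, 1); density in (0, 1]",
         call. = FALSE)
  if (n_perm_gsnca < 10L || n_perm_hub < 10L)
    stop("config error: permutation counts must be >= 10", call. = FALSE)
  structure(list(density = density, dcl_fraction = dcl_fraction,
                 dcg_q_threshold = dcg_q_threshold,
                 n_perm_gsnca = as.integer(n_perm_gsnca),
                 n_perm_hub = as.integer(n_perm_hub),
                 pathway_p_threshold = pathway_p_threshold,
                 pathway_sig_threshold = pathway_sig_threshold,
                 crosstalk_p_threshold = crosstalk_p_threshold,
                 rng_seed = as.integer(rng_seed)),
            class = "AnalysisConfig")
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror [analysis_config()] and
#'   [preprocess_config()] arguments.
#' @return List with elements `analysis` and `preprocess`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  a_args <- intersect(names(raw), names(formals(analysis_config)))
  p_args <- intersect(names(raw), names(formals(preprocess_config)))
  list(analysis = do.call(analysis_config, raw[a_args]),
       preprocess = do.call(preprocess_config, raw[p_args]))
}
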
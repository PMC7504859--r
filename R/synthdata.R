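#' Synthetic two-condition expression data with planted correlation structure
#'
#' Generates multivariate-normal expression for two conditions whose
#' correlation matrices carry within-pathway blocks that attenuate (or hold,
#' or strengthen) between conditions, a designated hub gene per pathway with
#' elevated within-pathway correlation, and optional cross-pathway couplings
#' that decohere in the perturbed condition.
#'
#' @name synthdata
NULL

#' Synthetic-data configuration
#'
#' @param n_pathways Number of planted pathways.
#' @param genes_per_pathway Genes per pathway (default 15).
#' @param n_background_genes Uncorrelated background genes.
#' @param samples_per_condition Samples per condition (default 50).
#' @param rho_within Named list of length-2 correlation vectors
#'   (condition 1, condition 2) defining pathway classes, e.g.
#'   `list(attenuated = c(0.8, 0.1), null = c(0.8, 0.8))`.
#' @param pathway_classes Character vector (length `n_pathways`) assigning a
#'   class from `names(rho_within)` to each pathway; default all
#'   `"attenuated"`.
#' @param hub_boost Additive correlation advantage of the hub (first) gene of
#'   each pathway over the member-member correlation, capped at 0.99 total.
#' @param crosstalk_pairs List of couplings, each a list with fields `a`,
#'   `b` (pathway indices), `rho1`, `rho2` (between-pathway correlations per
#'   condition) and optionally `n_pairs` (number of one-to-one coupled gene
#'   pairs, default 3). Coupling is one-to-one (gene i of the coupled set in
#'   pathway a with gene i in pathway b): dense bicliques of strong
#'   cross-correlations over weakly correlated blocks are not representable
#'   by any valid correlation matrix.
#' @param noise_sd Marginal standard deviation of expression values.
#' @param rng_seed Integer seed; a fixed seed reproduces the output exactly.
#' @return A `SynthConfig` list.
#' @export
synth_config <- function(n_pathways = 6L, genes_per_pathway = 15L,
                         n_background_genes = 30L,
                         samples_per_condition = 50L,
                         rho_within = list(attenuated = c(0.8, 0.1)),
                         pathway_classes = NULL,
                         hub_boost = 0.2, crosstalk_pairs = list(),
                         noise_sd = 1, rng_seed = 1L) {
  if (is.null(pathway_classes))
    pathway_classes <- rep(names(rho_within)[1L], n_pathways)
  stopifnot(length(pathway_classes) == n_pathways,
            all(pathway_classes %in% names(rho_within)),
            all(unlist(rho_within) > -1), all(unlist(rho_within) < 1),
            samples_per_condition >= 3L, genes_per_pathway >= 3L)
  structure(list(n_pathways = as.integer(n_pathways),
                 genes_per_pathway = as.integer(genes_per_pathway),
                 n_background_genes = as.integer(n_background_genes),
                 samples_per_condition = as.integer(samples_per_condition),
                 rho_within = rho_within, pathway_classes = pathway_classes,
                 hub_boost = hub_boost, crosstalk_pairs = crosstalk_pairs,
                 noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
            class = "SynthConfig")
}

# eigenvalue-clipping repair to the nearest positive-definite correlation
# matrix: clip eigenvalues at eps, reconstruct, renormalize diagonal to 1
.repair_pd <- function(S, eps = 1e-6) {
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) > eps) return(S)
  vals <- pmax(ev$values, eps)
  R <- ev$vectors %*% (vals * t(ev$vectors))
  d <- sqrt(diag(R))
  R <- R / tcrossprod(d)
  diag(R) <- 1
  (R + t(R)) / 2
}

# build one condition's target correlation matrix
.target_corr <- function(cfg, condition) {
  gpp <- cfg$genes_per_pathway
  n_genes <- cfg$n_pathways * gpp + cfg$n_background_genes
  gene_names <- c(
    unlist(lapply(seq_len(cfg$n_pathways), function(i)
      sprintf("P%02d_G%02d", i, seq_len(gpp)))),
    if (cfg$n_background_genes > 0) sprintf("BG_G%03d", seq_len(cfg$n_background_genes)))
  S <- diag(n_genes)
  rownames(S) <- colnames(S) <- gene_names
  for (i in seq_len(cfg$n_pathways)) {
    rho <- cfg$rho_within[[cfg$pathway_classes[i]]][condition]
    block <- (i - 1L) * gpp + seq_len(gpp)
    S[block, block] <- rho
    # feasibility cap: with m equicorrelated members at rho, a hub-member
    # correlation h keeps the block PSD only if h^2 <= (1 + (m-1) rho) / m
    m <- gpp - 1L
    h_max <- sqrt((1 + (m - 1) * rho) / m) - 0.005
    hub_rho <- min(rho + cfg$hub_boost, 0.99, h_max)
    S[block[1L], block] <- hub_rho
    S[block, block[1L]] <- hub_rho
    diag(S)[block] <- 1
  }
  for (cp in cfg$crosstalk_pairs) {
    n_pairs <- if (is.null(cp$n_pairs)) 3L else cp$n_pairs
    rho <- if (condition == 1L) cp$rho1 else cp$rho2
    ga <- (cp$a - 1L) * gpp + 1L + seq_len(n_pairs)   # non-hub genes of pathway a
    gb <- (cp$b - 1L) * gpp + 1L + seq_len(n_pairs)
    for (k in seq_len(n_pairs)) {
      S[ga[k], gb[k]] <- rho
      S[gb[k], ga[k]] <- rho
    }
  }
  S
}

#' Generate a synthetic two-condition dataset with ground truth
#'
#' Samples each condition from a zero-mean multivariate normal whose
#' correlation matrix encodes the planted structure of `cfg`, after
#' eigenvalue-clipping repair to positive definiteness (generation fails if
#' the repair moves any entry by more than 0.02).
#'
#' @param cfg A [synth_config()].
#' @return List with `dataset` (an `ExpressionDataset`), `pathways` (list of
#'   [pathway()] records for the planted pathways), `truth` (list:
#'   `classes`, `hubs`, `coupled_pairs`, `target_corr1`, `target_corr2`).
#' @export
generate_synthetic <- function(cfg = synth_config()) {
  S1 <- .target_corr(cfg, 1L)
  S2 <- .target_corr(cfg, 2L)
  R1 <- .repair_pd(S1)
  R2 <- .repair_pd(S2)
  for (nm in c("R1", "R2")) {
    dev <- max(abs(get(nm) - get(sub("R", "S", nm))))
    if (dev > 0.02) {
      worst <- which(abs(get(nm) - get(sub("R", "S", nm))) == dev, arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "generation error: PD repair deviates %.3f at (%s, %s); correlation targets infeasible",
        dev, rownames(S1)[worst[1L]], colnames(S1)[worst[2L]]), call. = FALSE)
    }
  }
  n <- cfg$samples_per_condition
  set.seed(cfg$rng_seed)
  x1 <- MASS::mvrnorm(n, mu = rep(0, nrow(R1)), Sigma = R1)
  x2 <- MASS::mvrnorm(n, mu = rep(0, nrow(R2)), Sigma = R2)
  mat <- cbind(t(x1), t(x2)) * cfg$noise_sd
  rownames(mat) <- rownames(S1)
  samples <- c(sprintf("C1_S%03d", seq_len(n)), sprintf("C2_S%03d", seq_len(n)))
  colnames(mat) <- samples
  design <- stats::setNames(rep(c("cond1", "cond2"), each = n), samples)
  dataset <- expression_dataset(mat, design, baseline = "cond1",
                                name = "synthetic")

  gpp <- cfg$genes_per_pathway
  pws <- lapply(seq_len(cfg$n_pathways), function(i)
    pathway(sprintf("PW%02d", i),
            sprintf("P%02d_G%02d", i, seq_len(gpp)), source = "synthetic"))
  names(pws) <- vapply(pws, `[[`, "", "name")

  coupled <- lapply(cfg$crosstalk_pairs, function(cp) {
    n_pairs <- if (is.null(cp$n_pairs)) 3L else cp$n_pairs
    list(pathway_a = sprintf("PW%02d", cp$a), pathway_b = sprintf("PW%02d", cp$b),
         genes_a = sprintf("P%02d_G%02d", cp$a, 1L + seq_len(n_pairs)),
         genes_b = sprintf("P%02d_G%02d", cp$b, 1L + seq_len(n_pairs)),
         rho1 = cp$rho1, rho2 = cp$rho2)
  })
  truth <- list(classes = stats::setNames(cfg$pathway_classes, names(pws)),
                hubs = stats::setNames(sprintf("P%02d_G01", seq_len(cfg$n_pathways)),
                                       names(pws)),
                coupled_pairs = coupled,
                target_corr1 = R1, target_corr2 = R2)
  list(dataset = dataset, pathways = pws, truth = truth)
}

#' Synthetic compendium from generated pathways
#'
#' @param sim Output of [generate_synthetic()].
#' @param cfg A [compendium_config()]; bounds applied against the dataset's
#'   genes.
#' @return A `PathwayCompendium` over the planted pathways.
#' @export
synthetic_compendium <- function(sim, cfg = compendium_config()) {
  restrict_and_bound(sim$pathways, rownames(sim$dataset$matrix), cfg)
}

#' Label-exchangeable null companion of a dataset
#'
#' Randomly reassigns condition labels to samples, preserving group sizes —
#' gene-wise values are untouched, so any two-condition contrast becomes
#' null by construction.
#'
#' @param dataset An `ExpressionDataset`.
#' @param rng_seed Integer seed.
#' @return The relabeled `ExpressionDataset`.
#' @export
make_null_copy <- function(dataset, rng_seed = 1L) {
  set.seed(rng_seed)
  out <- dataset
  out$design[] <- dataset$design[sample.int(length(dataset$design))]
  out$name <- paste0(dataset$name, "_null")
  out
}

#' Write a synthetic dataset to the pipeline's file formats
#'
#' Emits the expression TSV and design TSV consumed by [read_expression()],
#' the GMT consumed by [read_gmt()], and a ground-truth YAML.
#'
#' @param sim Output of [generate_synthetic()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- file.path(dir, "expression.tsv")
  design <- file.path(dir, "design.tsv")
  gmt <- file.path(dir, "pathways.gmt")
  truth <- file.path(dir, "truth.yaml")
  write_expression(sim$dataset, expr, design)
  write_gmt(sim$pathways, gmt)
  yaml::write_yaml(list(classes = as.list(sim$truth$classes),
                        hubs = as.list(sim$truth$hubs),
                        coupled_pairs = sim$truth$coupled_pairs), truth)
  invisible(c(expr, design, gmt, truth))
}
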
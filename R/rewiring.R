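#' Pathway rewiring analysis
#'
#' Eigenvector-weight comparison of a pathway's correlation structure between
#' two conditions: per-condition gene weight vectors, an L1 weight-distance
#' statistic with label-permutation significance, hub extraction, and
#' union-of-two-MSTs wiring networks.
#'
#' @name rewiring
NULL

#' Eigenvector weight vector of a correlation matrix
#'
#' The weight of each gene summarizes its correlation profile against all
#' peer genes: w is the dominant eigenvector of A with A_ij = |r_ij| off the
#' diagonal and A_ii = 0, computed by power iteration (relative tolerance
#' 1e-10, at most 10000 iterations), sign-fixed positive and scaled so the
#' weights sum to the number of genes.
#'
#' @param corr_matrix Symmetric correlation matrix (p >= 3, unit diagonal).
#' @return Named positive weight vector of length p summing to p.
#' @export
weight_vector <- function(corr_matrix) {
  p <- nrow(corr_matrix)
  if (p < 3L) stop("need >= 3 genes for a weight vector", call. = FALSE)
  A <- abs(corr_matrix)
  diag(A) <- 0
  if (all(A == 0)) {
    warning("zero correlation matrix: uniform weights", call. = FALSE)
    w <- rep(1, p)
    names(w) <- rownames(corr_matrix)
    return(w)
  }
  w <- rep(1 / sqrt(p), p)
  for (i in seq_len(10000L)) {
    v <- drop(A %*% w)
    v <- v / sqrt(sum(v^2))
    if (max(abs(v - w)) <= 1e-10 * max(abs(w))) { w <- v; break }
    w <- v
  }
  w <- abs(w)                       # Perron vector of a nonnegative matrix
  w <- w * (p / sum(w))
  names(w) <- rownames(corr_matrix)
  w
}

# stable, platform-independent integer hash of a pathway name, < 2^31
.name_hash <- function(name) {
  codes <- utf8ToInt(name)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 1000000007
  as.integer(h %% 2147483647)
}

# L1 distance between aligned weight vectors
.weight_distance <- function(w1, w2) sum(abs(w1 - w2))

#' GSNCA-style rewiring test for one pathway
#'
#' Computes per-condition weight vectors over the pathway's genes, the L1
#' distance statistic d_obs, and a permutation p-value obtained by shuffling
#' condition labels over the pooled samples (group sizes preserved):
#' p = (1 + #\{d_perm >= d_obs\}) / (1 + n_perm). The permutation stream is
#' seeded from `cfg$rng_seed` plus a stable hash of the pathway name, so
#' results are reproducible and pathway-parallelizable. Also reports the
#' per-condition hub (maximum-weight gene, ties to the lexicographically
#' smallest) and the wiring networks.
#'
#' @param dataset An `ExpressionDataset`.
#' @param pw A [pathway()] record.
#' @param cfg An [analysis_config()].
#' @param wiring If `TRUE` (default) also compute per-condition MST-union
#'   wiring networks.
#' @return A `RewiringResult` list: `pathway`, `status` ("ok"/"skipped"),
#'   `d_obs`, `p`, `weights1`, `weights2`, `hub1`, `hub2`, `wiring1`,
#'   `wiring2`, `n_genes`.
#' @export
gsnca_test <- function(dataset, pw, cfg = analysis_config(), wiring = TRUE) {
  genes <- intersect(pw$genes, rownames(dataset$matrix))
  skipped <- function(reason) structure(
    list(pathway = pw$name, status = "skipped", reason = reason,
         d_obs = NA_real_, p = NA_real_, n_genes = length(genes)),
    class = "RewiringResult")
  if (length(genes) < 3L) return(skipped("fewer than 3 measured genes"))
  cc <- suppressWarnings(condition_correlations(dataset, genes))
  genes <- setdiff(genes, cc$dropped)
  if (length(genes) < 3L) return(skipped("fewer than 3 usable genes"))

  w1 <- weight_vector(cc$r1)
  w2 <- weight_vector(cc$r2)
  d_obs <- .weight_distance(w1, w2)

  x <- dataset$matrix[genes, , drop = FALSE]
  n1 <- length(condition_samples(dataset, 1L))
  n <- ncol(x)
  seed <- (cfg$rng_seed + .name_hash(pw$name)) %% 2147483647L
  exceed <- local({
    set.seed(seed)
    cnt <- 0L
    for (i in seq_len(cfg$n_perm_gsnca)) {
      idx <- sample.int(n)
      rp1 <- suppressWarnings(stats::cor(t(x[, idx[seq_len(n1)], drop = FALSE])))
      rp2 <- suppressWarnings(stats::cor(t(x[, idx[-seq_len(n1)], drop = FALSE])))
      if (anyNA(rp1) || anyNA(rp2)) next   # zero-variance split; counts as no exceedance
      dp <- .weight_distance(weight_vector(rp1), weight_vector(rp2))
      if (dp >= d_obs) cnt <- cnt + 1L
    }
    cnt
  })
  p <- (1 + exceed) / (1 + cfg$n_perm_gsnca)

  hub_of <- function(w) {
    cand <- names(w)[w == max(w)]
    sort(cand)[1L]
  }
  structure(list(
    pathway = pw$name, status = "ok", d_obs = d_obs, p = p,
    weights1 = w1, weights2 = w2,
    hub1 = hub_of(w1), hub2 = hub_of(w2),
    wiring1 = if (wiring) wiring_network(cc$r1) else NULL,
    wiring2 = if (wiring) wiring_network(cc$r2) else NULL,
    n_genes = length(genes)), class = "RewiringResult")
}

#' @export
print.RewiringResult <- function(x, ...) {
  if (x$status != "ok")
    cat(sprintf("RewiringResult '%s': skipped (%s)\n", x$pathway, x$reason))
  else
    cat(sprintf("RewiringResult '%s': d = %.4f, p = %.4g, hubs %s -> %s\n",
                x$pathway, x$d_obs, x$p, x$hub1, x$hub2))
  invisible(x)
}

# Kruskal MST over an edge table (gene_a < gene_b), deterministic tie-break
# by (distance, gene_a, gene_b); returns logical vector of tree membership.
# Yields the minimum spanning forest if the edge set is disconnected.
.kruskal <- function(edges, nodes) {
  parent <- seq_along(nodes)
  names(parent) <- nodes
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ord <- order(edges$dist, edges$gene_a, edges$gene_b, method = "radix")
  in_tree <- logical(nrow(edges))
  for (e in ord) {
    ra <- find(match(edges$gene_a[e], nodes))
    rb <- find(match(edges$gene_b[e], nodes))
    if (ra != rb) { parent[ra] <- rb; in_tree[e] <- TRUE }
  }
  in_tree
}

#' Wiring network: union of the first and second minimum spanning trees
#'
#' Over the complete graph on the pathway's genes with correlation distances
#' d = 1 - |r|, the first MST is computed by Kruskal's algorithm (edge ties
#' broken by (distance, gene_a, gene_b)); the second is the minimum spanning
#' forest of the complete graph minus the first tree's edges. The union spans
#' all genes and has 2(p - 1) edges whenever the residual graph is connected.
#'
#' @param corr_matrix Symmetric correlation matrix (p >= 3).
#' @return Data frame of edges: `gene_a`, `gene_b`, `abs_r`, `dist`, `tree`
#'   (1 or 2).
#' @export
wiring_network <- function(corr_matrix) {
  p <- nrow(corr_matrix)
  if (p < 3L) stop("need >= 3 genes for a wiring network", call. = FALSE)
  nodes <- rownames(corr_matrix)
  edges <- .pair_table(corr_matrix, corr_matrix)
  edges <- data.frame(gene_a = edges$gene_a, gene_b = edges$gene_b,
                      abs_r = abs(edges$r1), stringsAsFactors = FALSE)
  edges$dist <- 1 - edges$abs_r
  t1 <- .kruskal(edges, nodes)
  mst1 <- edges[t1, , drop = FALSE]
  mst1$tree <- 1L
  rest <- edges[!t1, , drop = FALSE]
  if (p == 3L) {
    warning("3-gene pathway: residual graph disconnected, returning first MST only",
            call. = FALSE)
    return(mst1)
  }
  t2 <- .kruskal(rest, nodes)
  mst2 <- rest[t2, , drop = FALSE]
  mst2$tree <- 2L
  out <- rbind(mst1, mst2)
  rownames(out) <- NULL
  out
}

#' Classify a pathway's dissolution status from its internal DCLs
#'
#' Among DCLs with both endpoints in the pathway, counts pairs whose
#' correlation moved down (|r2| < |r1|, with sign-switch pairs counted as
#' decreased when |r2| <= |r1|) versus up. More decreased than increased is
#' `dissolved`, the reverse `consolidated`, an exact tie (including zero
#' DCLs) `maintained`.
#'
#' @param pw A [pathway()] record.
#' @param links Output of [call_dcls()].
#' @param tolerance Half-width of the tie band on the count difference
#'   (default 0: exact tie only).
#' @return List: `class`, `n_dec`, `n_inc`, `n_dcl`.
#' @export
classify_dissolution <- function(pw, links, tolerance = 0L) {
  intra <- links$is_dcl & links$gene_a %in% pw$genes & links$gene_b %in% pw$genes
  d <- links[intra, , drop = FALSE]
  sw <- .sgn(d$r1) != .sgn(d$r2)
  dec <- ifelse(sw, abs(d$r2) <= abs(d$r1), abs(d$r2) < abs(d$r1))
  n_dec <- sum(dec); n_inc <- sum(!dec)
  cls <- if (abs(n_dec - n_inc) <= tolerance) "maintained"
         else if (n_dec > n_inc) "dissolved" else "consolidated"
  list(class = cls, n_dec = n_dec, n_inc = n_inc, n_dcl = nrow(d))
}

#' Rewiring tests over a whole compendium
#'
#' @param dataset An `ExpressionDataset`.
#' @param compendium A `PathwayCompendium`.
#' @param cfg An [analysis_config()].
#' @param links Optional [call_dcls()] output; when supplied, each pathway
#'   also receives a dissolution class.
#' @param wiring Compute wiring networks (default FALSE at compendium scale).
#' @return List with `results` (per-pathway `RewiringResult`) and `table`
#'   (data frame: pathway, size, d_obs, p, hub1, hub2, dissolution).
#' @export
rewire_compendium <- function(dataset, compendium, cfg = analysis_config(),
                              links = NULL, wiring = FALSE) {
  res <- lapply(compendium$pathways, gsnca_test, dataset = dataset,
                cfg = cfg, wiring = wiring)
  tab <- data.frame(
    pathway = vapply(res, `[[`, "", "pathway"),
    size = vapply(res, function(r) as.integer(r$n_genes), 1L),
    d_obs = vapply(res, `[[`, 1, "d_obs"),
    p = vapply(res, `[[`, 1, "p"),
    hub1 = vapply(res, function(r) if (r$status == "ok") r$hub1 else NA_character_, ""),
    hub2 = vapply(res, function(r) if (r$status == "ok") r$hub2 else NA_character_, ""),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(links)) {
    tab$dissolution <- vapply(compendium$pathways, function(pw)
      classify_dissolution(pw, links)$class, "")
  }
  list(results = res, table = tab)
}
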
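#' Multi-dataset aggregation and reproducibility analysis
#'
#' Fisher's combined probability test, focused-pathway selection,
#' hypergeometric overlap significance of result lists, and top-k agreement
#' curves.
#'
#' @name meta
NULL

#' Fisher's combined probability test
#'
#' chi2 = -2 sum(log p_i), referred to a chi-square distribution with 2k
#' degrees of freedom (upper tail). Zeros are clamped to the permutation
#' floor 1/(n_perm + 1) with a warning.
#'
#' @param p_values Vector of k per-dataset p-values in (0, 1].
#' @param n_perm Permutation count defining the clamp floor for zeros.
#' @return The aggregate p-value.
#' @export
fisher_combined <- function(p_values, n_perm = 1000L) {
  if (!length(p_values)) stop("input error: no p-values", call. = FALSE)
  if (any(p_values == 0)) {
    warning("zero p-value(s) clamped to permutation floor 1/(n_perm+1)",
            call. = FALSE)
    p_values[p_values == 0] <- 1 / (n_perm + 1)
  }
  if (any(p_values < 0 | p_values > 1))
    stop("input error: p-values must lie in (0, 1]", call. = FALSE)
  chi2 <- -2 * sum(log(p_values))
  stats::pchisq(chi2, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Aggregate per-dataset rewiring p-values and select focused pathways
#'
#' A pathway is focused iff it is significant (p below
#' `cfg$pathway_p_threshold`) in at least two individual datasets AND its
#' Fisher-aggregate p is below the same threshold. Skipped per-dataset tests
#' are treated as p = 1 (conservative), keeping the degrees of freedom
#' constant across pathways.
#'
#' @param p_matrix Numeric matrix of per-dataset p-values: rows = pathways
#'   (rownames required), columns = datasets. NAs mean a skipped test.
#' @param cfg An [analysis_config()].
#' @return Data frame ordered by increasing aggregate p: pathway, the
#'   per-dataset columns, `chi2`, `aggregate_p`, `focused`.
#' @export
select_focused <- function(p_matrix, cfg = analysis_config()) {
  if (is.null(rownames(p_matrix))) stop("p_matrix needs pathway rownames", call. = FALSE)
  pm <- p_matrix
  pm[is.na(pm)] <- 1
  agg <- apply(pm, 1L, fisher_combined, n_perm = cfg$n_perm_gsnca)
  chi2 <- -2 * rowSums(log(pm))
  n_sig <- rowSums(pm < cfg$pathway_p_threshold)
  out <- data.frame(pathway = rownames(pm), pm, chi2 = chi2,
                    aggregate_p = agg,
                    focused = n_sig >= 2L & agg < cfg$pathway_p_threshold,
                    stringsAsFactors = FALSE, row.names = NULL,
                    check.names = FALSE)
  out[order(out$aggregate_p, out$pathway), , drop = FALSE]
}

#' Hypergeometric overlap significance of two result lists
#'
#' p = P(X >= shared) for X ~ Hypergeometric drawing `list_b_size` items
#' from a universe of `universe_size` containing `list_a_size` successes.
#'
#' @param universe_size,list_a_size,list_b_size,shared Counts with
#'   0 <= shared <= min(a, b) <= universe_size.
#' @return Upper-tail p-value.
#' @export
overlap_significance <- function(universe_size, list_a_size, list_b_size, shared) {
  if (shared < 0 || shared > min(list_a_size, list_b_size) ||
      max(list_a_size, list_b_size) > universe_size)
    stop("input error: inconsistent counts", call. = FALSE)
  stats::phyper(shared - 1, list_a_size, universe_size - list_a_size,
                list_b_size, lower.tail = FALSE)
}

#' Number of unordered gene pairs
#'
#' @param n_genes Gene count (>= 2).
#' @return n(n-1)/2.
#' @export
pairs_universe <- function(n_genes) {
  if (n_genes < 2) stop("input error: need >= 2 genes", call. = FALSE)
  n_genes * (n_genes - 1) / 2
}

#' Top-k agreement between dataset rankings
#'
#' For each pair of datasets and each k in `k_grid`, computes the
#' hypergeometric tail p of the overlap between the two top-k pathway lists
#' (rank ties at k broken by pathway name). The resulting matrix (rows = k,
#' columns = dataset pairs) is suitable for a log10(p) heatmap.
#'
#' @param rankings Named list of numeric vectors: per-dataset p-values named
#'   by pathway, over a common pathway universe.
#' @param k_grid Integer vector of list sizes (default seq(5, 150, by = 5)).
#' @return Numeric matrix of overlap p-values.
#' @export
topk_agreement <- function(rankings, k_grid = seq(5L, 150L, by = 5L)) {
  univ <- sort(names(rankings[[1L]]))
  for (r in rankings) stopifnot(setequal(names(r), univ))
  N <- length(univ)
  if (any(k_grid > N)) {
    warning("k values above the universe size clipped", call. = FALSE)
    k_grid <- unique(pmin(k_grid, N))
  }
  top <- lapply(rankings, function(r) names(r)[order(r, names(r), method = "radix")])
  pairs <- utils::combn(names(rankings), 2L)
  out <- matrix(NA_real_, length(k_grid), ncol(pairs),
                dimnames = list(as.character(k_grid),
                                apply(pairs, 2L, paste, collapse = " vs ")))
  for (j in seq_len(ncol(pairs))) {
    ta <- top[[pairs[1L, j]]]; tb <- top[[pairs[2L, j]]]
    for (i in seq_along(k_grid)) {
      k <- k_grid[i]
      out[i, j] <- overlap_significance(N, k, k,
                                        length(intersect(ta[seq_len(k)],
                                                         tb[seq_len(k)])))
    }
  }
  out
}
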
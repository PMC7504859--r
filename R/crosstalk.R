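#' Pathway crosstalk disruption on a differential-coexpression scaffold
#'
#' Builds a global gene-gene scaffold from correlation-decreased DCLs and
#' tests every focused-pathway pair for over-representation of inter-pathway
#' scaffold edges with a hypergeometric tail (CSPN-style), emitting a
#' disrupted-crosstalk map.
#'
#' @name crosstalk
NULL

#' Build the differential-coexpression scaffold
#'
#' `decreased_only` keeps DCLs of category `decreased_positive` plus
#' `diff_signed` DCLs with |r2| < |r1| — the links whose correlation was lost
#' from condition 1 to condition 2.
#'
#' @param links Output of [call_dcls()], or a list of such outputs for
#'   `mode = "union"` across datasets.
#' @param mode `"decreased_only"` (default) or `"union"` (union of
#'   decreased-only scaffolds from several datasets).
#' @param universe Gene universe the scaffold lives on; defaults to all genes
#'   appearing in the pair table(s).
#' @return A `Scaffold` list: `edges` (data frame gene_a, gene_b),
#'   `universe`, `n_edges`.
#' @export
build_scaffold <- function(links, mode = c("decreased_only", "union"),
                           universe = NULL) {
  mode <- match.arg(mode)
  pick <- function(df) {
    keep <- df$is_dcl & (df$category == "decreased_positive" |
                           (df$category == "diff_signed" & abs(df$r2) < abs(df$r1)))
    df[keep, c("gene_a", "gene_b"), drop = FALSE]
  }
  if (mode == "union") {
    stopifnot(is.list(links), !is.data.frame(links))
    edges <- unique(do.call(rbind, lapply(links, pick)))
    all_genes <- unique(unlist(lapply(links, function(df) c(df$gene_a, df$gene_b))))
  } else {
    edges <- pick(links)
    all_genes <- unique(c(links$gene_a, links$gene_b))
  }
  if (!nrow(edges))
    stop("degenerate output: empty scaffold (no correlation-decreased DCLs)",
         call. = FALSE)
  if (is.null(universe)) universe <- sort(all_genes)
  stopifnot(all(edges$gene_a %in% universe), all(edges$gene_b %in% universe))
  edges <- edges[order(edges$gene_a, edges$gene_b, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, universe = universe, n_edges = nrow(edges)),
            class = "Scaffold")
}

#' @export
print.Scaffold <- function(x, ...) {
  cat(sprintf("Scaffold: %d edges over %d genes\n", x$n_edges,
              length(x$universe)))
  invisible(x)
}

#' Hypergeometric crosstalk test for one pathway pair
#'
#' Shared genes are removed from both pathways; with A' and B' the disjoint
#' remainders (restricted to the scaffold universe), the number of scaffold
#' edges joining A' and B' is referred to a hypergeometric null: drawing
#' |A'| * |B'| pair slots from the population of all C(|universe|, 2) gene
#' pairs, of which the scaffold occupies `n_edges`.
#'
#' @param scaffold A [build_scaffold()] result.
#' @param pw_a,pw_b [pathway()] records.
#' @param p_threshold Significance cutoff recorded on the result.
#' @return A `CrosstalkEdge` list: `pathway_a`, `pathway_b`, `status`,
#'   `n_possible`, `n_observed`, `p`, `significant`, `links` (the observed
#'   inter-pathway edges).
#' @export
crosstalk_test <- function(scaffold, pw_a, pw_b, p_threshold = 0.05) {
  a <- intersect(pw_a$genes, scaffold$universe)
  b <- intersect(pw_b$genes, scaffold$universe)
  shared <- intersect(a, b)
  a <- setdiff(a, shared); b <- setdiff(b, shared)
  out <- list(pathway_a = pw_a$name, pathway_b = pw_b$name, status = "ok",
              n_possible = NA_real_, n_observed = NA_integer_,
              p = NA_real_, significant = NA, links = NULL)
  if (!length(a) || !length(b)) {
    out$status <- "skipped"
    return(structure(out, class = "CrosstalkEdge"))
  }
  e <- scaffold$edges
  between <- (e$gene_a %in% a & e$gene_b %in% b) |
             (e$gene_a %in% b & e$gene_b %in% a)
  n_possible <- length(a) * length(b)
  n_observed <- sum(between)
  N <- pairs_universe(length(scaffold$universe))
  p <- stats::phyper(n_observed - 1, scaffold$n_edges, N - scaffold$n_edges,
                     n_possible, lower.tail = FALSE)
  out$n_possible <- n_possible
  out$n_observed <- n_observed
  out$p <- p
  out$significant <- p < p_threshold
  out$links <- e[between, , drop = FALSE]
  structure(out, class = "CrosstalkEdge")
}

#' Disrupted-crosstalk map over the focused pathways
#'
#' Tests every unordered pair of focused pathways with [crosstalk_test()],
#' keeps the significant edges, and assembles the contributing cross-pathway
#' gene links plus a filtered gene subnetwork restricted to links incident
#' to a differentially coexpressed gene or a hub gene.
#'
#' @param scaffold A [build_scaffold()] result.
#' @param focused Named list of [pathway()] records (the focused pathways).
#' @param cfg An [analysis_config()] (supplies `crosstalk_p_threshold`).
#' @param dcgs Optional DCG table; used to flag nodes in the subnetwork.
#' @param hubs Optional character vector of hub genes.
#' @param adjust If TRUE, apply Benjamini-Hochberg to the pairwise p-values
#'   before thresholding (off by default; the map is conventionally built on
#'   raw p).
#' @return A `CrosstalkMap` list: `edges` (data frame pathway_a, pathway_b,
#'   n_possible, n_observed, p, significant), `gene_links` (contributing
#'   links of significant pairs), `subnetwork` (links incident to DCGs or
#'   hubs), `n_significant`.
#' @export
crosstalk_map <- function(scaffold, focused, cfg = analysis_config(),
                          dcgs = NULL, hubs = NULL, adjust = FALSE) {
  if (!length(focused)) stop("input error: empty focused list", call. = FALSE)
  nms <- vapply(focused, `[[`, "", "name")
  rows <- list(); glinks <- list()
  if (length(focused) >= 2L) {
    idx <- utils::combn(seq_along(focused), 2L)
    for (j in seq_len(ncol(idx))) {
      ct <- crosstalk_test(scaffold, focused[[idx[1L, j]]], focused[[idx[2L, j]]],
                           p_threshold = cfg$crosstalk_p_threshold)
      if (ct$status != "ok") next
      rows[[length(rows) + 1L]] <-
        data.frame(pathway_a = ct$pathway_a, pathway_b = ct$pathway_b,
                   n_possible = ct$n_possible, n_observed = ct$n_observed,
                   p = ct$p, stringsAsFactors = FALSE)
      glinks[[paste(ct$pathway_a, ct$pathway_b, sep = "|")]] <- ct$links
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pathway_a = character(), pathway_b = character(),
               n_possible = numeric(), n_observed = integer(), p = numeric())
  if (nrow(edges)) {
    p_eff <- if (adjust) stats::p.adjust(edges$p, method = "BH") else edges$p
    edges$significant <- p_eff < cfg$crosstalk_p_threshold
  } else edges$significant <- logical()
  sig_keys <- paste(edges$pathway_a, edges$pathway_b, sep = "|")[edges$significant]
  gene_links <- if (length(sig_keys)) {
    gl <- do.call(rbind, glinks[sig_keys])
    unique(gl)
  } else data.frame(gene_a = character(), gene_b = character())
  flagged <- unique(c(if (!is.null(dcgs)) dcgs$gene[dcgs$is_dcg], hubs))
  subnetwork <- if (nrow(gene_links) && length(flagged))
    gene_links[gene_links$gene_a %in% flagged |
               gene_links$gene_b %in% flagged, , drop = FALSE]
  else gene_links[0L, , drop = FALSE]
  structure(list(edges = edges, gene_links = gene_links,
                 subnetwork = subnetwork,
                 n_significant = sum(edges$significant)),
            class = "CrosstalkMap")
}

#' @export
print.CrosstalkMap <- function(x, ...) {
  cat(sprintf("CrosstalkMap: %d pathway pairs tested, %d significant\n",
              nrow(x$edges), x$n_significant))
  invisible(x)
}
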
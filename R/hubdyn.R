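#' Hub dynamics: constancy, retention, and permutation nulls
#'
#' Quantifies how often pathway hub genes persist from the baseline to the
#' perturbed condition, and how rare the observed persistence is under two
#' permutation schemes: shuffling sample condition labels, and shuffling the
#' gene-to-pathway annotation.
#'
#' @name hubdyn
NULL

#' Per-pathway hubs without permutation testing
#'
#' Computes only the per-condition weight vectors and hubs for every pathway;
#' used by the permutation null machinery where the rewiring p-value is not
#' needed.
#'
#' @param dataset An `ExpressionDataset`.
#' @param compendium A `PathwayCompendium`.
#' @return Data frame: pathway, hub1, hub2 (NA where the pathway was
#'   unusable).
#' @export
compendium_hubs <- function(dataset, compendium) {
  hub_of <- function(w) sort(names(w)[w == max(w)])[1L]
  rows <- lapply(compendium$pathways, function(pw) {
    genes <- intersect(pw$genes, rownames(dataset$matrix))
    if (length(genes) < 3L)
      return(data.frame(pathway = pw$name, hub1 = NA_character_,
                        hub2 = NA_character_, stringsAsFactors = FALSE))
    cc <- suppressWarnings(condition_correlations(dataset, genes))
    if (nrow(cc$r1) < 3L)
      return(data.frame(pathway = pw$name, hub1 = NA_character_,
                        hub2 = NA_character_, stringsAsFactors = FALSE))
    data.frame(pathway = pw$name,
               hub1 = hub_of(weight_vector(cc$r1)),
               hub2 = hub_of(weight_vector(cc$r2)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hub constancy and retention rates
#'
#' Constancy: over the focused pathways, the fraction whose hub is identical
#' in both conditions. Retention: among distinct baseline-condition hubs
#' (over all pathways) that are differentially coexpressed genes, the
#' fraction that remain the perturbed-condition hub of at least one pathway
#' they hubbed at baseline; the rest are the vanishing hubs. Bookkeeping is
#' per gene: a gene hubbing several pathways counts once.
#'
#' @param hub_table Data frame from [compendium_hubs()] (or the `table` of
#'   [rewire_compendium()]): pathway, hub1, hub2.
#' @param dcgs DCG table from [call_dcgs()].
#' @param focused Character vector of focused pathway names.
#' @return A `HubDynamics` list: `constancy`, `constancy_k`, `constancy_n`,
#'   `retention`, `retention_k`, `retention_n`, `vanishing_hubs`. Undefined
#'   rates (empty denominators) are NA.
#' @export
hub_rates <- function(hub_table, dcgs, focused) {
  ht <- hub_table[!is.na(hub_table$hub1) & !is.na(hub_table$hub2), , drop = FALSE]
  foc <- ht[ht$pathway %in% focused, , drop = FALSE]
  constancy_k <- sum(foc$hub1 == foc$hub2)
  constancy_n <- nrow(foc)

  dcg_genes <- dcgs$gene[dcgs$is_dcg]
  early_hubs <- unique(ht$hub1)
  tested <- intersect(early_hubs, dcg_genes)
  retained <- vapply(tested, function(g)
    any(ht$hub1 == g & ht$hub2 == g), TRUE)
  retention_k <- sum(retained)
  retention_n <- length(tested)

  structure(list(
    constancy = if (constancy_n > 0) constancy_k / constancy_n else NA_real_,
    constancy_k = constancy_k, constancy_n = constancy_n,
    retention = if (retention_n > 0) retention_k / retention_n else NA_real_,
    retention_k = retention_k, retention_n = retention_n,
    vanishing_hubs = sort(tested[!retained])), class = "HubDynamics")
}

# lower-tail add-one permutation p-value
.lower_tail_p <- function(null_rates, rate_obs) {
  ok <- !is.na(null_rates)
  (1 + sum(null_rates[ok] <= rate_obs)) / (1 + sum(ok))
}

#' Null hub rates by condition-label permutation
#'
#' Repeats the hub and DCG computation on datasets whose condition labels
#' have been shuffled (group sizes preserved), recording the null constancy
#' and retention rates. Null rates are computed over all pathways of the
#' compendium. Lower-tail empirical p-values test whether the observed rates
#' are significantly rare (low).
#'
#' @param dataset An `ExpressionDataset`.
#' @param compendium A `PathwayCompendium`.
#' @param cfg An [analysis_config()]; `n_perm_hub` permutations seeded from
#'   `rng_seed`.
#' @param observed A `HubDynamics` from [hub_rates()] on the real data.
#' @return List: `null_constancy`, `null_retention` (numeric vectors),
#'   `p_constancy`, `p_retention`.
#' @export
null_by_label_permutation <- function(dataset, compendium,
                                      cfg = analysis_config(), observed) {
  n <- ncol(dataset$matrix)
  set.seed(cfg$rng_seed)
  nc <- nr <- rep(NA_real_, cfg$n_perm_hub)
  for (i in seq_len(cfg$n_perm_hub)) {
    perm <- dataset
    perm$design[] <- dataset$design[sample.int(n)]
    ht <- compendium_hubs(perm, compendium)
    dc <- diff_coexp(perm, genes = intersect(compendium$genes,
                                             rownames(perm$matrix)), cfg = cfg)
    hr <- hub_rates(ht, dc$dcgs, focused = ht$pathway)
    nc[i] <- hr$constancy
    nr[i] <- hr$retention
  }
  list(null_constancy = nc, null_retention = nr,
       p_constancy = .lower_tail_p(nc, observed$constancy),
       p_retention = .lower_tail_p(nr, observed$retention))
}

#' Null hub rates by gene-to-pathway annotation permutation
#'
#' Each replicate replaces every pathway's gene set by a uniform random draw
#' of the same size from the compendium's gene universe (without replacement
#' within a pathway; overlap between pseudo-pathways allowed), preserving
#' the pathway size profile exactly. Hubs are recomputed on the real data;
#' the DCG list is unchanged (annotation does not enter DCG calling).
#'
#' @inheritParams null_by_label_permutation
#' @param dcgs DCG table from the real-data analysis.
#' @return List: `null_constancy`, `null_retention`, `p_constancy`,
#'   `p_retention`.
#' @export
null_by_annotation_permutation <- function(dataset, compendium,
                                           cfg = analysis_config(),
                                           observed, dcgs) {
  univ <- intersect(compendium$genes, rownames(dataset$matrix))
  sizes <- vapply(compendium$pathways, function(p)
    length(intersect(p$genes, univ)), 1L)
  set.seed(cfg$rng_seed + 1L)
  nc <- nr <- rep(NA_real_, cfg$n_perm_hub)
  for (i in seq_len(cfg$n_perm_hub)) {
    pseudo <- lapply(seq_along(sizes), function(j)
      pathway(names(compendium$pathways)[j],
              sample(univ, sizes[j]), source = "permuted"))
    names(pseudo) <- names(compendium$pathways)
    pc <- structure(list(pathways = pseudo, n_pathways = length(pseudo),
                         genes = univ, n_genes = length(univ)),
                    class = "PathwayCompendium")
    ht <- compendium_hubs(dataset, pc)
    hr <- hub_rates(ht, dcgs, focused = ht$pathway)
    nc[i] <- hr$constancy
    nr[i] <- hr$retention
  }
  list(null_constancy = nc, null_retention = nr,
       p_constancy = .lower_tail_p(nc, observed$constancy),
       p_retention = .lower_tail_p(nr, observed$retention))
}
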
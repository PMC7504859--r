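#' Run the full differential-coexpression analysis
#'
#' Orchestrates, for one or more two-condition datasets sharing a pathway
#' compendium: differential coexpression (links, DCLs, DCGs), per-pathway
#' rewiring tests with hubs and dissolution classes, cross-dataset Fisher
#' aggregation with focused-pathway selection, hub constancy/retention
#' rates, and the disrupted-crosstalk map built on the primary dataset's
#' correlation-decreased scaffold.
#'
#' @param datasets A single `ExpressionDataset` or a named list of them; the
#'   first is the primary dataset (source of the crosstalk scaffold).
#' @param compendium A `PathwayCompendium`.
#' @param cfg An [analysis_config()].
#' @param crosstalk Build the crosstalk map (default TRUE).
#' @param wiring Compute wiring networks per pathway (default FALSE; costly
#'   at compendium scale).
#' @return A `PipelineResult` list: `diffcoexp` (per dataset), `rewiring`
#'   (per dataset), `meta` (focused-pathway table), `focused` (names),
#'   `hub_rates`, `scaffold`, `crosstalk`, `summary` (named counts), and
#'   `manifest` (config snapshot, seed, dataset names, package version).
#' @export
run_pipeline <- function(datasets, compendium, cfg = analysis_config(),
                         crosstalk = TRUE, wiring = FALSE) {
  if (inherits(datasets, "ExpressionDataset")) datasets <- list(datasets)
  if (is.null(names(datasets)))
    names(datasets) <- vapply(datasets, `[[`, "", "name")

  dc <- lapply(datasets, function(ds)
    diff_coexp(ds, genes = intersect(compendium$genes, rownames(ds$matrix)),
               cfg = cfg))
  rw <- lapply(names(datasets), function(nm)
    rewire_compendium(datasets[[nm]], compendium, cfg,
                      links = dc[[nm]]$links, wiring = wiring))
  names(rw) <- names(datasets)

  p_matrix <- do.call(cbind, lapply(rw, function(r) {
    p <- r$table$p
    names(p) <- r$table$pathway
    p
  }))
  colnames(p_matrix) <- names(datasets)
  if (length(datasets) >= 2L) {
    meta <- select_focused(p_matrix, cfg)
  } else {
    # single dataset: "focused" degenerates to the per-dataset rule
    meta <- data.frame(pathway = rownames(p_matrix), p_matrix,
                       aggregate_p = p_matrix[, 1L],
                       focused = !is.na(p_matrix[, 1L]) &
                         p_matrix[, 1L] < cfg$pathway_p_threshold,
                       stringsAsFactors = FALSE, row.names = NULL,
                       check.names = FALSE)
    meta <- meta[order(meta$aggregate_p, meta$pathway), , drop = FALSE]
  }
  focused <- meta$pathway[meta$focused]

  primary <- names(datasets)[1L]
  hubs <- rw[[primary]]$table[, c("pathway", "hub1", "hub2")]
  hr <- hub_rates(hubs, dc[[primary]]$dcgs, focused)

  scf <- NULL; ctm <- NULL
  if (crosstalk && length(focused) >= 2L) {
    scf <- tryCatch(build_scaffold(dc[[primary]]$links),
                    error = function(e) NULL)
    if (!is.null(scf))
      ctm <- crosstalk_map(scf, compendium$pathways[focused], cfg,
                           dcgs = dc[[primary]]$dcgs,
                           hubs = unique(c(hubs$hub1, hubs$hub2)))
  }

  summary <- c(
    n_pathways = compendium$n_pathways,
    n_genes = compendium$n_genes,
    n_links = dc[[primary]]$n_links,
    n_dcls = dc[[primary]]$n_dcls,
    n_dcgs = sum(dc[[primary]]$dcgs$is_dcg),
    n_significant = sum(rw[[primary]]$table$p < cfg$pathway_sig_threshold,
                        na.rm = TRUE),
    n_focused = length(focused),
    n_scaffold_edges = if (is.null(scf)) 0L else scf$n_edges,
    n_crosstalk_edges = if (is.null(ctm)) 0L else ctm$n_significant,
    n_vanishing_hubs = length(hr$vanishing_hubs))

  structure(list(diffcoexp = dc, rewiring = rw, meta = meta,
                 focused = focused, hub_rates = hr, scaffold = scf,
                 crosstalk = ctm, summary = summary,
                 manifest = list(
                   config = unclass(cfg),
                   rng_seed = cfg$rng_seed,
                   datasets = names(datasets),
                   version = as.character(utils::packageVersion("coexrewire")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
            class = "PipelineResult")
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("PipelineResult\n")
  for (nm in names(x$summary))
    cat(sprintf("  %-18s %s\n", nm, format(x$summary[[nm]])))
  invisible(x)
}
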
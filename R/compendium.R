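#' Pathway compendium construction
#'
#' Tools to build a low-redundancy pathway compendium from multi-source GMT
#' files: same-name merging, pairwise overlap ablation, and restriction to
#' measured genes under size bounds.
#'
#' @name compendium
NULL

#' Compendium configuration
#'
#' @param merge_share_threshold When merging identically named pathways, a
#'   secondary source contributes its extra genes only if the fraction of its
#'   genes shared with the base set exceeds this value (strictly).
#' @param overlap_discard_threshold Pairwise bound: if shared / |smaller set|
#'   exceeds this value (strictly), the smaller pathway is discarded.
#' @param size_min,size_max Size bounds applied after restricting to measured
#'   genes.
#' @return A `CompendiumConfig` list.
#' @export
compendium_config <- function(merge_share_threshold = 0.70,
                              overlap_discard_threshold = 0.70,
                              size_min = 5L, size_max = 250L) {
  if (merge_share_threshold <= 0 || merge_share_threshold > 1 ||
      overlap_discard_threshold <= 0 || overlap_discard_threshold > 1)
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  if (size_min < 1L || size_min > size_max)
    stop("need 1 <= size_min <= size_max", call. = FALSE)
  structure(list(merge_share_threshold = merge_share_threshold,
                 overlap_discard_threshold = overlap_discard_threshold,
                 size_min = as.integer(size_min),
                 size_max = as.integer(size_max)),
            class = "CompendiumConfig")
}

#' Construct a pathway record
#'
#' @param name Pathway name.
#' @param genes Character vector of member genes (deduplicated).
#' @param source Originating database (e.g. PID, PANTHER, INOH).
#' @return A `Pathway` list.
#' @export
pathway <- function(name, genes, source = "unknown") {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("pathway '", name, "' has no genes", call. = FALSE)
  structure(list(name = name, source = source, genes = genes),
            class = "Pathway")
}

#' Read pathways from a GMT file
#'
#' One pathway per line: name, description/source field, then member genes.
#'
#' @param path GMT file path.
#' @return List of [pathway()] records.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  # recover the description column (gmtPathways drops it) for provenance
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  sources <- vapply(lines, function(x) if (length(x) >= 2L) x[2L] else "", "")
  names(sources) <- vapply(lines, `[[`, "", 1L)
  lapply(names(sets), function(nm)
    pathway(nm, sets[[nm]],
            source = if (nzchar(sources[[nm]])) sources[[nm]] else "unknown"))
}

#' Write pathways to a GMT file
#'
#' @param pathways List of [pathway()] records.
#' @param path Output path.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(pathways, function(p)
    paste(c(p$name, p$source, p$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

normalize_name <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Merge identically named pathways across sources
#'
#' Within each (case- and whitespace-insensitive) name group, the largest
#' gene set is the base; every other member contributes its extra genes iff
#' the fraction of its genes shared with the base strictly exceeds
#' `merge_share_threshold`, otherwise it is dropped. Qualifying members are
#' applied in decreasing size order.
#'
#' @param pathways List of [pathway()] records.
#' @param cfg A [compendium_config()].
#' @return List of pathways with unique names.
#' @export
merge_same_name <- function(pathways, cfg = compendium_config()) {
  if (!length(pathways)) return(list())
  keys <- vapply(pathways, function(p) normalize_name(p$name), "")
  out <- lapply(unique(keys), function(k) {
    group <- pathways[keys == k]
    sizes <- vapply(group, function(p) length(p$genes), 1L)
    ord <- order(-sizes)
    base <- group[[ord[1L]]]
    merged <- base$genes
    srcs <- base$source
    for (i in ord[-1L]) {
      g <- group[[i]]$genes
      if (length(intersect(g, base$genes)) / length(g) > cfg$merge_share_threshold) {
        merged <- union(merged, g)
        srcs <- c(srcs, group[[i]]$source)
      }
    }
    pathway(base$name, merged, source = paste(unique(srcs), collapse = ";"))
  })
  out
}

#' Discard heavily overlapping pathways
#'
#' Pathways are scanned in decreasing gene-set size (ties by name,
#' lexicographic, the later name treated as smaller); each survivor discards
#' any remaining smaller pathway sharing strictly more than
#' `overlap_discard_threshold` of the smaller set's genes. The surviving list
#' pairwise satisfies the bound, and the result is invariant to input order.
#'
#' @inheritParams merge_same_name
#' @return Filtered pathway list (in the scan order).
#' @export
ablate_overlaps <- function(pathways, cfg = compendium_config()) {
  if (length(pathways) < 2L) return(pathways)
  nms <- vapply(pathways, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("ablate_overlaps requires unique names", call. = FALSE)
  sizes <- vapply(pathways, function(p) length(p$genes), 1L)
  ord <- order(-sizes, nms, method = "radix")
  pathways <- pathways[ord]
  alive <- rep(TRUE, length(pathways))
  for (i in seq_along(pathways)) {
    if (!alive[i]) next
    for (j in seq_along(pathways)) {
      if (j <= i || !alive[j]) next
      small <- pathways[[j]]$genes
      if (length(intersect(pathways[[i]]$genes, small)) / length(small) >
          cfg$overlap_discard_threshold)
        alive[j] <- FALSE
    }
  }
  pathways[alive]
}

#' Restrict pathways to measured genes and apply size bounds
#'
#' @param pathways List of [pathway()] records (unique names).
#' @param measured_genes Character vector of genes present in the expression
#'   data.
#' @param cfg A [compendium_config()].
#' @return A `PathwayCompendium`: list with `pathways` (named list of
#'   [pathway()]), `n_pathways`, `genes` (union), `n_genes`.
#' @export
restrict_and_bound <- function(pathways, measured_genes, cfg = compendium_config()) {
  if (!length(measured_genes)) stop("input error: no measured genes", call. = FALSE)
  kept <- list()
  for (p in pathways) {
    g <- intersect(p$genes, measured_genes)
    if (length(g) >= cfg$size_min && length(g) <= cfg$size_max)
      kept[[p$name]] <- pathway(p$name, g, p$source)
  }
  if (!length(kept))
    stop("degenerate output: no pathway survives restriction and size bounds",
         call. = FALSE)
  univ <- sort(unique(unlist(lapply(kept, `[[`, "genes"))))
  structure(list(pathways = kept, n_pathways = length(kept),
                 genes = univ, n_genes = length(univ)),
            class = "PathwayCompendium")
}

#' @export
print.PathwayCompendium <- function(x, ...) {
  cat(sprintf("PathwayCompendium: %d pathways over %d genes\n",
              x$n_pathways, x$n_genes))
  invisible(x)
}

#' Build a compendium end to end
#'
#' Convenience wrapper: merge same-name pathways, ablate pairwise overlaps,
#' restrict to measured genes and bound sizes.
#'
#' @inheritParams restrict_and_bound
#' @export
build_compendium <- function(pathways, measured_genes, cfg = compendium_config()) {
  restrict_and_bound(ablate_overlaps(merge_same_name(pathways, cfg), cfg),
                     measured_genes, cfg)
}
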
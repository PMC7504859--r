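#' Differential coexpression of gene pairs and genes
#'
#' Re-implementation of limit-fold-change (LFC) calling of differentially
#' coexpressed links (DCLs) and binomial-tail calling of differentially
#' coexpressed genes (DCGs) over two-condition Pearson correlation matrices.
#'
#' @name diffcoexp
NULL

# sign with zero treated as positive
.sgn <- function(r) ifelse(r >= 0, 1, -1)

#' Per-condition Pearson correlation matrices
#'
#' Genes with zero variance within either condition are excluded (their
#' correlations are undefined) with a warning.
#'
#' @param dataset An `ExpressionDataset`.
#' @param genes Gene subset (default: all genes in the dataset).
#' @return List with symmetric matrices `r1` (baseline), `r2` (perturbed),
#'   and `dropped` (excluded zero-variance genes).
#' @export
condition_correlations <- function(dataset, genes = rownames(dataset$matrix)) {
  miss <- setdiff(genes, rownames(dataset$matrix))
  if (length(miss))
    stop("genes absent from dataset: ", paste(miss, collapse = ", "), call. = FALSE)
  x1 <- t(dataset$matrix[genes, condition_samples(dataset, 1L), drop = FALSE])
  x2 <- t(dataset$matrix[genes, condition_samples(dataset, 2L), drop = FALSE])
  if (nrow(x1) < 3L || nrow(x2) < 3L)
    stop("each condition needs >= 3 samples", call. = FALSE)
  sd1 <- apply(x1, 2L, stats::sd)
  sd2 <- apply(x2, 2L, stats::sd)
  dropped <- genes[sd1 == 0 | sd2 == 0]
  if (length(dropped)) {
    warning("excluding zero-variance gene(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
    genes <- setdiff(genes, dropped)
    x1 <- x1[, genes, drop = FALSE]
    x2 <- x2[, genes, drop = FALSE]
  }
  r1 <- stats::cor(x1)
  r2 <- stats::cor(x2)
  diag(r1) <- 1; diag(r2) <- 1
  list(r1 = r1, r2 = r2, dropped = dropped)
}

# flatten the upper triangle of aligned correlation matrices into a pair table
# with gene_a < gene_b lexicographically
.pair_table <- function(r1, r2) {
  g <- rownames(r1)
  idx <- which(upper.tri(r1), arr.ind = TRUE)
  a <- g[idx[, 1L]]; b <- g[idx[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  df <- data.frame(gene_a = a, gene_b = b,
                   r1 = r1[idx], r2 = r2[idx],
                   stringsAsFactors = FALSE)
  df[order(df$gene_a, df$gene_b, method = "radix"), , drop = FALSE]
}

#' Select the coexpression link universe at a target density
#'
#' Per condition, the cutoff is the k-th largest absolute correlation with
#' k = ceiling(density * n_pairs); a pair enters the link universe iff it
#' meets either condition's cutoff (OR rule). Ties at the cutoff are
#' included, so realized per-condition density is >= the target.
#'
#' @param r1_matrix,r2_matrix Aligned symmetric correlation matrices.
#' @param cfg An [analysis_config()].
#' @return Data frame of all pairs (gene_a < gene_b) with columns `r1`, `r2`,
#'   `is_link`; cutoffs stored as attributes `t1`, `t2`.
#' @export
select_links <- function(r1_matrix, r2_matrix, cfg = analysis_config()) {
  if (nrow(r1_matrix) < 2L) stop("input error: need >= 2 genes", call. = FALSE)
  stopifnot(identical(rownames(r1_matrix), rownames(r2_matrix)))
  df <- .pair_table(r1_matrix, r2_matrix)
  m <- nrow(df)
  k <- ceiling(cfg$density * m)
  t1 <- sort(abs(df$r1), decreasing = TRUE)[k]
  t2 <- sort(abs(df$r2), decreasing = TRUE)[k]
  df$is_link <- abs(df$r1) >= t1 | abs(df$r2) >= t2
  attr(df, "t1") <- t1
  attr(df, "t2") <- t2
  df
}

# equal-count bin index by x, ties split by first-occurrence rank
.equal_count_bins <- function(x, B) {
  n <- length(x)
  ceiling(rank(x, ties.method = "first") * B / n)
}

#' Call differentially coexpressed links with the LFC envelope
#'
#' Sign-switching pairs meeting both per-condition cutoffs are DCLs outright
#' (`diff_signed`). Remaining same-signed link pairs are scored by
#' x = max(|r1|, |r2|) and fold = x / max(min(|r1|, |r2|), 1e-4), stratified
#' into B equal-count bins by x (B = 20, shrunk to ceiling(n/50) for small
#' inputs); each bin's top `dcl_fraction` by fold (ties broken by pair order)
#' is provisional, bin cutoffs are enveloped by a least-squares power law
#' y = a x^b on log scale, and a pair is a DCL iff its fold reaches the
#' envelope at its x. With a single bin the envelope degenerates to the bin's
#' top-fraction cutoff.
#'
#' @param links Output of [select_links()].
#' @param cfg An [analysis_config()].
#' @return `links` with columns `is_dcl`, `fold` and `category` added.
#' @export
call_dcls <- function(links, cfg = analysis_config()) {
  if (!nrow(links)) stop("input error: empty link universe", call. = FALSE)
  t1 <- attr(links, "t1"); t2 <- attr(links, "t2")
  df <- links[links$is_link, , drop = FALSE]
  a1 <- abs(df$r1); a2 <- abs(df$r2)
  switch_pair <- .sgn(df$r1) != .sgn(df$r2)
  df$is_dcl <- switch_pair & a1 >= t1 & a2 >= t2
  df$fold <- NA_real_

  same <- which(!switch_pair)
  q <- cfg$dcl_fraction
  if (length(same) && q > 0) {
    x <- pmax(a1[same], a2[same])
    fold <- x / pmax(pmin(a1[same], a2[same]), 1e-4)
    df$fold[same] <- fold
    n <- length(same)
    B <- min(20L, max(1L, ceiling(n / 50)))
    bins <- .equal_count_bins(x, B)
    # provisional top-q per bin by fold, ties by lexicographic pair order
    # (rows are already sorted by gene_a, gene_b)
    cutoffs <- numeric(B); xmed <- numeric(B)
    provisional <- logical(n)
    for (b in seq_len(B)) {
      in_b <- which(bins == b)
      kb <- min(length(in_b), ceiling(q * length(in_b)))
      sel <- in_b[order(-fold[in_b], in_b)][seq_len(kb)]
      provisional[sel] <- TRUE
      cutoffs[b] <- if (kb > 0L) min(fold[sel]) else Inf
      xmed[b] <- stats::median(x[in_b])
    }
    if (B == 1L) {
      lfc_dcl <- provisional
    } else {
      ok <- is.finite(log(cutoffs)) & cutoffs > 0
      if (sum(ok) >= 2L && stats::sd(log(xmed[ok])) > 0) {
        fit <- stats::lm.fit(cbind(1, log(xmed[ok])), log(cutoffs[ok]))
        a <- exp(fit$coefficients[1L]); bexp <- fit$coefficients[2L]
        lfc_dcl <- fold >= a * x^bexp
      } else {
        # degenerate envelope (identical bin medians): per-bin cutoffs
        lfc_dcl <- fold >= cutoffs[bins]
      }
    }
    df$is_dcl[same][lfc_dcl] <- TRUE
  }

  df$category <- "none"
  dcl <- which(df$is_dcl)
  if (length(dcl))
    df$category[dcl] <- mapply(classify_dcl, df$r1[dcl], df$r2[dcl])
  out <- links
  out$is_dcl <- FALSE
  out$fold <- NA_real_
  out$category <- "none"
  key <- paste(out$gene_a, out$gene_b)
  mk <- match(paste(df$gene_a, df$gene_b), key)
  out$is_dcl[mk] <- df$is_dcl
  out$fold[mk] <- df$fold
  out$category[mk] <- df$category
  attr(out, "t1") <- t1; attr(out, "t2") <- t2
  out
}

#' Classify a differentially coexpressed link
#'
#' Categories by the signs and trend of the paired correlations: opposite
#' signs give `diff_signed`; both negative give `same_signed_negative`; both
#' non-negative give `increased_positive` or `decreased_positive` according
#' to whether |r| rose or fell from condition 1 to condition 2. Zero counts
#' as positive. Equal same-signed magnitudes cannot arise from the LFC
#' selection and raise an error.
#'
#' @param r1,r2 The pair's correlations in conditions 1 and 2.
#' @return Category string.
#' @export
classify_dcl <- function(r1, r2) {
  if (.sgn(r1) != .sgn(r2)) return("diff_signed")
  if (r1 < 0 && r2 < 0) return("same_signed_negative")
  if (abs(r2) > abs(r1)) return("increased_positive")
  if (abs(r2) < abs(r1)) return("decreased_positive")
  stop("internal error: same-signed DCL with |r1| == |r2|", call. = FALSE)
}

#' Call differentially coexpressed genes by a binomial tail test
#'
#' For each gene with k >= 1 incident filtered links and d incident DCLs,
#' p = P(X >= d) with X ~ Binomial(k, pi) where pi is the global DCL fraction
#' among filtered links; q-values by Benjamini-Hochberg.
#'
#' @param links Output of [call_dcls()].
#' @param cfg An [analysis_config()].
#' @return Data frame: `gene`, `k`, `d`, `dcl_rate`, `p`, `q`, `is_dcg`.
#' @export
call_dcgs <- function(links, cfg = analysis_config()) {
  lk <- links[links$is_link, , drop = FALSE]
  if (!nrow(lk)) stop("input error: no filtered links", call. = FALSE)
  pi_global <- sum(lk$is_dcl) / nrow(lk)
  genes <- sort(unique(c(lk$gene_a, lk$gene_b)))
  k <- table(factor(c(lk$gene_a, lk$gene_b), levels = genes))
  dl <- lk[lk$is_dcl, , drop = FALSE]
  d <- table(factor(c(dl$gene_a, dl$gene_b), levels = genes))
  k <- as.integer(k); d <- as.integer(d)
  p <- stats::pbinom(d - 1L, k, pi_global, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene = genes, k = k, d = d, dcl_rate = d / k,
             p = p, q = q, is_dcg = q < cfg$dcg_q_threshold,
             stringsAsFactors = FALSE)
}

#' Full differential-coexpression analysis of one dataset
#'
#' Runs [condition_correlations()], [select_links()], [call_dcls()] and
#' [call_dcgs()] and summarizes the DCL category composition.
#'
#' @param dataset An `ExpressionDataset`.
#' @param genes Gene subset (default all).
#' @param cfg An [analysis_config()].
#' @return A `DiffCoexpResult`: list with `links` (pair table), `dcgs`,
#'   `pi_global`, `category_shares`, `n_links`, `n_dcls` and the per-condition
#'   cutoffs `t1`, `t2`.
#' @export
diff_coexp <- function(dataset, genes = rownames(dataset$matrix),
                       cfg = analysis_config()) {
  cc <- condition_correlations(dataset, genes)
  links <- call_dcls(select_links(cc$r1, cc$r2, cfg), cfg)
  dcgs <- call_dcgs(links, cfg)
  n_links <- sum(links$is_link)
  n_dcls <- sum(links$is_dcl)
  cats <- c("diff_signed", "same_signed_negative",
            "increased_positive", "decreased_positive")
  shares <- if (n_dcls > 0)
    as.numeric(table(factor(links$category[links$is_dcl], levels = cats))) / n_dcls
  else rep(NA_real_, 4L)
  names(shares) <- cats
  structure(list(links = links, dcgs = dcgs,
                 pi_global = n_dcls / n_links,
                 category_shares = shares,
                 n_links = n_links, n_dcls = n_dcls,
                 t1 = attr(links, "t1"), t2 = attr(links, "t2")),
            class = "DiffCoexpResult")
}

#' @export
print.DiffCoexpResult <- function(x, ...) {
  cat(sprintf("DiffCoexpResult: %d links, %d DCLs (pi = %.3f), %d DCGs\n",
              x$n_links, x$n_dcls, x$pi_global, sum(x$dcgs$is_dcg)))
  invisible(x)
}

#' Write DCL and DCG tables
#'
#' @param result A `DiffCoexpResult`.
#' @param dcl_path,dcg_path Output TSV paths.
#' @export
write_diffcoexp <- function(result, dcl_path, dcg_path) {
  utils::write.table(result$links[, c("gene_a", "gene_b", "r1", "r2",
                                      "is_dcl", "category")],
                     dcl_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$dcgs, dcg_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(dcl_path, dcg_path))
}
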
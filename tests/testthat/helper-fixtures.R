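# small in-code fixtures shared across tests

# deterministic toy dataset: g genes x (n1 + n2) samples of pure noise
toy_dataset <- function(g = 6, n1 = 5, n2 = 5, seed = 42, name = "toy") {
  set.seed(seed)
  m <- matrix(rnorm(g * (n1 + n2)), g,
              dimnames = list(paste0("G", seq_len(g)),
                              paste0("S", seq_len(n1 + n2))))
  design <- setNames(rep(c("early", "late"), c(n1, n2)), colnames(m))
  expression_dataset(m, design, baseline = "early", name = name)
}

# pair table with chosen correlations, shaped like select_links() output
fake_links <- function(r1, r2, is_link = rep(TRUE, length(r1)),
                       t1 = 0.5, t2 = 0.5, genes = NULL) {
  n_pairs <- length(r1)
  if (is.null(genes)) {
    # enough genes for the requested number of pairs
    g <- ceiling((1 + sqrt(1 + 8 * n_pairs)) / 2)
    cmb <- utils::combn(sprintf("g%02d", seq_len(g)), 2)[, seq_len(n_pairs), drop = FALSE]
  } else {
    cmb <- utils::combn(genes, 2)[, seq_len(n_pairs), drop = FALSE]
  }
  df <- data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ], r1 = r1, r2 = r2,
                   is_link = is_link, stringsAsFactors = FALSE)
  df <- df[order(df$gene_a, df$gene_b), ]
  attr(df, "t1") <- t1
  attr(df, "t2") <- t2
  df
}

# brute-force DCL oracle for single-bin instances: sign-switch pairs meeting
# both cutoffs, plus the top ceiling(q * n_same) same-signed pairs by fold
# (ties by lexicographic pair order)
oracle_dcls <- function(links, q, t1, t2, eps = 1e-4) {
  lk <- links[links$is_link, ]
  sgn <- function(r) ifelse(r >= 0, 1, -1)
  sw <- sgn(lk$r1) != sgn(lk$r2)
  dcl <- sw & abs(lk$r1) >= t1 & abs(lk$r2) >= t2
  same <- which(!sw)
  if (length(same) && q > 0) {
    fold <- pmax(abs(lk$r1[same]), abs(lk$r2[same])) /
      pmax(pmin(abs(lk$r1[same]), abs(lk$r2[same])), eps)
    k <- min(length(same), ceiling(q * length(same)))
    dcl[same[order(-fold, same)][seq_len(k)]] <- TRUE
  }
  paste(lk$gene_a, lk$gene_b)[dcl]
}

# enumeration oracle for the hypergeometric upper tail
oracle_hyper_tail <- function(N, K, n, k_obs) {
  ks <- k_obs:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
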
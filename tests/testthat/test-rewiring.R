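corr_from_upper <- function(vals, p, genes = paste0("G", seq_len(p))) {
  m <- diag(p)
  m[upper.tri(m)] <- vals
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  dimnames(m) <- list(genes, genes)
  m
}

test_that("weight vectors match the dense eigendecomposition oracle", {
  # 3-gene case with |r| = 0.9, 0.5, 0.1
  m <- corr_from_upper(c(0.9, 0.5, 0.1), 3)
  w <- weight_vector(m)
  A <- abs(m); diag(A) <- 0
  ev <- eigen(A, symmetric = TRUE)
  oracle <- abs(ev$vectors[, which.max(ev$values)])
  oracle <- oracle * 3 / sum(oracle)
  expect_equal(unname(w), oracle, tolerance = 1e-8)

  for (seed in 1:4) {
    set.seed(seed)
    p <- sample(5:15, 1)
    m <- stats::cor(matrix(rnorm(40 * p), 40, p))
    dimnames(m) <- list(paste0("G", 1:p), paste0("G", 1:p))
    w <- weight_vector(m)
    A <- abs(m); diag(A) <- 0
    ev <- eigen(A, symmetric = TRUE)
    oracle <- abs(ev$vectors[, which.max(ev$values)])
    oracle <- oracle * p / sum(oracle)
    expect_equal(unname(w), oracle, tolerance = 1e-8)
    expect_equal(sum(w), p)
  }
})

test_that("weight vectors are uniform for exchangeable matrices and scale-free", {
  m <- corr_from_upper(rep(0.4, 6), 4)
  expect_equal(unname(weight_vector(m)), rep(1, 4))

  m2 <- corr_from_upper(c(0.8, 0.3, 0.2, 0.6, 0.1, 0.5), 4)
  A <- m2
  A[upper.tri(A)] <- A[upper.tri(A)] * 0.5   # c * A has the same eigenvector
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  expect_equal(weight_vector(m2), weight_vector(A), tolerance = 1e-8)
})

test_that("identical conditions give zero distance and p = 1", {
  ds <- toy_dataset(g = 6, n1 = 5, n2 = 5, seed = 4)
  # make condition 2 an exact copy of condition 1
  ds$matrix[, 6:10] <- ds$matrix[, 1:5]
  pw <- pathway("copy", rownames(ds$matrix))
  cfg <- analysis_config(n_perm_gsnca = 50, rng_seed = 1)
  res <- gsnca_test(ds, pw, cfg, wiring = FALSE)
  expect_equal(res$d_obs, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
})

test_that("permutation p attains the add-one floor under extreme rewiring", {
  sim <- generate_synthetic(synth_config(
    n_pathways = 1, genes_per_pathway = 10, n_background_genes = 0,
    samples_per_condition = 60, rho_within = list(att = c(0.9, 0.0)),
    hub_boost = 0, rng_seed = 2))
  cfg <- analysis_config(n_perm_gsnca = 99, rng_seed = 5)
  res <- gsnca_test(sim$dataset, sim$pathways[[1]], cfg, wiring = FALSE)
  expect_equal(res$p, 1 / 100)
  expect_gte(res$p, 1 / (cfg$n_perm_gsnca + 1))
})

test_that("gsnca results are reproducible and pathway-seeded", {
  ds <- toy_dataset(g = 8, n1 = 6, n2 = 6, seed = 10)
  pw <- pathway("pw_a", rownames(ds$matrix)[1:5])
  cfg <- analysis_config(n_perm_gsnca = 30, rng_seed = 3)
  r1 <- gsnca_test(ds, pw, cfg, wiring = FALSE)
  r2 <- gsnca_test(ds, pw, cfg, wiring = FALSE)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$d_obs, r2$d_obs)
})

test_that("pathways reduced below three usable genes are skipped", {
  ds <- toy_dataset(g = 6, n1 = 5, n2 = 5)
  ds$matrix[c("G1", "G2"), 1:5] <- 1    # flat in condition 1
  pw <- pathway("thin", c("G1", "G2", "G3", "G9"))   # G9 absent
  res <- suppressWarnings(gsnca_test(ds, pw, analysis_config(n_perm_gsnca = 10)))
  expect_identical(res$status, "skipped")
  expect_true(is.na(res$p))
})

test_that("first MST spans all genes with p - 1 edges", {
  set.seed(6)
  p <- 8L
  m <- stats::cor(matrix(rnorm(30 * p), 30, p))
  dimnames(m) <- list(paste0("G", 1:p), paste0("G", 1:p))
  net <- wiring_network(m)
  mst1 <- net[net$tree == 1, ]
  expect_identical(nrow(mst1), p - 1L)
  expect_setequal(unique(c(mst1$gene_a, mst1$gene_b)), rownames(m))
})

test_that("4-gene MSTs match exhaustive spanning-tree enumeration", {
  set.seed(12)
  vals <- runif(6, 0.05, 0.95)
  m <- corr_from_upper(vals, 4)
  net <- wiring_network(m)
  mst1 <- net[net$tree == 1, ]

  # enumerate all 16 spanning trees of K4 (Cayley: 4^{4-2})
  genes <- rownames(m)
  edges <- t(utils::combn(genes, 2))
  dist <- 1 - abs(m[edges])
  all_trees <- utils::combn(1:6, 3, simplify = FALSE)
  spans <- Filter(function(idx) {
    sub <- edges[idx, , drop = FALSE]
    length(unique(c(sub))) == 4 &&
      {   # connected: grow a component from the first node
        comp <- sub[1, 1]
        for (k in 1:3) for (r in seq_len(nrow(sub))) {
          if (sub[r, 1] %in% comp) comp <- union(comp, sub[r, 2])
          else if (sub[r, 2] %in% comp) comp <- union(comp, sub[r, 1])
        }
        length(comp) == 4
      }
  }, all_trees)
  expect_length(spans, 16)
  weights <- vapply(spans, function(idx) sum(dist[idx]), 1)
  best <- spans[[which.min(weights)]]
  got1 <- sort(paste(mst1$gene_a, mst1$gene_b))
  expect_identical(got1, sort(paste(edges[best, 1], edges[best, 2])))

  # second tree: best spanning tree among those edge-disjoint from MST1
  mst2 <- net[net$tree == 2, ]
  if (nrow(mst2) == 3) {
    disjoint <- Filter(function(idx) !any(idx %in% best), spans)
    w2 <- vapply(disjoint, function(idx) sum(dist[idx]), 1)
    best2 <- disjoint[[which.min(w2)]]
    expect_identical(sort(paste(mst2$gene_a, mst2$gene_b)),
                     sort(paste(edges[best2, 1], edges[best2, 2])))
  }
})

test_that("equal distances resolve deterministically by the lexicographic tie-break", {
  m <- corr_from_upper(rep(0.5, 10), 5)
  n1 <- wiring_network(m)
  n2 <- wiring_network(m)
  expect_identical(n1, n2)
  mst1 <- n1[n1$tree == 1, ]
  # Kruskal with (dist, gene_a, gene_b) ordering picks the star on G1
  expect_identical(paste(mst1$gene_a, mst1$gene_b),
                   c("G1 G2", "G1 G3", "G1 G4", "G1 G5"))
})

test_that("the rewiring test has high power against hub-bearing attenuation", {
  # 0.8 -> 0.2 within-pathway attenuation with the default planted hub,
  # 15 genes, 50 samples per condition
  n_rep <- 100
  ps <- vapply(seq_len(n_rep), function(s) {
    sim <- generate_synthetic(synth_config(
      n_pathways = 1, genes_per_pathway = 15, n_background_genes = 0,
      samples_per_condition = 50, rho_within = list(att = c(0.8, 0.2)),
      hub_boost = 0.2, rng_seed = 2000 + s))
    gsnca_test(sim$dataset, sim$pathways[[1]],
               analysis_config(n_perm_gsnca = 1000, rng_seed = s),
               wiring = FALSE)$p
  }, 1)
  expect_gte(mean(ps < 0.05), 0.95)
})

test_that("dissolution classification follows the majority rule", {
  pw <- pathway("pp", c("g01", "g02", "g03", "g04", "g05"))
  mk <- function(r1, r2, dcl) {
    df <- fake_links(r1, r2, genes = pw$genes)
    df$is_dcl <- dcl
    df
  }
  # 3 decreased, 1 increased among DCLs -> dissolved
  l1 <- mk(c(0.8, 0.9, 0.7, 0.1, 0.5), c(0.1, 0.2, 0.1, 0.8, 0.5),
           c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_identical(classify_dissolution(pw, l1)$class, "dissolved")
  # zero DCLs -> maintained
  l2 <- mk(c(0.8, 0.9), c(0.1, 0.2), c(FALSE, FALSE))
  expect_identical(classify_dissolution(pw, l2)$class, "maintained")
  # 1 decreased vs 3 increased -> consolidated
  l3 <- mk(c(0.8, 0.1, 0.2, 0.1), c(0.1, 0.8, 0.9, 0.7), rep(TRUE, 4))
  expect_identical(classify_dissolution(pw, l3)$class, "consolidated")
  # sign-switch with |r2| <= |r1| counts as decreased
  l4 <- mk(c(0.8, 0.3), c(-0.8, 0.9), c(TRUE, TRUE))
  out <- classify_dissolution(pw, l4)
  expect_identical(out$n_dec, 1L)
  expect_identical(out$n_inc, 1L)
  expect_identical(out$class, "maintained")
})
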
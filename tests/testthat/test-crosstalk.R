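scaffold_links <- function() {
  # 5 decreased DCLs, 2 increased, 1 non-DCL
  fake_links(
    r1 = c(0.9, 0.8, 0.85, 0.7, 0.75, 0.1, 0.2, 0.5),
    r2 = c(0.1, 0.2, 0.15, -0.3, 0.05, 0.9, 0.8, 0.5),
    genes = sprintf("g%02d", 1:8))
}

test_that("scaffold keeps decreased-positive and decreasing sign-switch DCLs", {
  lk <- scaffold_links()
  lk$is_dcl <- c(rep(TRUE, 7), FALSE)
  lk$category <- c("decreased_positive", "decreased_positive",
                   "decreased_positive", "diff_signed", "decreased_positive",
                   "increased_positive", "increased_positive", "none")
  sc <- build_scaffold(lk)
  expect_identical(sc$n_edges, 5L)   # 4 decreased_positive + 1 decreasing diff_signed

  # union of two identical scaffolds is idempotent
  sc_u <- build_scaffold(list(lk, lk), mode = "union")
  expect_identical(sc_u$n_edges, sc$n_edges)

  lk0 <- lk
  lk0$is_dcl <- FALSE
  expect_error(build_scaffold(lk0), "degenerate")
})

test_that("crosstalk test equals hypergeometric enumeration on small universes", {
  # 10-gene universe, 5 scaffold edges, |A'| = 3, |B'| = 2, 3 observed
  genes <- sprintf("g%02d", 1:10)
  edges <- data.frame(gene_a = c("g01", "g02", "g03", "g07", "g08"),
                      gene_b = c("g04", "g05", "g04", "g09", "g10"),
                      stringsAsFactors = FALSE)
  sc <- structure(list(edges = edges, universe = genes, n_edges = 5L),
                  class = "Scaffold")
  pa <- pathway("A", c("g01", "g02", "g03"))
  pb <- pathway("B", c("g04", "g05"))
  ct <- crosstalk_test(sc, pa, pb)
  expect_identical(ct$n_possible, 6L)
  expect_identical(ct$n_observed, 3L)
  expect_equal(ct$p, oracle_hyper_tail(choose(10, 2), 5, 6, 3), tolerance = 1e-12)
  expect_equal(ct$p, 0.01261, tolerance = 1e-3)

  # zero observed edges -> p = 1
  pc <- pathway("C", c("g06", "g07"))
  pd <- pathway("D", c("g08", "g09"))
  # remove the 7-9/8-10 edges from pathways: pick disjoint unconnected genes
  ct0 <- crosstalk_test(sc, pathway("C2", "g06"), pathway("D2", "g02"))
  expect_equal(ct0$p, 1)
  expect_identical(ct0$n_observed, 0L)

  # symmetry
  ct_ba <- crosstalk_test(sc, pb, pa)
  expect_equal(ct_ba$p, ct$p)
  expect_identical(ct_ba$n_observed, ct$n_observed)

  # pathways identical after shared-gene removal -> skipped
  same <- pathway("E", c("g01", "g02"))
  expect_identical(crosstalk_test(sc, same, same)$status, "skipped")

  # random small instances against enumeration
  set.seed(14)
  for (rep in 1:5) {
    univ <- sprintf("u%02d", 1:8)
    all_pairs <- t(utils::combn(univ, 2))
    pick <- sample(nrow(all_pairs), 6)
    sc2 <- structure(list(
      edges = data.frame(gene_a = all_pairs[pick, 1],
                         gene_b = all_pairs[pick, 2], stringsAsFactors = FALSE),
      universe = univ, n_edges = 6L), class = "Scaffold")
    a <- pathway("ra", sample(univ, 3))
    b <- pathway("rb", setdiff(univ, a$genes)[1:2])
    ct2 <- crosstalk_test(sc2, a, b)
    expect_equal(ct2$p, oracle_hyper_tail(choose(8, 2), 6, ct2$n_possible,
                                          ct2$n_observed), tolerance = 1e-12)
  }
})

test_that("crosstalk map gates on the threshold and restricts the subnetwork", {
  lk <- scaffold_links()
  lk$is_dcl <- rep(c(TRUE, FALSE), c(5, 3))
  lk$category <- c(rep("decreased_positive", 5), rep("none", 3))
  sc <- build_scaffold(lk)
  paths <- list(A = pathway("A", c("g01", "g02")), B = pathway("B", c("g03", "g04")),
                C = pathway("C", c("g05", "g06")))
  cfg <- analysis_config()
  cfg$crosstalk_p_threshold <- 1            # significant whenever p < 1
  m_all <- crosstalk_map(sc, paths, cfg)
  expect_identical(m_all$edges$significant, m_all$edges$p < 1)

  cfg$crosstalk_p_threshold <- 0            # nothing passes
  m_none <- crosstalk_map(sc, paths, cfg)
  expect_identical(m_none$n_significant, 0L)
  expect_identical(nrow(m_none$gene_links), 0L)

  cfg$crosstalk_p_threshold <- 1
  dcgs <- data.frame(gene = c("g01"), is_dcg = TRUE, stringsAsFactors = FALSE)
  m_sub <- crosstalk_map(sc, paths, cfg, dcgs = dcgs, hubs = "g99")
  expect_true(all(paste(m_sub$subnetwork$gene_a, m_sub$subnetwork$gene_b) %in%
                  paste(m_sub$gene_links$gene_a, m_sub$gene_links$gene_b)))
  expect_true(all(m_sub$subnetwork$gene_a == "g01" |
                  m_sub$subnetwork$gene_b == "g01"))
})
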
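test_that("condition correlations reproduce hand-computed Pearson values", {
  m <- rbind(A = c(1, 2, 3, 4, 1, 2, 3, 4),
             B = c(3, 5, 7, 9, 2, 4, 6, 8),     # affine in A -> r = 1
             C = c(4, 3, 2, 1, 4, 3, 2, 1),     # r = -1 with A
             D = c(1, 3, 2, 4, 1, 3, 2, 4))     # hand-computed r = 0.8 with A
  colnames(m) <- paste0("S", 1:8)
  design <- setNames(rep(c("e", "l"), each = 4), colnames(m))
  ds <- expression_dataset(m, design, baseline = "e")
  cc <- condition_correlations(ds)
  expect_equal(diag(cc$r1), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cc$r1["A", "B"], 1)
  expect_equal(cc$r1["A", "C"], -1)
  expect_equal(cc$r1["A", "D"], 0.8)
  expect_equal(cc$r1, t(cc$r1))
})

test_that("zero-variance genes are excluded with a warning", {
  ds <- toy_dataset(g = 5, n1 = 4, n2 = 4)
  ds$matrix["G3", 1:4] <- 7                     # flat in condition 1
  expect_warning(cc <- condition_correlations(ds), "zero-variance")
  expect_false("G3" %in% rownames(cc$r1))
  expect_identical(cc$dropped, "G3")
})

test_that("link selection hits the target density with the OR rule", {
  ds <- toy_dataset(g = 5, n1 = 6, n2 = 6, seed = 8)
  cc <- condition_correlations(ds)

  all_cfg <- analysis_config(density = 1)
  expect_true(all(select_links(cc$r1, cc$r2, all_cfg)$is_link))

  cfg <- analysis_config(density = 0.1)
  links <- select_links(cc$r1, cc$r2, cfg)
  expect_identical(nrow(links), 10L)
  # brute-force: cutoff is the ceiling(0.1 * 10) = 1st largest |r| per condition
  t1 <- max(abs(links$r1)); t2 <- max(abs(links$r2))
  expect_equal(attr(links, "t1"), t1)
  expect_equal(attr(links, "t2"), t2)
  expect_identical(links$is_link, abs(links$r1) >= t1 | abs(links$r2) >= t2)

  same <- select_links(cc$r1, cc$r1, cfg)
  expect_identical(same$is_link, abs(same$r1) >= attr(same, "t1"))
})

test_that("single-bin DCL calling equals the brute-force top-k oracle", {
  cfg <- analysis_config(dcl_fraction = 0.1)
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:30, 1)
    r1 <- runif(n, -0.9, 0.9)
    r2 <- runif(n, -0.9, 0.9)
    links <- fake_links(r1, r2, t1 = 0.6, t2 = 0.6)
    called <- call_dcls(links, cfg)
    got <- paste(called$gene_a, called$gene_b)[called$is_dcl]
    want <- oracle_dcls(links, 0.1, 0.6, 0.6)
    expect_setequal(got, want)
  }
})

test_that("20 same-signed pairs at fraction 0.1 yield the two largest folds", {
  set.seed(21)
  r1 <- runif(20, 0.1, 0.9)
  r2 <- runif(20, 0.1, 0.9)
  links <- fake_links(r1, r2, t1 = 0.95, t2 = 0.95)   # cutoffs exclude sign-switch path
  called <- call_dcls(links, analysis_config(dcl_fraction = 0.1))
  expect_identical(sum(called$is_dcl), 2L)
  fold <- pmax(r1, r2) / pmin(r1, r2)
  worst_selected <- min(called$fold[called$is_dcl])
  expect_gte(worst_selected, sort(fold, decreasing = TRUE)[2])
})

test_that("sign-switch pairs above both cutoffs are DCLs of type diff_signed", {
  links <- fake_links(c(0.9, 0.2, 0.5), c(-0.9, 0.3, 0.6), t1 = 0.6, t2 = 0.6)
  cfg <- analysis_config(dcl_fraction = 0.5)
  called <- call_dcls(links, cfg)
  row <- called[called$r1 == 0.9, ]
  expect_true(row$is_dcl)
  expect_identical(row$category, "diff_signed")
})

test_that("raising the DCL fraction never shrinks the single-bin DCL set", {
  set.seed(9)
  links <- fake_links(runif(25, 0.05, 0.95), runif(25, 0.05, 0.95),
                      t1 = 0.9, t2 = 0.9)
  counts <- vapply(c(0.05, 0.1, 0.2, 0.4), function(q)
    sum(call_dcls(links, analysis_config(dcl_fraction = q))$is_dcl), 1L)
  expect_true(all(diff(counts) >= 0))
})

test_that("DCL categories follow the sign/trend definitions", {
  expect_identical(classify_dcl(0.8, 0.1), "decreased_positive")
  expect_identical(classify_dcl(0.5, -0.6), "diff_signed")
  expect_identical(classify_dcl(-0.7, -0.2), "same_signed_negative")
  expect_identical(classify_dcl(0.1, 0.9), "increased_positive")
  expect_identical(classify_dcl(0, 0.3), "increased_positive")  # zero is positive
  expect_error(classify_dcl(0.4, 0.4), "internal error")
})

test_that("DCG binomial tail matches pmf summation and edge cases", {
  links <- fake_links(c(0.9, 0.8, 0.85), c(0.1, 0.75, 0.8),
                      t1 = 0.5, t2 = 0.5, genes = c("a", "b", "c"))
  called <- call_dcls(links, analysis_config(dcl_fraction = 0.34))
  dcgs <- call_dcgs(called, analysis_config())
  expect_true(all(dcgs$p[dcgs$d == 0] == 1))

  # direct pmf-summation oracle: P(X >= 5), X ~ Binom(10, 0.1)
  oracle <- sum(dbinom(5:10, 10, 0.1))
  expect_equal(pbinom(4, 10, 0.1, lower.tail = FALSE), oracle, tolerance = 1e-12)
  expect_equal(oracle, 0.001634937, tolerance = 1e-6)

  # saturated null: pi = 1 makes every tail probability 1
  expect_equal(pbinom(0:9, 10, 1, lower.tail = FALSE)[1], 1)
  expect_true(all(dcgs$q >= 0 & dcgs$q <= 1))
})

test_that("category shares partition the DCL set and pi stays in range", {
  ds <- toy_dataset(g = 12, n1 = 10, n2 = 10, seed = 3)
  res <- diff_coexp(ds, cfg = analysis_config())
  expect_lte(res$n_dcls, res$n_links)
  expect_gte(res$pi_global, 0)
  expect_lte(res$pi_global, 1)
  if (res$n_dcls > 0) {
    expect_equal(sum(res$category_shares), 1)
    counts <- table(res$links$category[res$links$is_dcl])
    expect_identical(sum(counts), res$n_dcls)
  }
  # every DCL is a link
  expect_true(all(res$links$is_link[res$links$is_dcl]))
})
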
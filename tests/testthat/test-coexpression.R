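test_that("perfectly related profiles hit r = +/-1 with both methods", {
  x <- seq_len(48) + 0.5
  mat <- rbind(a = x, b = x, c = -x)
  e <- pairwise_correlations(mat)
  ab <- e[e$gene_a == "a" & e$gene_b == "b", ]
  ac <- e[e$gene_a == "a" & e$gene_b == "c", ]
  expect_equal(ab$r_pearson, 1)
  expect_equal(ab$r_spearman, 1)
  expect_equal(ac$r_pearson, -1)
  expect_equal(ac$r_spearman, -1)
})

test_that("all r and p match the textbook double-loop oracle to 1e-10", {
  set.seed(20)
  mat <- matrix(stats::rnorm(20 * 48), 20, 48,
                dimnames = list(sprintf("g%02d", 1:20), NULL))
  e <- pairwise_correlations(mat)
  expect_equal(nrow(e), choose(20, 2))
  for (k in seq_len(nrow(e))) {
    x <- mat[e$gene_a[k], ]
    y <- mat[e$gene_b[k], ]
    op <- oracle_pearson(x, y)
    os <- oracle_spearman(x, y)
    expect_equal(e$r_pearson[k], op$r, tolerance = 1e-10)
    expect_equal(e$p_pearson[k], op$p, tolerance = 1e-10)
    expect_equal(e$r_spearman[k], os$r, tolerance = 1e-10)
    expect_equal(e$p_spearman[k], os$p, tolerance = 1e-10)
  }
})

test_that("zero-variance genes are excluded with a warning", {
  mat <- rbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5), c = c(2, 1, 4, 3))
  expect_warning(e <- pairwise_correlations(mat), "b")
  expect_false("b" %in% c(e$gene_a, e$gene_b))
  expect_equal(nrow(e), 1)
})

test_that("edge thresholding is a symmetric, monotone dual-method AND", {
  mk_edge <- function(rp, rs, pp = 1e-6, ps = 1e-6) {
    data.frame(gene_a = "a", gene_b = "b", r_pearson = rp,
               p_pearson = pp, r_spearman = rs, p_spearman = ps,
               stringsAsFactors = FALSE)
  }
  expect_equal(threshold_edges(mk_edge(0.79, 0.95))$entries["a", "b"], 0)
  expect_equal(threshold_edges(mk_edge(-0.9, -0.88))$entries["a", "b"], -1)
  # disagreeing signs never call
  expect_equal(threshold_edges(mk_edge(0.9, -0.9))$entries["a", "b"], 0)
  # p above cutoff blocks the call
  expect_equal(threshold_edges(mk_edge(0.9, 0.9, pp = 0.02))$entries["a", "b"], 0)
  # OR mode admits single-method passes with agreeing signs
  expect_equal(threshold_edges(mk_edge(0.9, 0.5), mode = "or")$entries["a", "b"], 1)

  set.seed(8)
  sim <- gen_diurnal_matrix(20, 48,
                            data.frame(size = c(6, 6),
                                       phase = c(0, acos(-0.9 / 0.95))),
                            seed = 8)
  e <- pairwise_correlations(sim$matrix)
  loose <- threshold_edges(e, r_cut = 0.7, p_cut = 0.05)
  tight <- threshold_edges(e, r_cut = 0.85, p_cut = 0.001)
  # symmetry, zero diagonal
  expect_identical(loose$entries, t(loose$entries))
  expect_true(all(diag(loose$entries) == 0))
  # tightening never adds entries
  expect_true(all(loose$entries[tight$entries != 0] != 0))
  # nonzero count equals an independent recount of the filter
  pass <- abs(e$r_pearson) >= 0.7 & abs(e$r_spearman) >= 0.7 &
    e$p_pearson < 0.05 & e$p_spearman < 0.05 &
    sign(e$r_pearson) == sign(e$r_spearman)
  expect_equal(sum(loose$entries != 0) / 2, sum(pass))
})

test_that("first-PC ordering makes anti-correlated blocks contiguous", {
  set.seed(13)
  sim <- gen_diurnal_matrix(16, 48,
                            data.frame(size = c(8, 8), phase = c(0, pi)),
                            seed = 13)
  ord <- order_by_first_pc(sim$matrix)
  blockA <- sim$truth$gene_id[sim$truth$module == 1]
  posA <- sort(match(blockA, ord))
  expect_equal(posA, seq(posA[1], length.out = 8))  # contiguous

  expect_equal(order_by_first_pc(matrix(1:5, 1,
                                        dimnames = list("g1", NULL))), "g1")
  flat <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(ord2 <- order_by_first_pc(flat), "degenerate")
  expect_equal(ord2, c("a", "b"))
})

test_that("sign clustering recovers antagonistic modules", {
  set.seed(17)
  sim <- gen_diurnal_matrix(24, 48,
                            data.frame(size = c(10, 10), phase = c(0, pi)),
                            seed = 17)
  e <- pairwise_correlations(sim$matrix)
  bsm <- threshold_edges(e)
  cl <- detect_sign_clusters(bsm, k = 2)
  modA <- sim$truth$gene_id[sim$truth$module == 1]
  modB <- sim$truth$gene_id[sim$truth$module == 2]
  expect_equal(length(unique(cl$labels[modA])), 1)
  expect_equal(length(unique(cl$labels[modB])), 1)
  expect_false(cl$labels[modA[1]] == cl$labels[modB[1]])
  expect_true(cl$antagonistic)

  # a single all-positive module is not antagonistic
  simp <- gen_diurnal_matrix(10, 48, data.frame(size = 10, phase = 0),
                             seed = 2)
  clp <- detect_sign_clusters(
    threshold_edges(pairwise_correlations(simp$matrix)), k = 2)
  expect_false(clp$antagonistic)

  # all-zero matrix yields no clusters
  noise <- matrix(stats::rnorm(5 * 48), 5, 48,
                  dimnames = list(letters[1:5], NULL))
  bz <- threshold_edges(pairwise_correlations(noise))
  expect_equal(length(detect_sign_clusters(bz)$labels), 0)
})
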
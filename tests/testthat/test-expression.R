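test_that("rpkm follows the direct formula and is linear in counts", {
  expect_equal(rpkm(10, 2000, 1e6), 5)
  expect_equal(rpkm(0, 2000, 1e6), 0)
  expect_equal(rpkm(20, 2000, 1e6), 2 * rpkm(10, 2000, 1e6))
  expect_equal(rpkm(10, 2000, 2e6), rpkm(10, 2000, 1e6) / 2)
  expect_error(rpkm(10, 0, 1e6), "gene_length")
  expect_error(rpkm(10, 2000, 0), "library_size")
})

test_that("log2 ratios use the control column and the pseudocount contract", {
  m <- matrix(c(2, 2, 8, 2, 0, 0), nrow = 2,
              dimnames = list(c("g1", "g2"), c("D0", "D3", "D6")))
  lr <- log2_ratio_matrix(m, "D0", pseudocount = 0)
  expect_equal(lr["g1", "D3"], 2)        # 8 / 2
  expect_equal(lr["g2", "D3"], 0)        # equal values
  expect_equal(unname(lr[, "D0"]), c(0, 0))
  lr1 <- log2_ratio_matrix(m, "D0", pseudocount = 1)
  expect_equal(lr1["g2", "D6"], log2(1 / 3))   # (0+1)/(2+1)
  zz <- matrix(c(0, 0), 1, dimnames = list("g", c("D0", "D3")))
  expect_equal(log2_ratio_matrix(zz, "D0", pseudocount = 1)["g", "D3"], 0)
  expect_error(log2_ratio_matrix(m, "DX"), "control column")
})

test_that("fold-change classes follow the two-fold rule with up precedence", {
  lr <- rbind(up = c(0, 1.2, 2.1, 0.5), flat = c(0, 0.9, -0.8, 0.2),
              down = c(0, -1.5, -0.2, 0), both = c(0, 1.4, -2.2, 0))
  colnames(lr) <- c("D0", "D1", "D3", "D6")
  calls <- fold_change_classify(lr, threshold = 2, control = "D0")
  cls <- setNames(calls$class, calls$gene_id)
  expect_identical(unname(cls[c("up", "flat", "down", "both")]),
                   c("up", "unresponsive", "down", "up"))
  expect_true(calls$both_directions[calls$gene_id == "both"])
  s <- attr(calls, "summary")
  expect_identical(unname(s), c(2L, 1L, 1L))
})

test_that("planted 44 up / 19 down responders are recovered at zero noise", {
  sim <- simulate_expression_matrix(seed = 3)
  lr <- log2_ratio_matrix(sim$matrix, sim$control, pseudocount = 0)
  calls <- fold_change_classify(lr, threshold = 2, control = sim$control)
  s <- attr(calls, "summary")
  expect_identical(unname(s[c("up", "down")]), c(44L, 19L))
  expect_identical(calls$class,
                   sim$truth$class[match(calls$gene_id, sim$truth$gene_id)])
})

test_that("classification keeps >= 95% sensitivity for 4-fold effects under noise", {
  sim <- simulate_expression_matrix(n_genes = 500, n_up = 120, n_down = 60,
                                    up_fold_range = c(4, 1024),
                                    down_fold_range = c(4, 64),
                                    noise = 0.25, seed = 9)
  lr <- log2_ratio_matrix(sim$matrix, sim$control, pseudocount = 1)
  calls <- fold_change_classify(lr, threshold = 2, control = sim$control)
  truth <- sim$truth$class[match(calls$gene_id, sim$truth$gene_id)]
  sens <- mean(calls$class[truth != "unresponsive"] == truth[truth != "unresponsive"])
  expect_gte(sens, 0.95)
})

test_that("hierarchical clustering orders leaves deterministically", {
  m <- rbind(a = c(0, 0, 0), b = c(0, 0, 0), c = c(5, 5, 5))
  hc <- hierarchical_cluster(m, metric = "euclidean", linkage = "average")
  expect_equal(min(hc$heights), 0)   # identical rows merge at height 0

  x <- matrix(c(0, 0.1, 10, 10.1), 4, 1,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  cut2 <- hierarchical_cluster(x, k = 2)$clusters
  expect_identical(unname(cut2[c("a", "b")]), c(1L, 1L))
  expect_identical(unname(cut2[c("c", "d")]), c(2L, 2L))

  set.seed(4)
  r <- matrix(rnorm(40), 8, 5, dimnames = list(letters[1:8], NULL))
  o1 <- hierarchical_cluster(r)$order
  o2 <- hierarchical_cluster(r[sample(8), ])$order
  expect_true(identical(o1, o2) || identical(o1, rev(o2)) ||
                setequal(o1, o2))   # same leaf set; order stable up to mirror

  cm <- rbind(flat = c(1, 1, 1), g2 = c(1, 2, 3))
  expect_error(hierarchical_cluster(cm, metric = "correlation"),
               "constant expression row.*flat")
  expect_error(hierarchical_cluster(cm[1, , drop = FALSE]), ">= 2 genes")
})

test_that("2^-ddCt relative expression is exact on constructed Ct tables", {
  # treated dCt 2 vs control dCt 1 -> 0.5
  tgt <- c(ctrl = 21, trt = 23)
  ref <- c(ctrl = 20, trt = 21)
  r <- delta_delta_ct(tgt, ref, "ctrl")
  expect_equal(r$rel_expr[r$sample == "trt"], 0.5)
  expect_equal(r$rel_expr[r$sample == "ctrl"], 1)

  # planted 8-fold induction: ddCt = -3
  tgt2 <- c(D0 = 25, D3 = 22)
  ref2 <- c(D0 = 20, D3 = 20)
  r2 <- delta_delta_ct(tgt2, ref2, "D0")
  expect_equal(r2$rel_expr[r2$sample == "D3"], 8)

  # technical replicates give a finite SE
  tgtm <- rbind(D0 = c(25, 25.2, 24.8), D3 = c(22, 22.1, 21.9))
  refm <- rbind(D0 = c(20, 20, 20), D3 = c(20, 20, 20))
  rm <- delta_delta_ct(tgtm, refm, "D0")
  expect_true(all(rm$se >= 0))
  expect_equal(rm$rel_expr[rm$sample == "D3"], 8, tolerance = 0.1)

  expect_error(delta_delta_ct(c(a = 1, b = 2), c(a = 1), "a"),
               "missing reference.*b")
  expect_error(delta_delta_ct(c(a = NA, b = 2), c(a = 1, b = 1), "a"),
               "non-finite")
})
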
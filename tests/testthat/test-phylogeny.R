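# independent pairwise Needleman-Wunsch score oracle (linear gap)
nw_score_oracle <- function(s1, s2, gap = -8) {
  B <- wrkyfamkit:::blosum62()
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  M <- matrix(0, length(a) + 1, length(b) + 1)
  M[, 1] <- gap * (0:length(a)); M[1, ] <- gap * (0:length(b))
  for (i in seq_along(a)) for (j in seq_along(b)) {
    M[i + 1, j + 1] <- max(M[i, j] + B[a[i], b[j]],
                           M[i, j + 1] + gap, M[i + 1, j] + gap)
  }
  M[length(a) + 1, length(b) + 1]
}

aln_score <- function(aln, gap = -8) {
  B <- wrkyfamkit:::blosum62()
  m <- alignment_matrix(aln)
  s <- 0
  for (j in seq_len(ncol(m))) {
    s <- s + if (any(m[, j] == "-")) gap else B[m[1, j], m[2, j]]
  }
  s
}

test_that("progressive alignment matches pairwise NW and is order-stable", {
  ident <- progressive_align(c(a = "MKVLW", b = "MKVLW"))
  expect_identical(unname(unclass(ident)), c("MKVLW", "MKVLW"))

  aln <- progressive_align(c(s1 = "ACDEF", s2 = "ACEF"))
  expect_identical(nchar(aln[["s1"]]), 5L)
  expect_identical(sum(alignment_matrix(aln) == "-"), 1L)
  expect_equal(aln_score(aln), nw_score_oracle("ACDEF", "ACEF"))

  seqs <- c(x = "MKWVFAGHILK", y = "MKWVFGHILK", z = "MKWVFAGHILRR",
            w = "MKYVFAGHILK")
  a1 <- progressive_align(seqs)
  a2 <- progressive_align(seqs[c(3, 1, 4, 2)])
  expect_identical(unclass(a1)[names(seqs)], unclass(a2)[names(seqs)])
  # ungapping recovers inputs
  expect_identical(gsub("-", "", unclass(a1)[names(seqs)]), seqs)

  expect_error(progressive_align(c(only = "MKV")), ">= 2")
})

test_that("pairwise deletion distances count mismatches over comparable sites", {
  aln <- c(a = "AAAAAAAAAA", b = "AAAAAAAATT")
  d <- distance_matrix(aln, model = "p")
  expect_equal(d["a", "b"], 0.2)
  expect_equal(diag(d), c(a = 0, b = 0))

  # gapped columns excluded pairwise: a/b comparable at 4 sites, 1 mismatch
  g <- c(a = "AC-GTA", b = "AC-GAA", c = "ACCG--")
  dg <- distance_matrix(g, model = "p")
  expect_equal(dg["a", "b"], 1 / 5)
  expect_equal(dg["a", "c"], 0)

  pois <- distance_matrix(aln, model = "poisson")
  expect_equal(pois["a", "b"], -log(0.8))

  none <- c(a = "AA--", b = "--TT")
  expect_error(distance_matrix(none), "no comparable columns.*a / b")

  # invariant to taxon reordering
  d2 <- distance_matrix(g[c(2, 3, 1)], model = "p")
  expect_equal(d2[rownames(dg), colnames(dg)], dg)
})

test_that("nj_tree solves the three-point case and demands symmetry", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  pend <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(pend[c("A", "B", "C")], c(A = 1, B = 1, C = 3))

  bad <- d; bad[1, 2] <- 3
  expect_error(nj_tree(bad), "not symmetric")
  expect_error(nj_tree(d[1:2, 1:2]), ">= 3 taxa")
})

test_that("nj_tree recovers random additive trees exactly", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  for (i in 1:20) {
    tr <- ape::unroot(ape::rtree(8, br = function(n) runif(n, 0.1, 1)))
    dm <- ape::cophenetic.phylo(tr)
    dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
    est <- nj_tree(dm)
    expect_equal(as.numeric(phangorn::RF.dist(est, tr)), 0)
    # path lengths reproduce the additive input matrix
    back <- ape::cophenetic.phylo(est)[rownames(dm), colnames(dm)]
    expect_equal(back, dm, tolerance = 1e-8)
  }
})

test_that("nj_tree is deterministic under tied Q values", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  t1 <- ape::write.tree(nj_tree(d))
  t2 <- ape::write.tree(nj_tree(d))
  expect_identical(t1, t2)
})

test_that("bootstrap supports are seeded, bounded and maximal for clean splits", {
  # every column supports the same split -> 100
  aln <- c(a = "AAAACCCC", b = "AAAACCCC", c = "TTTTGGGG", d = "TTTTGGGG")
  tr <- bootstrap_support(aln, n_replicates = 50, seed = 3)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))

  set.seed(99)
  rand <- setNames(vapply(1:5, function(i) {
    paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  }, character(1)), paste0("t", 1:5))
  tb <- bootstrap_support(rand, n_replicates = 30, seed = 5)
  sup <- suppressWarnings(as.numeric(tb$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  tb2 <- bootstrap_support(rand, n_replicates = 30, seed = 5)
  expect_identical(ape::write.tree(tb), ape::write.tree(tb2))
  expect_error(bootstrap_support(rand, n_replicates = 0), ">= 1")
})
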
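test_that("ng86_kaks reproduces hand-counted sites and differences", {
  r <- ng86_kaks("GGTGGA", "GGCGGA")
  expect_equal(r$S, 2)
  expect_equal(r$N, 4)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$ps, 0.5)
  expect_equal(r$ks, -0.75 * log(1 - 4 * 0.5 / 3))
  expect_equal(r$ka, 0)

  ident <- ng86_kaks("ATGGCT", "ATGGCT")
  expect_equal(c(ident$ka, ident$ks), c(0, 0))
  expect_true(is.na(ident$omega))

  expect_error(ng86_kaks("ATGTAAGCT", "ATGGCTGCT"), "internal stop")
  expect_error(ng86_kaks("ATGG", "ATGG"), "divisible by 3")
})

test_that("ng86_kaks is symmetric and S + N = 3 x codons", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    a <- paste(random_sense_codons(n), collapse = "")
    b <- paste(random_sense_codons(n), collapse = "")
    r1 <- ng86_kaks(a, b)
    r2 <- ng86_kaks(b, a)
    expect_equal(r1[c("ka", "ks", "S", "N", "Sd", "Nd")],
                 r2[c("ka", "ks", "S", "N", "Sd", "Nd")])
    expect_equal(r1$S + r1$N, 3 * n)
  }
})

test_that("ng86 counts match a brute-force pathway enumerator on codon pairs", {
  set.seed(23)
  checked <- 0
  while (checked < 150) {
    pair <- random_sense_codons(2)
    oracle <- brute_pathway_counts(pair[1], pair[2])
    if (is.null(oracle)) next   # every pathway passes through a stop
    r <- ng86_kaks(pair[1], pair[2])
    expect_equal(c(r$Sd, r$Nd), unname(oracle), tolerance = 1e-12)
    expect_equal(r$S, (brute_syn_sites(pair[1]) + brute_syn_sites(pair[2])) / 2)
    checked <- checked + 1
  }
})

test_that("codon rate matrices are proper generators with stochastic P(t)", {
  m <- codon_model(2.5, data.frame(weight = 1, omega_bg = 0.4, omega_fg = 0.4))
  q <- codon_rate_matrix(m, 0.4)
  expect_equal(max(abs(rowSums(q))), 0, tolerance = 1e-12)
  expect_true(all(q[row(q) != col(q)] >= 0))
  for (t in c(0.01, 0.3, 2, 10)) {
    p <- codon_pmatrix(m, 0.4, t)
    expect_equal(max(abs(rowSums(p) - 1)), 0, tolerance = 1e-10)
    expect_true(all(p >= 0))
  }
  # neutral normalization: mean rate 1 at omega = 1
  q1 <- codon_rate_matrix(m, 1)
  expect_equal(-sum(m$pi * diag(q1)), 1, tolerance = 1e-12)
})

test_that("codon likelihood matches closed-form cases and the pulley principle", {
  m <- codon_model(2, data.frame(weight = 1, omega_bg = 0.5, omega_fg = 0.5))
  tr0 <- ape::read.tree(text = "(A:0,B:0);")
  ll <- codon_log_likelihood(c(A = "AAA", B = "AAA"), tr0, m)
  expect_equal(as.numeric(ll), log(1 / 61))

  # marginalizing one leaf over all 61 codon states gives pi of the other
  ct <- wrkyfamkit:::codon_tables()
  tr <- ape::read.tree(text = "(A:0.3,B:0.2);")
  tot <- sum(vapply(ct$codons, function(cod) {
    exp(as.numeric(codon_log_likelihood(c(A = "GCT", B = cod), tr, m)))
  }, numeric(1)))
  expect_equal(tot, 1 / 61, tolerance = 1e-10)

  # lnL invariant to the pruning root (re-rooting at either internal node)
  tr4 <- ape::read.tree(text = "((A:0.2,B:0.4):0.15,(C:0.3,D:0.25):0.1);")
  aln4 <- c(A = "ATGAAA", B = "ATGAAG", C = "CTGAAA", D = "ATGCAA")
  cp <- wrkyfamkit:::codon_patterns(aln4)
  lls <- vapply(c(5L, 6L, 7L), function(root) {
    po <- wrkyfamkit:::tree_postorder(tr4, root)
    sum(wrkyfamkit:::class_site_loglik_cpp(
      po$edge, po$length, 0L, cp$patterns, 7L, po$root, m$pi, ct$type,
      m$kappa, 0.5, 0.5)[1, ] * cp$weights)
  }, numeric(1))
  expect_equal(max(lls) - min(lls), 0, tolerance = 1e-9)
})

test_that("likelihood_ratio_test computes the chi-square test from lnL values", {
  r <- likelihood_ratio_test(-9212.750, -9230.368)
  expect_equal(r$statistic, 35.236)
  expect_true(r$p_value < 0.01)
  expect_identical(r$df, 1L)

  same <- likelihood_ratio_test(-100, -100)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  q <- likelihood_ratio_test(-100, -100 - 6.635 / 2)
  expect_equal(q$p_value, 0.01, tolerance = 1e-3)

  mix <- likelihood_ratio_test(-100, -100 - 6.635 / 2, null_dist = "mixture")
  expect_equal(mix$p_value, q$p_value / 2, tolerance = 1e-9)

  expect_error(likelihood_ratio_test(-101, -100), "optimizer failure")
})

test_that("codon simulation is seeded, degenerate at zero length, and model-consistent", {
  tr <- bs_sim_tree()
  s1 <- simulate_codon_alignment(tr, 40, foreground = "A", seed = 5)
  s2 <- simulate_codon_alignment(tr, 40, foreground = "A", seed = 5)
  expect_identical(s1$alignment, s2$alignment)
  expect_identical(s1$site_class, s2$site_class)

  tz <- tr; tz$edge.length[] <- 0
  sz <- simulate_codon_alignment(tz, 30, seed = 2)
  expect_identical(length(unique(sz$alignment)), 1L)

  expect_error(simulate_codon_alignment(tr, 10, proportions = c(1, 1, 0, 0)),
               "sum to 1")
  expect_error(simulate_codon_alignment(tr, 10, omega2 = 0.5), "omega2")
})

test_that("with no selected classes, pairwise omega matches the class mixture", {
  # p2a = p2b = 0: evolution is a mixture of omega0 and neutral sites, so the
  # NG86 dN/dS over replicates should center near p0*omega0 + p1
  tr2 <- ape::read.tree(text = "(X:0.15,Y:0.15);")
  p0 <- 0.5; w0 <- 0.2
  omegas <- vapply(1:100, function(s) {
    sim <- simulate_codon_alignment(tr2, 150, kappa = 2,
                                    proportions = c(p0, 1 - p0, 0, 0),
                                    omega0 = w0, omega2 = 1, seed = s)
    r <- ng86_kaks(sim$alignment[[1]], sim$alignment[[2]])
    r$omega
  }, numeric(1))
  expect_equal(mean(omegas, na.rm = TRUE), p0 * w0 + (1 - p0), tolerance = 0.12)
})

test_that("branch-site fits are nested and respect the model-A weight constraint", {
  tr <- bs_sim_tree()
  sim <- simulate_codon_alignment(tr, 150, foreground = "A", omega2 = 1, seed = 31)
  res <- branch_site_test(sim$alignment, tr, "A", pi = "equal")
  expect_true(res$alternative$lnL >= res$null$lnL - 1e-9)
  expect_true(res$lrt$statistic >= 0)
  for (f in list(res$alternative, res$null)) {
    expect_equal(f$p0 + f$p1 + f$p2a + f$p2b, 1, tolerance = 1e-8)
    expect_equal(f$p2a / f$p2b, f$p0 / f$p1, tolerance = 1e-6)
    expect_true(f$w0 > 0 && f$w0 < 1)
  }
  expect_equal(res$null$w2, 1)
  expect_true(res$alternative$w2 >= 1)
})
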
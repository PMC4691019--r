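test_that("generators are pure functions of their seed", {
  s1 <- family_plant_spec(
    n_members = c("1" = 2, "2a" = 2, "2b" = 0, "2c" = 0, "2d" = 0,
                  "2e" = 0, "3" = 2),
    tandem_clusters = data.frame(chromosome = "Chr1", size = 2, group = "2a",
                                 max_gap = 3),
    segmental_blocks = data.frame(anchors = 5, window = 50, group = "3"),
    background_per_chromosome = c(Chr1 = 120, Chr2 = 120),
    seed = 4)
  g1 <- generate_annotated_genome(s1)
  g2 <- generate_annotated_genome(s1)
  expect_identical(g1$proteins, g2$proteins)
  expect_identical(g1$cds, g2$cds)
  expect_identical(g1$truth$members, g2$truth$members)

  e1 <- simulate_expression_matrix(n_genes = 30, n_up = 5, n_down = 5, seed = 2)
  e2 <- simulate_expression_matrix(n_genes = 30, n_up = 5, n_down = 5, seed = 2)
  expect_identical(e1$matrix, e2$matrix)
})

test_that("planted proteins carry their group's exact motif architecture", {
  g <- default_genome()
  tm <- g$truth$members
  g3 <- g$proteins[[tm$id[tm$template == "3"][1]]]
  # Group 3: WRKYGQK then C-X7-C-X23-H-X-C
  expect_true(grepl("WRKYGQK.{10}C.{7}C.{23}H.C", g3))
  g2a <- g$proteins[[tm$id[tm$template == "2a"][1]]]
  expect_true(grepl("WRKYGQK.{10}C.{4}C.{22}H.H", g2a))
  g1p <- g$proteins[[tm$id[tm$template == "1" & !tm$single_domain][1]]]
  expect_identical(lengths(regmatches(g1p, gregexpr("WRKYGQK", g1p))), 2L)
  # background genes never contain the heptapeptide
  bg <- g$proteins[!names(g$proteins) %in% tm$id]
  expect_false(any(grepl("WRKYGQK", bg, fixed = TRUE)))
})

test_that("a spec with zero family members scans to an empty family", {
  spec <- family_plant_spec(
    n_members = c("1" = 0, "2a" = 0, "2b" = 0, "2c" = 0, "2d" = 0,
                  "2e" = 0, "3" = 0),
    tandem_clusters = data.frame(chromosome = character(), size = integer(),
                                 group = character(), max_gap = integer()),
    segmental_blocks = data.frame(anchors = integer(), window = integer(),
                                  group = character()),
    background_per_chromosome = c(Chr1 = 80), seed = 1)
  g <- generate_annotated_genome(spec)
  sc <- scan_proteome(g$proteins)
  expect_identical(nrow(sc$members), 0L)
})

test_that("overfull chromosomes are rejected", {
  spec <- family_plant_spec(
    n_members = c("1" = 0, "2a" = 12, "2b" = 0, "2c" = 0, "2d" = 0,
                  "2e" = 0, "3" = 0),
    tandem_clusters = data.frame(chromosome = rep("Chr1", 6), size = 2,
                                 group = "2a", max_gap = 10),
    segmental_blocks = data.frame(anchors = integer(), window = integer(),
                                  group = character()),
    background_per_chromosome = c(Chr1 = 30), seed = 1)
  expect_error(generate_annotated_genome(spec), "cannot hold")
})

test_that("expression simulator honors the planted-fold contracts", {
  sim <- simulate_expression_matrix(n_genes = 10, n_up = 1, n_down = 0,
                                    up_fold_range = c(4, 4), noise = 0, seed = 6)
  lr <- log2_ratio_matrix(sim$matrix, sim$control, pseudocount = 0)
  up <- sim$truth$gene_id[sim$truth$class == "up"]
  expect_equal(max(lr[up, ]), 2)   # planted 4-fold, zero noise -> exactly 2

  flat <- simulate_expression_matrix(n_genes = 20, n_up = 0, n_down = 0,
                                     noise = 0, seed = 6)
  lrf <- log2_ratio_matrix(flat$matrix, flat$control, pseudocount = 0)
  calls <- fold_change_classify(lrf, threshold = 2, control = flat$control)
  expect_true(all(calls$class == "unresponsive"))

  expect_error(simulate_expression_matrix(up_fold_range = c(0, 4)),
               "positive")
  expect_error(simulate_expression_matrix(noise = -1), "noise")
})
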
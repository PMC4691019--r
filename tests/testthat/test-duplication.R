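# a linear toy chromosome set: gene ids gN placed at consecutive ranks
toy_annotation <- function(n = 60, chroms = "chr1") {
  genes <- list()
  for (ch in chroms) {
    for (i in seq_len(n)) {
      id <- sprintf("%s_g%02d", ch, i - 1L)
      s <- (i - 1L) * 1000L
      genes[[id]] <- gene_model(id, ch, s, s + 300L, "+")
    }
  }
  genome_annotation(genes)
}

test_that("tandem clusters follow the 10-gene rule with single linkage", {
  ann <- toy_annotation()
  fam <- c("chr1_g05", "chr1_g12")
  cl <- find_tandem_clusters(ann, fam)          # gap 7 <= 10
  expect_identical(length(unique(cl$cluster_id)), 1L)
  expect_setequal(cl$gene_id, fam)

  none <- find_tandem_clusters(ann, c("chr1_g05", "chr1_g20"))  # gap 15
  expect_identical(nrow(none), 0L)

  # transitivity: 5,12,20 chain into one cluster
  tri <- find_tandem_clusters(ann, c("chr1_g05", "chr1_g12", "chr1_g20"))
  expect_identical(length(unique(tri$cluster_id)), 1L)
  expect_identical(nrow(tri), 3L)

  expect_error(find_tandem_clusters(ann, "nope"), "unknown gene")

  # idempotent and order-invariant
  sh <- find_tandem_clusters(ann, rev(fam))
  expect_identical(sh$gene_id, cl$gene_id)
})

plant_block <- function(n_anchors, reversed = FALSE) {
  ann <- toy_annotation(n = 60, chroms = c("chr1", "chr2"))
  offs <- seq_len(n_anchors) - (n_anchors %/% 2)
  offs <- offs[offs != 0]
  while (length(offs) < n_anchors) offs <- c(offs, max(offs) + 1L)
  fa <- 30L; fb <- 30L
  b_offs <- if (reversed) -offs else offs
  hom <- data.frame(
    a = sprintf("chr1_g%02d", fa + offs),
    b = sprintf("chr2_g%02d", fb + b_offs),
    stringsAsFactors = FALSE)
  list(ann = ann, hom = hom,
       fam = c("chr1_g30", "chr2_g30"))
}

test_that("synteny blocks need min_pairs collinear anchors within the window", {
  pb <- plant_block(8)
  bl <- find_synteny_blocks(pb$ann, pb$fam, pb$hom)
  expect_identical(nrow(bl), 1L)
  expect_identical(bl$anchors, 8L)
  expect_true(bl$evalue <= 0.01)

  # two homologous pairs are below the three-pair rule
  pb2 <- plant_block(8)
  bl2 <- find_synteny_blocks(pb2$ann, pb2$fam, pb2$hom[1:2, ])
  expect_identical(nrow(bl2), 0L)

  # inversion: anchors reversed on one chromosome still chain
  pbr <- plant_block(8, reversed = TRUE)
  blr <- find_synteny_blocks(pbr$ann, pbr$fam, pbr$hom)
  expect_identical(blr$anchors, 8L)

  expect_error(find_synteny_blocks(pb$ann, pb$fam, pb$hom,
                                   window = 2, min_pairs = 3),
               "window must be >= min_pairs")
})

test_that("block E-value decreases as anchors accumulate", {
  ev <- vapply(c(3, 5, 8, 12), function(k) {
    pb <- plant_block(k)
    bl <- find_synteny_blocks(pb$ann, pb$fam, pb$hom, evalue_cutoff = 1)
    bl$evalue[1]
  }, numeric(1))
  expect_true(all(diff(ev) < 0))
})

test_that("duplication classes follow the segmental > tandem > proximal > dispersed precedence", {
  ann <- toy_annotation(n = 60, chroms = c("chr1", "chr2"))
  fam <- c("chr1_g05", "chr1_g08", "chr1_g30", "chr2_g30", "chr1_g50",
           "chr2_g05", "chr2_g50")
  hom <- data.frame(
    a = c("chr1_g05", "chr1_g30", "chr1_g50", "chr1_g05"),
    b = c("chr1_g08", "chr2_g30", "chr2_g05", "chr1_g30"))
  clusters <- find_tandem_clusters(ann, fam)
  blocks <- data.frame(gene_a = "chr1_g30", gene_b = "chr2_g30",
                       anchors = 5L, evalue = 1e-6)
  ty <- classify_duplication_types(ann, fam, hom, blocks, clusters)
  cls <- setNames(ty$class, ty$gene_id)
  expect_identical(cls[["chr1_g30"]], "segmental")  # in block and homolog set
  expect_identical(cls[["chr1_g05"]], "tandem")     # 3 ranks from its homolog
  expect_identical(cls[["chr1_g08"]], "tandem")
  expect_identical(cls[["chr1_g50"]], "dispersed")  # homolog on other chrom
  expect_identical(cls[["chr2_g05"]], "dispersed")
  expect_identical(cls[["chr2_g50"]], "singleton")  # no homolog at all

  # gene in both a block and a cluster is segmental
  fam2 <- c("chr1_g30", "chr1_g33", "chr2_g30")
  hom2 <- data.frame(a = c("chr1_g30", "chr1_g30"), b = c("chr1_g33", "chr2_g30"))
  cl2 <- find_tandem_clusters(ann, fam2)
  ty2 <- classify_duplication_types(ann, fam2, hom2, blocks, cl2)
  expect_identical(ty2$class[ty2$gene_id == "chr1_g30"], "segmental")
  expect_identical(ty2$class[ty2$gene_id == "chr1_g33"], "tandem")
})

test_that("block Ks summaries exclude saturated pairs and flag degenerate cases", {
  cds <- c(a1 = "ATGGCTGCTGCA", a2 = "ATGGCTGCTGCA",
           b1 = "ATGGCTGCTGCA", b2 = "ATGGCTGCCGCA")
  anchors <- data.frame(a = c("a1", "b1"), b = c("a2", "b2"))
  s <- summarize_block_ks(anchors, cds)
  expect_identical(s$flag, "ok")
  expect_identical(s$n_used, 2L)
  expect_equal(s$mean_ks, mean(c(0, ng86_kaks(cds[["b1"]], cds[["b2"]])$ks)))

  ident <- summarize_block_ks(data.frame(a = c("a1", "a1"), b = c("a2", "a2")), cds)
  expect_equal(ident$mean_ks, 0)
  expect_equal(ident$sd_ks, 0)

  one <- summarize_block_ks(data.frame(a = "a1", b = "a2"), cds)
  expect_identical(one$flag, "single_pair")
  expect_equal(one$sd_ks, 0)

  # saturated pair (every synonymous site differs) is dropped; none usable
  sat <- c(x = "TTATTATTATTATTATTA", y = "CTGCTGCTGCTGCTGCTG")
  allsat <- summarize_block_ks(data.frame(a = "x", b = "y"), sat)
  expect_identical(allsat$flag, "undefined")
  expect_true(is.na(allsat$mean_ks))

  expect_error(summarize_block_ks(data.frame(a = "a1", b = "zz"), cds),
               "missing CDS")
})

test_that("planted genome structures are recovered exactly at zero noise", {
  g <- default_genome()
  ids <- g$truth$members$id
  cl <- find_tandem_clusters(g$annotation, ids)
  got <- sort(vapply(split(cl$gene_id, cl$cluster_id),
                     function(x) paste(sort(x), collapse = ","), character(1)))
  want <- sort(vapply(split(g$truth$tandem$gene_id, g$truth$tandem$cluster_id),
                      function(x) paste(sort(x), collapse = ","), character(1)))
  expect_identical(unname(got), unname(want))

  bl <- find_synteny_blocks(g$annotation, ids, g$truth$homology)
  tb <- g$truth$blocks
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_setequal(key(bl$gene_a, bl$gene_b), key(tb$gene_a, tb$gene_b))
  m <- merge(data.frame(k = key(bl$gene_a, bl$gene_b), found = bl$anchors),
             data.frame(k = key(tb$gene_a, tb$gene_b), planted = tb$anchors))
  expect_identical(m$found, m$planted)
})
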
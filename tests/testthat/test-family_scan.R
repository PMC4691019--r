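test_that("find_wrky_domains locates planted C2H2 and C2HC fingers", {
  p <- planted_protein("C2H2", x1 = 4L, x2 = 22L)
  h <- find_wrky_domains(p, id = "p1")
  expect_identical(nrow(h), 1L)
  expect_identical(h$finger_type, "C2H2")
  expect_identical(h$x1, 4L)
  expect_identical(h$x2, 22L)
  expect_identical(h$hept_start, 10L)

  p3 <- planted_protein("C2HC")
  h3 <- find_wrky_domains(p3)
  expect_identical(h3$finger_type, "C2HC")
  expect_identical(c(h3$x1, h3$x2), c(7L, 23L))

  two <- paste0(planted_protein("C2H2"), planted_protein("C2H2", x1 = 5L, x2 = 23L))
  h2 <- find_wrky_domains(two)
  expect_identical(nrow(h2), 2L)
  expect_true(all(diff(h2$hept_start) > 0))

  # heptapeptide with no finger in the window
  lone <- paste0("MAAAA", "WRKYGQK", paste(rep("A", 60), collapse = ""))
  hl <- find_wrky_domains(lone)
  expect_identical(hl$finger_type, "none")

  expect_identical(nrow(find_wrky_domains("MKVLAAAA")), 0L)

  # heptapeptide variants are found only when configured
  var <- gsub("WRKYGQK", "WRKYGKK", planted_protein("C2H2"))
  expect_identical(nrow(find_wrky_domains(var)), 0L)
  hv <- find_wrky_domains(var, heptapeptides = c("WRKYGQK", "WRKYGKK"))
  expect_identical(hv$heptapeptide, "WRKYGKK")
  expect_identical(hv$finger_type, "C2H2")
})

test_that("reported finger spacers always satisfy the motif constraints", {
  set.seed(42)
  for (i in 1:200) {
    prot <- paste(sample(c("A", "C", "H", "W", "R", "K", "Y", "G", "Q"),
                         sample(40:150, 1), TRUE), collapse = "")
    prot <- paste0(prot, planted_protein(sample(c("C2H2", "C2HC"), 1)))
    h <- find_wrky_domains(prot)
    h <- h[h$finger_type != "none", , drop = FALSE]
    for (j in seq_len(nrow(h))) {
      if (h$finger_type[j] == "C2H2") {
        expect_true(h$x1[j] %in% c(4L, 5L) && h$x2[j] %in% c(22L, 23L))
      } else {
        expect_identical(c(h$x1[j], h$x2[j]), c(7L, 23L))
      }
      expect_true(all(diff(c(h$hept_start[j], h$c1[j], h$c2[j], h$h1[j], h$h2[j])) > 0))
    }
  }
})

test_that("classify_group follows domain count and finger type", {
  h_c2h2 <- find_wrky_domains(planted_protein("C2H2"))
  h_c2hc <- find_wrky_domains(planted_protein("C2HC"))
  two <- find_wrky_domains(paste0(planted_protein("C2H2"), planted_protein("C2H2")))
  expect_identical(classify_group(two), "1")
  expect_identical(classify_group(h_c2h2), "2")
  expect_identical(classify_group(h_c2hc), "3")
  expect_identical(classify_group(h_c2h2[0, ]), "unclassified")
  none <- find_wrky_domains(paste0("M", "WRKYGQK", paste(rep("A", 80), collapse = "")))
  expect_identical(classify_group(none), "unclassified")
  # pure function of the hit multiset: order never matters
  expect_identical(classify_group(two[2:1, ]), "1")
})

test_that("assign_subgroup follows nearest reference and the Group-1 override", {
  tr <- ape::read.tree(text = paste0(
    "((m1:0,ref2a:0):1,(ref2b:0.1,x:0.4):1,((m2:0.05,ref1:0.05):0.5,ref3:1):1);"))
  refs <- c(ref2a = "2a", ref2b = "2b", ref1 = "1", ref3 = "3")
  r1 <- assign_subgroup("m1", tr, refs)
  expect_identical(r1$subgroup, "2a")
  expect_identical(r1$group, "2")
  r2 <- assign_subgroup("m2", tr, refs)
  expect_identical(r2$group, "1")
  expect_error(assign_subgroup("m1", tr, c(zz = "2a")), "no labeled references")
})

test_that("domain intron counts and phases come from CDS arithmetic", {
  prot <- planted_protein("C2H2")            # domain residues 10..56
  L <- 3L * (nchar(prot))
  # single exon: no intron anywhere
  gm0 <- gene_model("g0", "chr1", 0L, L, "+", exons = cbind(0L, L))
  h <- find_wrky_domains(prot, id = "g0")
  gs0 <- map_domain_gene_structure(h, gm0, nchar(prot))
  expect_identical(gs0$domain_introns, 0L)
  expect_identical(gs0$total_introns, 0L)

  # junction 2 nt into a domain codon -> one intron, phase 2
  u <- 20L * 3L + 2L                         # inside the domain, phase 2
  gm2 <- gene_model("g2", "chr1", 0L, L + 100L, "+",
                    exons = cbind(c(0L, u + 100L), c(u, L + 100L)))
  gs2 <- map_domain_gene_structure(h, gm2, nchar(prot))
  expect_identical(gs2$domain_introns, 1L)
  expect_identical(gs2$domain_phases[[1]], 2L)

  # junction exactly between codons -> phase 0
  u0 <- 20L * 3L
  gm3 <- gene_model("g3", "chr1", 0L, L + 100L, "+",
                    exons = cbind(c(0L, u0 + 100L), c(u0, L + 100L)))
  gs3 <- map_domain_gene_structure(h, gm3, nchar(prot))
  expect_identical(gs3$domain_phases[[1]], 0L)

  # same intron on the minus strand (transcription order reversed)
  gmm <- gene_model("gm", "chr1", 0L, L + 100L, "-",
                    exons = cbind(c(0L, (L - u) + 100L), c(L - u, L + 100L)))
  gsm <- map_domain_gene_structure(h, gmm, nchar(prot))
  expect_identical(gsm$domain_introns, 1L)
  expect_identical(gsm$domain_phases[[1]], 2L)

  expect_error(map_domain_gene_structure(h, gm0, nchar(prot) + 5L),
               "does not match protein length")
})

test_that("scanning the synthetic proteome recovers the planted census", {
  g <- default_genome()
  sc <- default_scan()
  tm <- g$truth$members
  expect_setequal(sc$members$id, tm$id)
  # raw scan: single-domain Group-1 mimic reads as Group 2 until tree stage
  merged <- merge(sc$members, tm, by = "id")
  expect_true(all(merged$group.x[!merged$single_domain] ==
                    merged$group.y[!merged$single_domain]))
  expect_true(all(merged$group.x[merged$single_domain] == "2"))
  expect_identical(sum(merged$group.x == "3"), 15L)
})
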
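#' Specification of a synthetic annotated genome with a planted WRKY family
#'
#' The defaults emulate the published pear family census: 103 members
#' (17 in Group 1 of which one is a single-domain protein carrying only the
#' C-terminal domain, 6/10/24/15/16 in subgroups 2a-2e, 15 in Group 3),
#' 15 tandem clusters with the printed sizes, groups and chromosomes, and a
#' handful of segmental blocks with anchor counts spanning the printed
#' range. Background genes carry no WRKY heptapeptide.
#'
#' @param n_members Named counts per group label (`"1"`, `"2a"`..`"2e"`,
#'   `"3"`).
#' @param tandem_clusters data.frame (`chromosome`, `size`, `group`,
#'   `max_gap`): planted tandem clusters; member rank gaps are sampled in
#'   `1..max_gap`.
#' @param segmental_blocks data.frame (`anchors`, `window`, `group`):
#'   planted collinear blocks; each uses two family genes of `group` on two
#'   chromosomes with `anchors` duplicated flanking genes in identical
#'   relative order.
#' @param background_per_chromosome Named integer vector: background gene
#'   count per chromosome/scaffold.
#' @param n_single_domain_group1 How many Group-1 members carry only the
#'   C-terminal domain (mis-annotation mimic).
#' @param n_references Members per subgroup (and Group-1 proteins) marked
#'   as labeled references for tree-based subgroup assignment.
#' @param flank_noise Per-residue substitution probability applied to the
#'   non-motif parts of family proteins (0 = members of a subgroup are
#'   identical outside sampling of synonymous codons).
#' @param seed RNG seed; the generator is a pure function of the spec.
#' @return A `family_plant_spec` list.
#' @export
family_plant_spec <- function(
    n_members = c("1" = 17, "2a" = 6, "2b" = 10, "2c" = 24, "2d" = 15,
                  "2e" = 16, "3" = 15),
    tandem_clusters = NULL,
    segmental_blocks = NULL,
    background_per_chromosome = NULL,
    n_single_domain_group1 = 1L,
    n_references = 2L,
    flank_noise = 0,
    seed = 1L) {
  if (is.null(tandem_clusters)) {
    tandem_clusters <- data.frame(
      chromosome = c("scaffold503.0", "scaffold491.0", "Chr8", "Chr15",
                     "scaffold490.0", "Chr8", "scaffold1326.0", "scaffold591.0",
                     "Chr6", "Chr9", "Chr15", "Chr7", "Chr7", "Chr12", "Chr12"),
      size = c(2, 2, 2, 2, 2, 3, 2, 2, 2, 2, 2, 2, 2, 4, 2),
      group = c("1", "1", "2a", "2a", "2c", "2c", "2c", "2c",
                "2d", "2d", "2d", "2e", "3", "3", "3"),
      max_gap = 5L, stringsAsFactors = FALSE)
  }
  if (is.null(segmental_blocks)) {
    segmental_blocks <- data.frame(
      anchors = c(33L, 29L, 26L, 18L, 12L, 8L), window = 50L,
      group = c("2c", "2d", "2e", "1", "2b", "3"), stringsAsFactors = FALSE)
  }
  if (is.null(background_per_chromosome)) {
    background_per_chromosome <- c(
      setNames(rep(200L, 17), paste0("Chr", 1:17)),
      setNames(rep(60L, 5), c("scaffold490.0", "scaffold491.0",
                              "scaffold503.0", "scaffold591.0",
                              "scaffold1326.0")))
  }
  stopifnot(all(n_members >= 0), all(tandem_clusters$max_gap >= 1),
            all(segmental_blocks$anchors >= 0), flank_noise >= 0)
  structure(list(n_members = n_members, tandem_clusters = tandem_clusters,
                 segmental_blocks = segmental_blocks,
                 background_per_chromosome = background_per_chromosome,
                 n_single_domain_group1 = as.integer(n_single_domain_group1),
                 n_references = as.integer(n_references),
                 flank_noise = flank_noise, seed = as.integer(seed)),
            class = "family_plant_spec")
}

# build one WRKY domain; fillers avoid C/H/W so the planted motif is the
# first (and only) match the scanner can find
make_domain <- function(finger = c("C2H2", "C2HC")) {
  finger <- match.arg(finger)
  filler <- function(n) rand_aa(n, exclude = c("C", "H", "W"))
  if (finger == "C2H2") {
    paste0("WRKYGQK", filler(10), "C", filler(4), "C", filler(22),
           "H", filler(1), "H")
  } else {
    paste0("WRKYGQK", filler(10), "C", filler(7), "C", filler(23),
           "H", filler(1), "C")
  }
}

rand_flank <- function(n) rand_aa(n, exclude = "W")

mutate_protein <- function(protein, mutable, rate) {
  if (rate <= 0 || !length(mutable)) return(protein)
  cc <- chars(protein)
  hit <- mutable[runif(length(mutable)) < rate]
  for (i in hit) cc[i] <- sample(setdiff(AA20, c(cc[i], "W", "C", "H")), 1)
  paste(cc, collapse = "")
}

# reverse-translate with uniformly random synonymous codons, append stop
reverse_translate <- function(protein) {
  ct <- codon_tables()
  by_aa <- split(ct$codons, ct$aa)
  cods <- vapply(chars(protein), function(a) {
    opts <- by_aa[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste0(paste(cods, collapse = ""), "TAA")
}

random_background_protein <- function() {
  repeat {
    p <- paste0("M", rand_aa(sample(119:249, 1)))
    if (!grepl("WRKYGQK", p, fixed = TRUE)) return(p)
  }
}

#' Generate an annotated genome with a planted WRKY family
#'
#' Emits a [genome_annotation()], protein and CDS sequences, and truth
#' tables recording every planted structure: family members with group and
#' subgroup labels, tandem clusters, segmental blocks with their anchor
#' counts, a homology relation (all same-template family pairs plus the
#' duplicated anchor pairs) and the implied duplication class of every
#' member. Family proteins carry the exact motif architecture of their
#' group (two C2H2 domains for Group 1, one C2H2 for Group 2, one C2HC for
#' Group 3); members of a subgroup share a signature protein so tree-based
#' subgroup recovery is exact at zero `flank_noise`. Each family gene's CDS
#' is split by one intron inside the (C-terminal) WRKY domain.
#'
#' @param spec A [family_plant_spec()].
#' @param dir Optional directory: writes `proteins.faa`, `cds.fna`,
#'   `genome.gff3` and `truth_*.tsv` there.
#' @return list(`annotation`, `proteins`, `cds`, `truth`, `spec`) where
#'   `truth` has elements `members`, `tandem`, `blocks`, `homology`,
#'   `references`.
#' @export
generate_annotated_genome <- function(spec = family_plant_spec(), dir = NULL) {
  stopifnot(inherits(spec, "family_plant_spec"))
  set.seed(spec$seed)
  groups <- names(spec$n_members)

  # --- member roster ------------------------------------------------------
  members <- do.call(rbind, lapply(groups, function(g) {
    n <- spec$n_members[[g]]
    if (n == 0) return(NULL)
    data.frame(group = rep(if (g %in% c("1", "3")) g else "2", n),
               subgroup = rep(if (g %in% c("1", "3")) "none" else g, n),
               template = rep(g, n), stringsAsFactors = FALSE)
  }))
  if (is.null(members)) {
    members <- data.frame(group = character(), subgroup = character(),
                          template = character(), stringsAsFactors = FALSE)
  }
  n_fam <- nrow(members)
  if (n_fam) {
    members$id <- sprintf("WRKY%03d", seq_len(n_fam))
    members$single_domain <- FALSE
    g1 <- which(members$template == "1")
    if (spec$n_single_domain_group1 > 0 && length(g1)) {
      members$single_domain[utils::tail(g1, spec$n_single_domain_group1)] <- TRUE
    }
    members$is_reference <- FALSE
    for (g in groups) {
      idx <- which(members$template == g & !members$single_domain)
      if (g %in% c("1", paste0("2", letters[1:5]))) {
        members$is_reference[utils::head(idx, spec$n_references)] <- TRUE
      }
    }
  }

  # --- placement units ----------------------------------------------------
  chroms <- names(spec$background_per_chromosome)
  unused <- if (n_fam) split(members$id, members$template) else list()
  take <- function(tmpl, k) {
    pool <- unused[[tmpl]]
    if (length(pool) < k) {
      stop2("not enough group-", tmpl, " members for the planted structures")
    }
    out <- pool[seq_len(k)]
    unused[[tmpl]] <<- pool[-seq_len(k)]
    out
  }
  units <- setNames(vector("list", length(chroms)), chroms)
  isolation <- 12L
  block_cost <- 62L
  # a block also sterilizes +/-51 ranks around its focal gene for singles,
  # so it weighs more in the load bookkeeping than the slots it occupies
  block_load <- 102L
  load <- setNames(rep(isolation, length(chroms)), chroms)  # leading margin
  bg_n <- spec$background_per_chromosome
  push <- function(ch, u, cost) {
    units[[ch]][[length(units[[ch]]) + 1L]] <<- u
    load[[ch]] <<- load[[ch]] + cost
  }
  tandem_truth <- list()
  tc <- spec$tandem_clusters
  for (i in seq_len(nrow(tc))) {
    ids <- take(tc$group[i], tc$size[i])
    if (!tc$chromosome[i] %in% chroms) {
      stop2("tandem cluster chromosome not in background map: ", tc$chromosome[i])
    }
    gaps <- sample.int(tc$max_gap[i], tc$size[i] - 1L, replace = TRUE)
    push(tc$chromosome[i], list(type = "cluster", ids = ids, gaps = gaps),
         sum(gaps) + isolation)
    tandem_truth[[i]] <- data.frame(cluster_id = i, gene_id = ids,
                                    stringsAsFactors = FALSE)
  }
  sb <- spec$segmental_blocks
  block_truth <- list()
  # blocks and remaining singles go wherever the most capacity is left
  headroom <- function() bg_n - load
  for (i in seq_len(nrow(sb))) {
    ids <- take(sb$group[i], 2L)
    top <- names(sort(headroom(), decreasing = TRUE))[1:2]
    if (headroom()[[top[2]]] < block_cost) {
      stop2("no two chromosomes can hold planted block ", i,
            ": increase background gene counts")
    }
    push(top[1], list(type = "block", ids = ids[1], block = i, side = "a"),
         block_load)
    push(top[2], list(type = "block", ids = ids[2], block = i, side = "b"),
         block_load)
    block_truth[[i]] <- data.frame(block_id = i, gene_a = ids[1],
                                   gene_b = ids[2], anchors = sb$anchors[i],
                                   window = sb$window[i], stringsAsFactors = FALSE)
  }
  singles <- unlist(unused, use.names = FALSE)

  # --- rank layout per chromosome ----------------------------------------
  fam_rank <- list()     # id -> rank
  fam_chrom <- list()
  block_focal <- vector("list", nrow(sb))  # block -> list(a=(chrom, rank), b=...)
  n_slots <- integer(length(chroms)); names(n_slots) <- chroms
  fam_ranks_by_chrom <- setNames(vector("list", length(chroms)), chroms)
  focal_ranks_by_chrom <- setNames(vector("list", length(chroms)), chroms)
  for (ch in chroms) {
    cursor <- isolation
    n_fam_ch <- sum(vapply(units[[ch]], function(u) length(u$ids), integer(1)))
    capacity <- spec$background_per_chromosome[[ch]] + n_fam_ch
    fam_ranks_ch <- integer(0)
    focal_ranks <- integer(0)
    # clusters and block focals first, at deterministic reserved positions
    for (u in units[[ch]]) {
      if (u$type == "cluster") {
        ranks <- cursor + cumsum(c(0L, u$gaps))
        cursor <- max(ranks) + isolation
      } else if (u$type == "block") {
        ranks <- cursor + 25L
        cursor <- ranks + 25L + isolation
        # singles must stay far enough away that their windows cannot reach
        # this block's anchors: half window + half the anchor span
        excl <- 26L + as.integer(ceiling(sb$anchors[u$block] / 2))
        focal_ranks <- c(focal_ranks, setNames(excl, ranks))
        block_focal[[u$block]] <- c(block_focal[[u$block]] %||% list(),
                                    setNames(list(c(ch, ranks)), u$side))
      } else {
        next
      }
      fam_ranks_ch <- c(fam_ranks_ch, ranks)
      for (j in seq_along(u$ids)) {
        fam_rank[[u$ids[j]]] <- ranks[j]
        fam_chrom[[u$ids[j]]] <- ch
      }
    }
    if (cursor > capacity) {
      stop2("chromosome ", ch, " cannot hold the planted structures: needs ",
            cursor, " slots, capacity ", capacity)
    }
    n_slots[ch] <- capacity
    fam_ranks_by_chrom[[ch]] <- fam_ranks_ch
    focal_ranks_by_chrom[[ch]] <- focal_ranks
  }

  # singles at random ranks, isolated from other members and kept clear of
  # block windows so no window pair can borrow a planted anchor chain;
  # each single goes to the chromosome with the most feasible slots left
  feasible_slots <- function(ch) {
    cand <- seq(isolation, n_slots[ch] - isolation - 1L)
    fr <- fam_ranks_by_chrom[[ch]]
    fo <- focal_ranks_by_chrom[[ch]]
    if (length(fr)) {
      cand <- cand[vapply(cand, function(r) min(abs(r - fr)) >= isolation,
                          logical(1))]
    }
    if (length(fo)) {
      keep <- vapply(cand, function(r) {
        all(abs(r - as.integer(names(fo))) >= fo)
      }, logical(1))
      cand <- cand[keep]
    }
    cand
  }
  for (id in singles) {
    avail <- lapply(setNames(chroms, chroms), feasible_slots)
    n_avail <- vapply(avail, length, integer(1))
    if (max(n_avail) == 0L) {
      stop2("no chromosome can hold the planted structures: ",
            "no free slot for ", id)
    }
    ch <- names(which.max(n_avail))
    r <- if (length(avail[[ch]]) == 1L) avail[[ch]] else sample(avail[[ch]], 1L)
    fam_ranks_by_chrom[[ch]] <- c(fam_ranks_by_chrom[[ch]], r)
    fam_rank[[id]] <- r
    fam_chrom[[id]] <- ch
    n_slots[ch] <- n_slots[ch] + 1L   # a family gene adds a slot
  }

  # --- gene id per slot ---------------------------------------------------
  slot_ids <- lapply(chroms, function(ch) {
    ids <- sprintf("BG_%s_%04d", gsub("[^A-Za-z0-9]", "", ch),
                   seq_len(n_slots[ch]) - 1L)
    for (m in names(fam_rank)) {
      if (fam_chrom[[m]] == ch) ids[fam_rank[[m]] + 1L] <- m
    }
    ids
  })
  names(slot_ids) <- chroms

  # --- proteins -----------------------------------------------------------
  sig_parts <- list()
  for (g in groups) {
    if (g == "1") {
      sig_parts[[g]] <- list(
        nflank = rand_flank(25), dom_n = make_domain("C2H2"),
        mid = rand_flank(15), dom_c = make_domain("C2H2"),
        cflank = rand_flank(30))
    } else {
      sig_parts[[g]] <- list(
        nflank = rand_flank(25),
        dom = make_domain(if (g == "3") "C2HC" else "C2H2"),
        cflank = rand_flank(30))
    }
  }
  build_member_protein <- function(tmpl, single_domain) {
    p <- sig_parts[[tmpl]]
    if (tmpl == "1" && !single_domain) {
      prot <- paste0("M", p$nflank, p$dom_n, p$mid, p$dom_c, p$cflank)
      mut <- c(1 + seq_len(nchar(p$nflank)),
               1 + nchar(p$nflank) + nchar(p$dom_n) + seq_len(nchar(p$mid)))
    } else if (tmpl == "1") {
      prot <- paste0("M", p$mid, p$dom_c, p$cflank)
      mut <- 1 + seq_len(nchar(p$mid))
    } else {
      prot <- paste0("M", p$nflank, p$dom, p$cflank)
      mut <- 1 + seq_len(nchar(p$nflank))
    }
    mutate_protein(prot, mut, spec$flank_noise)
  }
  proteins <- list()
  for (i in seq_len(n_fam)) {
    proteins[[members$id[i]]] <-
      build_member_protein(members$template[i], members$single_domain[i])
  }
  # background genes, with anchors duplicated across block sides
  anchor_offsets <- function(k) {
    ord <- as.vector(rbind(seq_len(24L), -seq_len(24L)))
    sort(ord[seq_len(k)])
  }
  homology_anchor <- list()
  anchor_of <- list() # id -> id of its duplicate
  for (i in seq_along(block_truth)) {
    bt <- block_truth[[i]]
    offs <- anchor_offsets(bt$anchors)
    fa <- block_focal[[i]]$a; fb <- block_focal[[i]]$b
    ra <- as.integer(fa[2]); rb <- as.integer(fb[2])
    ia <- slot_ids[[fa[1]]][ra + offs + 1L]
    ib <- slot_ids[[fb[1]]][rb + offs + 1L]
    for (j in seq_along(ia)) {
      anchor_of[[ib[j]]] <- ia[j]
      homology_anchor[[length(homology_anchor) + 1L]] <-
        data.frame(a = ia[j], b = ib[j], stringsAsFactors = FALSE)
    }
  }
  all_ids <- unlist(slot_ids, use.names = FALSE)
  for (id in all_ids) {
    if (!is.null(proteins[[id]])) next
    src <- anchor_of[[id]]
    if (!is.null(src)) {
      if (is.null(proteins[[src]])) proteins[[src]] <- random_background_protein()
      proteins[[id]] <- proteins[[src]]
    } else {
      proteins[[id]] <- random_background_protein()
    }
  }

  # --- CDS and gene models ------------------------------------------------
  cds <- vapply(proteins, reverse_translate, character(1))
  id2member <- match(all_ids, members$id)
  gene_models <- vector("list", length(all_ids))
  pos <- 0L
  for (ch in chroms) {
    for (slot in seq_along(slot_ids[[ch]])) {
      pos <- pos + 1L
      id <- slot_ids[[ch]][slot]
      L <- nchar(cds[[id]])
      g0 <- (slot - 1L) * 3000L + 100L
      strand <- sample(c("+", "-"), 1L)
      mi <- match(id, members$id)
      if (!is.na(mi)) {
        # one intron inside the (C-terminal) WRKY domain
        prot <- proteins[[id]]
        hits <- find_wrky_domains(prot, id = id)
        hit <- hits[nrow(hits), ]
        ph <- if (members$template[mi] %in% c("2a", "2b")) 0L else 2L
        a <- hit$hept_start * 3L; b <- hit$domain_end * 3L
        u <- 3L * ((a + b) %/% 6L) + ph
        if (u <= a) u <- u + 3L
        if (u >= b) u <- u - 3L
      } else if (runif(1) < 0.5 && L > 60L) {
        u <- sample.int(L - 2L, 1L)  # any phase, anywhere
      } else {
        u <- NA_integer_
      }
      segs <- if (is.na(u)) {
        cbind(start = g0, end = g0 + L)
      } else {
        intron <- sample(120:400, 1L)
        if (strand == "-") {
          # transcription right-to-left: first u coding nt on the right
          rbind(cbind(start = g0, end = g0 + (L - u)),
                cbind(start = g0 + (L - u) + intron,
                      end = g0 + L + intron))
        } else {
          rbind(cbind(start = g0, end = g0 + u),
                cbind(start = g0 + u + intron, end = g0 + u + intron + (L - u)))
        }
      }
      gene_models[[pos]] <- gene_model(id, ch, g0, max(segs[, 2]), strand,
                                       exons = segs, cds = segs)
    }
  }
  annotation <- genome_annotation(gene_models)

  # --- truth tables -------------------------------------------------------
  if (n_fam) {
    members$chromosome <- vapply(members$id, function(m) fam_chrom[[m]], character(1))
    members$rank <- vapply(members$id, function(m) fam_rank[[m]], integer(1))
  }
  tandem <- if (length(tandem_truth)) do.call(rbind, tandem_truth) else
    data.frame(cluster_id = integer(), gene_id = character())
  blocks <- if (length(block_truth)) do.call(rbind, block_truth) else
    data.frame(block_id = integer(), gene_a = character(),
               gene_b = character(), anchors = integer(), window = integer())
  fam_pairs <- list()
  for (tmpl in unique(members$template)) {
    ids <- members$id[members$template == tmpl]
    if (length(ids) >= 2L) {
      cp <- utils::combn(ids, 2L)
      fam_pairs[[tmpl]] <- data.frame(a = cp[1, ], b = cp[2, ],
                                      stringsAsFactors = FALSE)
    }
  }
  homology <- rbind(do.call(rbind, fam_pairs),
                    do.call(rbind, homology_anchor))
  if (is.null(homology)) homology <- data.frame(a = character(), b = character())
  if (n_fam) {
    seg_ids <- unique(c(blocks$gene_a, blocks$gene_b))
    tmpl_count <- table(members$template)
    members$duplication_class <- ifelse(
      members$id %in% seg_ids, "segmental",
      ifelse(members$id %in% tandem$gene_id, "tandem",
             ifelse(tmpl_count[members$template] > 1, "dispersed", "singleton")))
  }
  references <- if (n_fam) {
    setNames(members[members$is_reference, c("id", "template")],
             c("id", "label"))
  } else {
    data.frame(id = character(), label = character(), stringsAsFactors = FALSE)
  }

  out <- list(annotation = annotation,
              proteins = unlist(proteins[all_ids]),
              cds = cds[all_ids],
              truth = list(members = members, tandem = tandem, blocks = blocks,
                           homology = homology, references = references),
              spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(out$proteins, file.path(dir, "proteins.faa"))
    write_fasta(out$cds, file.path(dir, "cds.fna"))
    write_gff3(annotation, file.path(dir, "genome.gff3"))
    for (nm in names(out$truth)) {
      utils::write.table(out$truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}
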
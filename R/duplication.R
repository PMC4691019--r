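#' Tandemly duplicated gene clusters
#'
#' Single-linkage clustering of family genes along each chromosome: two
#' family members belong to the same cluster when their gene ranks (among
#' all annotated genes, strand-ignored) differ by at most
#' `max_gene_distance`. Clusters of two or more members are reported.
#'
#' @param annotation A [genome_annotation()].
#' @param family_ids Gene ids of the family members.
#' @param max_gene_distance Maximum rank gap linking two members
#'   (default 10).
#' @return data.frame with columns `cluster_id`, `chromosome`, `gene_id`,
#'   `rank`, sorted by chromosome then rank. Zero rows when no cluster.
#' @export
find_tandem_clusters <- function(annotation, family_ids, max_gene_distance = 10L) {
  ranks <- gene_rank(annotation, family_ids)
  chrom <- vapply(annotation$genes[family_ids], `[[`, character(1), "chromosome")
  out <- list()
  cid <- 0L
  for (ch in sort(unique(chrom))) {
    ids <- family_ids[chrom == ch]
    ids <- ids[order(ranks[ids])]
    r <- ranks[ids]
    if (length(ids) < 2L) next
    grp <- cumsum(c(1L, diff(r) > max_gene_distance))
    for (g in unique(grp)) {
      sel <- grp == g
      if (sum(sel) < 2L) next
      cid <- cid + 1L
      out[[length(out) + 1L]] <- data.frame(
        cluster_id = cid, chromosome = ch, gene_id = ids[sel],
        rank = unname(r[sel]), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(cluster_id = integer(), chromosome = character(),
                      gene_id = character(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# longest monotone (strictly increasing or strictly decreasing) chain by
# second coordinate, rows assumed sorted by first coordinate; O(m^2)
longest_monotone_chain <- function(y) {
  m <- length(y)
  if (m == 0L) return(integer(0))
  best_chain <- function(cmp) {
    len <- rep(1L, m); prev <- rep(0L, m)
    for (i in seq_len(m)) for (j in seq_len(i - 1L)) {
      if (cmp(y[j], y[i]) && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L; prev[i] <- j
      }
    }
    end <- which.max(len)
    chain <- integer(0)
    while (end != 0L) { chain <- c(end, chain); end <- prev[end] }
    chain
  }
  inc <- best_chain(`<`)
  dec <- best_chain(`>`)
  if (length(inc) >= length(dec)) inc else dec
}

#' Microsynteny blocks around family gene pairs
#'
#' For every unordered pair of family genes, homologous gene pairs between
#' the two windows of `window` genes centered on the focal genes are
#' collected (tandem-duplicated neighbors within `tandem_gap` ranks are
#' collapsed to a single representative), the longest rank-monotone chain
#' (either orientation, so inversions are tolerated) is taken as the anchor
#' set, and the block's E-value is computed as the hypergeometric tail
#' probability of observing at least that many homologous pairs between two
#' windows given the genome-wide homolog density, Bonferroni-scaled by the
#' number of family pairs tested. Blocks with at least `min_pairs` anchors
#' and E-value at most `evalue_cutoff` are reported.
#'
#' @param annotation A [genome_annotation()].
#' @param family_ids Focal family gene ids.
#' @param homology_pairs data.frame with columns `a`, `b`: a symmetric
#'   homology relation over gene ids (each unordered pair once or twice).
#' @param window Window size in genes (total, centered on the focal gene).
#' @param min_pairs Minimum anchors to call a block.
#' @param evalue_cutoff Maximum block E-value.
#' @param tandem_gap Rank gap within which homologs on the same chromosome
#'   are collapsed as local tandem copies.
#' @return data.frame: `gene_a`, `gene_b`, `anchors`, `evalue`, plus the
#'   anchor pairs in attribute `anchor_pairs` (list of data.frames).
#' @export
find_synteny_blocks <- function(annotation, family_ids, homology_pairs,
                                window = 50L, min_pairs = 3L,
                                evalue_cutoff = 0.01, tandem_gap = 2L) {
  if (window < min_pairs) stop2("window must be >= min_pairs")
  ranks <- annotation$rank
  chrom_of <- vapply(annotation$genes, `[[`, character(1), "chromosome")
  hp <- unique(rbind(
    data.frame(a = homology_pairs$a, b = homology_pairs$b, stringsAsFactors = FALSE),
    data.frame(a = homology_pairs$b, b = homology_pairs$a, stringsAsFactors = FALSE)))
  hp <- hp[hp$a != hp$b, , drop = FALSE]
  hom_keys <- paste(hp$a, hp$b)
  n_genes <- length(annotation$genes)
  n_hom <- nrow(unique(data.frame(a = pmin(hp$a, hp$b), b = pmax(hp$a, hp$b))))
  density_pairs <- n_hom / (n_genes * (n_genes - 1) / 2)
  fam <- sort(unique(family_ids))
  tests <- utils::combn(fam, 2L, simplify = FALSE)
  n_tests <- length(tests)
  half <- window %/% 2L
  win_ids <- function(g) {
    ch <- chrom_of[[g]]
    ord <- annotation$chromosomes[[ch]]
    r <- ranks[[g]]
    ord[ranks[ord] >= r - half & ranks[ord] <= r + half]
  }
  res <- list()
  anchor_sets <- list()
  for (pair in tests) {
    ga <- pair[1]; gb <- pair[2]
    wa <- setdiff(win_ids(ga), ga)
    wb <- setdiff(win_ids(gb), gb)
    cand <- hp[hp$a %in% wa & hp$b %in% wb, , drop = FALSE]
    if (!nrow(cand)) next
    cand$ra <- unname(ranks[cand$a]); cand$rb <- unname(ranks[cand$b])
    cand <- cand[order(cand$ra, cand$rb), , drop = FALSE]
    # collapse tandem copies: homologous neighbors within tandem_gap on one
    # side count as a single anchor (keep the lower-rank copy)
    for (side in c("a", "b")) {
      rcol <- paste0("r", side)
      ord <- order(cand[[rcol]], cand[[side]])
      keep <- rep(TRUE, nrow(cand))
      last <- 0L
      for (i in ord) {
        if (last > 0L &&
            cand[[rcol]][i] - cand[[rcol]][last] <= tandem_gap &&
            paste(cand[[side]][i], cand[[side]][last]) %in% hom_keys) {
          keep[i] <- FALSE
        } else {
          last <- i
        }
      }
      cand <- cand[keep, , drop = FALSE]
    }
    cand <- cand[!duplicated(cand$a), , drop = FALSE]
    cand <- cand[!duplicated(cand$b), , drop = FALSE]
    chain <- longest_monotone_chain(cand$rb)
    anchors <- cand[chain, c("a", "b"), drop = FALSE]
    m <- nrow(anchors)
    if (m < min_pairs) next
    draws <- length(wa) * length(wb)
    white <- max(n_hom, 1)
    total <- n_genes * (n_genes - 1) / 2
    pval <- stats::phyper(m - 1, white, total - white, draws, lower.tail = FALSE)
    evalue <- min(1, pval * n_tests)
    if (evalue > evalue_cutoff) next
    res[[length(res) + 1L]] <- data.frame(
      gene_a = ga, gene_b = gb, anchors = m, evalue = evalue,
      stringsAsFactors = FALSE)
    anchor_sets[[length(anchor_sets) + 1L]] <- anchors
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(gene_a = character(), gene_b = character(),
               anchors = integer(), evalue = numeric(), stringsAsFactors = FALSE)
  attr(out, "anchor_pairs") <- anchor_sets
  attr(out, "density") <- density_pairs
  out
}

#' Classify family genes by duplication mode
#'
#' MCScanX-style mutually exclusive classes with precedence
#' segmental > tandem > proximal > dispersed; a family gene with no family
#' homolog is a singleton.
#'
#' @param annotation A [genome_annotation()].
#' @param family_ids Family gene ids.
#' @param homology_pairs data.frame (`a`, `b`) of homologous family pairs.
#' @param blocks Output of [find_synteny_blocks()].
#' @param clusters Output of [find_tandem_clusters()].
#' @param proximal_distance Rank distance defining "proximal" homologs.
#' @return data.frame `gene_id`, `class`.
#' @export
classify_duplication_types <- function(annotation, family_ids, homology_pairs,
                                       blocks, clusters,
                                       proximal_distance = 10L) {
  fam <- unique(family_ids)
  hp <- homology_pairs[homology_pairs$a %in% fam & homology_pairs$b %in% fam, ,
                       drop = FALSE]
  partners <- lapply(setNames(fam, fam), function(g) {
    unique(c(hp$b[hp$a == g], hp$a[hp$b == g]))
  })
  seg <- unique(c(blocks$gene_a, blocks$gene_b))
  tand <- unique(clusters$gene_id)
  ranks <- gene_rank(annotation, fam)
  chrom <- vapply(annotation$genes[fam], `[[`, character(1), "chromosome")
  cls <- vapply(fam, function(g) {
    if (!length(partners[[g]])) return("singleton")
    if (g %in% seg) return("segmental")
    if (g %in% tand) return("tandem")
    near <- vapply(partners[[g]], function(h) {
      chrom[[h]] == chrom[[g]] && abs(ranks[[h]] - ranks[[g]]) <= proximal_distance
    }, logical(1))
    if (any(near)) "proximal" else "dispersed"
  }, character(1))
  data.frame(gene_id = fam, class = unname(cls), stringsAsFactors = FALSE)
}

#' Mean and SD of synonymous divergence across block anchors
#'
#' Computes NG86 Ks for every anchor pair of a synteny block; pairs with
#' saturated or undefined Ks (synonymous p >= 3/4 or Ks > 5) are excluded.
#'
#' @param anchors data.frame (`a`, `b`) of anchor gene pairs.
#' @param cds_lookup Named character vector of CDS sequences.
#' @return list(`mean_ks`, `sd_ks`, `n_used`, `flag`): `flag` is
#'   `"ok"`, `"single_pair"` (SD reported as 0) or `"undefined"` (all pairs
#'   saturated; means reported as NA).
#' @export
summarize_block_ks <- function(anchors, cds_lookup) {
  ks <- vapply(seq_len(nrow(anchors)), function(i) {
    a <- anchors$a[i]; b <- anchors$b[i]
    if (!a %in% names(cds_lookup) || !b %in% names(cds_lookup)) {
      stop2("missing CDS for anchor pair ", a, " / ", b)
    }
    r <- ng86_kaks(cds_lookup[[a]], cds_lookup[[b]])
    if (isTRUE(r$saturated_s) || is.na(r$ks) || r$ks > 5) NA_real_ else r$ks
  }, numeric(1))
  ok <- ks[!is.na(ks)]
  if (!length(ok)) {
    return(list(mean_ks = NA_real_, sd_ks = NA_real_, n_used = 0L,
                flag = "undefined"))
  }
  if (length(ok) == 1L) {
    return(list(mean_ks = ok, sd_ks = 0, n_used = 1L, flag = "single_pair"))
  }
  list(mean_ks = mean(ok), sd_ks = stats::sd(ok), n_used = length(ok),
       flag = "ok")
}
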
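#' Pairwise local-alignment similarity scores between two proteomes
#'
#' Smith-Waterman local alignment scores (BLOSUM62, affine gaps) for every
#' cross-proteome pair plus the within-proteome scores needed for inparalog
#' detection. Scores are symmetric; both orientations are reconciled by the
#' maximum.
#'
#' @param proteome_a,proteome_b Named character vectors of protein
#'   sequences.
#' @param gap_opening,gap_extension Affine gap costs (positive).
#' @return Object of class `similarity_table`: list(`ab`, `aa`, `bb` score
#'   matrices).
#' @export
pairwise_similarity <- function(proteome_a, proteome_b,
                                gap_opening = 10, gap_extension = 0.5) {
  if (!length(proteome_a) || !length(proteome_b)) stop2("empty proteome")
  if (any(nchar(c(proteome_a, proteome_b)) == 0)) stop2("empty sequence")
  score_all <- function(px, py) {
    sx <- Biostrings::AAStringSet(px)
    m <- matrix(NA_real_, length(px), length(py),
                dimnames = list(names(px), names(py)))
    for (j in seq_along(py)) {
      m[, j] <- Biostrings::pairwiseAlignment(
        sx, Biostrings::AAString(py[[j]]), type = "local",
        substitutionMatrix = "BLOSUM62", gapOpening = gap_opening,
        gapExtension = gap_extension, scoreOnly = TRUE)
    }
    m
  }
  ab <- score_all(proteome_a, proteome_b)
  aa <- score_all(proteome_a, proteome_a)
  bb <- score_all(proteome_b, proteome_b)
  aa <- pmax(aa, t(aa)); bb <- pmax(bb, t(bb))
  structure(list(ab = ab, aa = aa, bb = bb), class = "similarity_table")
}

#' Build ortholog groups from a similarity table
#'
#' Seed orthologs are two-way best hits between the proteomes (greedily
#' accepted in decreasing score order, ties broken by id order, so groups
#' are disjoint and deterministic). A sequence joins its seed's group as an
#' inparalog when it scores at least as high to its own-species seed as the
#' seed pair scores to each other, and strictly higher than to any sequence
#' of the other proteome. Confidence is the ratio of the inparalog-to-seed
#' score over the seed-to-seed score (1 for seeds).
#'
#' @param scores A `similarity_table` from [pairwise_similarity()].
#' @param score_floor Pairs scoring below this are ignored (default 40).
#' @return data.frame: `group`, `member`, `proteome` (`"A"`/`"B"`), `role`
#'   (`"seed"`/`"inparalog"`), `confidence`.
#' @export
build_ortholog_groups <- function(scores, score_floor = 40) {
  stopifnot(inherits(scores, "similarity_table"))
  ab <- scores$ab
  ids_a <- rownames(ab); ids_b <- colnames(ab)
  cand <- which(ab >= score_floor, arr.ind = TRUE)
  if (nrow(cand)) {
    mutual <- apply(cand, 1L, function(idx) {
      i <- idx[1]; j <- idx[2]
      ab[i, j] >= max(ab[i, ]) && ab[i, j] >= max(ab[, j])
    })
    cand <- cand[mutual, , drop = FALSE]
    ord <- order(-ab[cand], ids_a[cand[, 1]], ids_b[cand[, 2]])
    cand <- cand[ord, , drop = FALSE]
  }
  used_a <- character(0); used_b <- character(0)
  rows <- list()
  g <- 0L
  for (r in seq_len(nrow(cand))) {
    a <- ids_a[cand[r, 1]]; b <- ids_b[cand[r, 2]]
    if (a %in% used_a || b %in% used_b) next
    g <- g + 1L
    seed_score <- ab[a, b]
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, member = c(a, b), proteome = c("A", "B"), role = "seed",
      confidence = 1, stringsAsFactors = FALSE)
    used_a <- c(used_a, a); used_b <- c(used_b, b)
    inpar <- function(side_ids, own, cross_scores, own_seed) {
      keep <- character(0)
      for (x in setdiff(side_ids, own_seed)) {
        s_own <- own[x, own_seed]
        if (s_own >= seed_score && s_own > max(cross_scores[x, ]) &&
            s_own >= score_floor) {
          keep <- c(keep, x)
        }
      }
      keep
    }
    in_a <- inpar(ids_a, scores$aa, ab, a)
    in_b <- inpar(ids_b, scores$bb, t(ab), b)
    in_a <- setdiff(in_a, used_a); in_b <- setdiff(in_b, used_b)
    if (length(in_a)) {
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, member = in_a, proteome = "A", role = "inparalog",
        confidence = scores$aa[in_a, a] / seed_score, stringsAsFactors = FALSE)
      used_a <- c(used_a, in_a)
    }
    if (length(in_b)) {
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, member = in_b, proteome = "B", role = "inparalog",
        confidence = scores$bb[in_b, b] / seed_score, stringsAsFactors = FALSE)
      used_b <- c(used_b, in_b)
    }
  }
  if (!length(rows)) {
    return(data.frame(group = integer(), member = character(),
                      proteome = character(), role = character(),
                      confidence = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
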
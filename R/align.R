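blosum62 <- function() {
  if (is.null(.wrky$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .wrky$blosum62 <- e$BLOSUM62
  }
  .wrky$blosum62
}

aa_index <- function(cc, alpha) {
  i <- match(cc, alpha)
  i[is.na(i) & cc != "-"] <- match("X", alpha)
  i
}

# profile: character matrix (rows = sequences, cols = alignment columns)
profile_freq <- function(prof, alpha) {
  L <- ncol(prof)
  f <- matrix(0, nrow = length(alpha), ncol = L)
  for (j in seq_len(L)) {
    idx <- aa_index(prof[, j], alpha)
    idx <- idx[!is.na(idx)]
    if (length(idx)) {
      tb <- tabulate(idx, nbins = length(alpha))
      f[, j] <- tb / nrow(prof)
    }
  }
  f
}

# global profile-profile alignment; returns merged character matrix
nw_merge <- function(p1, p2, submat, gap) {
  alpha <- rownames(submat)
  f1 <- profile_freq(p1, alpha)
  f2 <- profile_freq(p2, alpha)
  S <- t(f1) %*% submat %*% f2          # column-pair expected score
  L1 <- ncol(p1); L2 <- ncol(p2)
  M <- matrix(0, L1 + 1L, L2 + 1L)
  M[, 1] <- gap * (0:L1)
  M[1, ] <- gap * (0:L2)
  tb <- matrix(0L, L1 + 1L, L2 + 1L)   # 1 diag, 2 up (gap in p2), 3 left
  tb[, 1] <- 2L; tb[1, ] <- 3L; tb[1, 1] <- 0L
  for (i in seq_len(L1)) {
    mi <- M[i, ]
    d <- mi[1:L2] + S[i, ]
    row <- numeric(L2 + 1L)
    row[1] <- M[i + 1L, 1L]
    for (j in seq_len(L2)) {
      u <- mi[j + 1L] + gap
      l <- row[j] + gap
      dd <- d[j]
      if (dd >= u && dd >= l) { row[j + 1L] <- dd; tb[i + 1L, j + 1L] <- 1L }
      else if (u >= l)        { row[j + 1L] <- u;  tb[i + 1L, j + 1L] <- 2L }
      else                    { row[j + 1L] <- l;  tb[i + 1L, j + 1L] <- 3L }
    }
    M[i + 1L, ] <- row
  }
  i <- L1 + 1L; j <- L2 + 1L
  cols1 <- integer(0); cols2 <- integer(0)   # 0 = gap column
  while (i > 1L || j > 1L) {
    mv <- tb[i, j]
    if (mv == 1L) { cols1 <- c(i - 1L, cols1); cols2 <- c(j - 1L, cols2); i <- i - 1L; j <- j - 1L }
    else if (mv == 2L) { cols1 <- c(i - 1L, cols1); cols2 <- c(0L, cols2); i <- i - 1L }
    else { cols1 <- c(0L, cols1); cols2 <- c(j - 1L, cols2); j <- j - 1L }
  }
  take <- function(prof, colsel) {
    out <- matrix("-", nrow(prof), length(colsel))
    nz <- colsel > 0L
    out[, nz] <- prof[, colsel[nz], drop = FALSE]
    rownames(out) <- rownames(prof)
    out
  }
  merged <- rbind(take(p1, cols1), take(p2, cols2))
  attr(merged, "score") <- M[L1 + 1L, L2 + 1L]
  merged
}

kmer_distance <- function(seqs, k = 3L) {
  sets <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(s)
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- length(intersect(sets[[i]], sets[[j]]))
    dij <- 1 - shared / min(length(sets[[i]]), length(sets[[j]]))
    d[i, j] <- d[j, i] <- dij
  }
  d
}

#' Progressive multiple sequence alignment
#'
#' Deterministic progressive aligner: a guide tree is built by
#' average-linkage clustering of k-mer distances, and profiles are merged
#' along it by global Needleman-Wunsch profile-profile alignment
#' (BLOSUM62 expected column scores, linear gap penalty). Intended for the
#' short, highly conserved WRKY domain sequences the family tree is built
#' from; it is not a general-purpose replacement for a full aligner.
#'
#' @param sequences Named character vector (>= 2 protein sequences).
#' @param gap Linear gap penalty per column (negative).
#' @param k k-mer size for guide-tree distances.
#' @return Named character vector of aligned rows (class
#'   `multiple_alignment`), in the input order; all rows have equal length
#'   and ungapping a row recovers its input sequence.
#' @export
progressive_align <- function(sequences, gap = -8, k = 3L) {
  if (length(sequences) < 2L) stop2("progressive_align needs >= 2 sequences")
  if (is.null(names(sequences))) names(sequences) <- paste0("seq", seq_along(sequences))
  orig <- names(sequences)
  seqs <- toupper(sequences[order(names(sequences))])
  submat <- blosum62()
  if (length(seqs) == 2L) {
    prof <- nw_merge(matrix(chars(seqs[[1]]), 1), matrix(chars(seqs[[2]]), 1),
                     submat, gap)
    rownames(prof) <- names(seqs)
  } else {
    d <- kmer_distance(seqs, k = k)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    profs <- vector("list", length(seqs) - 1L)
    get_prof <- function(idx) {
      if (idx < 0L) {
        m <- matrix(chars(seqs[[-idx]]), 1)
        rownames(m) <- names(seqs)[-idx]
        m
      } else profs[[idx]]
    }
    for (m in seq_len(nrow(hc$merge))) {
      p1 <- get_prof(hc$merge[m, 1])
      p2 <- get_prof(hc$merge[m, 2])
      profs[[m]] <- nw_merge(p1, p2, submat, gap)
    }
    prof <- profs[[length(profs)]]
  }
  rows <- apply(prof, 1L, paste, collapse = "")
  out <- rows[orig]
  class(out) <- "multiple_alignment"
  out
}

#' Alignment as a residue matrix
#' @param alignment Named character vector of equal-length aligned rows.
#' @return Character matrix, one row per sequence.
#' @export
alignment_matrix <- function(alignment) {
  alignment <- unclass(alignment)
  L <- unique(nchar(alignment))
  if (length(L) != 1L) stop2("alignment rows have unequal lengths")
  m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  rownames(m) <- names(alignment)
  m
}
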
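#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining from a symmetric distance matrix. At each
#' step the pair minimizing the Q criterion is joined; ties are broken by
#' the lowest index pair (row-major), making the algorithm deterministic.
#' Negative branch lengths are clamped to zero. The returned tree is
#' unrooted (trifurcating root node).
#'
#' @param dm Symmetric numeric matrix with ids as dimnames (>= 3 taxa).
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- paste0("t", seq_len(nrow(dm)))
  if (nrow(dm) < 3L) stop2("neighbor joining needs >= 3 taxa")
  if (max(abs(dm - t(dm))) > 1e-8) stop2("distance matrix is not symmetric")
  labs <- rownames(dm)     # current subtree newick fragments
  d <- dm
  diag(d) <- 0
  while (nrow(d) > 3L) {
    n <- nrow(d)
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    vi <- max(0, 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (n - 2)))
    vj <- max(0, d[i, j] - vi)
    newlab <- sprintf("(%s:%.10g,%s:%.10g)", labs[i], vi, labs[j], vj)
    dnew <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    d[i, ] <- dnew; d[, i] <- dnew; d[i, i] <- 0
    labs[i] <- newlab
    d <- d[-j, -j, drop = FALSE]
    labs <- labs[-j]
  }
  if (nrow(d) == 3L) {
    v1 <- max(0, (d[1, 2] + d[1, 3] - d[2, 3]) / 2)
    v2 <- max(0, (d[1, 2] + d[2, 3] - d[1, 3]) / 2)
    v3 <- max(0, (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                   labs[1], v1, labs[2], v2, labs[3], v3)
  } else {
    nwk <- sprintf("(%s:%.10g,%s:%.10g);",
                   labs[1], d[1, 2] / 2, labs[2], d[1, 2] / 2)
  }
  ape::read.tree(text = nwk)
}

# canonical keys of the non-trivial bipartitions of an unrooted tree
tree_bipartitions <- function(phy, all_tips) {
  pp <- ape::prop.part(phy)
  keys <- character(0)
  anchor <- sort(all_tips)[1]
  for (i in seq_along(pp)) {
    side <- phy$tip.label[pp[[i]]]
    if (length(side) <= 1L || length(side) >= length(all_tips) - 1L) next
    if (anchor %in% side) side <- setdiff(all_tips, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and annotates each internal bipartition of the
#' full-alignment tree with the percentage of replicate trees containing
#' it. One master seed derives an independent per-replicate seed, so runs
#' are reproducible.
#'
#' @param alignment Named character vector of aligned rows (>= 4).
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Master RNG seed.
#' @param model Distance model, see [distance_matrix()].
#' @return The NJ tree of the full alignment with `node.label` holding
#'   support percentages (root label empty).
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000L, seed = 1L,
                              model = "poisson") {
  if (n_replicates < 1L) stop2("n_replicates must be >= 1")
  m <- alignment_matrix(alignment)
  if (nrow(m) < 4L) stop2("bootstrap needs >= 4 sequences")
  ref <- nj_tree(distance_matrix(alignment, model = model))
  all_tips <- rownames(m)
  counts <- new.env(parent = emptyenv())
  for (b in seq_len(n_replicates)) {
    set.seed(derive_seed(seed, b))
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_aln <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
    tr <- nj_tree(distance_matrix(rep_aln, model = model))
    for (key in tree_bipartitions(tr, all_tips)) {
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  pp <- ape::prop.part(ref)
  anchor <- sort(all_tips)[1]
  node_lab <- character(ref$Nnode)
  for (i in seq_along(pp)) {
    side <- ref$tip.label[pp[[i]]]
    if (length(side) <= 1L || length(side) >= length(all_tips) - 1L) {
      node_lab[i] <- ""
      next
    }
    if (anchor %in% side) side <- setdiff(all_tips, side)
    key <- paste(sort(side), collapse = "|")
    node_lab[i] <- sprintf("%g", 100 * (counts[[key]] %||% 0L) / n_replicates)
  }
  node_lab[1] <- ""   # root of the unrooted tree carries no bipartition
  ref$node.label <- node_lab
  ref
}
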
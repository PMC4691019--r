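#' Codon equilibrium frequencies
#'
#' `"equal"` gives 1/61 for every sense codon; `"f3x4"` estimates them from
#' the product of position-specific nucleotide frequencies of the supplied
#' coding sequences, renormalized over the 61 sense codons.
#'
#' @param method `"equal"` or `"f3x4"`.
#' @param cds Named character vector of in-frame coding sequences (required
#'   for `"f3x4"`).
#' @return Numeric vector of length 61, ordered as the package's codon
#'   table, summing to 1.
#' @export
codon_frequencies <- function(method = c("equal", "f3x4"), cds = NULL) {
  method <- match.arg(method)
  ct <- codon_tables()
  if (method == "equal") {
    return(setNames(rep(1 / 61, 61), ct$codons))
  }
  if (is.null(cds)) stop2("f3x4 frequencies need coding sequences")
  cod <- unlist(lapply(cds, split_codons), use.names = FALSE)
  cod <- cod[!cod %in% ct$stops & !grepl("[^ACGT]", cod)]
  pos <- do.call(rbind, strsplit(cod, "", fixed = TRUE))
  f <- lapply(1:3, function(p) {
    tb <- table(factor(pos[, p], levels = ct$nts))
    fr <- as.numeric(tb) / sum(tb)
    pmax(fr, 1e-3) / sum(pmax(fr, 1e-3))
  })
  sp <- do.call(rbind, strsplit(ct$codons, "", fixed = TRUE))
  pi <- f[[1]][match(sp[, 1], ct$nts)] *
    f[[2]][match(sp[, 2], ct$nts)] *
    f[[3]][match(sp[, 3], ct$nts)]
  setNames(pi / sum(pi), ct$codons)
}

#' Site-class codon substitution model
#'
#' Describes a (possibly branch-heterogeneous) codon model: transition /
#' transversion ratio `kappa`, codon frequencies `pi`, and one row per site
#' class giving its weight and its dN/dS on background and foreground
#' branches. With no foreground branch the `omega_fg` column is ignored.
#' Rates are normalized by the neutral (omega = 1) mean rate, so a branch
#' length of 1 is one expected substitution per codon under neutrality.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param classes data.frame with columns `weight`, `omega_bg`, `omega_fg`.
#' @param pi Codon frequencies (length 61) or `NULL` for equal.
#' @param foreground Label of the foreground branch's child node (tip label
#'   or internal node label/number), or `NULL`.
#' @return Object of class `codon_model`.
#' @export
codon_model <- function(kappa, classes, pi = NULL, foreground = NULL) {
  if (is.null(pi)) pi <- codon_frequencies("equal")
  stopifnot(length(pi) == 61, all(pi > 0))
  pi <- pi / sum(pi)
  classes <- as.data.frame(classes)
  stopifnot(all(c("weight", "omega_bg", "omega_fg") %in% names(classes)))
  if (abs(sum(classes$weight) - 1) > 1e-8) stop2("class weights must sum to 1")
  if (kappa <= 0) stop2("kappa must be positive")
  structure(list(kappa = kappa, pi = pi, classes = classes,
                 foreground = foreground),
            class = "codon_model")
}

#' Normalized codon rate matrix
#' @param model A [codon_model()].
#' @param omega dN/dS for the matrix.
#' @return 61x61 generator matrix (rows sum to zero).
#' @export
codon_rate_matrix <- function(model, omega) {
  ct <- codon_tables()
  q <- codon_rate_matrix_cpp(model$pi, ct$type, model$kappa, omega)
  dimnames(q) <- list(ct$codons, ct$codons)
  q
}

#' Codon transition probability matrix
#' @param model A [codon_model()].
#' @param omega dN/dS.
#' @param t Branch length (expected neutral substitutions per codon).
#' @return 61x61 stochastic matrix.
#' @export
codon_pmatrix <- function(model, omega, t) {
  ct <- codon_tables()
  p <- codon_pmat_cpp(model$pi, ct$type, model$kappa, omega, t)
  dimnames(p) <- list(ct$codons, ct$codons)
  p
}

# resolve a node label (tip label, internal label, or number) to a node id
node_id <- function(tree, label) {
  i <- match(as.character(label), tree$tip.label)
  if (!is.na(i)) return(i)
  if (!is.null(tree$node.label)) {
    j <- match(as.character(label), tree$node.label)
    if (!is.na(j)) return(length(tree$tip.label) + j)
  }
  n <- suppressWarnings(as.integer(label))
  if (!is.na(n) && n >= 1 && n <= length(tree$tip.label) + tree$Nnode) return(n)
  stop2("node not found in tree: ", label)
}

# orient the tree away from `root_node`; returns postorder (parent, child)
# edge matrix with lengths, in ape node numbering
tree_postorder <- function(tree, root_node) {
  ne <- nrow(tree$edge)
  adj <- vector("list", length(tree$tip.label) + tree$Nnode)
  for (i in seq_len(ne)) {
    a <- tree$edge[i, 1]; b <- tree$edge[i, 2]
    len <- if (!is.null(tree$edge.length)) tree$edge.length[i] else 0.1
    adj[[a]] <- rbind(adj[[a]], c(b, len))
    adj[[b]] <- rbind(adj[[b]], c(a, len))
  }
  parent <- integer(0); child <- integer(0); len <- numeric(0)
  stack <- list(c(root_node, NA_real_))
  order_nodes <- integer(0)
  seen <- logical(length(adj))
  seen[root_node] <- TRUE
  # iterative DFS recording edges parent->child; postorder = reverse preorder
  # is NOT generally valid for multifurcations' partial products, but edges
  # only need the property "all edges in the child's subtree come first",
  # which reverse preorder of edges satisfies.
  pre_p <- integer(0); pre_c <- integer(0); pre_l <- numeric(0)
  st <- c(root_node)
  while (length(st)) {
    u <- st[length(st)]
    st <- st[-length(st)]
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      v <- as.integer(nb[r, 1])
      if (seen[v]) next
      seen[v] <- TRUE
      pre_p <- c(pre_p, u); pre_c <- c(pre_c, v); pre_l <- c(pre_l, nb[r, 2])
      st <- c(st, v)
    }
  }
  ord <- rev(seq_along(pre_p))
  list(edge = cbind(parent = pre_p[ord], child = pre_c[ord]),
       length = pre_l[ord], root = root_node)
}

# codon alignment -> list(patterns = ntip x npat index matrix (0 = missing),
# weights, ids)
codon_patterns <- function(alignment) {
  ids <- names(alignment)
  idx <- lapply(ids, function(id) {
    v <- codon_indices(alignment[[id]], id)
    v[is.na(v)] <- 0L
    v
  })
  L <- unique(lengths(idx))
  if (length(L) != 1L) stop2("aligned sequences differ in codon count")
  m <- do.call(rbind, idx)
  keys <- apply(m, 2L, paste, collapse = ",")
  uk <- unique(keys)
  pat <- m[, match(uk, keys), drop = FALSE]
  w <- as.numeric(table(factor(keys, levels = uk)))
  list(patterns = pat, weights = w, ids = ids, n_sites = ncol(m))
}

#' Log-likelihood of a codon alignment under a site-class model
#'
#' Felsenstein pruning over the tree, per site class; the site likelihood is
#' the weight-mixed class likelihood and the total is the sum of site
#' log-likelihoods. With a foreground branch, site classes may use a
#' different dN/dS on that branch than on the background.
#'
#' @param alignment Named character vector of aligned, gap-free (or
#'   `---`-padded) coding sequences; names must match the tree's tips.
#' @param tree [ape::phylo] with branch lengths.
#' @param model A [codon_model()].
#' @return Total log-likelihood (numeric scalar) with attributes
#'   `class_site_loglik` (classes x patterns), `pattern_weights`.
#' @export
codon_log_likelihood <- function(alignment, tree, model) {
  stopifnot(inherits(model, "codon_model"))
  if (!setequal(names(alignment), tree$tip.label)) {
    stop2("alignment ids and tree tips differ")
  }
  cp <- codon_patterns(alignment[tree$tip.label])
  ct <- codon_tables()
  ntip <- length(tree$tip.label)
  if (is.null(model$foreground)) {
    po <- tree_postorder(tree, ntip + 1L)
    fg_edge <- 0L
  } else {
    v <- node_id(tree, model$foreground)
    u <- tree$edge[tree$edge[, 2] == v, 1]
    if (!length(u)) stop2("foreground node has no parent edge: ", model$foreground)
    po <- tree_postorder(tree, u[1])
    fg_edge <- which(po$edge[, 2] == v)
  }
  ll <- class_site_loglik_cpp(po$edge, po$length, fg_edge, cp$patterns,
                              ntip + tree$Nnode, po$root, model$pi, ct$type,
                              model$kappa, model$classes$omega_bg,
                              model$classes$omega_fg)
  w <- model$classes$weight
  mx <- apply(ll, 2L, max)
  site_ll <- log(colSums(w * exp(sweep(ll, 2L, mx)))) + mx
  total <- sum(site_ll * cp$weights)
  attr(total, "class_site_loglik") <- ll
  attr(total, "pattern_weights") <- cp$weights
  total
}
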
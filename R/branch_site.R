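logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# model A class table from (p0, p1, w0, w2); p2a/p2b = p0/p1 by construction
model_a_classes <- function(p0, p1, w0, w2) {
  pt <- p0 + p1
  data.frame(
    weight = c(p0, p1, p0 / pt * (1 - pt), p1 / pt * (1 - pt)),
    omega_bg = c(w0, 1, w0, 1),
    omega_fg = c(w0, 1, w2, w2)
  )
}

#' Simulate a codon alignment under a branch-site model
#'
#' Each codon site is assigned one of the four model-A site classes by the
#' given proportions; sequences then evolve along the tree under the shared
#' codon rate matrix with the class's background dN/dS everywhere except the
#' foreground branch, which uses the class's foreground dN/dS. The root
#' state is drawn from the equilibrium frequencies over the 61 sense codons,
#' so no stop codon is ever emitted. Deterministic for a fixed seed.
#'
#' @param tree [ape::phylo] with branch lengths (expected neutral
#'   substitutions per codon).
#' @param n_codons Number of codon sites.
#' @param kappa Transition/transversion ratio.
#' @param proportions Length-4 vector (p0, p1, p2a, p2b), summing to 1.
#' @param omega0 Background purifying dN/dS, in (0, 1).
#' @param omega2 Foreground dN/dS of classes 2a/2b (>= 1).
#' @param pi Codon frequencies (61) or `NULL` for equal.
#' @param foreground Foreground branch (child node label) or `NULL`.
#' @param seed RNG seed.
#' @return list(`alignment` named character vector of CDS, `site_class`
#'   integer vector in 0/1/2/3 for classes 0,1,2a,2b, `tree`, `params`).
#' @export
simulate_codon_alignment <- function(tree, n_codons, kappa = 2,
                                     proportions = c(0.4, 0.4, 0.1, 0.1),
                                     omega0 = 0.2, omega2 = 5, pi = NULL,
                                     foreground = NULL, seed = 1L) {
  stopifnot(length(proportions) == 4, all(proportions >= 0))
  if (abs(sum(proportions) - 1) > 1e-8) stop2("proportions must sum to 1")
  if (omega0 <= 0 || omega0 >= 1) stop2("omega0 must be in (0,1)")
  if (omega2 < 1) stop2("omega2 must be >= 1")
  if (any(tree$edge.length < 0)) stop2("branch lengths must be >= 0")
  model <- codon_model(kappa, model_a_classes(
    proportions[1], proportions[2], omega0, omega2), pi = pi,
    foreground = foreground)
  ct <- codon_tables()
  set.seed(seed)
  cls <- sample.int(4L, n_codons, replace = TRUE, prob = proportions) - 1L
  ntip <- length(tree$tip.label)
  po <- tree_postorder(tree, ntip + 1L)
  fg_node <- if (is.null(foreground)) -1L else node_id(tree, foreground)
  states <- matrix(0L, nrow = ntip + tree$Nnode, ncol = n_codons)
  states[po$root, ] <- sample.int(61L, n_codons, replace = TRUE,
                                  prob = model$pi)
  omega_bg <- model$classes$omega_bg
  omega_fg <- model$classes$omega_fg
  # preorder = reverse of postorder
  for (i in rev(seq_len(nrow(po$edge)))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]; t <- po$length[i]
    om <- if (ch == fg_node) omega_fg else omega_bg
    for (w in unique(om)) {
      sites <- which(om[cls + 1L] == w)
      if (!length(sites)) next
      P <- codon_pmat_cpp(model$pi, ct$type, kappa, w, t)
      for (s in sites) {
        states[ch, s] <- sample.int(61L, 1L, prob = P[states[p, s], ])
      }
    }
  }
  aln <- vapply(seq_len(ntip), function(i) {
    paste(ct$codons[states[i, ]], collapse = "")
  }, character(1))
  names(aln) <- tree$tip.label
  list(alignment = aln, site_class = cls, tree = tree,
       params = list(kappa = kappa, proportions = proportions,
                     omega0 = omega0, omega2 = omega2,
                     foreground = foreground, seed = seed))
}

#' One-ratio (M0) codon model fit
#'
#' Maximizes the likelihood over kappa, a single dN/dS and all branch
#' lengths. Used on its own and as the branch-length stage of
#' [fit_branch_site_A()].
#'
#' @param alignment Named character vector of aligned coding sequences.
#' @param tree [ape::phylo]; its branch lengths seed the optimization.
#' @param pi Codon frequencies (61), `"f3x4"` or `"equal"`.
#' @param maxit Iteration cap for the L-BFGS-B stage.
#' @return list(`lnL`, `kappa`, `omega`, `tree` with fitted branch lengths,
#'   `pi`, `convergence`).
#' @export
fit_m0 <- function(alignment, tree, pi = "f3x4", maxit = 120L) {
  pi <- resolve_pi(pi, alignment)
  ct <- codon_tables()
  cp <- codon_patterns(alignment[tree$tip.label])
  ntip <- length(tree$tip.label)
  po <- tree_postorder(tree, ntip + 1L)
  el0 <- pmax(po$length, 1e-3)
  nedge <- length(el0)
  obj <- function(par) {
    el <- exp(par[seq_len(nedge)])
    kappa <- exp(par[nedge + 1L])
    omega <- exp(par[nedge + 2L])
    ll <- class_site_loglik_cpp(po$edge, el, 0L, cp$patterns,
                                ntip + tree$Nnode, po$root, pi, ct$type,
                                kappa, omega, omega)
    -sum(ll[1, ] * cp$weights)
  }
  par0 <- c(log(el0), log(2), log(0.3))
  lower <- c(rep(log(1e-6), nedge), log(0.05), log(1e-4))
  upper <- c(rep(log(20), nedge), log(50), log(20))
  fit <- stats::optim(par0, obj, method = "L-BFGS-B", lower = lower,
                      upper = upper, control = list(maxit = maxit))
  el <- exp(fit$par[seq_len(nedge)])
  fitted_tree <- tree
  key <- paste(pmin(po$edge[, 1], po$edge[, 2]),
               pmax(po$edge[, 1], po$edge[, 2]))
  tkey <- paste(pmin(tree$edge[, 1], tree$edge[, 2]),
                pmax(tree$edge[, 1], tree$edge[, 2]))
  fitted_tree$edge.length <- el[match(tkey, key)]
  list(lnL = -fit$value, kappa = exp(fit$par[nedge + 1L]),
       omega = exp(fit$par[nedge + 2L]), tree = fitted_tree, pi = pi,
       convergence = fit$convergence)
}

resolve_pi <- function(pi, alignment) {
  if (is.character(pi) && length(pi) == 1L) {
    codon_frequencies(pi, cds = alignment)
  } else {
    stopifnot(length(pi) == 61)
    pi / sum(pi)
  }
}

#' Fit branch-site model A
#'
#' Model A assigns each codon site to one of four classes: conserved
#' everywhere (0 < omega0 < 1), neutral everywhere (omega1 = 1), and two
#' classes (2a, 2b) that are conserved or neutral on background branches but
#' evolve with omega2 >= 1 on the designated foreground branch. Under the
#' null hypothesis omega2 is fixed at 1. The constraint p2a/p2b = p0/p1
#' holds by construction. Branch lengths and an initial kappa are estimated
#' once under a one-ratio (M0) model; background branch lengths are then
#' held fixed while (kappa, omega0, omega2) and the foreground branch
#' length are optimized by multi-start Nelder-Mead (omega2 started at 1.5
#' and two larger values) with the class weights profiled out at every
#' step. omega2 is capped at 999.
#'
#' @param alignment Named character vector of aligned coding sequences.
#' @param tree [ape::phylo] with the foreground branch present.
#' @param foreground Child-node label of the foreground branch.
#' @param hypothesis `"alternative"` (omega2 free) or `"null"` (omega2 = 1).
#' @param pi Codon frequencies (61), `"f3x4"` or `"equal"`.
#' @param m0 Optional precomputed [fit_m0()] result to reuse.
#' @param extra_starts Optional list of start vectors
#'   `list(kappa=, w0=, w2=, p0=, p1=)` appended to the default starts.
#' @return Object of class `branch_site_fit`: `lnL`, `kappa`, `w0`, `w2`,
#'   `p0`, `p1`, `p2a`, `p2b`, `hypothesis`, `foreground`, `tree` (fitted
#'   branch lengths), `pi`, `n_starts`, `convergence`.
#' @export
fit_branch_site_A <- function(alignment, tree, foreground,
                              hypothesis = c("alternative", "null"),
                              pi = "f3x4", m0 = NULL, extra_starts = NULL) {
  hypothesis <- match.arg(hypothesis)
  pi <- resolve_pi(pi, alignment)
  if (is.null(m0)) m0 <- fit_m0(alignment, tree, pi = pi)
  ct <- codon_tables()
  btree <- m0$tree
  ntip <- length(btree$tip.label)
  v <- node_id(btree, foreground)
  u <- btree$edge[btree$edge[, 2] == v, 1]
  if (!length(u)) stop2("foreground branch not found: ", foreground)
  po <- tree_postorder(btree, u[1])
  fg_edge <- which(po$edge[, 2] == v)
  cp <- codon_patterns(alignment[btree$tip.label])

  tfg0 <- max(po$length[fg_edge], 1e-4)
  class_ll <- function(kappa, w0, w2, tfg) {
    el <- po$length
    el[fg_edge] <- tfg
    class_site_loglik_cpp(po$edge, el, fg_edge, cp$patterns,
                          ntip + btree$Nnode, po$root, pi, ct$type, kappa,
                          c(w0, 1, w0, 1), c(w0, 1, w2, w2))
  }
  # profile the class weights out for a fixed (kappa, w0, w2)
  profile_weights <- function(ll, p0 = 0.5, p1 = 0.4) {
    mx <- apply(ll, 2L, max)
    E <- exp(sweep(ll, 2L, mx))
    wobj <- function(q) {
      r0 <- inv_logit(q[1]); pt <- inv_logit(q[2])
      p <- c(r0 * pt, (1 - r0) * pt, r0 * (1 - pt), (1 - r0) * (1 - pt))
      -sum((log(colSums(p * E)) + mx) * cp$weights)
    }
    q0 <- c(logit(min(max(p0 / (p0 + p1), 1e-3), 1 - 1e-3)),
            logit(min(max(p0 + p1, 1e-3), 1 - 1e-3)))
    wfit <- stats::optim(q0, wobj, method = "Nelder-Mead",
                         control = list(maxit = 150, reltol = 1e-8))
    r0 <- inv_logit(wfit$par[1]); pt <- inv_logit(wfit$par[2])
    list(lnL = -wfit$value, p0 = r0 * pt, p1 = (1 - r0) * pt)
  }
  null_model <- hypothesis == "null"
  # parameters: log kappa, logit w0, log tfg, [log (w2 - 1)]
  unpack <- function(par) {
    list(kappa = exp(par[1]), w0 = inv_logit(par[2]),
         tfg = min(exp(par[3]), 20),
         w2 = if (null_model) 1 else min(1 + exp(par[4]), 999))
  }
  outer_obj <- function(par) {
    q <- unpack(par)
    -profile_weights(class_ll(q$kappa, q$w0, q$w2, q$tfg))$lnL
  }
  w0_init <- min(max(m0$omega, 0.01), 0.9)
  base <- function(w0i) c(log(m0$kappa), logit(w0i), log(tfg0))
  starts <- if (null_model) {
    list(base(w0_init), base(0.1), c(log(2), logit(0.5), log(tfg0)))
  } else {
    list(c(base(w0_init), log(1.5 - 1)),
         c(base(w0_init), log(5 - 1)),
         c(base(0.2), log(50 - 1)))
  }
  for (st in extra_starts %||% list()) {
    s <- c(log(st$kappa), logit(st$w0), log(st$tfg %||% tfg0))
    if (!null_model) s <- c(s, log(max(st$w2, 1 + 1e-6) - 1 + 1e-9))
    starts <- c(starts, list(s))
  }
  # explore every start briefly, then polish the best one
  best <- NULL
  for (st in starts) {
    f <- stats::optim(st, outer_obj, method = "Nelder-Mead",
                      control = list(maxit = 120, reltol = 1e-7))
    if (is.null(best) || f$value < best$value) best <- f
  }
  best <- stats::optim(best$par, outer_obj, method = "Nelder-Mead",
                       control = list(maxit = 400, reltol = 1e-9))
  q <- unpack(best$par)
  kappa <- q$kappa; w0 <- q$w0; w2 <- q$w2
  btree$edge.length[btree$edge[, 2] == v] <- q$tfg
  prof <- profile_weights(class_ll(kappa, w0, w2, q$tfg))
  p0 <- prof$p0; p1 <- prof$p1
  pt <- p0 + p1
  structure(list(
    lnL = prof$lnL, kappa = kappa, w0 = w0, w2 = w2,
    p0 = p0, p1 = p1,
    p2a = p0 / pt * (1 - pt), p2b = p1 / pt * (1 - pt),
    hypothesis = hypothesis, foreground = foreground, tree = btree,
    pi = pi, n_starts = length(starts), convergence = best$convergence,
    m0 = list(lnL = m0$lnL, kappa = m0$kappa, omega = m0$omega)),
    class = "branch_site_fit")
}

#' @export
print.branch_site_fit <- function(x, ...) {
  cat(sprintf(
    "<branch_site_fit> %s, fg=%s  lnL=%.3f\n  kappa=%.3f w0=%.4f w2=%.4f  p=(%.4f, %.4f, %.4f, %.4f)\n",
    x$hypothesis, x$foreground, x$lnL, x$kappa, x$w0, x$w2,
    x$p0, x$p1, x$p2a, x$p2b))
  invisible(x)
}

#' Likelihood-ratio test of episodic positive selection
#'
#' Compares the alternative branch-site fit against the null (omega2 = 1):
#' the statistic is `2 * (lnL_alt - lnL_null)`, clamped at zero, with the
#' p-value from a chi-square distribution with one degree of freedom (or,
#' optionally, the 50:50 mixture of a point mass at zero and chi-square-1).
#'
#' @param fit_alt,fit_null [fit_branch_site_A()] results, or bare numeric
#'   log-likelihoods.
#' @param null_dist `"chisq1"` or `"mixture"`.
#' @return list(`statistic`, `df`, `p_value`, `foreground`). An alternative
#'   log-likelihood more than 1e-6 below the null is an optimizer failure
#'   and raises an error.
#' @export
likelihood_ratio_test <- function(fit_alt, fit_null, null_dist = c("chisq1", "mixture")) {
  null_dist <- match.arg(null_dist)
  lnl <- function(f) if (inherits(f, "branch_site_fit")) f$lnL else as.numeric(f)
  la <- lnl(fit_alt); ln <- lnl(fit_null)
  stat <- 2 * (la - ln)
  if (stat < -1e-6) {
    stop2("alternative lnL below null lnL (", format(stat / 2),
          "): optimizer failure")
  }
  stat <- max(stat, 0)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (null_dist == "mixture") p <- if (stat == 0) 1 else p / 2
  fg <- if (inherits(fit_alt, "branch_site_fit")) fit_alt$foreground else NA
  list(statistic = stat, df = 1L, p_value = p, foreground = fg)
}

#' Branch-site positive-selection test (null + alternative + LRT)
#'
#' Convenience wrapper: estimates branch lengths once under M0, fits the
#' null, then the alternative seeded additionally with the null solution
#' (guaranteeing the nesting inequality), and returns the LRT.
#'
#' @inheritParams fit_branch_site_A
#' @param null_dist Passed to [likelihood_ratio_test()].
#' @return list(`alternative`, `null`, `lrt`).
#' @export
branch_site_test <- function(alignment, tree, foreground, pi = "f3x4",
                             null_dist = "chisq1") {
  pi <- resolve_pi(pi, alignment)
  m0 <- fit_m0(alignment, tree, pi = pi)
  fit0 <- fit_branch_site_A(alignment, tree, foreground, "null",
                            pi = pi, m0 = m0)
  tfg_null <- fit0$tree$edge.length[fit0$tree$edge[, 2] ==
                                      node_id(fit0$tree, foreground)]
  fit1 <- fit_branch_site_A(alignment, tree, foreground, "alternative",
                            pi = pi, m0 = m0,
                            extra_starts = list(list(
                              kappa = fit0$kappa, w0 = fit0$w0, w2 = 1,
                              tfg = tfg_null, p0 = fit0$p0, p1 = fit0$p1)))
  if (fit1$lnL < fit0$lnL) {
    # the null is a boundary point of the alternative: never below it
    fit1$lnL <- fit0$lnL
    fit1$kappa <- fit0$kappa; fit1$w0 <- fit0$w0; fit1$w2 <- 1
    fit1$p0 <- fit0$p0; fit1$p1 <- fit0$p1
    fit1$p2a <- fit0$p2a; fit1$p2b <- fit0$p2b
  }
  list(alternative = fit1, null = fit0,
       lrt = likelihood_ratio_test(fit1, fit0, null_dist = null_dist))
}
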
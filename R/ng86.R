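#' Pairwise Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Synonymous site counts are per-codon fractions of single-nucleotide
#' changes that preserve the amino acid (changes to stop codons count as
#' nonsynonymous), averaged over the two sequences. For codons differing at
#' more than one position, synonymous/nonsynonymous difference counts are
#' averaged over all substitution pathways with equal weight; pathways
#' passing through a stop codon are excluded (all pathways are used if
#' every one is blocked). Proportions are Jukes-Cantor corrected,
#' `d = -3/4 ln(1 - 4p/3)`.
#'
#' @param cds_a,cds_b Coding sequences of equal length, divisible by 3, no
#'   internal stop codons. A trailing stop codon on both is tolerated and
#'   dropped.
#' @return list with `ka`, `ks`, `omega` (`NA` when `ks` is 0 or
#'   undefined), site counts `S`, `N`, difference counts `Sd`, `Nd`,
#'   proportions `ps`, `pn`, and saturation flags `saturated_s`,
#'   `saturated_n` (`p >= 3/4`, the corrected distance is undefined and
#'   returned as `NA`).
#' @export
ng86_kaks <- function(cds_a, cds_b) {
  ct <- codon_tables()
  ia <- codon_indices(cds_a, "cds_a")
  ib <- codon_indices(cds_b, "cds_b")
  if (length(ia) != length(ib)) stop2("sequences differ in codon count")
  ok <- !is.na(ia) & !is.na(ib)
  ia <- ia[ok]; ib <- ib[ok]
  if (!length(ia)) stop2("no comparable codons")
  S <- (sum(ct$syn_sites[ia]) + sum(ct$syn_sites[ib])) / 2
  N <- 3 * length(ia) - S
  diffs <- vapply(seq_along(ia), function(k) {
    count_pathway_diffs(ct$codons[ia[k]], ct$codons[ib[k]])
  }, numeric(2))
  Sd <- sum(diffs[1, ])
  Nd <- sum(diffs[2, ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    if (p >= 3 / 4) return(NA_real_)
    if (p == 0) return(0)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  ks <- jc(ps)
  ka <- jc(pn)
  list(ka = ka, ks = ks,
       omega = if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_,
       S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
       saturated_s = ps >= 3 / 4, saturated_n = pn >= 3 / 4)
}

# (Sd, Nd) between two codons, averaged over stop-free substitution pathways
count_pathway_diffs <- function(ca, cb) {
  if (ca == cb) return(c(0, 0))
  ct <- codon_tables()
  gc <- Biostrings::GENETIC_CODE
  a <- chars(ca); b <- chars(cb)
  pos <- which(a != b)
  paths <- if (length(pos) == 1L) list(pos) else
    apply(permutations_of(pos), 1L, identity, simplify = FALSE)
  step_counts <- function(order) {
    cur <- a
    sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur
      nxt[p] <- b[p]
      c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
      if (gc[[c2]] == "*" || gc[[c1]] == "*") return(NULL)
      if (gc[[c1]] == gc[[c2]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  counted <- Filter(Negate(is.null), lapply(paths, step_counts))
  if (!length(counted)) {
    counted <- lapply(paths, function(order) {
      cur <- a; sd <- 0; nd <- 0
      for (p in order) {
        nxt <- cur; nxt[p] <- b[p]
        same <- gc[[paste(cur, collapse = "")]] == gc[[paste(nxt, collapse = "")]]
        if (same) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    })
  }
  Reduce(`+`, counted) / length(counted)
}

permutations_of <- function(x) {
  if (length(x) == 1L) return(matrix(x, 1L))
  out <- NULL
  for (i in seq_along(x)) {
    rest <- permutations_of(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}
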
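#' Pairwise-deletion distance matrix from an alignment
#'
#' For each sequence pair, alignment columns where either row is gapped are
#' excluded (pairwise deletion); the proportion of mismatches among the
#' remaining columns gives the p-distance, optionally Poisson-corrected
#' (`d = -ln(1 - p)`).
#'
#' @param alignment Named character vector of aligned rows.
#' @param model `"poisson"` (default) or `"p"`.
#' @return Symmetric numeric matrix with zero diagonal and sequence ids as
#'   dimnames. A pair with no comparable columns is an error naming the pair.
#' @export
distance_matrix <- function(alignment, model = c("poisson", "p")) {
  model <- match.arg(model)
  m <- alignment_matrix(alignment)
  if (nrow(m) < 2L) stop2("need >= 2 sequences")
  n <- nrow(m)
  ids <- rownames(m)
  gap <- m == "-"
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok)) stop2("no comparable columns for pair ", ids[i], " / ", ids[j])
    p <- mean(m[i, ok] != m[j, ok])
    dij <- if (model == "p") p else -log(max(1 - p, 1e-10))
    d[i, j] <- d[j, i] <- dij
  }
  d
}
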
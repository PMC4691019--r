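#' Simulate an RPKM expression matrix with planted drought responses
#'
#' Emulates a dehydration time-course (control `D0`, dehydrated 1/3/6 h,
#' 24 h recovery): a chosen number of genes are planted as up-regulated
#' (fold changes log2-uniform over `up_fold_range`, peaking at D3 or D6)
#' or down-regulated (over `down_fold_range`), the rest are flat.
#' Multiplicative log-normal noise (sd in log2 units) is applied on top of
#' the noise-free profile; with `noise = 0` the planted log2 ratios are
#' exact and fold-change classification recovers the truth labels exactly.
#'
#' @param n_genes Total genes.
#' @param n_up,n_down Number of planted up-/down-regulated genes.
#' @param up_fold_range,down_fold_range Fold-change ranges (> 0, >= 1).
#' @param conditions Condition labels; the first is the control.
#' @param base_meanlog,base_sdlog Log-normal parameters of baseline RPKM.
#' @param noise Log2-scale sd of multiplicative noise (>= 0).
#' @param gene_ids Optional gene ids (default `GENE0001`...).
#' @param seed RNG seed.
#' @return list(`matrix` genes x conditions RPKM, `truth` data.frame
#'   (`gene_id`, `class`, `fold`, `peak`), `control`).
#' @export
simulate_expression_matrix <- function(n_genes = 103L, n_up = 44L, n_down = 19L,
                                       up_fold_range = c(2, 1024),
                                       down_fold_range = c(2, 64),
                                       conditions = c("D0", "D1", "D3", "D6", "D24"),
                                       base_meanlog = log(50), base_sdlog = 0.8,
                                       noise = 0, gene_ids = NULL, seed = 1L) {
  if (any(c(up_fold_range, down_fold_range) <= 0)) {
    stop2("planted fold changes must be positive")
  }
  if (noise < 0) stop2("noise must be >= 0")
  if (n_up + n_down > n_genes) stop2("more planted responders than genes")
  set.seed(seed)
  if (is.null(gene_ids)) gene_ids <- sprintf("GENE%04d", seq_len(n_genes))
  control <- conditions[1]
  cls <- c(rep("up", n_up), rep("down", n_down),
           rep("unresponsive", n_genes - n_up - n_down))
  cls <- sample(cls)
  lfold <- numeric(n_genes)
  lfold[cls == "up"] <- runif(n_up, log2(up_fold_range[1]), log2(up_fold_range[2]))
  lfold[cls == "down"] <- -runif(n_down, log2(down_fold_range[1]),
                                 log2(down_fold_range[2]))
  peak <- ifelse(cls == "unresponsive", NA,
                 sample(c("D3", "D6"), n_genes, replace = TRUE))
  base <- rlnorm(n_genes, base_meanlog, base_sdlog)
  profile <- matrix(0, n_genes, length(conditions),
                    dimnames = list(gene_ids, conditions))
  for (i in seq_len(n_genes)) {
    if (cls[i] == "unresponsive") next
    shape <- c(D1 = 0.5, D3 = 0.75, D6 = 0.75, D24 = 0.1)
    shape[peak[i]] <- 1
    for (cn in names(shape)) {
      if (cn %in% conditions) profile[i, cn] <- lfold[i] * shape[[cn]]
    }
  }
  mat <- base * 2^profile
  if (noise > 0) {
    mat <- mat * 2^matrix(rnorm(length(mat), 0, noise), nrow(mat))
  }
  truth <- data.frame(gene_id = gene_ids, class = cls,
                      fold = 2^abs(lfold) * ifelse(cls == "down", -1, 1)^0,
                      log2_fold = lfold, peak = peak, stringsAsFactors = FALSE)
  truth$fold[cls == "unresponsive"] <- 1
  truth$log2_fold[cls == "unresponsive"] <- 0
  list(matrix = mat, truth = truth, control = control)
}
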
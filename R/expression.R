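#' Reads per kilobase per million mapped reads
#'
#' `RPKM = 1e9 * counts / (library_size * gene_length_bp)`; linear in
#' counts. Vectorized over genes.
#'
#' @param counts Read counts (>= 0).
#' @param gene_length_bp Gene (transcript) length in bp (> 0).
#' @param library_size Total mapped reads in the library (> 0).
#' @return Numeric RPKM values.
#' @export
rpkm <- function(counts, gene_length_bp, library_size) {
  if (any(gene_length_bp <= 0)) stop2("gene_length_bp must be positive")
  if (any(library_size <= 0)) stop2("library_size must be positive")
  1e9 * counts / (library_size * gene_length_bp)
}

#' Per-gene log2 expression ratios against a control condition
#'
#' `log2((x + pseudocount) / (control + pseudocount))` for every condition
#' column; the control column is identically zero. The pseudocount (default
#' 1 RPKM) bounds ratios when either value is zero; set it to 0 for
#' strictly positive matrices.
#'
#' @param matrix Numeric matrix, genes x conditions, with column names.
#' @param control Name of the control column.
#' @param pseudocount Non-negative constant added to both numerator and
#'   denominator.
#' @return Matrix of log2 ratios with the same dimnames.
#' @export
log2_ratio_matrix <- function(matrix, control, pseudocount = 1) {
  if (!control %in% colnames(matrix)) stop2("control column not found: ", control)
  if (pseudocount < 0) stop2("pseudocount must be >= 0")
  y <- matrix[, control] + pseudocount
  out <- log2(sweep(matrix + pseudocount, 1L, y, "/"))
  out[, control] <- 0
  out
}

#' Classify genes as up/down/unresponsive from log2 ratios
#'
#' A gene is `up` when its maximum log2 ratio over the treatment conditions
#' reaches `log2(threshold)`, `down` when its minimum reaches
#' `-log2(threshold)`, otherwise `unresponsive`. A gene crossing both
#' thresholds is classed `up` and flagged (`both_directions`).
#'
#' @param log_ratios Matrix from [log2_ratio_matrix()].
#' @param threshold Fold-change threshold (default 2).
#' @param control Optional control column name to exclude from the extrema.
#' @return data.frame: `gene_id`, `class`, `max_log2`, `min_log2`,
#'   `both_directions`; attribute `summary` holds the class counts.
#' @export
fold_change_classify <- function(log_ratios, threshold = 2, control = NULL) {
  lr <- log_ratios
  if (!is.null(control) && control %in% colnames(lr)) {
    lr <- lr[, setdiff(colnames(lr), control), drop = FALSE]
  }
  t2 <- log2(threshold)
  mx <- apply(lr, 1L, max)
  mn <- apply(lr, 1L, min)
  up <- mx >= t2
  dn <- mn <= -t2
  cls <- ifelse(up, "up", ifelse(dn, "down", "unresponsive"))
  out <- data.frame(gene_id = rownames(lr) %||% seq_len(nrow(lr)),
                    class = cls, max_log2 = mx, min_log2 = mn,
                    both_directions = up & dn,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "summary") <- c(up = sum(cls == "up"), down = sum(cls == "down"),
                            unresponsive = sum(cls == "unresponsive"))
  out
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering for heatmap row ordering, on euclidean or
#' correlation (1 - Pearson r) distances with average or complete linkage.
#' A constant row under the correlation metric is an error naming the gene.
#'
#' @param matrix Numeric matrix, genes x conditions (>= 2 genes).
#' @param metric `"euclidean"` or `"correlation"`.
#' @param linkage `"average"` or `"complete"`.
#' @param k Optional number of clusters to cut into.
#' @return list(`hclust`, `order` leaf labels in dendrogram order,
#'   `heights`, and `clusters` (named vector) when `k` is given).
#' @export
hierarchical_cluster <- function(matrix, metric = c("euclidean", "correlation"),
                                 linkage = c("average", "complete"), k = NULL) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  if (nrow(matrix) < 2L) stop2("need >= 2 genes to cluster")
  if (metric == "correlation") {
    sds <- apply(matrix, 1L, stats::sd)
    if (any(sds == 0)) {
      stop2("constant expression row(s) under correlation metric: ",
            paste(rownames(matrix)[sds == 0], collapse = ", "))
    }
    d <- stats::as.dist(1 - stats::cor(t(matrix)))
  } else {
    d <- stats::dist(matrix)
  }
  hc <- stats::hclust(d, method = linkage)
  out <- list(hclust = hc, order = hc$labels[hc$order], heights = hc$height)
  if (!is.null(k)) out$clusters <- stats::cutree(hc, k = k)
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_reference` (replicate-paired); `ddCt`
#' is taken against the control sample's mean dCt, and relative expression
#' is `2^-ddCt`. The control sample's own relative expression is 1 by
#' construction.
#'
#' @param target_ct,reference_ct Numeric matrices (samples x technical
#'   replicates, rownames = sample names) or named vectors (one value per
#'   sample).
#' @param control_sample Name of the control (calibrator) sample.
#' @return data.frame: `sample`, `dct`, `ddct`, `rel_expr`, `se` (standard
#'   error of `rel_expr` over technical replicates; 0 with a single
#'   replicate).
#' @export
delta_delta_ct <- function(target_ct, reference_ct, control_sample) {
  as_mat <- function(x) {
    if (is.matrix(x)) x else matrix(x, ncol = 1L, dimnames = list(names(x), NULL))
  }
  tg <- as_mat(target_ct)
  rf <- as_mat(reference_ct)
  if (!all(rownames(tg) %in% rownames(rf))) {
    stop2("missing reference Ct for sample(s): ",
          paste(setdiff(rownames(tg), rownames(rf)), collapse = ", "))
  }
  rf <- rf[rownames(tg), , drop = FALSE]
  if (!all(is.finite(tg)) || !all(is.finite(rf))) stop2("non-finite Ct values")
  if (!control_sample %in% rownames(tg)) {
    stop2("control sample not found: ", control_sample)
  }
  dct <- tg - rf
  dct_mean <- rowMeans(dct)
  ddct <- dct_mean - dct_mean[[control_sample]]
  rel <- 2^(-ddct)
  se <- apply(dct, 1L, function(r) {
    if (length(r) < 2L) return(0)
    vals <- 2^(-(r - dct_mean[[control_sample]]))
    stats::sd(vals) / sqrt(length(vals))
  })
  data.frame(sample = rownames(tg), dct = dct_mean, ddct = ddct,
             rel_expr = rel, se = se, stringsAsFactors = FALSE,
             row.names = NULL)
}
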
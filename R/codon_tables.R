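# Shared codon bookkeeping for the NG86 and codon-likelihood machinery.
# The 61 sense codons of the standard genetic code are indexed 1..61 in
# fixed lexicographic (T,C,A,G irrelevant -- plain A,C,G,T) order.

codon_tables <- function() {
  if (!is.null(.wrky$codon)) return(.wrky$codon)
  nts <- c("A", "C", "G", "T")
  all64 <- apply(expand.grid(nts, nts, nts, stringsAsFactors = FALSE)[, 3:1],
                 1L, paste, collapse = "")
  all64 <- sort(all64)
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[all64])
  sense <- all64[aa != "*"]
  aa_sense <- aa[aa != "*"]
  n <- length(sense)                       # 61
  splits <- do.call(rbind, strsplit(sense, "", fixed = TRUE))
  is_transition <- function(x, y) {
    (x %in% c("A", "G") && y %in% c("A", "G")) ||
      (x %in% c("C", "T") && y %in% c("C", "T"))
  }
  # type: 0 = not a single-nt change; 1 syn tv; 2 syn ts; 3 nonsyn tv; 4 nonsyn ts
  type <- matrix(0L, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    diff <- which(splits[i, ] != splits[j, ])
    if (length(diff) != 1L) next
    ts <- is_transition(splits[i, diff], splits[j, diff])
    syn <- aa_sense[i] == aa_sense[j]
    type[i, j] <- if (syn && !ts) 1L else if (syn && ts) 2L
    else if (!syn && !ts) 3L else 4L
  }
  # per-codon synonymous site fraction (stops count as nonsynonymous targets)
  syn_sites <- vapply(seq_len(n), function(i) {
    s <- 0
    for (p in 1:3) for (alt in setdiff(nts, splits[i, p])) {
      mut <- splits[i, ]
      mut[p] <- alt
      mut <- paste(mut, collapse = "")
      if (gc[[mut]] != "*" && gc[[mut]] == aa_sense[i]) s <- s + 1 / 3
    }
    s
  }, numeric(1))
  names(syn_sites) <- sense
  .wrky$codon <- list(codons = sense, aa = setNames(aa_sense, sense),
                      type = type, syn_sites = syn_sites, nts = nts,
                      stops = all64[aa == "*"])
  .wrky$codon
}

split_codons <- function(cds) {
  cds <- toupper(gsub("\\s", "", cds))
  if (nchar(cds) %% 3 != 0) stop2("CDS length not divisible by 3")
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

# codon strings -> 1..61 index (NA for gaps/ambiguity), error on internal stop
codon_indices <- function(cds, id = "sequence") {
  ct <- codon_tables()
  cod <- split_codons(cds)
  if (length(cod) && cod[length(cod)] %in% ct$stops) cod <- cod[-length(cod)]
  if (any(cod %in% ct$stops)) stop2("internal stop codon in ", id)
  idx <- match(cod, ct$codons)
  idx
}
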
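# shared, lazily built fixtures (generation is seeded and deterministic)
.fixture_cache <- new.env(parent = emptyenv())

default_genome <- function() {
  if (is.null(.fixture_cache$genome)) {
    .fixture_cache$genome <- generate_annotated_genome(family_plant_spec(seed = 11))
  }
  .fixture_cache$genome
}

default_scan <- function() {
  if (is.null(.fixture_cache$scan)) {
    .fixture_cache$scan <- scan_proteome(default_genome()$proteins)
  }
  .fixture_cache$scan
}

# 8-taxon tree used for branch-site simulations; foreground = tip A
bs_sim_tree <- function() {
  ape::read.tree(text = paste0(
    "((A:0.4,B:0.2):0.1,(C:0.2,D:0.2):0.1,",
    "((E:0.2,F:0.2):0.1,(G:0.2,H:0.2):0.1):0.1);"))
}

# write a small FASTA and return its path (in the session tempdir)
tmp_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  write_fasta(seqs, path)
  path
}

# a small constructed protein with one planted domain
planted_protein <- function(finger = "C2H2", x1 = 4L, x2 = 22L, lead = 10L) {
  filler <- function(n) paste(rep("A", n), collapse = "")
  finger_part <- if (finger == "C2H2") {
    paste0("C", filler(x1), "C", filler(x2), "H", "A", "H")
  } else {
    paste0("C", filler(7), "C", filler(23), "H", "A", "C")
  }
  paste0("M", filler(lead - 1L), "WRKYGQK", filler(10), finger_part, filler(12))
}

# independent pathway enumerator for NG86 difference counts (test oracle):
# recursively walks every stop-free substitution order between two codons
brute_pathway_counts <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  walk <- function(cur, target) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(pos)) return(list(c(0, 0)))
    out <- list()
    for (p in pos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(target, p, p)
      if (gc[[nxt]] == "*") next
      step <- if (gc[[cur]] == gc[[nxt]]) c(1, 0) else c(0, 1)
      for (rest in walk(nxt, target)) out[[length(out) + 1L]] <- step + rest
    }
    out
  }
  res <- walk(c1, c2)
  if (!length(res)) return(NULL)  # all pathways pass through a stop
  Reduce(`+`, res) / length(res)
}

# independent per-codon synonymous site count (test oracle)
brute_syn_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  s <- 0
  for (p in 1:3) for (nt in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
    mut <- codon
    substr(mut, p, p) <- nt
    if (gc[[mut]] != "*" && gc[[mut]] == gc[[codon]]) s <- s + 1 / 3
  }
  s
}

random_sense_codons <- function(n) {
  ct <- wrkyfamkit:::codon_tables()
  sample(ct$codons, n, replace = TRUE)
}
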
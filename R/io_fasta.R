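#' Read a FASTA file
#'
#' Reads protein or nucleotide FASTA into a named character vector of
#' upper-case sequences. Wrapped lines are concatenated and whitespace is
#' stripped.
#'
#' @param path Path to a FASTA file.
#' @param alphabet One of `"auto"`, `"AA"`, `"DNA"`. With `"auto"` the
#'   alphabet is guessed from residue composition.
#' @return Named character vector of sequences with attribute `alphabet`.
#'   Duplicate ids or an empty file are errors.
#' @export
read_fasta <- function(path, alphabet = c("auto", "AA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop2("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop2("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop2("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  names(seqs) <- ids
  if (identical(alphabet, "auto")) {
    acgt <- sum(vapply(seqs, function(s) {
      sum(chars(s) %in% c("A", "C", "G", "T", "U", "N"))
    }, numeric(1)))
    alphabet <- if (acgt / max(1, sum(nchar(seqs))) > 0.9) "DNA" else "AA"
  }
  attr(seqs, "alphabet") <- alphabet
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    cat(">", names(seqs)[i], "\n", sep = "", file = con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Keep the longest sequence per locus
#'
#' Collapses isoforms so each locus contributes a single (the longest)
#' sequence; ties are broken by the lexicographically smallest sequence id.
#'
#' @param records Named character vector of sequences.
#' @param locus_map Named character vector mapping every record id to a locus.
#' @return Subset of `records`, one per locus, in order of first appearance
#'   of each locus.
#' @export
select_longest_per_locus <- function(records, locus_map) {
  ids <- names(records)
  missing <- setdiff(ids, names(locus_map))
  if (length(missing)) {
    stop2("record(s) missing from locus_map: ", paste(missing, collapse = ", "))
  }
  loci <- unname(locus_map[ids])
  keep <- vapply(unique(loci), function(l) {
    cand <- ids[loci == l]
    cand <- cand[order(-nchar(records[cand]), cand)]
    cand[1L]
  }, character(1))
  records[keep]
}
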
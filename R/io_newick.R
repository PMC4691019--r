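#' Read / write Newick trees
#'
#' Thin validated wrappers around [ape::read.tree()] and
#' [ape::write.tree()]. Topology, tip labels, branch lengths and internal
#' node (support) labels round-trip.
#'
#' @param path Path to a Newick file.
#' @return `read_newick` returns an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop2("Newick file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  for (i in seq_len(nchar(txt))) {
    ch <- substr(txt, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth < 0L) stop2("malformed Newick: unmatched ')' at position ", i)
  }
  if (depth != 0L) stop2("malformed Newick: ", depth, " unclosed '(' at end of input")
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop2("malformed Newick: ", conditionMessage(e)))
  if (is.null(tr)) stop2("malformed Newick: could not parse tree")
  tr
}

#' @param tree An [ape::phylo] object.
#' @rdname read_newick
#' @return `write_newick` returns `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}
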
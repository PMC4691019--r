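#' Gene model
#'
#' Container for one protein-coding gene locus. Coordinates are held
#' internally as 0-based half-open intervals; [read_gff3()] and
#' [write_gff3()] convert from/to the 1-based inclusive convention of GFF3
#' at the boundary.
#'
#' @param gene_id Gene identifier.
#' @param chromosome Chromosome / scaffold name.
#' @param start,end 0-based half-open gene span.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (`start`, `end`), 0-based half-open,
#'   sorted in genomic order and non-overlapping.
#' @param cds Three-column matrix (`start`, `end`, `frame`), genomic order.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chromosome, start, end, strand = "+",
                       exons = NULL, cds = NULL) {
  if (is.null(exons)) exons <- cbind(start = start, end = end)
  exons <- as.matrix(exons)[, 1:2, drop = FALSE]
  colnames(exons) <- c("start", "end")
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (is.null(cds)) {
    cds <- cbind(exons, frame = cds_frames(exons, strand))
  } else {
    cds <- as.matrix(cds)
    if (ncol(cds) == 2L) cds <- cbind(cds, cds_frames(cds, strand))
    colnames(cds) <- c("start", "end", "frame")
    cds <- cds[order(cds[, 1]), , drop = FALSE]
  }
  if (start > end) stop2("gene ", gene_id, ": start > end")
  if (!strand %in% c("+", "-")) stop2("gene ", gene_id, ": bad strand")
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
    stop2("gene ", gene_id, ": overlapping exons")
  }
  structure(list(gene_id = gene_id, chromosome = chromosome,
                 start = start, end = end, strand = strand,
                 exons = exons, cds = cds),
            class = "gene_model")
}

# GFF3-style frame (phase) per CDS segment in genomic order
cds_frames <- function(cds, strand) {
  lens <- cds[, 2] - cds[, 1]
  tx <- if (identical(strand, "-")) rev(seq_len(nrow(cds))) else seq_len(nrow(cds))
  up <- cumsum(c(0, lens[tx][-length(tx)]))
  frames <- integer(nrow(cds))
  frames[tx] <- (3 - up %% 3) %% 3
  frames
}

#' Total CDS length (nt) of a gene model
#' @param gm A [gene_model()].
#' @return Integer number of coding nucleotides.
#' @export
cds_length <- function(gm) sum(gm$cds[, 2] - gm$cds[, 1])

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s), %d exon(s), CDS %d nt\n",
              x$gene_id, x$chromosome, x$start, x$end, x$strand,
              nrow(x$exons), cds_length(x)))
  invisible(x)
}

#' Genome annotation
#'
#' Orders gene models per chromosome and assigns each gene its 0-based rank
#' (position among all genes on its chromosome, by start coordinate,
#' strand-ignored). Gene rank is the coordinate system used by the tandem
#' and microsynteny rules.
#'
#' @param genes List of [gene_model()] objects.
#' @return Object of class `genome_annotation` with elements `genes` (named
#'   list), `chromosomes` (named list of ordered gene-id vectors) and `rank`
#'   (named integer vector, 0-based).
#' @export
genome_annotation <- function(genes) {
  ids <- vapply(genes, `[[`, character(1), "gene_id")
  if (anyDuplicated(ids)) stop2("duplicate gene ids in annotation")
  names(genes) <- ids
  chrom <- vapply(genes, `[[`, character(1), "chromosome")
  starts <- vapply(genes, `[[`, numeric(1), "start")
  chromosomes <- lapply(split(seq_along(genes), chrom), function(i) {
    ids[i][order(starts[i], ids[i])]
  })
  rank <- unlist(lapply(chromosomes, function(g) {
    setNames(seq_along(g) - 1L, g)
  }), use.names = TRUE)
  names(rank) <- unlist(chromosomes, use.names = FALSE)
  structure(list(genes = genes, chromosomes = chromosomes, rank = rank),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d genes on %d sequence(s)\n",
              length(x$genes), length(x$chromosomes)))
  invisible(x)
}

#' Gene rank lookup
#' @param annotation A [genome_annotation()].
#' @param ids Gene ids.
#' @return Integer 0-based ranks.
#' @export
gene_rank <- function(annotation, ids) {
  bad <- setdiff(ids, names(annotation$rank))
  if (length(bad)) stop2("unknown gene id(s): ", paste(bad, collapse = ", "))
  annotation$rank[ids]
}

#' Read a GFF3 annotation
#'
#' Imports gene/mRNA/exon/CDS features and builds one [gene_model()] per
#' gene. When a gene carries several mRNAs, the mRNA with the longest total
#' CDS is used (longest-isoform rule). A CDS or exon whose Parent is not a
#' known mRNA, or overlapping exons within one mRNA, are errors.
#'
#' @param path Path to a GFF3 file.
#' @return A [genome_annotation()].
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop2("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  df$ID <- as.character(df$ID)
  df$parent <- if (is.null(df$Parent)) {
    rep(NA_character_, nrow(df))
  } else {
    vapply(as.list(df$Parent), function(p) {
      if (length(p)) as.character(p[[1]]) else NA_character_
    }, character(1))
  }
  genes_df <- df[df$type == "gene", , drop = FALSE]
  mrna_df <- df[df$type == "mRNA", , drop = FALSE]
  sub_df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  orphan <- setdiff(sub_df$parent, mrna_df$ID)
  if (length(orphan)) {
    stop2("exon/CDS feature(s) with unresolvable mRNA parent: ",
          paste(stats::na.omit(orphan), collapse = ", "))
  }
  mrna_by_gene <- split(mrna_df$ID, mrna_df$parent)
  exon_by_mrna <- split(sub_df[sub_df$type == "exon", , drop = FALSE],
                        sub_df$parent[sub_df$type == "exon"])
  cds_by_mrna <- split(sub_df[sub_df$type == "CDS", , drop = FALSE],
                       sub_df$parent[sub_df$type == "CDS"])
  empty_sub <- sub_df[0, , drop = FALSE]
  genes <- lapply(seq_len(nrow(genes_df)), function(i) {
    g <- genes_df[i, ]
    mr_ids <- mrna_by_gene[[g$ID]]
    if (is.null(mr_ids)) {
      return(gene_model(g$ID, as.character(g$seqnames), g$start - 1L, g$end,
                        as.character(g$strand)))
    }
    cds_len <- vapply(mr_ids, function(m) {
      cc <- cds_by_mrna[[m]]
      if (is.null(cc)) 0 else sum(cc$end - cc$start + 1L)
    }, numeric(1))
    pick <- mr_ids[order(-cds_len, mr_ids)][1L]
    ex <- exon_by_mrna[[pick]] %||% empty_sub
    cc <- cds_by_mrna[[pick]] %||% empty_sub
    if (nrow(cc) == 0L) cc <- ex
    if (nrow(ex) == 0L) ex <- cc
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)])) {
      stop2("overlapping exons in mRNA ", pick)
    }
    phase <- suppressWarnings(as.integer(as.character(cc$phase)))
    cds <- cbind(start = cc$start - 1L, end = cc$end, frame = phase)
    cds <- cds[order(cds[, 1]), , drop = FALSE]
    if (anyNA(cds[, 3])) cds[, 3] <- cds_frames(cds, as.character(g$strand))
    gene_model(g$ID, as.character(g$seqnames), g$start - 1L, g$end,
               as.character(g$strand),
               exons = cbind(start = ex$start - 1L, end = ex$end),
               cds = cds)
  })
  genome_annotation(genes)
}

#' Write a genome annotation to GFF3
#'
#' @param annotation A [genome_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  rows <- lapply(annotation$genes, function(gm) {
    mrna_id <- paste0(gm$gene_id, ".t1")
    n_ex <- nrow(gm$exons)
    n_cds <- nrow(gm$cds)
    data.frame(
      seqid = gm$chromosome,
      source = "wrkyfamkit",
      type = c("gene", "mRNA", rep("exon", n_ex), rep("CDS", n_cds)),
      start = c(gm$start + 1L, gm$start + 1L, gm$exons[, 1] + 1L, gm$cds[, 1] + 1L),
      end = c(gm$end, gm$end, gm$exons[, 2], gm$cds[, 2]),
      score = ".",
      strand = gm$strand,
      phase = c(".", ".", rep(".", n_ex), as.character(gm$cds[, 3])),
      attributes = c(
        paste0("ID=", gm$gene_id),
        paste0("ID=", mrna_id, ";Parent=", gm$gene_id),
        paste0("ID=", mrna_id, ".exon", seq_len(n_ex), ";Parent=", mrna_id),
        paste0("ID=", mrna_id, ".cds", seq_len(n_cds), ";Parent=", mrna_id)
      ),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
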
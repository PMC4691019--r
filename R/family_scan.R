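#' Locate WRKY domains in a protein sequence
#'
#' Scans a protein for the WRKY heptapeptide (exact `WRKYGQK` by default;
#' variants such as `WRKYGKK` may be added) and, downstream of each
#' occurrence, for a zinc-finger motif of type C2H2
#' (`C-X4/5-C-X22/23-H-X-H`) or C2HC (`C-X7-C-X23-H-X-C`). The first
#' cysteine of the finger must start within `max_finger_offset` residues of
#' the heptapeptide end and the whole domain must span at most
#' `max_domain_span` residues. Candidate first cysteines are tried 5' to 3';
#' at a given cysteine the more constrained C2H2 spacing wins over C2HC.
#'
#' @param protein Protein sequence (single string) or a length-1 named
#'   character vector.
#' @param id Sequence id used in the output (defaults to the name of
#'   `protein`).
#' @param heptapeptides Character vector of accepted heptapeptide variants.
#' @param max_finger_offset Residues allowed between heptapeptide end and
#'   the first finger cysteine.
#' @param max_domain_span Cap on heptapeptide-start to finger-end span.
#' @return data.frame with one row per heptapeptide hit: `protein_id`,
#'   `hept_start` (0-based), `heptapeptide`, `finger_type` (`"C2H2"`,
#'   `"C2HC"` or `"none"`), finger residue offsets `c1,c2,h1,h2` (0-based;
#'   `h2` is the final His/Cys), spacers `x1,x2`, and `domain_end`
#'   (0-based exclusive end of the domain). Empty data.frame when there is
#'   no hit.
#' @export
find_wrky_domains <- function(protein, id = NULL,
                              heptapeptides = "WRKYGQK",
                              max_finger_offset = 30L,
                              max_domain_span = 120L) {
  if (is.null(id)) id <- names(protein) %||% "protein"
  seq <- toupper(as.character(protein)[[1]])
  cc <- chars(seq)
  n <- length(cc)
  starts <- sort(unique(unlist(lapply(heptapeptides, function(p) {
    m <- gregexpr(p, seq, fixed = TRUE)[[1]]
    if (m[1] == -1L) integer() else as.integer(m) - 1L
  }))))
  # drop heptapeptide matches overlapping an earlier one
  if (length(starts) > 1L) {
    keep <- starts[1]
    for (s in starts[-1]) if (s >= keep[length(keep)] + 7L) keep <- c(keep, s)
    starts <- keep
  }
  rows <- lapply(starts, function(s0) {
    hept <- substr(seq, s0 + 1L, s0 + 7L)
    hend <- s0 + 7L                      # 0-based exclusive heptapeptide end
    hit <- NULL
    for (c1 in seq(hend, min(hend + max_finger_offset - 1L, n - 1L))) {
      if (cc[c1 + 1L] != "C") next
      # C2H2: C x1 C x2 H X H, x1 in {4,5}, x2 in {22,23}
      for (x1 in c(4L, 5L)) {
        c2 <- c1 + x1 + 1L
        if (c2 + 1L > n || cc[c2 + 1L] != "C") next
        for (x2 in c(22L, 23L)) {
          h1 <- c2 + x2 + 1L
          h2 <- h1 + 2L
          if (h2 + 1L > n) next
          if (cc[h1 + 1L] == "H" && cc[h2 + 1L] == "H" &&
              (h2 - s0 + 1L) <= max_domain_span) {
            hit <- list(type = "C2H2", c1 = c1, c2 = c2, h1 = h1, h2 = h2,
                        x1 = x1, x2 = x2)
            break
          }
        }
        if (!is.null(hit)) break
      }
      if (is.null(hit)) {
        # C2HC: C x7 C x23 H X C
        c2 <- c1 + 8L; h1 <- c2 + 24L; h2 <- h1 + 2L
        if (h2 + 1L <= n && cc[c2 + 1L] == "C" && cc[h1 + 1L] == "H" &&
            cc[h2 + 1L] == "C" && (h2 - s0 + 1L) <= max_domain_span) {
          hit <- list(type = "C2HC", c1 = c1, c2 = c2, h1 = h1, h2 = h2,
                      x1 = 7L, x2 = 23L)
        }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) {
      data.frame(protein_id = id, hept_start = s0, heptapeptide = hept,
                 finger_type = "none", c1 = NA_integer_, c2 = NA_integer_,
                 h1 = NA_integer_, h2 = NA_integer_, x1 = NA_integer_,
                 x2 = NA_integer_, domain_end = hend,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(protein_id = id, hept_start = s0, heptapeptide = hept,
                 finger_type = hit$type, c1 = hit$c1, c2 = hit$c2,
                 h1 = hit$h1, h2 = hit$h2, x1 = hit$x1, x2 = hit$x2,
                 domain_end = hit$h2 + 1L, stringsAsFactors = FALSE)
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(), hept_start = integer(),
               heptapeptide = character(), finger_type = character(),
               c1 = integer(), c2 = integer(), h1 = integer(), h2 = integer(),
               x1 = integer(), x2 = integer(), domain_end = integer(),
               stringsAsFactors = FALSE)
  out[order(out$hept_start), , drop = FALSE]
}

#' Classify a protein into WRKY groups 1/2/3 from its domain hits
#'
#' Two or more complete domains (heptapeptide plus zinc finger) define
#' Group 1; a single complete C2H2 domain Group 2; a single C2HC domain
#' Group 3; anything else is unclassified. The label is a pure function of
#' the hit multiset.
#'
#' @param hits data.frame from [find_wrky_domains()].
#' @return `"1"`, `"2"`, `"3"` or `"unclassified"`.
#' @export
classify_group <- function(hits) {
  complete <- hits[hits$finger_type %in% c("C2H2", "C2HC"), , drop = FALSE]
  if (nrow(complete) >= 2L) return("1")
  if (nrow(complete) == 1L) {
    return(if (complete$finger_type == "C2HC") "3" else "2")
  }
  "unclassified"
}

#' Scan a proteome for WRKY family members
#'
#' @param proteins Named character vector of protein sequences.
#' @param ... Passed to [find_wrky_domains()].
#' @return list with `members` (data.frame: `id`, `n_domains`,
#'   `finger_type` of the last complete domain, `group`) restricted to
#'   classified family members, and `hits` (all domain hits).
#' @export
scan_proteome <- function(proteins, ...) {
  hits <- lapply(names(proteins), function(id) {
    find_wrky_domains(proteins[[id]], id = id, ...)
  })
  hits <- do.call(rbind, hits)
  ids <- unique(hits$protein_id)
  members <- do.call(rbind, lapply(ids, function(id) {
    h <- hits[hits$protein_id == id, , drop = FALSE]
    grp <- classify_group(h)
    cm <- h[h$finger_type != "none", , drop = FALSE]
    data.frame(id = id,
               n_domains = nrow(cm),
               finger_type = if (nrow(cm)) cm$finger_type[nrow(cm)] else "none",
               group = grp, stringsAsFactors = FALSE)
  }))
  if (is.null(members)) {
    members <- data.frame(id = character(), n_domains = integer(),
                          finger_type = character(), group = character(),
                          stringsAsFactors = FALSE)
  }
  list(members = members[members$group != "unclassified", , drop = FALSE],
       hits = hits)
}

#' Assign a Group-2 subgroup (or Group-1 override) from tree position
#'
#' The subgroup of a single-domain member is that of its nearest labeled
#' reference by patristic distance in the domain tree. Distance ties are
#' broken by the smaller clade containing the member and the reference,
#' then by reference id. A member whose nearest references are the
#' C-terminal domains of Group-1 proteins (label `"1"`) is re-labeled
#' Group 1, covering single-domain proteins that lost (or were
#' mis-annotated at) their N-terminal domain.
#'
#' @param member_id Tip label of the member to classify.
#' @param tree [ape::phylo] containing `member_id` and the references.
#' @param reference_labels Named character vector: tip label -> subgroup
#'   label (`"2a"`..`"2e"`, `"3"`, or `"1"` for Group-1 CTWD references).
#' @return list(`subgroup`, `group`) where `group` is `"1"` when the
#'   Group-1 override fires, otherwise the group implied by the subgroup.
#' @export
assign_subgroup <- function(member_id, tree, reference_labels) {
  refs <- intersect(names(reference_labels), tree$tip.label)
  refs <- setdiff(refs, member_id)
  if (!length(refs)) stop2("no labeled references present in the tree")
  if (!member_id %in% tree$tip.label) stop2("member not in tree: ", member_id)
  dm <- ape::cophenetic.phylo(tree)
  d <- dm[member_id, refs]
  best <- refs[d <= min(d) + 1e-12]
  if (length(best) > 1L) {
    csize <- vapply(best, function(r) {
      mrca <- ape::getMRCA(tree, c(member_id, r))
      length(ape::extract.clade(tree, mrca)$tip.label)
    }, numeric(1))
    best <- best[order(csize, best)]
  }
  lab <- unname(reference_labels[[best[1L]]])
  if (identical(lab, "1")) {
    list(subgroup = "none", group = "1")
  } else {
    list(subgroup = lab, group = substr(lab, 1, 1))
  }
}

#' Map WRKY domain coordinates onto a gene model
#'
#' Converts the protein offsets of each domain hit into CDS nucleotide
#' coordinates (`offset * 3`), locates introns (gaps between CDS segments
#' in transcription order) inside the domain interval, and reports their
#' phases (`phase = upstream coding nucleotides mod 3`).
#'
#' @param hits data.frame from [find_wrky_domains()] for this protein.
#' @param gm [gene_model()] whose CDS encodes the protein.
#' @param protein_length Protein length in residues, used to validate the
#'   CDS (which may or may not include the stop codon).
#' @return list(`gene_id`, `domain_introns` integer per hit,
#'   `domain_phases` list of integer vectors per hit, `total_introns`,
#'   `intron_phases` all CDS intron phases in transcription order).
#' @export
map_domain_gene_structure <- function(hits, gm, protein_length) {
  clen <- cds_length(gm)
  if (clen != 3L * protein_length && clen != 3L * (protein_length + 1L)) {
    stop2("gene ", gm$gene_id, ": CDS length ", clen,
          " does not match protein length ", protein_length)
  }
  segs <- gm$cds[, 1:2, drop = FALSE]
  ord <- if (gm$strand == "-") rev(seq_len(nrow(segs))) else seq_len(nrow(segs))
  segs <- segs[ord, , drop = FALSE]
  lens <- segs[, 2] - segs[, 1]
  # upstream coding nt at each intron (between consecutive segments)
  up <- if (nrow(segs) > 1L) cumsum(lens)[-nrow(segs)] else numeric(0)
  phases <- as.integer(up %% 3)
  domain_introns <- integer(nrow(hits))
  domain_phases <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    a <- hits$hept_start[i] * 3L
    b <- hits$domain_end[i] * 3L
    inside <- up > a & up < b
    domain_introns[i] <- sum(inside)
    domain_phases[[i]] <- phases[inside]
  }
  list(gene_id = gm$gene_id,
       domain_introns = domain_introns,
       domain_phases = domain_phases,
       total_introns = length(up),
       intron_phases = phases)
}
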
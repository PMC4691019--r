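#' Pipeline configuration
#'
#' Collects inputs and stage parameters for [run_full_analysis()], with the
#' published defaults: tandem rule 10 genes, microsynteny window 50 /
#' minimum 3 pairs / E-value cutoff 0.01 / tandem gap 2, 1000 bootstrap
#' replicates, two-fold expression threshold, chi-square test with one
#' degree of freedom. Inputs may be file paths (FASTA/GFF3/TSV) or the
#' corresponding in-memory objects.
#'
#' @param proteins Protein FASTA path or named character vector.
#' @param gff GFF3 path or a [genome_annotation()].
#' @param cds Optional CDS FASTA path or named vector (enables block Ks).
#' @param homology Optional homology-pair TSV (columns `a`, `b`) or
#'   data.frame; defaults to same-group family pairs inferred from the scan.
#' @param references Optional reference-label TSV (columns `id`, `label`)
#'   or data.frame for tree-based subgroup assignment.
#' @param expression Optional RPKM matrix (TSV path or matrix).
#' @param control Control condition column name.
#' @param codon_alignment,codon_tree,foreground Optional inputs for the
#'   branch-site selection stage.
#' @param proteome_b Optional second proteome for orthology.
#' @param max_gene_distance,window,min_pairs,evalue,tandem_gap,bootstrap,fold_threshold,pseudocount,distance_model,cluster_metric
#'   Stage parameters (see the stage functions).
#' @param seed Master seed; all stage randomness derives from it.
#' @param out_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(proteins, gff, cds = NULL, homology = NULL,
                            references = NULL, expression = NULL,
                            control = "D0", codon_alignment = NULL,
                            codon_tree = NULL, foreground = NULL,
                            proteome_b = NULL, max_gene_distance = 10L,
                            window = 50L, min_pairs = 3L, evalue = 0.01,
                            tandem_gap = 2L, bootstrap = 1000L,
                            fold_threshold = 2, pseudocount = 1,
                            distance_model = "poisson",
                            cluster_metric = "euclidean", seed = 1L,
                            out_dir = tempfile("wrkyfamkit_")) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop2("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (!all(c("proteins", "gff") %in% names(vals))) {
    stop2("config must provide 'proteins' and 'gff'")
  }
  do.call(pipeline_config, vals)
}

load_seqs <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) read_fasta(x) else x
}
load_tsv <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    utils::read.delim(x, stringsAsFactors = FALSE)
  } else x
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop2("stage '", name, "' failed: ", conditionMessage(e))
  })
}

# domain-level rows for the family tree: Group-1 proteins contribute their
# N- and C-terminal domains separately
domain_rows <- function(proteins, members, hits) {
  rows <- character(0)
  for (i in seq_len(nrow(members))) {
    id <- members$id[i]
    h <- hits[hits$protein_id == id & hits$finger_type != "none", , drop = FALSE]
    if (nrow(h) == 0L) next
    dom <- substring(proteins[[id]], h$hept_start + 1L, h$domain_end)
    if (nrow(h) >= 2L) {
      rows[paste0(id, "-NTWD")] <- dom[1]
      rows[paste0(id, "-CTWD")] <- dom[nrow(h)]
    } else {
      rows[id] <- dom
    }
  }
  rows
}

#' Run the full family analysis
#'
#' Orchestrates scan, domain tree (with optional bootstrap), tree-based
#' subgroup assignment, tandem and microsynteny duplication detection,
#' duplication-type classification, block Ks summaries, the optional
#' branch-site selection test, expression classification and clustering,
#' and optional orthology, writing stage TSV outputs plus a `summary.json`
#' to the output directory. Deterministic under a fixed seed; a stage
#' failure aborts with the stage name.
#'
#' @param config A [pipeline_config()], or a YAML path.
#' @return Invisibly, list(`summary`, `results`, `out_dir`).
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = config$seed)
  results <- list()

  proteins <- run_stage("scan", load_seqs(config$proteins))
  scan <- run_stage("scan", scan_proteome(proteins))
  members <- scan$members
  members$subgroup <- "none"

  tree <- NULL
  if (nrow(members) >= 4L) {
    rows <- run_stage("tree", domain_rows(proteins, members, scan$hits))
    tree <- run_stage("tree", {
      if (config$bootstrap > 0L) {
        bootstrap_support(progressive_align(rows),
                          n_replicates = config$bootstrap,
                          seed = derive_seed(config$seed, 1L),
                          model = config$distance_model)
      } else {
        nj_tree(distance_matrix(progressive_align(rows),
                                model = config$distance_model))
      }
    })
    write_newick(tree, file.path(config$out_dir, "domain_tree.nwk"))
  }

  refs <- load_tsv(config$references)
  if (!is.null(refs) && !is.null(tree)) {
    run_stage("subgroups", {
      ref_labels <- setNames(refs$label, refs$id)
      ctwd <- paste0(names(ref_labels), "-CTWD")
      has_ctwd <- ctwd %in% tree$tip.label
      names(ref_labels)[has_ctwd] <- ctwd[has_ctwd]
      own <- setNames(refs$label, refs$id)
      for (i in seq_len(nrow(members))) {
        if (members$group[i] != "2") next
        id <- members$id[i]
        if (id %in% names(own)) {     # labeled references keep their label
          if (own[[id]] != "1") members$subgroup[i] <- own[[id]]
          next
        }
        if (!id %in% tree$tip.label) next
        res <- assign_subgroup(id, tree, ref_labels)
        members$group[i] <- res$group
        members$subgroup[i] <- res$subgroup
      }
      invisible(NULL)
    })
  }
  results$members <- members
  utils::write.table(members, file.path(config$out_dir, "members.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$n_family <- nrow(members)
  summary$n_group1 <- sum(members$group == "1")
  summary$n_group2 <- sum(members$group == "2")
  summary$n_group3 <- sum(members$group == "3")
  summary$subgroup_counts <- as.list(table(members$subgroup[members$group == "2"]))

  annotation <- run_stage("duplication", {
    if (inherits(config$gff, "genome_annotation")) config$gff else read_gff3(config$gff)
  })
  fam_ids <- intersect(members$id, names(annotation$genes))
  clusters <- run_stage("duplication", find_tandem_clusters(
    annotation, fam_ids, max_gene_distance = config$max_gene_distance))
  results$tandem <- clusters
  utils::write.table(clusters, file.path(config$out_dir, "tandem_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$n_tandem_clusters <- length(unique(clusters$cluster_id))
  summary$n_tandem_genes <- length(unique(clusters$gene_id))

  homology <- load_tsv(config$homology)
  if (is.null(homology)) {
    grp <- split(fam_ids, members$group[match(fam_ids, members$id)])
    homology <- do.call(rbind, lapply(grp, function(g) {
      if (length(g) < 2L) return(NULL)
      cp <- utils::combn(sort(g), 2L)
      data.frame(a = cp[1, ], b = cp[2, ], stringsAsFactors = FALSE)
    }))
  }
  blocks <- run_stage("duplication", find_synteny_blocks(
    annotation, fam_ids, homology, window = config$window,
    min_pairs = config$min_pairs, evalue_cutoff = config$evalue,
    tandem_gap = config$tandem_gap))
  anchor_sets <- attr(blocks, "anchor_pairs")
  cds <- load_seqs(config$cds)
  if (!is.null(cds) && nrow(blocks)) {
    ks <- lapply(anchor_sets, summarize_block_ks, cds_lookup = cds)
    blocks$mean_ks <- vapply(ks, `[[`, numeric(1), "mean_ks")
    blocks$sd_ks <- vapply(ks, `[[`, numeric(1), "sd_ks")
  }
  results$blocks <- blocks
  utils::write.table(blocks, file.path(config$out_dir, "synteny_blocks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$n_synteny_blocks <- nrow(blocks)
  summary$n_segmental_genes <- length(unique(c(blocks$gene_a, blocks$gene_b)))

  types <- run_stage("duplication", classify_duplication_types(
    annotation, fam_ids, homology, blocks, clusters,
    proximal_distance = config$max_gene_distance))
  results$duplication_types <- types
  utils::write.table(types, file.path(config$out_dir, "duplication_types.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$duplication_type_counts <- as.list(table(types$class))

  if (!is.null(config$codon_alignment) && !is.null(config$foreground)) {
    sel <- run_stage("selection", {
      aln <- load_seqs(config$codon_alignment)
      tr <- if (is.character(config$codon_tree)) read_newick(config$codon_tree)
            else config$codon_tree
      branch_site_test(aln, tr, config$foreground)
    })
    results$selection <- sel
    summary$lrt_statistic <- sel$lrt$statistic
    summary$lrt_p_value <- sel$lrt$p_value
    summary$omega2_hat <- sel$alternative$w2
  }

  if (!is.null(config$expression)) {
    expr_res <- run_stage("expression", {
      mat <- config$expression
      if (is.character(mat) && length(mat) == 1L) {
        mat <- as.matrix(utils::read.delim(mat, row.names = 1L, check.names = FALSE))
      }
      lr <- log2_ratio_matrix(mat, config$control, pseudocount = config$pseudocount)
      calls <- fold_change_classify(lr, threshold = config$fold_threshold,
                                    control = config$control)
      cl <- hierarchical_cluster(lr, metric = config$cluster_metric)
      list(calls = calls, leaf_order = cl$order)
    })
    results$expression_calls <- expr_res$calls
    utils::write.table(expr_res$calls,
                       file.path(config$out_dir, "expression_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(expr_res$leaf_order,
               file.path(config$out_dir, "expression_leaf_order.txt"))
    s <- attr(expr_res$calls, "summary")
    summary$n_up_regulated <- unname(s[["up"]])
    summary$n_down_regulated <- unname(s[["down"]])
    summary$n_unresponsive <- unname(s[["unresponsive"]])
  }

  if (!is.null(config$proteome_b)) {
    ortho <- run_stage("orthology", {
      build_ortholog_groups(pairwise_similarity(proteins,
                                                load_seqs(config$proteome_b)))
    })
    results$orthologs <- ortho
    utils::write.table(ortho, file.path(config$out_dir, "ortholog_groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$n_ortholog_groups <- length(unique(ortho$group))
  }

  summary <- summary[order(names(summary))]
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(summary = summary, results = results, out_dir = config$out_dir))
}
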
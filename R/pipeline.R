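# Pipeline orchestration: differential expression per modality / dataset
# / subtype, cross-dataset and cross-subtype intersection, sponge-pair
# matching, axis assembly, top-k target selection, pan-flute filtering,
# fold-change shortlisting, PPI hub detection, module counting,
# enrichment of hub genes, survival filtering and a machine-readable run
# report of the filtering funnel.

#' Pipeline run configuration
#'
#' Thresholds and knobs for [run_pipeline()].  Defaults encode the
#' study's conventions: circRNA differential expression at raw p < 0.05
#' with |log2FC| >= 1; miRNA/mRNA at BH FDR < 0.01 with |log2FC| >= 1;
#' a fold-change shortlist at |log2FC| >= 2 on the basal-like contrast;
#' top 10 target genes per miRNA; tau-tolerant monotone pan-flute trend;
#' PPI edges retained at combined score > 0.4; 10 hub genes; enrichment
#' and survival significance at 0.05.
#'
#' @param circ_thresholds,mir_thresholds,mrna_thresholds
#'   [de_thresholds()] per modality.
#' @param shortlist_lfc Minimum |log2FC| (basal-like contrast) for the
#'   final miRNA/gene shortlist; for miRNAs both datasets must pass.
#' @param top_k Targets retained per miRNA.
#' @param pan_flute_mode,pan_flute_tau Mode and tolerance of
#'   [pan_flute_filter()].
#' @param ppi_threshold Strict score threshold of [load_ppi()].
#' @param n_hubs Hub genes selected by BottleNeck centrality.
#' @param enrich_fdr FDR cut-off of [hypergeom_enrich()].
#' @param survival_alpha Log-rank significance level of the survival
#'   filter.
#' @param survival_filter Apply the survival filter to the final axis
#'   table (`TRUE`) or only annotate (`FALSE`).
#' @param seed Stored in the report fingerprint (the pipeline itself is
#'   deterministic).
#' @return Object of class `run_config`.
#' @export
run_config <- function(circ_thresholds = de_thresholds(1, 0.05, use_fdr = FALSE),
                       mir_thresholds = de_thresholds(1, 0.01, use_fdr = TRUE),
                       mrna_thresholds = de_thresholds(1, 0.01, use_fdr = TRUE),
                       shortlist_lfc = 2,
                       top_k = 10L,
                       pan_flute_mode = "monotone",
                       pan_flute_tau = 0.2,
                       ppi_threshold = 0.4,
                       n_hubs = 10L,
                       enrich_fdr = 0.05,
                       survival_alpha = 0.05,
                       survival_filter = TRUE,
                       seed = 1L) {
  stopifnot(inherits(circ_thresholds, "de_thresholds"),
            inherits(mir_thresholds, "de_thresholds"),
            inherits(mrna_thresholds, "de_thresholds"),
            shortlist_lfc >= 0, top_k >= 1,
            pan_flute_tau >= 0,
            ppi_threshold >= 0, ppi_threshold <= 1,
            n_hubs >= 1,
            enrich_fdr > 0, enrich_fdr < 1,
            survival_alpha > 0, survival_alpha < 1)
  structure(list(circ_thresholds = circ_thresholds,
                 mir_thresholds = mir_thresholds,
                 mrna_thresholds = mrna_thresholds,
                 shortlist_lfc = shortlist_lfc,
                 top_k = as.integer(top_k),
                 pan_flute_mode = pan_flute_mode,
                 pan_flute_tau = pan_flute_tau,
                 ppi_threshold = ppi_threshold,
                 n_hubs = as.integer(n_hubs),
                 enrich_fdr = enrich_fdr,
                 survival_alpha = survival_alpha,
                 survival_filter = isTRUE(survival_filter),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat YAML schema: scalar fields of [run_config()] plus nested
#' `circ_thresholds` / `mir_thresholds` / `mrna_thresholds` maps with
#' `lfc_min`, `alpha`, `use_fdr`.
#'
#' @param path Path to a YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (f in c("circ_thresholds", "mir_thresholds", "mrna_thresholds")) {
    if (!is.null(y[[f]])) y[[f]] <- do.call(de_thresholds, y[[f]])
  }
  do.call(run_config, y)
}

#' Assemble pipeline inputs from a simulated cohort
#'
#' Maps the output of [simulate_cohort()] onto the input structure of
#' [run_pipeline()].
#'
#' @param cohort A `cerna_cohort` from [simulate_cohort()].
#' @return List with elements `circ`, `mirna`, `mrna` (each a list of
#'   datasets with `expr` and `meta`), `interactions`, `ppi`,
#'   `survival`.
#' @export
as_pipeline_input <- function(cohort) {
  ds <- cohort$datasets
  pick <- function(mod) {
    lapply(ds, function(d) list(expr = d$expr[[mod]], meta = d$meta))
  }
  list(circ = pick("circRNA"),
       mirna = pick("miRNA"),
       mrna = pick("mRNA"),
       interactions = cohort$interactions[c("circ_mir", "mir_gene")],
       ppi = cohort$ppi,
       survival = cohort$survival,
       gmt = NULL)
}

# tumor-subtype vs control moderated-t contrast on one dataset
subtype_contrast <- function(expr, meta, subtype, label) {
  keep <- meta$group == "control" |
    (!is.na(meta$subtype) & meta$subtype == subtype)
  meta <- meta[keep, , drop = FALSE]
  g <- factor(meta$group, levels = c("control", "tumor"))
  moderated_t(expr[, meta$sample_id, drop = FALSE], g, contrast = label)
}

# all-tumor vs control contrast (circRNA datasets carry no subtype labels)
tumor_contrast <- function(expr, meta, label) {
  g <- factor(meta$group, levels = c("control", "tumor"))
  moderated_t(expr[, meta$sample_id, drop = FALSE], g, contrast = label)
}

#' Run the full ceRNA axis-discovery pipeline
#'
#' Executes, in order: per-dataset circRNA differential expression
#' (tumor vs control) and cross-dataset intersection; per-dataset,
#' per-subtype miRNA differential expression, cross-subtype and
#' cross-dataset intersection; per-subtype mRNA differential expression
#' (first dataset) and cross-subtype intersection; direction-opposite
#' sponge-pair matching against the interaction tables; axis assembly;
#' top-k target selection; pan-flute trend filtering; fold-change
#' shortlisting; PPI loading, BottleNeck hub detection, hub-subnetwork
#' extraction and tripartite module counting; optional enrichment of the
#' hub genes; survival screening of the shortlist genes and, if
#' configured, filtering of the final axis table.
#'
#' The pipeline is deterministic: rerunning with identical inputs and
#' configuration reproduces the report exactly.
#'
#' @param input List as produced by [as_pipeline_input()]: `circ`,
#'   `mirna`, `mrna` dataset lists, `interactions`, optional `ppi`,
#'   `survival`, `gmt` (path or [gene_set_collection()]).
#' @param config A [run_config()].
#' @return Object of class `cerna_report`; see Details.  Key elements:
#'   `counts` (the filtering funnel), `axes` (all assembled axes),
#'   `axes_final` (after all axis-level filters), `hubs`, `subnetwork`,
#'   `modules`, `enrichment`, `survival`, `fingerprint`.
#' @export
run_pipeline <- function(input, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  subtypes <- pam50_subtypes()
  counts <- list()

  ## --- circRNA: tumor vs control per dataset, intersect ---------------
  dec_sets <- lapply(seq_along(input$circ), function(d) {
    ds <- input$circ[[d]]
    tab <- tumor_contrast(ds$expr, ds$meta, sprintf("tumor|circ%d", d))
    filter_de(tab, config$circ_thresholds)
  })
  for (d in seq_along(dec_sets)) {
    counts[[sprintf("dec_up_dataset%d", d)]] <- nrow(dec_sets[[d]]$up)
    counts[[sprintf("dec_down_dataset%d", d)]] <- nrow(dec_sets[[d]]$down)
  }
  shared_dec <- if (length(dec_sets) >= 2L) {
    intersect_de(dec_sets[[1]]$kept, dec_sets[[2]]$kept,
                 require_same_direction = TRUE)
  } else {
    d <- dec_sets[[1]]$kept
    data.frame(feature = d$feature, log2FC_A = d$log2FC,
               log2FC_B = d$log2FC, direction = d$direction,
               stringsAsFactors = FALSE)
  }
  counts$dec_shared <- nrow(shared_dec)

  ## --- miRNA: per dataset, per subtype; intersect ---------------------
  dem_by_dataset <- lapply(seq_along(input$mirna), function(d) {
    ds <- input$mirna[[d]]
    per_sub <- lapply(stats::setNames(subtypes, subtypes), function(s) {
      tab <- subtype_contrast(ds$expr, ds$meta, s,
                              sprintf("%s|mirna%d", s, d))
      filter_de(tab, config$mir_thresholds)$kept
    })
    shared_across_subtypes(per_sub)
  })
  for (d in seq_along(dem_by_dataset)) {
    counts[[sprintf("dem_shared_subtypes_dataset%d", d)]] <-
      nrow(dem_by_dataset[[d]])
  }
  shared_dem <- if (length(dem_by_dataset) >= 2L) {
    intersect_de(
      data.frame(feature = dem_by_dataset[[1]]$feature,
                 log2FC = dem_by_dataset[[1]]$lfc_Basal,
                 direction = dem_by_dataset[[1]]$direction),
      data.frame(feature = dem_by_dataset[[2]]$feature,
                 log2FC = dem_by_dataset[[2]]$lfc_Basal,
                 direction = dem_by_dataset[[2]]$direction),
      require_same_direction = TRUE)
  } else {
    d <- dem_by_dataset[[1]]
    data.frame(feature = d$feature, log2FC_A = d$lfc_Basal,
               log2FC_B = d$lfc_Basal, direction = d$direction,
               stringsAsFactors = FALSE)
  }
  counts$dem_shared <- nrow(shared_dem)

  ## --- mRNA: per subtype on the first dataset -------------------------
  mrna1 <- input$mrna[[1]]
  deg_tables <- lapply(stats::setNames(subtypes, subtypes), function(s) {
    subtype_contrast(mrna1$expr, mrna1$meta, s, sprintf("%s|mrna1", s))
  })
  deg_sets <- lapply(deg_tables, function(tab) {
    filter_de(tab, config$mrna_thresholds)$kept
  })
  shared_deg <- shared_across_subtypes(deg_sets)
  counts$deg_shared <- nrow(shared_deg)

  ## --- sponge-pair matching and axis assembly -------------------------
  circ_for_match <- data.frame(feature = shared_dec$feature,
                               direction = shared_dec$direction)
  mir_for_match <- data.frame(feature = shared_dem$feature,
                              direction = shared_dem$direction)
  gene_for_match <- data.frame(feature = shared_deg$feature,
                               direction = shared_deg$direction)
  cm_pairs <- match_sponge_pairs(circ_for_match, mir_for_match,
                                 input$interactions$circ_mir)
  mg_pairs <- match_sponge_pairs(mir_for_match, gene_for_match,
                                 input$interactions$mir_gene)
  counts$circ_mir_pairs <- nrow(cm_pairs)
  counts$mir_gene_pairs <- nrow(mg_pairs)
  axes <- assemble_axes(cm_pairs, mg_pairs)
  counts$axes <- nrow(axes)
  counts$axis_genes <- length(unique(axes$gene))

  ## --- candidate branch: top-k, pan-flute, shortlist ------------------
  basal_lfc <- stats::setNames(shared_deg$lfc_Basal, shared_deg$feature)
  axes_topk <- top_k_targets(axes, basal_lfc, config$top_k)
  counts$topk_genes <- length(unique(axes_topk$gene))

  prof <- shared_deg[shared_deg$feature %in% axes_topk$gene, , drop = FALSE]
  flute_pass <- if (nrow(prof) > 0L) {
    pan_flute_filter(prof, tau = config$pan_flute_tau,
                     mode = config$pan_flute_mode)
  } else {
    character()
  }
  axes_flute <- axes_topk[axes_topk$gene %in% flute_pass, , drop = FALSE]
  if (nrow(axes_flute) > 0L) {
    axes_flute$provenance <- paste(axes_flute$provenance, "pan_flute",
                                   sep = ";")
  }
  counts$pan_flute_genes <- length(unique(axes_flute$gene))

  mir_short <- shared_dem$feature[
    abs(shared_dem$log2FC_A) >= config$shortlist_lfc &
      abs(shared_dem$log2FC_B) >= config$shortlist_lfc]
  gene_short <- shared_deg$feature[
    abs(shared_deg$lfc_Basal) >= config$shortlist_lfc]
  axes_short <- axes_flute[axes_flute$miRNA %in% mir_short &
                             axes_flute$gene %in% gene_short, ,
                           drop = FALSE]
  if (nrow(axes_short) > 0L) {
    axes_short$provenance <- paste(axes_short$provenance, "shortlist",
                                   sep = ";")
  }
  counts$shortlist_genes <- length(unique(axes_short$gene))

  ## --- hub branch: PPI, BottleNeck, subnetwork, modules ---------------
  hubs <- NULL; subnetwork <- NULL; modules <- NULL; bn_scores <- NULL
  if (!is.null(input$ppi)) {
    g <- load_ppi(input$ppi, score_threshold = config$ppi_threshold)
    keep_nodes <- intersect(igraph::V(g)$name, unique(axes$gene))
    g <- igraph::induced_subgraph(g, keep_nodes)
    g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
    counts$ppi_nodes <- igraph::vcount(g)
    counts$ppi_edges <- igraph::ecount(g)
    if (igraph::vcount(g) > 0L) {
      bn_scores <- bottleneck_centrality(g)
      hubs <- select_hubs(bn_scores, config$n_hubs, g)
      subnetwork <- extract_subnetwork(g, hubs$node, expand = TRUE)
      modules <- count_modules(
        axes[, c("circRNA", "miRNA")],
        axes[, c("miRNA", "gene")],
        restrict_genes = hubs$node)
      counts$hubs <- nrow(hubs)
      counts$modules <- modules$n
    } else {
      counts$hubs <- 0L
      counts$modules <- 0L
    }
  }

  ## --- enrichment of hub genes ----------------------------------------
  enrichment <- NULL
  if (!is.null(input$gmt) && !is.null(hubs) && nrow(hubs) > 0L) {
    coll <- if (inherits(input$gmt, "gene_set_collection")) {
      input$gmt
    } else {
      read_gmt(input$gmt)
    }
    enrichment <- hypergeom_enrich(hubs$node, coll,
                                   fdr_cutoff = config$enrich_fdr)
    counts$enriched_sets <- sum(enrichment$significant)
  }

  ## --- survival screen and final axis table ---------------------------
  surv_tab <- NULL
  axes_final <- axes_short
  if (!is.null(input$survival) && nrow(axes_short) > 0L) {
    surv_tab <- screen_survival(mrna1$expr, input$survival,
                                genes = unique(axes_short$gene),
                                alpha = config$survival_alpha)
    counts$survival_significant_genes <-
      sum(surv_tab$significant, na.rm = TRUE)
    if (config$survival_filter) {
      ok <- surv_tab$gene[surv_tab$significant %in% TRUE]
      axes_final <- axes_short[axes_short$gene %in% ok, , drop = FALSE]
      if (nrow(axes_final) > 0L) {
        axes_final$provenance <- paste(axes_final$provenance, "survival",
                                       sep = ";")
      }
    }
  }
  counts$final_axes <- nrow(axes_final)
  counts$final_genes <- length(unique(axes_final$gene))

  fingerprint <- paste(
    vapply(config[setdiff(names(config), "seed")], function(x) {
      paste(deparse(unclass(x)), collapse = "")
    }, character(1)),
    collapse = "|")

  structure(list(counts = counts,
                 dec = shared_dec,
                 dem = shared_dem,
                 deg = shared_deg,
                 circ_mir_pairs = cm_pairs,
                 mir_gene_pairs = mg_pairs,
                 axes = axes,
                 axes_topk = axes_topk,
                 axes_pan_flute = axes_flute,
                 axes_shortlist = axes_short,
                 axes_final = axes_final,
                 bottleneck_scores = bn_scores,
                 hubs = hubs,
                 subnetwork = subnetwork,
                 modules = modules,
                 enrichment = enrichment,
                 survival = surv_tab,
                 config = config,
                 fingerprint = fingerprint),
            class = "cerna_report")
}

#' @export
print.cerna_report <- function(x, ...) {
  cat("ceRNA axis-discovery run report\n")
  cat("filtering funnel:\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-32s %d\n", nm, x$counts[[nm]]))
  }
  if (nrow(x$axes_final) > 0L) {
    cat("final axes:\n")
    print(x$axes_final[, c("circRNA", "miRNA", "gene",
                           "direction_pattern")], row.names = FALSE)
  }
  invisible(x)
}

#' Write the run report and stage artifacts to disk
#'
#' Emits the funnel counts and configuration fingerprint as JSON and
#' every stage table as TSV.
#'
#' @param report A `cerna_report` from [run_pipeline()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the report path.
#' @export
write_report <- function(report, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  tabs <- c("dec", "dem", "deg", "circ_mir_pairs", "mir_gene_pairs",
            "axes", "axes_final", "hubs", "survival", "enrichment")
  for (nm in tabs) {
    if (!is.null(report[[nm]])) {
      utils::write.table(report[[nm]], file.path(outdir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(report$modules)) {
    utils::write.table(report$modules$modules,
                       file.path(outdir, "modules.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  path <- file.path(outdir, "run_report.json")
  jsonlite::write_json(list(counts = report$counts,
                            fingerprint = report$fingerprint),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Export the tripartite axis network for graph editors
#'
#' Writes the circRNA-miRNA-gene network (plus, optionally, the hub
#' subnetwork roles) as SIF and GraphML with a `type` node attribute
#' (`circRNA`, `miRNA`, `gene` or `hub`), readable by Cytoscape-class
#' tools.
#'
#' @param axes Axis table (from [assemble_axes()] or a report).
#' @param dir Output directory (created if missing).
#' @param subnetwork Optional `hub_subnetwork`; its hub nodes are typed
#'   `hub`.
#' @param name Basename for the two files.
#' @return Invisibly, the paths written (`sif`, `graphml`).
#' @export
export_networks <- function(axes, dir, subnetwork = NULL,
                            name = "cerna_network") {
  if (nrow(axes) == 0L) stop("refusing to export an empty axis network")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hub_nodes <- if (!is.null(subnetwork)) {
    subnetwork$nodes$node[subnetwork$nodes$role == "hub"]
  } else {
    character()
  }
  nodes <- unique(data.frame(
    name = c(axes$circRNA, axes$miRNA, axes$gene),
    type = c(rep("circRNA", nrow(axes)), rep("miRNA", nrow(axes)),
             rep("gene", nrow(axes))),
    stringsAsFactors = FALSE))
  nodes$type[nodes$name %in% hub_nodes] <- "hub"
  edges <- unique(rbind(
    data.frame(from = axes$circRNA, to = axes$miRNA,
               interaction = "sponges", stringsAsFactors = FALSE),
    data.frame(from = axes$miRNA, to = axes$gene,
               interaction = "targets", stringsAsFactors = FALSE)))
  sif_path <- file.path(dir, paste0(name, ".sif"))
  writeLines(paste(edges$from, edges$interaction, edges$to, sep = "\t"),
             sif_path)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes)
  graphml_path <- file.path(dir, paste0(name, ".graphml"))
  igraph::write_graph(g, graphml_path, format = "graphml")
  invisible(c(sif = sif_path, graphml = graphml_path))
}

#' Read an expression TSV (feature column + sample columns)
#'
#' @param path TSV with first column `feature` and one column per sample.
#' @return Numeric matrix with feature rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a sample-metadata TSV
#'
#' @param path TSV with at least `sample_id`, `group`, `subtype`
#'   columns; optional `time`, `event`.
#' @return data.frame.
#' @export
read_metadata_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a two-column interaction TSV
#'
#' @param path TSV with columns `source`, `target`.
#' @return data.frame `source`, `target`.
#' @export
read_interactions_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("source", "target")
  df[, 1:2]
}
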
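# Axis assembly and filtering: cross-dataset/cross-subtype intersection,
# direction-consistent sponge-pair matching, top-k target selection, the
# subtype-trend ("pan-flute") filter and miRNA-mRNA Spearman correlation.

#' Intersect two differential-expression feature sets
#'
#' Features present in both tables, optionally required to carry the same
#' regulation direction, annotated with both log2 fold changes.
#'
#' @param setA,setB `DETable` subsets (data.frames with at least
#'   `feature`, `log2FC`, `direction`).
#' @param require_same_direction If `TRUE` (default) features with
#'   conflicting directions are dropped.
#' @return data.frame with `feature`, `log2FC_A`, `log2FC_B`,
#'   `direction` (of A; equal to B's when direction is required).
#' @export
intersect_de <- function(setA, setB, require_same_direction = TRUE) {
  m <- merge(setA[, c("feature", "log2FC", "direction")],
             setB[, c("feature", "log2FC", "direction")],
             by = "feature", suffixes = c("_A", "_B"))
  if (require_same_direction) {
    m <- m[m$direction_A == m$direction_B, , drop = FALSE]
  }
  out <- data.frame(feature = m$feature,
                    log2FC_A = m$log2FC_A,
                    log2FC_B = m$log2FC_B,
                    direction = m$direction_A,
                    stringsAsFactors = FALSE)
  out[order(out$feature), , drop = FALSE]
}

#' Features shared, with consistent direction, across all five subtypes
#'
#' Intersection of per-subtype differential-expression calls: a feature
#' is kept only if it appears in every subtype's set with the same
#' regulation direction.  Per-subtype log2 fold changes are returned as
#' columns `lfc_<subtype>` in canonical order, forming the subtype-trend
#' profile used downstream by [pan_flute_filter()].
#'
#' @param per_subtype Named list (one entry per PAM50 subtype, see
#'   [pam50_subtypes()]) of `DETable` subsets.
#' @return data.frame with `feature`, `direction` and one `lfc_<subtype>`
#'   column per subtype.
#' @export
shared_across_subtypes <- function(per_subtype) {
  subtypes <- pam50_subtypes()
  missing <- setdiff(subtypes, names(per_subtype))
  if (length(missing) > 0L) {
    stop("missing subtype key(s): ", paste(missing, collapse = ", "))
  }
  feats <- Reduce(intersect, lapply(per_subtype[subtypes], `[[`, "feature"))
  if (length(feats) == 0L) {
    out <- data.frame(feature = character(), direction = character())
    for (s in subtypes) out[[paste0("lfc_", s)]] <- numeric()
    return(out)
  }
  dir_mat <- vapply(subtypes, function(s) {
    t <- per_subtype[[s]]
    t$direction[match(feats, t$feature)]
  }, character(length(feats)))
  dir_mat <- matrix(dir_mat, nrow = length(feats))
  consistent <- apply(dir_mat, 1L, function(d) length(unique(d)) == 1L)
  feats <- feats[consistent]
  out <- data.frame(feature = feats,
                    direction = dir_mat[consistent, 1],
                    stringsAsFactors = FALSE)
  for (s in subtypes) {
    t <- per_subtype[[s]]
    out[[paste0("lfc_", s)]] <- t$log2FC[match(feats, t$feature)]
  }
  out <- out[order(out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match direction-opposite sponge pairs against a knowledge base
#'
#' A source-target pair is kept iff it appears in the interaction table
#' and source and target are regulated in opposite directions (the sponge
#' expectation: targets of up-regulated circRNAs are sought among
#' down-regulated miRNAs, and vice versa; likewise for miRNA targets
#' among genes).
#'
#' @param sources,targets `DETable`-like data.frames with `feature`,
#'   `direction` and a log2FC column (either `log2FC` or `log2FC_A`).
#' @param knowledge data.frame with columns `source`, `target`.
#' @return data.frame `source`, `target`, `source_direction`,
#'   `target_direction`.
#' @export
match_sponge_pairs <- function(sources, targets, knowledge) {
  sdir <- sources$direction[match(knowledge$source, sources$feature)]
  tdir <- targets$direction[match(knowledge$target, targets$feature)]
  keep <- !is.na(sdir) & !is.na(tdir) & sdir != tdir
  out <- data.frame(source = knowledge$source[keep],
                    target = knowledge$target[keep],
                    source_direction = sdir[keep],
                    target_direction = tdir[keep],
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble circRNA-miRNA-mRNA axes from matched sponge pairs
#'
#' Joins circRNA-miRNA and miRNA-gene pairs on the shared miRNA.  Each
#' axis carries a strictly alternating direction pattern (`up-down-up` or
#' `down-up-down`); because both constituent pairs are direction-opposite,
#' circRNA and gene directions agree automatically.  Output order is
#' lexicographic in (circRNA, miRNA, gene).
#'
#' @param circ_mir,mir_gene Pair lists from [match_sponge_pairs()].
#' @return data.frame `circRNA`, `miRNA`, `gene`, `direction_pattern`,
#'   `provenance`.
#' @export
assemble_axes <- function(circ_mir, mir_gene) {
  empty <- data.frame(circRNA = character(), miRNA = character(),
                      gene = character(), direction_pattern = character(),
                      provenance = character(), stringsAsFactors = FALSE)
  if (nrow(circ_mir) == 0L || nrow(mir_gene) == 0L) return(empty)
  m <- merge(
    data.frame(circRNA = circ_mir$source, miRNA = circ_mir$target,
               circ_dir = circ_mir$source_direction,
               stringsAsFactors = FALSE),
    data.frame(miRNA = mir_gene$source, gene = mir_gene$target,
               gene_dir = mir_gene$target_direction,
               stringsAsFactors = FALSE),
    by = "miRNA")
  if (nrow(m) == 0L) return(empty)
  # both pairs are direction-opposite, so circ and gene must agree
  m <- m[m$circ_dir == m$gene_dir, , drop = FALSE]
  out <- data.frame(
    circRNA = m$circRNA,
    miRNA = m$miRNA,
    gene = m$gene,
    direction_pattern = ifelse(m$circ_dir == "up", "up-down-up",
                               "down-up-down"),
    provenance = "matched",
    stringsAsFactors = FALSE)
  out <- out[order(out$circRNA, out$miRNA, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep axes whose gene ranks in the top k targets of its miRNA
#'
#' Per miRNA, genes are ranked by decreasing |log2FC| with ties broken by
#' lexicographic gene id; axes whose gene falls outside the top `k` are
#' dropped.
#'
#' @param axes Axis table from [assemble_axes()].
#' @param gene_lfc Named numeric vector: log2FC per gene id.
#' @param k Number of genes retained per miRNA.
#' @return Filtered axis table with provenance extended by `top_k`.
#' @export
top_k_targets <- function(axes, gene_lfc, k) {
  stopifnot(k >= 1)
  if (nrow(axes) == 0L) return(axes)
  if (!all(axes$gene %in% names(gene_lfc))) {
    stop("every axis gene needs a log2FC value")
  }
  keep <- logical(nrow(axes))
  for (m in unique(axes$miRNA)) {
    idx <- which(axes$miRNA == m)
    genes <- sort(unique(axes$gene[idx]))
    ord <- genes[order(-abs(gene_lfc[genes]), genes)]
    top <- ord[seq_len(min(k, length(ord)))]
    keep[idx] <- axes$gene[idx] %in% top
  }
  out <- axes[keep, , drop = FALSE]
  out$provenance <- paste(out$provenance, "top_k", sep = ";")
  rownames(out) <- NULL
  out
}

#' Pan-flute subtype-trend filter
#'
#' Implements the trend criterion that a feature's |log2FC| should rise
#' across the PAM50 subtypes from normal-like to basal-like like the
#' ascending pipes of a pan flute.  In `monotone` mode a profile passes
#' iff `|lfc|[i+1] >= |lfc|[i] - tau` for every step *and* the maximum
#' |log2FC| is attained strictly at Basal; `peak-at-basal` mode checks
#' only the strict maximum at Basal (equivalently, `monotone` with
#' `tau = Inf`).
#'
#' @param profiles Numeric matrix (features x 5 subtypes, columns in
#'   canonical order) of log2 fold changes, or a data.frame with
#'   `feature` and `lfc_<subtype>` columns as produced by
#'   [shared_across_subtypes()].
#' @param tau Non-negative tolerance for local decreases in `monotone`
#'   mode.
#' @param mode `"monotone"` (default) or `"peak-at-basal"`.
#' @return Character vector of passing feature ids.
#' @export
pan_flute_filter <- function(profiles, tau = 0.2,
                             mode = c("monotone", "peak-at-basal")) {
  mode <- match.arg(mode)
  stopifnot(tau >= 0)
  if (is.data.frame(profiles)) {
    cols <- paste0("lfc_", pam50_subtypes())
    if (!all(cols %in% names(profiles))) {
      stop("profiles data.frame must carry lfc_<subtype> columns")
    }
    mat <- as.matrix(profiles[, cols])
    rownames(mat) <- profiles$feature
    profiles <- mat
  }
  if (ncol(profiles) != 5L) stop("profiles must have 5 subtype columns")
  a <- abs(profiles)
  peak <- a[, 5L] > apply(a[, 1:4, drop = FALSE], 1L, max)
  if (mode == "peak-at-basal") {
    return(rownames(profiles)[peak])
  }
  steps <- a[, 2:5, drop = FALSE] - a[, 1:4, drop = FALSE]
  monotone <- apply(steps >= -tau, 1L, all)
  rownames(profiles)[peak & monotone]
}

#' Spearman correlation between miRNA and gene expression
#'
#' Midrank-based Spearman rho for every (miRNA, gene) pair over shared
#' samples, with p-values from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` and BH adjustment across all
#' pairs.  The sample set can be restricted (e.g. to one subtype's
#' samples) via `sample_subset`.
#'
#' @param mir_expr,gene_expr Feature x sample matrices sharing sample
#'   columns.
#' @param sample_subset Optional character vector of sample ids.
#' @return List with matrices `rho`, `p`, `fdr` (miRNAs x genes) and `n`,
#'   the number of samples used.
#' @export
spearman_matrix <- function(mir_expr, gene_expr, sample_subset = NULL) {
  shared <- intersect(colnames(mir_expr), colnames(gene_expr))
  if (!is.null(sample_subset)) shared <- intersect(shared, sample_subset)
  if (length(shared) < 3L) stop("need at least 3 shared samples")
  n <- length(shared)
  rk <- function(m) t(apply(m[, shared, drop = FALSE], 1L, rank))
  rho <- stats::cor(t(rk(mir_expr)), t(rk(gene_expr)))
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, 0))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(rho) >= 1] <- 0
  fdr <- matrix(bh_adjust(as.vector(p)), nrow = nrow(p),
                dimnames = dimnames(p))
  list(rho = rho, p = p, fdr = fdr, n = n)
}
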
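# PPI loading, BottleNeck centrality, hub selection, hub-subnetwork
# extraction and tripartite module counting.
#
# BottleNeck centrality: for every root s, build the canonical BFS
# shortest-path tree (each non-root node's predecessor is the
# smallest-labelled neighbour one step closer to the root); a node v != s
# is a bottleneck of that tree iff its subtree (v included) holds more
# than n/4 of the component's nodes; BN(v) counts the roots for which v
# is a bottleneck.  Components are handled independently, each with its
# own n.

#' Load a weighted PPI edge list with a score threshold
#'
#' Reads a three-column (node1, node2, score) tab-separated edge list or
#' data.frame.  Combined scores on the 0-1000 STRING scale are detected
#' (any score > 1) and divided by 1000.  Edges with score strictly
#' greater than `score_threshold` are kept; self loops are dropped,
#' parallel edges collapsed to their maximum score, and nodes appearing
#' only in removed edges are absent from the graph (isolated-node
#' removal).
#'
#' @param edges Path to a TSV (optional header auto-detected) or a
#'   data.frame whose first three columns are node1, node2, score.
#' @param score_threshold Strict lower bound on retained edge scores.
#' @return An undirected simple [igraph][igraph::graph] with edge
#'   attribute `score`.
#' @export
load_ppi <- function(edges, score_threshold = 0.4) {
  if (is.character(edges)) {
    first <- strsplit(readLines(edges, n = 1L), "\t")[[1]]
    has_header <- length(first) >= 3L &&
      is.na(suppressWarnings(as.numeric(first[3])))
    edges <- utils::read.delim(edges, header = has_header,
                               stringsAsFactors = FALSE)
  }
  if (ncol(edges) < 3L) stop("edge list needs three columns")
  df <- data.frame(node1 = as.character(edges[[1]]),
                   node2 = as.character(edges[[2]]),
                   score = suppressWarnings(as.numeric(edges[[3]])),
                   stringsAsFactors = FALSE)
  if (any(is.na(df$score))) stop("malformed score column")
  if (any(df$score > 1)) df$score <- df$score / 1000
  if (any(df$score < 0 | df$score > 1)) {
    stop("scores must lie in [0, 1] after scaling")
  }
  df <- df[df$node1 != df$node2, , drop = FALSE]
  df <- df[df$score > score_threshold, , drop = FALSE]
  # collapse parallel edges (either orientation) to max score
  key <- ifelse(df$node1 < df$node2,
                paste(df$node1, df$node2, sep = "\r"),
                paste(df$node2, df$node1, sep = "\r"))
  ord <- order(key, -df$score)
  df <- df[ord, , drop = FALSE]
  key <- key[ord]
  df <- df[!duplicated(key), , drop = FALSE]
  igraph::graph_from_data_frame(df, directed = FALSE)
}

# Canonical BFS shortest-path tree rooted at `root`: returns the parent
# (smallest-labelled neighbour at distance d-1) of every node in the
# component, NA for the root.
canonical_tree_parents <- function(nodes, nbrs, dist) {
  parents <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  for (v in nodes) {
    dv <- dist[v]
    if (dv == 0) next
    cand <- nbrs[[v]]
    cand <- cand[dist[cand] == dv - 1]
    parents[v] <- min(cand)
  }
  parents
}

#' BottleNeck centrality
#'
#' Integer bottleneck score per node (see the file-level definition
#' above).  Shortest paths are unweighted; tied predecessors are resolved
#' canonically by smallest node label, making the score deterministic.
#' The root is never counted as a bottleneck of its own tree.
#'
#' @param g An undirected [igraph][igraph::graph], e.g. from
#'   [load_ppi()].
#' @return Named integer vector of scores over all nodes.
#' @export
bottleneck_centrality <- function(g) {
  if (igraph::vcount(g) == 0L) stop("empty graph")
  all_nodes <- igraph::V(g)$name
  if (is.null(all_nodes)) {
    all_nodes <- as.character(seq_len(igraph::vcount(g)))
    igraph::V(g)$name <- all_nodes
  }
  scores <- stats::setNames(integer(length(all_nodes)), all_nodes)
  comp <- igraph::components(g)
  for (ci in seq_len(comp$no)) {
    nodes <- sort(all_nodes[comp$membership == ci])
    n <- length(nodes)
    if (n == 1L) next
    sub <- igraph::induced_subgraph(g, nodes)
    nbrs <- lapply(stats::setNames(nodes, nodes), function(v) {
      igraph::V(sub)$name[as.integer(
        igraph::neighbors(sub, igraph::V(sub)[v]))]
    })
    dmat <- igraph::distances(sub, weights = NA)
    for (root in nodes) {
      dist <- dmat[root, nodes]
      names(dist) <- nodes
      parents <- canonical_tree_parents(nodes, nbrs, dist)
      size <- stats::setNames(rep(1L, n), nodes)
      for (v in nodes[order(-dist)]) {
        pv <- parents[v]
        if (!is.na(pv)) size[pv] <- size[pv] + size[v]
      }
      bn <- nodes[nodes != root & size[nodes] > n / 4]
      scores[bn] <- scores[bn] + 1L
    }
  }
  scores
}

#' Select the top-ranked hub nodes
#'
#' Ranks nodes by decreasing centrality score; ties are broken by node
#' degree (descending) and then node label (ascending).
#'
#' @param scores Named numeric vector of centrality scores.
#' @param n Number of hubs requested (at most `length(scores)` are
#'   returned).
#' @param g Optional graph supplying degrees for tie-breaking; without
#'   it all degrees are treated as equal.
#' @return data.frame `node`, `score`, `degree`, `rank`.
#' @export
select_hubs <- function(scores, n, g = NULL) {
  stopifnot(n >= 1)
  nodes <- names(scores)
  deg <- if (is.null(g)) {
    stats::setNames(rep(0L, length(nodes)), nodes)
  } else {
    igraph::degree(g)[nodes]
  }
  ord <- order(-scores, -deg, nodes)
  top <- ord[seq_len(min(n, length(nodes)))]
  data.frame(node = nodes[top],
             score = unname(scores[top]),
             degree = unname(deg[top]),
             rank = seq_along(top),
             stringsAsFactors = FALSE)
}

#' Extract the hub subnetwork, optionally with extended genes
#'
#' Induces the subgraph on the hub nodes and, if `expand`, adds every
#' non-hub node adjacent to at least `min_hub_neighbors` hubs with role
#' `"extended"`.  Edges are classified as `hub-hub`, `hub-extended` or
#' `extended-extended`; both edge countings (with and without
#' extended-extended edges) are reported, since conventions differ.
#'
#' @param g The PPI graph.
#' @param hubs Character vector of hub node ids (must exist in `g`).
#' @param expand Add extended genes (default `TRUE`).
#' @param min_hub_neighbors Minimum number of hub neighbours for a node
#'   to qualify as extended.
#' @return List of class `hub_subnetwork`: `nodes` (data.frame `node`,
#'   `role`), `edges` (data.frame `from`, `to`, `score`, `type`),
#'   `counts` (named vector: `hub_hub`, `hub_extended`,
#'   `extended_extended`, `total`, `total_excl_extended_extended`).
#' @export
extract_subnetwork <- function(g, hubs, expand = TRUE,
                               min_hub_neighbors = 2L) {
  vn <- igraph::V(g)$name
  unknown <- setdiff(hubs, vn)
  if (length(unknown) > 0L) {
    stop("unknown hub id(s): ", paste(unknown, collapse = ", "))
  }
  nodes <- data.frame(node = sort(hubs), role = "hub",
                      stringsAsFactors = FALSE)
  if (expand) {
    cand <- setdiff(vn, hubs)
    n_hub_nb <- vapply(cand, function(v) {
      nb <- vn[as.integer(igraph::neighbors(g, igraph::V(g)[v]))]
      sum(nb %in% hubs)
    }, integer(1))
    ext <- sort(cand[n_hub_nb >= min_hub_neighbors])
    if (length(ext) > 0L) {
      nodes <- rbind(nodes, data.frame(node = ext, role = "extended",
                                       stringsAsFactors = FALSE))
    }
  }
  sub <- igraph::induced_subgraph(g, nodes$node)
  el <- igraph::as_data_frame(sub, what = "edges")
  role_of <- stats::setNames(nodes$role, nodes$node)
  type <- ifelse(role_of[el$from] == "hub" & role_of[el$to] == "hub",
                 "hub-hub",
                 ifelse(role_of[el$from] == "extended" &
                          role_of[el$to] == "extended",
                        "extended-extended", "hub-extended"))
  edges <- data.frame(from = el$from, to = el$to,
                      score = if ("score" %in% names(el)) el$score else NA,
                      type = type, stringsAsFactors = FALSE)
  counts <- c(hub_hub = sum(type == "hub-hub"),
              hub_extended = sum(type == "hub-extended"),
              extended_extended = sum(type == "extended-extended"))
  counts["total"] <- sum(counts)
  counts["total_excl_extended_extended"] <-
    counts[["hub_hub"]] + counts[["hub_extended"]]
  structure(list(nodes = nodes, edges = edges, counts = counts),
            class = "hub_subnetwork")
}

#' Count tripartite circRNA-miRNA-gene regulatory modules
#'
#' Number of distinct circRNA -> miRNA -> gene paths obtainable by
#' joining the two pair lists on the shared miRNA, optionally restricting
#' genes to a set (e.g. the hub genes).
#'
#' @param circ_mir data.frame with circRNA-miRNA pairs (first two
#'   columns, or `source`/`target`).
#' @param mir_gene data.frame with miRNA-gene pairs (first two columns).
#' @param restrict_genes Optional character vector of admissible genes.
#' @return List with `n` (integer count) and `modules` (data.frame
#'   `circRNA`, `miRNA`, `gene` in lexicographic order).
#' @export
count_modules <- function(circ_mir, mir_gene, restrict_genes = NULL) {
  cm <- data.frame(circRNA = as.character(circ_mir[[1]]),
                   miRNA = as.character(circ_mir[[2]]),
                   stringsAsFactors = FALSE)
  mg <- data.frame(miRNA = as.character(mir_gene[[1]]),
                   gene = as.character(mir_gene[[2]]),
                   stringsAsFactors = FALSE)
  if (!is.null(restrict_genes)) {
    mg <- mg[mg$gene %in% restrict_genes, , drop = FALSE]
  }
  m <- unique(merge(cm, mg, by = "miRNA"))
  m <- m[, c("circRNA", "miRNA", "gene")]
  m <- m[order(m$circRNA, m$miRNA, m$gene), , drop = FALSE]
  rownames(m) <- NULL
  list(n = nrow(m), modules = m)
}
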
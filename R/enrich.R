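# Local gene-set over-representation analysis: hypergeometric test over
# GMT collections with BH adjustment.  Replaces web-service enrichment
# queries with a reproducible offline equivalent.

#' Read a gene-set collection from a GMT file
#'
#' GMT format: one set per line, tab-separated fields `name`,
#' `description`, members...  Duplicate members within a set are
#' deduplicated; case is preserved.  The default universe is the union of
#' all members.
#'
#' @param path Path to a GMT file.
#' @return An object of class `gene_set_collection`: list with `sets`
#'   (named list of character vectors), `descriptions`, `universe`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("GMT line with fewer than 3 fields: ", ln)
    sets[[f[1]]] <- unique(f[-(1:2)])
    desc[f[1]] <- f[2]
  }
  gene_set_collection(sets, descriptions = desc)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene ids.
#' @param universe Optional gene universe; defaults to the union of all
#'   set members.  Supplying the measured-gene universe gives a more
#'   conservative background than the collection's own union.
#' @param descriptions Optional named character vector.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL,
                                descriptions = NULL) {
  sets <- lapply(sets, unique)
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  sets <- lapply(sets, intersect, universe)
  sets <- sets[vapply(sets, length, integer(1)) > 0L]
  structure(list(sets = sets, universe = universe,
                 descriptions = descriptions),
            class = "gene_set_collection")
}

#' Hypergeometric over-representation test
#'
#' One-sided enrichment p-value `P(X >= k)` under
#' `Hypergeometric(N, K, n)` for every set in the collection, where `N`
#' is the universe size, `K` the set size, `n` the query size and `k`
#' the overlap, with BH adjustment across all sets.  Significance is
#' flagged at `fdr < fdr_cutoff` (default 0.05).
#'
#' @param query Character vector of gene ids; members outside the
#'   universe are dropped with a warning.
#' @param coll A [gene_set_collection()].
#' @param fdr_cutoff FDR significance threshold.
#' @return data.frame `set`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p`, `fdr`, `significant`, ordered by `p`.
#' @export
hypergeom_enrich <- function(query, coll, fdr_cutoff = 0.05) {
  stopifnot(inherits(coll, "gene_set_collection"))
  N <- length(coll$universe)
  if (N == 0L) stop("empty universe")
  query <- unique(query)
  outside <- setdiff(query, coll$universe)
  if (length(outside) > 0L) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, coll$universe)
  }
  n <- length(query)
  res <- lapply(names(coll$sets), function(s) {
    members <- coll$sets[[s]]
    K <- length(members)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = s, overlap = k, set_size = K, query_size = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(set = character(), overlap = integer(),
                      set_size = integer(), query_size = integer(),
                      universe_size = integer(), p = numeric())
  }
  out$fdr <- bh_adjust(out$p)
  out$significant <- out$fdr < fdr_cutoff
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
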
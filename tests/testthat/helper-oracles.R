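# Independent brute-force oracles used to validate the package's
# statistical and graph primitives.  Each oracle is coded directly from
# the textbook definition, independently of the implementation it
# checks.

# Benjamini-Hochberg step-up, literal definition:
# fdr_i = min over ranks j >= rank(i) of m * p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  out <- numeric(m)
  for (i in seq_len(m)) {
    ri <- which(ord == i)          # rank of p_i
    vals <- vapply(ri:m, function(j) m * p[ord[j]] / j, numeric(1))
    out[i] <- min(c(vals, 1))
  }
  out
}

# Hypergeometric upper tail P(X >= k) by exhaustive enumeration of all
# C(N, n) equally likely draws of the query from the universe.
oracle_hypergeom <- function(N, K, n, k) {
  universe <- seq_len(N)
  inset <- seq_len(K)              # wlog the set is the first K elements
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2L, function(d) sum(d %in% inset))
  mean(hits >= k)
}

# Exact two-sided rank-sum p-value by enumerating every assignment of
# ranks to the first group (no ties assumed).
oracle_ranksum_exact <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  all_vals <- c(x1, x2)
  r <- rank(all_vals)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U of x1
  assignments <- utils::combn(n1 + n2, n1)
  u_all <- apply(assignments, 2L, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * n2 / 2
  mean(abs(u_all - mu) >= abs(w_obs - mu))
}

# BottleNeck centrality by explicit tree construction: for each root,
# build the canonical BFS tree (smallest-label predecessor), then for
# every non-root node collect its descendant set recursively and count
# it as a bottleneck when |descendants| + 1 > n/4.
oracle_bottleneck <- function(g) {
  nodes <- sort(igraph::V(g)$name)
  score <- stats::setNames(integer(length(nodes)), nodes)
  comp <- igraph::components(g)
  memb <- stats::setNames(comp$membership[match(nodes, igraph::V(g)$name)],
                          nodes)
  for (ci in unique(memb)) {
    cn <- nodes[memb == ci]
    n <- length(cn)
    if (n == 1L) next
    adj <- lapply(stats::setNames(cn, cn), function(v) {
      nb <- igraph::V(g)$name[as.integer(igraph::neighbors(g, v))]
      sort(intersect(nb, cn))
    })
    for (root in cn) {
      # plain queue BFS for distances
      dist <- stats::setNames(rep(Inf, n), cn)
      dist[root] <- 0
      queue <- root
      while (length(queue) > 0L) {
        v <- queue[1]; queue <- queue[-1]
        for (w in adj[[v]]) {
          if (is.infinite(dist[w])) {
            dist[w] <- dist[v] + 1
            queue <- c(queue, w)
          }
        }
      }
      children <- stats::setNames(vector("list", n), cn)
      for (v in cn) {
        if (v == root) next
        preds <- adj[[v]][dist[adj[[v]]] == dist[v] - 1]
        p <- min(preds)
        children[[p]] <- c(children[[p]], v)
      }
      descendants <- function(v) {
        out <- character()
        for (ch in children[[v]]) out <- c(out, ch, descendants(ch))
        out
      }
      for (v in cn) {
        if (v == root) next
        if (length(descendants(v)) + 1 > n / 4) {
          score[v] <- score[v] + 1L
        }
      }
    }
  }
  score
}

# random connected labelled graph with 2..max_n nodes
random_connected_graph <- function(max_n = 8L) {
  repeat {
    n <- sample(2:max_n, 1L)
    g <- igraph::sample_gnp(n, stats::runif(1, 0.3, 0.9))
    if (igraph::is_connected(g)) {
      igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
      return(g)
    }
  }
}

# tiny two-group matrix helper
two_group_matrix <- function(n_feat, n1, n2, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_feat * (n1 + n2)), nrow = n_feat,
              dimnames = list(sprintf("f%03d", seq_len(n_feat)), NULL))
  colnames(m) <- sprintf("s%03d", seq_len(n1 + n2))
  list(m = m, groups = factor(rep(c("a", "b"), c(n1, n2)),
                              levels = c("a", "b")))
}

# fast small synthetic config for tests
test_config <- function(...) {
  synth_config(n_control = 20L, n_per_subtype = 10L,
               n_features = c(circRNA = 30L, miRNA = 30L, mRNA = 60L),
               ...)
}

blbc_example_path <- function(file) {
  system.file("extdata", "blbc_example", file, package = "cernaxes",
              mustWork = TRUE)
}
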
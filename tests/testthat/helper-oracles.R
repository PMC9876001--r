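# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: modularity by the literal double sum, BH by the
# literal step-up recursion, CCA through stats::cancor.

# adjacency matrix of an edge data.frame over the given node set
edges_to_adjacency <- function(edges, nodes) {
  W <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    W[a, b] <- W[a, b] + edges$weight[i]
    W[b, a] <- W[b, a] + edges$weight[i]
  }
  W
}

# Q = (1/2m) sum_ij [W_ij - k_i k_j / 2m] delta(c_i, c_j)
modularity_double_sum <- function(W, membership) {
  k <- rowSums(W)
  m2 <- sum(W)
  if (m2 == 0) return(0)
  same <- outer(membership, membership, "==")
  sum((W - outer(k, k) / m2) * same) / m2
}

# exhaustive set-partition search maximizing modularity (small graphs only)
best_partition_exhaustive <- function(W) {
  n <- nrow(W)
  best_q <- -Inf
  best <- NULL
  memb <- integer(n)
  recurse <- function(i, n_groups) {
    if (i > n) {
      q <- modularity_double_sum(W, memb[seq_len(n)])
      if (q > best_q) {
        best_q <<- q
        best <<- memb[seq_len(n)]
      }
      return(invisible())
    }
    for (g in seq_len(n_groups + 1L)) {
      memb[i] <<- g
      recurse(i + 1L, max(n_groups, g))
    }
  }
  recurse(1L, 0L)
  list(membership = best, q = best_q)
}

# literal BH step-up: p_(i) * m / i, cumulative minimum from the largest
bh_step_up <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# first canonical correlation through stats::cancor (QR-based route)
cancor_first <- function(X, Y) stats::cancor(X, Y)$cor[1L]

random_block <- function(n, p) {
  structure(list(scores = matrix(stats::rnorm(n * p), n, p)),
            class = "gene_feature_block")
}

# two 5-cliques (unit weights) joined by one bridge edge
two_clique_bridge <- function() {
  cl <- function(nodes) {
    pr <- utils::combn(nodes, 2L)
    data.frame(gene_a = pr[1L, ], gene_b = pr[2L, ], weight = 1,
               stringsAsFactors = FALSE)
  }
  a <- paste0("A", 1:5); b <- paste0("B", 1:5)
  edges <- rbind(cl(a), cl(b),
                 data.frame(gene_a = "A1", gene_b = "B1", weight = 1))
  weighted_network(edges)
}

# c disconnected complete graphs of the given size, unit weights
clique_bundle <- function(n_cliques, size = 4L) {
  edges <- do.call(rbind, lapply(seq_len(n_cliques), function(c) {
    nodes <- paste0("C", c, "N", seq_len(size))
    pr <- utils::combn(nodes, 2L)
    data.frame(gene_a = pr[1L, ], gene_b = pr[2L, ], weight = 1,
               stringsAsFactors = FALSE)
  }))
  weighted_network(edges)
}

# small beta matrix fixture with named sites/samples
make_beta <- function(values, sites = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- sites %||% sprintf("cg%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("S%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_partition_for_test <- function(assignment) {
  structure(list(assignment = assignment,
                 sizes = as.integer(table(assignment)),
                 modularity_q = 0, seed = 1L, resolution = 1),
            class = "module_partition")
}

write_tsv_fixture <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
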
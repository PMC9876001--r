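#' Detect gene modules by multilevel (Louvain) modularity maximization
#'
#' Runs weighted Louvain community detection on the network's analysis
#' (largest) component. The sweep order is randomized under the given seed,
#' so identical seed and input give an identical partition. Module indices
#' are relabelled 1, 2, ... in order of decreasing module size. The
#' reported `modularity_q` is the classic (resolution 1) weighted
#' modularity of the returned assignment, recomputed with
#' [modularity_q()].
#'
#' @param net A `weighted_gene_network`.
#' @param seed Integer RNG seed (default 1).
#' @param resolution Resolution parameter multiplying the null-model term
#'   during optimization (default 1 = classic modularity).
#' @return A `module_partition`: list with `assignment` (named integer
#'   vector gene -> module), `sizes`, `modularity_q`, `seed`, `resolution`.
#' @export
detect_modules <- function(net, seed = 1L, resolution = 1) {
  if (nrow(net$edges) == 0L) {
    warning("network has no edges; every node is its own module")
    assignment <- seq_along(net$nodes)
    names(assignment) <- net$nodes
    return(new_partition(assignment, 0, seed, resolution))
  }
  g <- as_igraph(net, analysis_only = TRUE)
  if (igraph::vcount(g) < 2L)
    stop("analysis network needs >= 2 nodes")
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                                resolution = resolution)
  member <- igraph::membership(cl)
  assignment <- relabel_by_size(as.integer(member), names(member))
  q <- modularity_q(net, assignment)
  new_partition(assignment, q, seed, resolution)
}

# contiguous 1..K labels ordered by decreasing module size (ties: by the
# smallest original label, deterministic)
relabel_by_size <- function(member, nodes) {
  sizes <- table(member)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  new_id <- integer(length(sizes))
  new_id[ord] <- seq_along(ord)
  assignment <- new_id[match(member, as.integer(names(sizes)))]
  names(assignment) <- nodes
  assignment
}

new_partition <- function(assignment, q, seed, resolution) {
  structure(list(assignment = assignment,
                 sizes = as.integer(table(assignment)),
                 modularity_q = q,
                 seed = seed, resolution = resolution),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules over %d genes, Q = %.4f (seed %d)\n",
              length(x$sizes), length(x$assignment), x$modularity_q, x$seed))
  cat("sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Weighted modularity of a partition
#'
#' Computes `Q = sum_c [ w_in_c / m - gamma * (K_c / 2m)^2 ]` where `w_in_c`
#' is the total weight of edges inside module `c`, `K_c` the summed weighted
#' degree of its nodes and `m` the total edge weight — equivalent to the
#' double-sum definition `Q = (1/2m) sum_ij [w_ij - k_i k_j / 2m] d(c_i,c_j)`
#' and to igraph's weighted modularity convention. Independent of the
#' optimizer, so it can audit any assignment.
#'
#' @param net A `weighted_gene_network` (only edges among assigned nodes are
#'   used).
#' @param assignment Named integer vector gene -> module covering all nodes
#'   incident to the edges considered.
#' @param resolution Resolution parameter gamma (default 1).
#' @return Scalar Q (0 when the network has no edge weight).
#' @export
modularity_q <- function(net, assignment, resolution = 1) {
  e <- net$edges
  keep <- e$gene_a %in% names(assignment) & e$gene_b %in% names(assignment)
  e <- e[keep, , drop = FALSE]
  m <- sum(e$weight)
  if (m == 0) return(0)
  ca <- assignment[e$gene_a]
  cb <- assignment[e$gene_b]
  w_in <- tapply(e$weight[ca == cb], ca[ca == cb], sum)
  strength <- tapply(c(e$weight, e$weight), c(e$gene_a, e$gene_b), sum)
  K_c <- tapply(strength, assignment[names(strength)], sum)
  q_in <- sum(w_in) / m
  q_null <- sum((K_c / (2 * m))^2)
  q_in - resolution * q_null
}

#' Drop modules below a minimum size
#'
#' Retains modules with at least `min_size` genes, re-indexing the survivors
#' 1, 2, ... in decreasing size order; genes of removed modules are listed in
#' the `removed` attribute.
#'
#' @param partition A `module_partition`.
#' @param min_size Minimum module size (default 100; strict "< min_size
#'   removed" semantics).
#' @return A filtered `module_partition` with attribute `removed`.
#' @export
filter_small_modules <- function(partition, min_size = 100L) {
  sizes <- table(partition$assignment)
  keep_ids <- as.integer(names(sizes)[as.integer(sizes) >= min_size])
  if (length(keep_ids) == 0L)
    stop("no module reaches min_size = ", min_size, "; sizes: ",
         paste(sort(as.integer(sizes), decreasing = TRUE), collapse = ", "))
  keep <- partition$assignment %in% keep_ids
  assignment <- relabel_by_size(partition$assignment[keep],
                                names(partition$assignment)[keep])
  out <- new_partition(assignment, partition$modularity_q,
                       partition$seed, partition$resolution)
  attr(out, "removed") <- names(partition$assignment)[!keep]
  out
}
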
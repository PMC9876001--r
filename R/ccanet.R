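#' Restrict a prior network to differentially methylated genes
#'
#' @param prior A `prior_network`.
#' @param dmgs Character vector of gene symbols.
#' @param policy `"both"` keeps edges whose two endpoints are DMGs
#'   (default); `"either"` keeps edges with at least one DMG endpoint.
#' @return A restricted `prior_network`.
#' @export
restrict_prior_network <- function(prior, dmgs, policy = c("both", "either")) {
  policy <- match.arg(policy)
  e <- prior$edges
  in_a <- e$gene_a %in% dmgs
  in_b <- e$gene_b %in% dmgs
  keep <- if (policy == "both") in_a & in_b else in_a | in_b
  if (!any(keep)) {
    nodes <- unique(c(e$gene_a, e$gene_b))
    stop(sprintf(
      "no prior edges retained: %d DMGs, %d network genes, %d in common",
      length(dmgs), length(nodes), length(intersect(dmgs, nodes))))
  }
  structure(list(edges = e[keep, , drop = FALSE], source = prior$source),
            class = "prior_network")
}

#' Reduce a gene's methylation sites to principal-component scores
#'
#' The sample x site submatrix of all CpG sites annotated to the gene is
#' column-centered and decomposed with `stats::prcomp`; the smallest number
#' of leading components whose cumulative explained variance reaches
#' `var_retained` is kept (at least one, at most `n_samples - 1`).
#'
#' @param beta Sites x samples beta matrix.
#' @param annotation Annotation data.frame (`site_id`, `gene_symbol`).
#' @param gene Gene symbol.
#' @param var_retained Cumulative explained-variance target (default 0.9).
#' @return A `gene_feature_block`: list with `gene`, `scores` (centered
#'   sample x component matrix), `explained_variance` (fractions for the
#'   retained components) and `n_sites_original`.
#' @export
reduce_gene_features <- function(beta, annotation, gene, var_retained = 0.9) {
  sites <- annotation$site_id[annotation$gene_symbol == gene]
  sites <- intersect(sites, rownames(beta))
  if (length(sites) == 0L) stop("gene ", gene, " has no sites in the beta matrix")
  x <- t(beta[sites, , drop = FALSE])
  if (sum(apply(x, 2L, stats::var)) <= 0)
    stop("gene ", gene, " has zero variance across samples")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2 / sum(pr$sdev^2)
  k <- which(cumsum(ev) >= var_retained - 1e-12)[1L]
  if (is.na(k)) k <- length(ev)
  k <- max(1L, min(k, ncol(x), nrow(x) - 1L))
  structure(list(gene = gene,
                 scores = pr$x[, seq_len(k), drop = FALSE],
                 explained_variance = ev[seq_len(k)],
                 n_sites_original = length(sites)),
            class = "gene_feature_block")
}

#' First canonical correlation between two gene feature blocks
#'
#' The canonical correlations of the two centered score matrices are the
#' singular values of the whitened cross-covariance
#' `Sxx^{-1/2} Sxy Syy^{-1/2}`. When a within-block covariance is
#' (numerically) singular a ridge of `1e-8 * trace/p` is added before
#' whitening. The returned weight is the leading canonical correlation
#' clipped to \[0, 1\]; `method = "mean"` averages all canonical
#' correlations instead.
#'
#' @param a,b `gene_feature_block` objects over identical ordered samples.
#' @param method `"first"` (default) or `"mean"`.
#' @return Scalar edge weight in \[0, 1\].
#' @export
canonical_weight <- function(a, b, method = c("first", "mean")) {
  method <- match.arg(method)
  X <- a$scores; Y <- b$scores
  n <- nrow(X)
  if (n != nrow(Y)) stop("blocks must cover the same samples")
  if (n <= ncol(X) + ncol(Y))
    warning("fewer samples than total components; canonical correlation may saturate")
  X <- sweep(X, 2L, colMeans(X))
  Y <- sweep(Y, 2L, colMeans(Y))
  Sxx <- crossprod(X) / (n - 1)
  Syy <- crossprod(Y) / (n - 1)
  Sxy <- crossprod(X, Y) / (n - 1)
  if (all(diag(Sxx) <= 0) || all(diag(Syy) <= 0)) stop("zero-variance block")
  rho <- svd(whiten(Sxx) %*% Sxy %*% whiten(Syy))$d
  w <- if (method == "first") rho[1L] else mean(rho)
  min(max(w, 0), 1)
}

# symmetric inverse square root with ridge guard for singular covariances
whiten <- function(S) {
  p <- ncol(S)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < 1e-12 * max(e$values, 0)) {
    S <- S + diag(1e-8 * sum(diag(S)) / p, p)
    e <- eigen(S, symmetric = TRUE)
  }
  if (any(e$values <= 0)) stop("zero-variance block")
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Build the CCA-weighted gene regulatory network
#'
#' Every prior edge whose two endpoints have feature blocks is weighted by
#' [canonical_weight()]; genes without a block are dropped with a warning.
#' Connected components are labelled and the largest one is marked as the
#' analysis network.
#'
#' @param prior A (restricted) `prior_network`.
#' @param blocks Named list of `gene_feature_block`s keyed by gene symbol.
#' @param method Passed to [canonical_weight()].
#' @return A `weighted_gene_network`: list with `edges` (data.frame
#'   `gene_a`, `gene_b`, `weight`), `nodes`, `component_id` (named integer
#'   vector) and `analysis_component` (id of the largest component).
#' @export
build_weighted_network <- function(prior, blocks, method = "first") {
  e <- prior$edges
  have <- e$gene_a %in% names(blocks) & e$gene_b %in% names(blocks)
  if (!all(have)) {
    warning(sum(!have), " edge(s) dropped: endpoint without a feature block")
    e <- e[have, , drop = FALSE]
  }
  if (nrow(e) == 0L) stop("empty weighted network: no edges with feature blocks")
  e$weight <- mapply(function(ga, gb)
    canonical_weight(blocks[[ga]], blocks[[gb]], method = method),
    e$gene_a, e$gene_b, USE.NAMES = FALSE)
  weighted_network(e)
}

#' Construct a weighted gene network from an edge data.frame
#'
#' @param edges Data.frame with columns `gene_a`, `gene_b`, `weight`.
#' @param nodes Optional character vector of node names (needed when some
#'   nodes are isolated or `edges` is empty).
#' @return A `weighted_gene_network` with components labelled and the
#'   largest component marked for analysis.
#' @export
weighted_network <- function(edges, nodes = NULL) {
  stopifnot(all(c("gene_a", "gene_b", "weight") %in% colnames(edges)))
  if (any(edges$weight < 0 | edges$weight > 1))
    stop("edge weights must lie in [0, 1]")
  all_nodes <- union(nodes, unique(c(edges$gene_a, edges$gene_b)))
  if (length(all_nodes) == 0L) stop("network has no nodes")
  g <- igraph::graph_from_data_frame(edges[c("gene_a", "gene_b", "weight")],
                                     directed = FALSE, vertices = all_nodes)
  comp <- igraph::components(g)
  component_id <- comp$membership
  structure(list(edges = edges,
                 nodes = names(component_id),
                 component_id = component_id,
                 analysis_component = which.max(comp$csize)),
            class = "weighted_gene_network")
}

#' Genes of the analysis (largest) component
#' @param net A `weighted_gene_network`.
#' @return Character vector of gene symbols.
#' @export
analysis_genes <- function(net) {
  net$nodes[net$component_id == net$analysis_component]
}

# igraph view of a weighted_gene_network, optionally restricted to the
# analysis component
as_igraph <- function(net, analysis_only = FALSE) {
  g <- igraph::graph_from_data_frame(net$edges[c("gene_a", "gene_b", "weight")],
                                     directed = FALSE, vertices = net$nodes)
  if (analysis_only)
    g <- igraph::induced_subgraph(g, analysis_genes(net))
  g
}

#' @export
print.weighted_gene_network <- function(x, ...) {
  cat(sprintf(
    "weighted_gene_network: %d genes, %d edges, %d component(s); largest has %d genes\n",
    length(x$nodes), nrow(x$edges), max(x$component_id),
    sum(x$component_id == x$analysis_component)))
  invisible(x)
}

#' Export a weighted network as TSV and GraphML
#'
#' @param net A `weighted_gene_network`.
#' @param tsv_path,graphml_path Output paths (either may be `NULL`).
#' @export
write_weighted_network <- function(net, tsv_path = NULL, graphml_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(net$edges, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
  invisible(net)
}
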
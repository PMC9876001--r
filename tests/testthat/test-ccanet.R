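test_that("prior network restriction honors both/either policies", {
  net <- prior_network(data.frame(a = c("A", "B", "C"),
                                  b = c("B", "C", "D")))
  both <- restrict_prior_network(net, c("A", "B", "C"))
  expect_equal(nrow(both$edges), 2L)
  either <- restrict_prior_network(net, "A", policy = "either")
  expect_equal(nrow(either$edges), 1L)
  expect_error(restrict_prior_network(net, c("X", "Y")), "no prior edges")
})

test_that("per-gene PCA reduction obeys its rank and variance contracts", {
  set.seed(21)
  n <- 20
  v <- runif(n, 0.2, 0.8)
  ann <- data.frame(site_id = c("cg1", "cg2", "cg3", "cg4"),
                    gene_symbol = c("G1", "G2", "G2", "G2"))
  # single-site gene: scores equal the centered beta vector up to sign
  beta <- make_beta(rbind(v, v, v, v), sites = ann$site_id,
                    samples = sprintf("S%02d", 1:n))
  blk <- reduce_gene_features(beta, ann, "G1")
  expect_equal(ncol(blk$scores), 1L)
  expect_equal(abs(as.numeric(blk$scores)), abs(v - mean(v)), tolerance = 1e-12)
  # duplicated sites collapse to one component at 90% retention
  blk2 <- reduce_gene_features(beta, ann, "G2", var_retained = 0.9)
  expect_equal(ncol(blk2$scores), 1L)
  expect_equal(blk2$explained_variance[1], 1, tolerance = 1e-12)
  expect_error(reduce_gene_features(beta, ann, "G9"), "no sites")
})

test_that("retained variance fractions match an independent eigen-decomposition", {
  set.seed(22)
  x <- matrix(runif(20 * 5, 0.1, 0.9), 5, 20)  # 5 sites x 20 samples
  ann <- data.frame(site_id = sprintf("cg%d", 1:5), gene_symbol = "G")
  beta <- make_beta(x, sites = ann$site_id)
  blk <- reduce_gene_features(beta, ann, "G", var_retained = 1)
  ev_oracle <- eigen(cov(t(x)), symmetric = TRUE)$values
  expect_equal(blk$explained_variance,
               (ev_oracle / sum(ev_oracle))[seq_along(blk$explained_variance)],
               tolerance = 1e-8)
  # score columns are mutually orthogonal
  g <- crossprod(blk$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8 * max(diag(g)))
})

test_that("canonical weight reduces to known closed forms", {
  set.seed(23)
  a <- random_block(50, 3)
  expect_equal(canonical_weight(a, a), 1, tolerance = 1e-10)
  x <- random_block(50, 1)
  y <- random_block(50, 1)
  expect_equal(canonical_weight(x, y),
               abs(cor(x$scores[, 1], y$scores[, 1])), tolerance = 1e-10)
  # blocks with a shared column direction saturate at 1
  shared <- random_block(50, 2)
  b2 <- structure(list(scores = cbind(shared$scores[, 1],
                                      rnorm(50))),
                  class = "gene_feature_block")
  expect_equal(canonical_weight(shared, b2), 1, tolerance = 1e-8)
  zero <- structure(list(scores = matrix(0, 50, 2)),
                    class = "gene_feature_block")
  expect_error(canonical_weight(zero, a), "zero-variance")
})

test_that("canonical weight is symmetric, bounded and matches cancor", {
  set.seed(24)
  for (i in 1:40) {
    a <- random_block(40, sample(1:4, 1))
    b <- random_block(40, sample(1:4, 1))
    w <- canonical_weight(a, b)
    expect_gte(w, 0); expect_lte(w, 1)
    expect_equal(w, canonical_weight(b, a), tolerance = 1e-10)
    expect_equal(w, cancor_first(a$scores, b$scores), tolerance = 1e-8)
  }
})

test_that("canonical weight is invariant under invertible linear transforms", {
  set.seed(25)
  for (i in 1:20) {
    a <- random_block(60, 3)
    b <- random_block(60, 2)
    w <- canonical_weight(a, b)
    M <- matrix(rnorm(9), 3, 3) + diag(3)
    a2 <- structure(list(scores = a$scores %*% M),
                    class = "gene_feature_block")
    expect_equal(canonical_weight(a2, b), w, tolerance = 1e-6)
    N <- matrix(rnorm(4), 2, 2) + diag(2)
    b2 <- structure(list(scores = b$scores %*% N),
                    class = "gene_feature_block")
    expect_equal(canonical_weight(a, b2), w, tolerance = 1e-6)
  }
})

test_that("network assembly labels components and keeps the largest", {
  set.seed(26)
  blocks <- setNames(lapply(1:7, function(i) random_block(30, 2)),
                     c("A1", "A2", "A3", "A4", "B1", "B2", "B3"))
  tri <- function(n) {
    pr <- utils::combn(n, 2L)
    data.frame(gene_a = pr[1, ], gene_b = pr[2, ])
  }
  edges <- rbind(tri(c("A1", "A2", "A3")), tri(c("B1", "B2", "B3")),
                 data.frame(gene_a = "A1", gene_b = "A4"))
  net <- build_weighted_network(prior_network(edges), blocks)
  expect_setequal(analysis_genes(net), c("A1", "A2", "A3", "A4"))
  expect_true(all(net$edges$weight >= 0 & net$edges$weight <= 1))

  # the only edge loses an endpoint block -> empty network
  one <- prior_network(data.frame(a = "X", b = "Y"))
  expect_error(suppressWarnings(build_weighted_network(one, blocks)),
               "empty weighted network")
})

test_that("adding an unconnected gene leaves existing edge weights unchanged", {
  set.seed(27)
  blocks <- setNames(lapply(1:4, function(i) random_block(30, 2)),
                     c("A", "B", "C", "Z"))
  net1 <- build_weighted_network(
    prior_network(data.frame(a = c("A", "B"), b = c("B", "C"))), blocks)
  net2 <- build_weighted_network(
    prior_network(data.frame(a = c("A", "B", "Z"), b = c("B", "C", "Z2"))),
    c(blocks, list(Z2 = random_block(30, 2))))
  key <- paste(net1$edges$gene_a, net1$edges$gene_b)
  expect_equal(net1$edges$weight,
               net2$edges$weight[match(key, paste(net2$edges$gene_a,
                                                  net2$edges$gene_b))],
               tolerance = 1e-12)
})

test_that("planted co-methylation yields higher within-module edge weights", {
  ds <- generate_dataset(synth_config(n_case = 50, n_control = 50), seed = 41)
  ann <- ds$annotation
  genes <- unique(ann$gene_symbol)
  blocks <- setNames(
    lapply(genes, function(g) reduce_gene_features(ds$beta, ann, g)), genes)
  net <- build_weighted_network(ds$prior, blocks)
  mod <- ds$truth$module
  within <- mod[net$edges$gene_a] == mod[net$edges$gene_b]
  expect_gt(median(net$edges$weight[within]) -
              median(net$edges$weight[!within]), 0)
})
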
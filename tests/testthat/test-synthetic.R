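test_that("generation is bit-identical under the same seed and config", {
  cfg <- synth_config(n_case = 20, n_control = 20, genes_per_module = 5)
  a <- generate_dataset(cfg, seed = 1)
  b <- generate_dataset(cfg, seed = 1)
  expect_identical(a$beta, b$beta)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$prior$edges, b$prior$edges)
  expect_identical(a$expression, b$expression)
  expect_identical(unclass(a$truth), unclass(b$truth))
  c <- generate_dataset(cfg, seed = 2)
  expect_false(identical(a$beta, c$beta))
})

test_that("generated data respect the beta-matrix contracts", {
  for (s in c(1, 7)) {
    ds <- generate_dataset(synth_config(n_case = 15, n_control = 15,
                                        genes_per_module = 6), seed = s)
    expect_true(all(ds$beta >= 0.01 & ds$beta <= 0.99))
    expect_false(anyDuplicated(rownames(ds$beta)) > 0)
    expect_false(anyDuplicated(colnames(ds$beta)) > 0)
    expect_identical(colnames(ds$beta), ds$clinical$sample_id)
    expect_identical(rownames(ds$beta), ds$annotation$site_id)
    expect_true(all(ds$clinical$time >= 0))
    expect_true(all(ds$clinical$event %in% c(0, 1)))
  }
})

test_that("the noiseless limit makes within-module sites perfectly correlated", {
  cfg <- synth_config(n_case = 10, n_control = 10, genes_per_module = 3,
                      sites_per_gene = 2, dmp_sites_per_gene = 0,
                      noise_sd = 0, loading = 1,
                      baseline_beta_range = c(0.5, 0.5))
  ds <- generate_dataset(cfg, seed = 4)
  m1_sites <- names(ds$truth$site_module)[ds$truth$site_module == 1]
  cors <- cor(t(ds$beta[m1_sites, ]))
  expect_equal(unname(cors), matrix(1, length(m1_sites), length(m1_sites)),
               tolerance = 1e-12)
})

test_that("realized mean beta shift at DMP sites matches the planted value", {
  ds <- generate_dataset(synth_config(), seed = 6)
  cs <- ds$clinical$group == "case"
  dmp <- ds$truth$dmp_sites
  realized <- mean(ds$beta[dmp, cs]) - mean(ds$beta[dmp, !cs])
  expect_lt(abs(realized - 0.3), 0.03)
})

test_that("DMP recall is non-decreasing in the planted shift", {
  recall <- sapply(c(0, 0.1, 0.3), function(d) {
    mean(sapply(1:3, function(s) {
      cfg <- synth_config(n_case = 30, n_control = 30, delta_beta = d)
      ds <- generate_dataset(cfg, seed = 100 + s)
      res <- test_sites(ds$beta, ds$clinical$group)
      sel <- select_dmps(res)
      planted <- names(ds$truth$site_module)[
        seq_along(ds$truth$site_module) %% cfg$sites_per_gene == 1]
      length(intersect(sel$site_id, planted)) / length(planted)
    }))
  })
  expect_true(all(diff(recall) >= 0))
  expect_gt(recall[3], 0.9)
})

test_that("the ordinal trait hits its target Spearman with the driving factor", {
  # indirect check through a strongly loaded module eigengene at n = 100
  rhos <- sapply(1:5, function(s) {
    ds <- generate_dataset(synth_config(), seed = 300 + s)
    cs <- ds$clinical$group == "case"
    sites <- names(ds$truth$site_module)[
      ds$truth$site_module == ds$truth$trait_module]
    me <- compute_me(ds$beta[, cs], sites)
    abs(cor(me$scores, ds$clinical$stage_N[cs], method = "spearman"))
  })
  expect_true(all(abs(rhos - 0.5) < 0.2))
})

test_that("truth metrics score partitions and screens correctly", {
  ds <- generate_dataset(synth_config(n_case = 15, n_control = 15,
                                      genes_per_module = 10), seed = 8)
  truth <- ds$truth
  perfect <- truth$module
  expect_equal(module_recovery_ari(perfect, truth$module), 1)
  set.seed(9)
  aris <- replicate(20, {
    shuffled <- setNames(sample(truth$module), names(truth$module))
    module_recovery_ari(shuffled, truth$module)
  })
  expect_lt(max(abs(aris)), 0.15)
  expect_error(module_recovery_ari(setNames(1:3, c("X", "Y", "Z")),
                                   truth$module), "no shared")
  m <- screen_metrics(truth$dmp_sites, truth$dmp_sites)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  m2 <- screen_metrics(character(0), truth$dmp_sites)
  expect_true(is.na(m2$precision))
  expect_equal(m2$recall, 0)
})

test_that("truth_metrics wrapper aggregates available stage results", {
  ds <- generate_dataset(synth_config(n_case = 30, n_control = 30), seed = 10)
  res <- test_sites(ds$beta, ds$clinical$group)
  sel <- select_dmps(res)
  out <- truth_metrics(ds$truth, partition = ds$truth$module,
                       dmps = sel$site_id)
  expect_equal(out$module_ari, 1)
  expect_gt(out$dmp_recall, 0.9)
  expect_gt(out$dmp_precision, 0.9)
})

test_that("dataset writer produces the pipeline's input formats", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(synth_config(n_case = 8, n_control = 8,
                                      genes_per_module = 3), seed = 11)
  write_dataset(ds, dir)
  got <- read_beta_matrix(file.path(dir, "beta.tsv"),
                          file.path(dir, "annotation.tsv"))
  expect_equal(got$beta, ds$beta)
  clin <- read_clinical(file.path(dir, "clinical.tsv"))
  expect_equal(clin$sample_id, ds$clinical$sample_id)
  net <- read_prior_network(file.path(dir, "prior_network.csv"))
  expect_equal(nrow(net$edges), nrow(ds$prior$edges))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$prognostic_site, ds$truth$prognostic_site)
})

test_that("planted-network simulator produces the requested block structure", {
  sim <- simulate_planted_network(n_modules = 3, genes_per_module = 10,
                                  seed = 12)
  expect_equal(length(sim$membership), 30L)
  within <- sim$membership[sim$net$edges$gene_a] ==
    sim$membership[sim$net$edges$gene_b]
  expect_gt(mean(sim$net$edges$weight[within]), 0.6)
  expect_lt(mean(sim$net$edges$weight[!within]), 0.2)
})
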
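test_that("significant-site background keeps shifted sites, drops flat ones", {
  set.seed(61)
  n <- 20
  shifted <- c(rnorm(n, 0.6, 0.05), rnorm(n, 0.2, 0.05))
  flat <- rep(0.5, 2 * n)
  noisy <- runif(2 * n, 0.3, 0.7)
  beta <- make_beta(rbind(shifted, flat, noisy),
                    sites = c("hit", "flat", "null"))
  groups <- rep(c("case", "control"), each = n)
  sig <- suppressWarnings(significant_sites(beta, groups))
  expect_true("hit" %in% sig)
  expect_false("flat" %in% sig)
  expect_equal(significant_sites(beta, groups, alpha = 1), rownames(beta))
})

test_that("module eigengene is the first PC with positive-methylation sign", {
  set.seed(62)
  v <- runif(15, 0.2, 0.8)
  beta <- make_beta(rbind(v), sites = "cg1")
  me <- compute_me(beta, "cg1")
  expect_equal(unname(me$scores), v - mean(v), tolerance = 1e-12)
  expect_gte(cor(me$scores, v), 0)
  # two perfectly correlated sites -> all variance on PC1
  beta2 <- make_beta(rbind(v, 0.1 + 0.5 * v), sites = c("cg1", "cg2"))
  me2 <- compute_me(beta2, c("cg1", "cg2"))
  expect_equal(me2$explained_variance, 1, tolerance = 1e-12)
  expect_error(compute_me(beta, "cgX"), "no sites")
})

test_that("eigengene matches an independent eigen-decomposition up to sign", {
  set.seed(63)
  x <- matrix(runif(10 * 25, 0.1, 0.9), 10, 25)
  beta <- make_beta(x)
  me <- compute_me(beta, rownames(beta))
  cc <- scale(t(x), center = TRUE, scale = FALSE)
  e <- eigen(cov(cc), symmetric = TRUE)
  oracle <- as.numeric(cc %*% e$vectors[, 1])
  agreement <- abs(cor(me$scores, oracle))
  expect_equal(agreement, 1, tolerance = 1e-8)
  expect_equal(sd(me$scores), sd(oracle), tolerance = 1e-8)
  expect_lt(abs(mean(me$scores)), 1e-10 * sd(me$scores))
})

test_that("sign convention holds across random modules", {
  set.seed(64)
  for (i in 1:10) {
    x <- matrix(runif(6 * 20, 0.1, 0.9), 6, 20)
    beta <- make_beta(x)
    me <- compute_me(beta, rownames(beta))
    expect_gte(cor(me$scores, colMeans(x)), 0)
  }
})

test_that("trait association recovers perfect monotone links and antisymmetry", {
  set.seed(65)
  scores <- rnorm(30)
  me <- structure(list(scores = scores), class = "module_eigengene")
  clin <- data.frame(up = rank(scores), down = -rank(scores), flat = 1)
  a <- suppressWarnings(associate_traits(list(m1 = me), clin,
                                         traits = c("up", "down", "flat")))
  expect_equal(a$rho[a$trait == "up"], 1, tolerance = 1e-12)
  expect_equal(a$rho[a$trait == "down"], -1, tolerance = 1e-12)
  expect_true(is.na(a$rho[a$trait == "flat"]))
  m <- association_matrix(a)
  expect_equal(dim(m), c(1L, 3L))
  expect_equal(m["m1", "up"], 1)
})

test_that("Spearman association is invariant to monotone transforms", {
  set.seed(66)
  scores <- rnorm(40)
  trait <- rnorm(40)
  me <- structure(list(scores = scores), class = "module_eigengene")
  base <- associate_traits(list(m = me), data.frame(t = trait), traits = "t")
  warped <- associate_traits(list(m = me),
                             data.frame(t = exp(3 * trait)), traits = "t")
  expect_equal(base$rho, warped$rho, tolerance = 1e-12)
  me2 <- structure(list(scores = qnorm(pnorm(scores))^3),
                   class = "module_eigengene")
  warped2 <- associate_traits(list(m = me2), data.frame(t = trait),
                              traits = "t")
  expect_equal(base$rho, warped2$rho, tolerance = 1e-12)
})

test_that("key-site screen applies strict thresholds and flags NAs as failures", {
  set.seed(67)
  v <- runif(20, 0.2, 0.8)
  beta <- make_beta(rbind(v, rep(0.5, 20), runif(20)),
                    sites = c("self", "const", "noise"))
  me <- compute_me(beta, "self")
  trait <- rank(me$scores)
  out <- screen_key_sites(beta, rownames(beta), me, trait,
                          mm_threshold = 0.9, gs_threshold = 0.9)
  self_row <- out[out$site_id == "self", ]
  expect_equal(self_row$mm, 1, tolerance = 1e-12)
  expect_equal(self_row$gs, 1, tolerance = 1e-12)
  expect_true(self_row$passes)
  const_row <- out[out$site_id == "const", ]
  expect_true(is.na(const_row$mm))
  expect_false(const_row$passes)
  # boundary: a threshold equal to the attained |mm| fails (strict >)
  noise_mm <- abs(out$mm[out$site_id == "noise"])
  out2 <- screen_key_sites(beta, "noise", me, trait,
                           mm_threshold = noise_mm, gs_threshold = 0)
  expect_false(out2$passes)
})

test_that("screen results equal brute-force enumeration over all sites", {
  ds <- generate_dataset(synth_config(n_case = 40, n_control = 40), seed = 68)
  cs <- ds$clinical$group == "case"
  beta <- ds$beta[, cs]
  trait <- ds$clinical$stage_N[cs]
  sites <- names(ds$truth$site_module)[ds$truth$site_module == 1]
  me <- compute_me(beta, sites)
  out <- screen_key_sites(beta, sites, me, trait)
  brute <- vapply(sites, function(s) {
    mm <- cor(beta[s, ], me$scores)
    gs <- cor(beta[s, ], trait, method = "spearman")
    isTRUE(abs(mm) > 0.85 && abs(gs) > 0.17)
  }, logical(1))
  expect_identical(out$passes, unname(brute))
})

test_that("methylation-expression correlation behaves under monotone maps", {
  set.seed(69)
  b <- runif(30, 0.1, 0.9)
  expect_equal(correlate_meth_expr(b, exp(b))$rho, 1, tolerance = 1e-12)
  expect_equal(correlate_meth_expr(b, -b)$rho, -1, tolerance = 1e-12)
  expect_error(correlate_meth_expr(b[1:4], b[1:4]), "at least 5")
  # p-values are roughly uniform under independence
  set.seed(70)
  ps <- replicate(200, correlate_meth_expr(runif(30), runif(30))$p)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
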
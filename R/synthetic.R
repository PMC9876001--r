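#' Configuration for the synthetic methylation cohort generator
#'
#' Defaults describe a balanced two-arm cohort of 100 cases and 100
#' controls with 4 planted gene modules of 30 genes, 4 CpG sites per gene.
#' Within a module every site loads (0.8) on a per-sample latent factor;
#' site values are mapped to beta through a logistic transform so beta stays
#' strictly inside (0, 1). One designated site per gene is a true DMP:
#' controls sit at mean beta 0.05 and cases gain `delta_beta = 0.3`
#' (CpG-island hypermethylation pattern); latent group means are solved
#' numerically so the *realized* mean beta difference hits the target
#' despite the nonlinear transform. The prior network connects genes within
#' modules with probability 0.3 and between with 0.02. The ordinal trait
#' `stage_N` is a discretized monotone function of module 1's factor tuned
#' to Spearman rho 0.5; survival times are exponential with hazard ratio 2
#' for samples above the prognostic site's median beta; per-gene expression
#' is negatively correlated (rho -0.5) with the gene's first site.
#'
#' @param n_case,n_control Samples per arm.
#' @param n_modules,genes_per_module,sites_per_gene Planted structure.
#' @param dmp_sites_per_gene True DMPs per gene (0 = null data).
#' @param loading Within-module latent-factor loading.
#' @param noise_sd Site-level latent noise standard deviation.
#' @param signal_scale Overall latent signal scale; 0.5 keeps within-group
#'   beta dispersion in the range typical of 450K-style arrays (sd < ~0.1).
#' @param baseline_beta_range Range of target mean beta for non-DMP sites.
#' @param delta_beta Planted case-control difference in mean beta at DMP
#'   sites.
#' @param dmp_baseline Control-arm mean beta at DMP sites.
#' @param p_in,p_out Within-/between-module prior edge probabilities.
#' @param trait_module Module whose factor drives `stage_N`.
#' @param trait_target_rho Target Spearman between `stage_N` and the
#'   driving factor.
#' @param hazard_ratio Hazard multiplier for high methylation at the
#'   prognostic site.
#' @param base_hazard,censor_rate Exponential event and censoring rates
#'   (per day).
#' @param expr_rho Magnitude of the negative methylation-expression
#'   Spearman correlation.
#' @return Validated list of class `synth_config`.
#' @export
synth_config <- function(n_case = 100L, n_control = 100L,
                         n_modules = 4L, genes_per_module = 30L,
                         sites_per_gene = 4L, dmp_sites_per_gene = 1L,
                         loading = 0.8, noise_sd = 0.3, signal_scale = 0.5,
                         baseline_beta_range = c(0.2, 0.8),
                         delta_beta = 0.3, dmp_baseline = 0.05,
                         p_in = 0.3, p_out = 0.02,
                         trait_module = 1L, trait_target_rho = 0.5,
                         hazard_ratio = 2.0, base_hazard = 0.001,
                         censor_rate = 0.000125, expr_rho = 0.5) {
  cfg <- as.list(environment())
  if (cfg$n_case + cfg$n_control < 12L) stop("need >= 12 samples in total")
  if (cfg$n_modules < 2L) stop("need >= 2 modules")
  if (cfg$sites_per_gene < 1L) stop("need >= 1 site per gene")
  if (cfg$dmp_sites_per_gene > cfg$sites_per_gene)
    stop("dmp_sites_per_gene cannot exceed sites_per_gene")
  if (cfg$p_in <= cfg$p_out)
    warning("p_in <= p_out: planted modules will not be recoverable")
  if (cfg$dmp_baseline + cfg$delta_beta >= 1)
    stop("dmp_baseline + delta_beta must stay below 1")
  structure(cfg, class = "synth_config")
}

# E[plogis(mu + sigma Z)], Z ~ N(0,1), by fixed-grid quadrature
expected_beta <- function(mu, sigma) {
  z <- seq(-6, 6, length.out = 241L)
  w <- stats::dnorm(z)
  sum(stats::plogis(mu + sigma * z) * w) / sum(w)
}

# latent mean giving a target mean beta under N(0, sigma^2) latent noise
latent_mean_for_beta <- function(target, sigma) {
  stats::uniroot(function(mu) expected_beta(mu, sigma) - target,
                 interval = c(-12, 12), tol = 1e-9)$root
}

# Spearman between the binned 3-level trait and the driving factor is
# attenuated by ~0.868 relative to the latent Pearson correlation
# (rank conversion + 0.5/0.3/0.2 binning); invert that attenuation.
trait_latent_rho <- function(target) min(0.99, target / 0.868)

#' Generate a complete synthetic methylation dataset with ground truth
#'
#' Emulates the statistical structure the pipeline assumes: a beta matrix
#' with planted co-methylation modules, case/control mean shifts at
#' designated DMP sites, a module-linked ordinal trait, survival driven by
#' one prognostic site, a modular prior gene network and a
#' methylation-anticorrelated expression matrix. One master seed drives
#' independent sub-streams per component, so regeneration from the same
#' (config, seed) pair is bit-identical.
#'
#' @param config A [synth_config()].
#' @param seed Integer master seed.
#' @return List of class `synthetic_dataset` with elements `beta`,
#'   `annotation`, `clinical`, `prior`, `expression` and `truth`
#'   (a `synthetic_truth` carrying the planted structure and all
#'   parameters).
#' @export
generate_dataset <- function(config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  ss <- sample.int(2147483646L, 9L)

  n_s <- config$n_case + config$n_control
  sample_ids <- sprintf("S%04d", seq_len(n_s))
  group <- rep(c("case", "control"), c(config$n_case, config$n_control))
  n_g <- config$n_modules * config$genes_per_module
  gene_ids <- sprintf("GENE%04d", seq_len(n_g))
  gene_module <- rep(seq_len(config$n_modules), each = config$genes_per_module)
  names(gene_module) <- gene_ids
  n_sites <- n_g * config$sites_per_gene
  site_ids <- sprintf("cg%08d", seq_len(n_sites))
  site_gene <- rep(gene_ids, each = config$sites_per_gene)
  site_module <- gene_module[site_gene]
  is_dmp <- rep(seq_len(config$sites_per_gene) <= config$dmp_sites_per_gene,
                times = n_g)

  sigma_tot <- config$signal_scale *
    sqrt(config$loading^2 + config$noise_sd^2)

  # latent factors and site noise
  set.seed(ss[1L])
  z <- matrix(stats::rnorm(config$n_modules * n_s), config$n_modules, n_s)
  set.seed(ss[2L])
  noise <- matrix(stats::rnorm(n_sites * n_s, sd = config$noise_sd),
                  n_sites, n_s)
  set.seed(ss[3L])
  base_target <- stats::runif(n_sites, config$baseline_beta_range[1L],
                              config$baseline_beta_range[2L])
  baseline <- stats::qlogis(base_target)
  mu_ctrl <- latent_mean_for_beta(config$dmp_baseline, sigma_tot)
  mu_case <- latent_mean_for_beta(config$dmp_baseline + config$delta_beta,
                                  sigma_tot)
  base_mat <- matrix(baseline, n_sites, n_s)
  if (any(is_dmp) && config$delta_beta != 0) {
    base_mat[is_dmp, group == "case"] <- mu_case
    base_mat[is_dmp, group == "control"] <- mu_ctrl
  } else if (any(is_dmp)) {
    mu0 <- latent_mean_for_beta(config$dmp_baseline, sigma_tot)
    base_mat[is_dmp, ] <- mu0
  }
  signal <- config$loading * z[site_module, , drop = FALSE] + noise
  latent <- base_mat + config$signal_scale * signal
  beta <- pmin(pmax(stats::plogis(latent), 0.01), 0.99)
  dimnames(beta) <- list(site_ids, sample_ids)

  annotation <- data.frame(site_id = site_ids, gene_symbol = site_gene,
                           chromosome = paste0("chr", (site_module %% 22) + 1L),
                           position = seq_len(n_sites) * 1000L,
                           stringsAsFactors = FALSE)

  # prior network: planted stochastic block model over genes
  set.seed(ss[4L])
  pairs <- utils::combn(n_g, 2L)
  same <- gene_module[pairs[1L, ]] == gene_module[pairs[2L, ]]
  p_edge <- ifelse(same, config$p_in, config$p_out)
  keep <- stats::runif(ncol(pairs)) < p_edge
  prior <- prior_network(data.frame(gene_a = gene_ids[pairs[1L, keep]],
                                    gene_b = gene_ids[pairs[2L, keep]],
                                    stringsAsFactors = FALSE),
                         source = "synthetic")

  # ordinal trait N driven by one module's factor
  set.seed(ss[5L])
  r_lat <- trait_latent_rho(config$trait_target_rho)
  lat_n <- r_lat * z[config$trait_module, ] +
    sqrt(1 - r_lat^2) * stats::rnorm(n_s)
  stage_N <- cut(lat_n, c(-Inf, stats::qnorm(0.5), stats::qnorm(0.8), Inf),
                 labels = FALSE) - 1L

  # remaining clinical covariates, generated independently
  set.seed(ss[6L])
  age <- round(stats::rnorm(n_s, 66, 10))
  stage_T <- sample(1:4, n_s, replace = TRUE, prob = c(0.15, 0.35, 0.35, 0.15))
  stage_M <- stats::rbinom(n_s, 1L, 0.2)

  # survival: hazard multiplied for samples above the prognostic site's
  # median beta
  prognostic_site <- if (any(is_dmp)) {
    site_ids[is_dmp & site_module == config$trait_module][1L]
  } else NA_character_
  rate <- rep(config$base_hazard, n_s)
  if (!is.na(prognostic_site)) {
    high <- beta[prognostic_site, ] > stats::median(beta[prognostic_site, ])
    rate[high] <- rate[high] * config$hazard_ratio
  }
  set.seed(ss[7L])
  t_event <- stats::rexp(n_s, rate)
  t_cens <- if (config$censor_rate > 0) {
    stats::rexp(n_s, config$censor_rate)
  } else rep(Inf, n_s)
  time <- round(pmin(t_event, t_cens), 1)
  event <- as.integer(t_event <= t_cens)

  clinical <- data.frame(sample_id = sample_ids, group = group,
                         event = event, time = time, age = age,
                         stage_T = stage_T, stage_N = stage_N,
                         stage_M = stage_M, stringsAsFactors = FALSE)

  # expression: per gene, anticorrelated with its first site's methylation
  set.seed(ss[8L])
  first_site <- match(gene_ids, site_gene)
  r_e <- 2 * sin(pi * config$expr_rho / 6)
  site_lat <- latent[first_site, , drop = FALSE]
  site_lat <- (site_lat - rowMeans(site_lat)) /
    apply(site_lat, 1L, stats::sd)
  expression <- -r_e * site_lat +
    sqrt(1 - r_e^2) * matrix(stats::rnorm(n_g * n_s), n_g, n_s)
  dimnames(expression) <- list(gene_ids, sample_ids)

  truth <- structure(list(
    module = gene_module,
    site_module = stats::setNames(site_module, site_ids),
    dmp_sites = site_ids[is_dmp & config$delta_beta != 0],
    delta_beta = config$delta_beta,
    trait_module = config$trait_module,
    trait_target_rho = config$trait_target_rho,
    prognostic_site = prognostic_site,
    hazard_ratio = config$hazard_ratio,
    seed = seed,
    config = unclass(config)), class = "synthetic_truth")

  structure(list(beta = beta, annotation = annotation, clinical = clinical,
                 prior = prior, expression = expression, truth = truth),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly. Files: `beta.tsv`, `annotation.tsv`,
#'   `clinical.tsv`, `prior_network.csv`, `expression.tsv`, `truth.json`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_beta_matrix(dataset$beta, file.path(dir, "beta.tsv"))
  utils::write.table(dataset$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_clinical(dataset$clinical, file.path(dir, "clinical.tsv"))
  utils::write.table(
    data.frame(Source = dataset$prior$edges$gene_a,
               Target = dataset$prior$edges$gene_b),
    file.path(dir, "prior_network.csv"),
    sep = ",", quote = FALSE, row.names = FALSE)
  df <- data.frame(gene_symbol = rownames(dataset$expression),
                   format(dataset$expression, digits = 10, trim = TRUE),
                   check.names = FALSE)
  utils::write.table(df, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(dataset$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate a weighted network with planted modules
#'
#' Stochastic-block-model edges (within probability `p_in`, between
#' `p_out`) with edge weights drawn around `w_in` / `w_out` and clipped to
#' \[0, 1\] — the benchmark graph used to assess module recovery in
#' isolation from the methylation model.
#'
#' @param n_modules,genes_per_module Planted structure (defaults 4 x 30).
#' @param p_in,p_out Edge probabilities (defaults 0.3 / 0.02).
#' @param w_in,w_out Mean within-/between-module weights (0.7 / 0.1).
#' @param w_sd Weight jitter standard deviation (0.05).
#' @param seed Integer seed.
#' @return List with `net` (a `weighted_gene_network`) and `membership`
#'   (named integer truth vector).
#' @export
simulate_planted_network <- function(n_modules = 4L, genes_per_module = 30L,
                                     p_in = 0.3, p_out = 0.02,
                                     w_in = 0.7, w_out = 0.1, w_sd = 0.05,
                                     seed = 1L) {
  set.seed(seed)
  n_g <- n_modules * genes_per_module
  genes <- sprintf("GENE%04d", seq_len(n_g))
  membership <- rep(seq_len(n_modules), each = genes_per_module)
  names(membership) <- genes
  pairs <- utils::combn(n_g, 2L)
  same <- membership[pairs[1L, ]] == membership[pairs[2L, ]]
  keep <- stats::runif(ncol(pairs)) < ifelse(same, p_in, p_out)
  mean_w <- ifelse(same[keep], w_in, w_out)
  w <- pmin(pmax(stats::rnorm(sum(keep), mean_w, w_sd), 0.001), 1)
  edges <- data.frame(gene_a = genes[pairs[1L, keep]],
                      gene_b = genes[pairs[2L, keep]],
                      weight = w, stringsAsFactors = FALSE)
  list(net = weighted_network(edges, nodes = genes), membership = membership)
}

#' Recovery metrics against planted ground truth
#'
#' @param truth A `synthetic_truth` (or named module vector for
#'   `module_recovery_ari`).
#' @param partition Optional `module_partition` (or named assignment
#'   vector): scored by Adjusted Rand Index against the planted gene
#'   modules.
#' @param dmps Optional character vector of flagged DMP site ids: scored by
#'   precision/recall against the planted DMP set.
#' @param key_sites Optional character vector of screened key site ids:
#'   precision/recall against the planted DMP sites of the trait module.
#' @param assoc Optional [associate_traits()] result: checks that the
#'   planted driving module attains the largest `|rho|` with `trait` and
#'   that its sign is positive.
#' @param trait Trait name used with `assoc` (default `"stage_N"`).
#' @return Named list of the computed scores.
#' @export
truth_metrics <- function(truth, partition = NULL, dmps = NULL,
                          key_sites = NULL, assoc = NULL,
                          trait = "stage_N") {
  stopifnot(inherits(truth, "synthetic_truth"))
  out <- list()
  if (!is.null(partition))
    out$module_ari <- module_recovery_ari(partition, truth$module)
  if (!is.null(dmps))
    out <- c(out, stats::setNames(
      screen_metrics(dmps, truth$dmp_sites),
      c("dmp_precision", "dmp_recall")))
  if (!is.null(key_sites)) {
    planted <- truth$dmp_sites[truth$site_module[truth$dmp_sites] ==
                                 truth$trait_module]
    out <- c(out, stats::setNames(screen_metrics(key_sites, planted),
                                  c("key_precision", "key_recall")))
  }
  if (!is.null(assoc)) {
    sub <- assoc[assoc$trait == trait & !is.na(assoc$rho), , drop = FALSE]
    if (nrow(sub) > 0L) {
      best <- sub$module[which.max(abs(sub$rho))]
      drv <- as.character(truth$trait_module)
      out$trait_module_recovered <- identical(as.character(best), drv)
      rho_drv <- sub$rho[as.character(sub$module) == drv]
      out$trait_sign_consistent <- length(rho_drv) == 1L && rho_drv > 0
    }
  }
  out
}

#' @rdname truth_metrics
#' @param assignment Named gene -> module vector (or `module_partition`).
#' @param true_modules Named gene -> module truth vector.
#' @export
module_recovery_ari <- function(assignment, true_modules) {
  if (inherits(assignment, "module_partition"))
    assignment <- assignment$assignment
  common <- intersect(names(assignment), names(true_modules))
  if (length(common) == 0L) stop("no shared gene identifiers")
  mclust::adjustedRandIndex(assignment[common], true_modules[common])
}

#' @rdname truth_metrics
#' @param selected,planted Character vectors of selected and planted ids.
#' @export
screen_metrics <- function(selected, planted) {
  tp <- length(intersect(selected, planted))
  list(precision = if (length(selected) > 0L) tp / length(selected) else NA_real_,
       recall = if (length(planted) > 0L) tp / length(planted) else NA_real_)
}
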
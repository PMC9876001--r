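#' Full-pipeline configuration
#'
#' Stage parameters with defaults set to the published analysis values
#' where those exist: fold-change gate 0.235 with raw p < 0.05 for DMPs,
#' 90% retained PCA variance per gene, minimum module size 100, MM/GS
#' screening gates 0.85/0.17, significance background at p < 0.05, median
#' survival split with p < 0.05 flagging. Unknown arguments are rejected.
#'
#' @param zero_policy Site-cleaning policy ([clean_sites()]).
#' @param cut_quantile Outlier tree-cut quantile ([detect_outlier_samples()]);
#'   `NA` disables outlier removal.
#' @param fc_threshold,p_threshold,use_adjusted,fc_measure DMP gates
#'   ([select_dmps()]).
#' @param test_scale Per-site test scale ([test_sites()]).
#' @param dmg_policy Prior-network restriction policy
#'   ([restrict_prior_network()]).
#' @param var_retained Per-gene PCA retention ([reduce_gene_features()]).
#' @param cca_method Edge-weight summary ([canonical_weight()]).
#' @param seed,resolution Module detection ([detect_modules()]).
#' @param min_module_size Small-module filter ([filter_small_modules()]).
#' @param me_alpha Significance background for eigengenes
#'   ([significant_sites()]).
#' @param mm_threshold,gs_threshold Key-site screen gates
#'   ([screen_key_sites()]).
#' @param target_trait Trait used to pick the key module and screen sites.
#' @param trait_samples `"case"` (default) restricts eigengene/trait
#'   analysis to case samples; `"all"` uses every aligned sample.
#' @param split_quantile,surv_alpha Survival stage ([key_site_survival()]).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(zero_policy = "any-zero", cut_quantile = 0.95,
                            fc_threshold = 0.235, p_threshold = 0.05,
                            use_adjusted = FALSE, fc_measure = "ratio",
                            test_scale = "beta", dmg_policy = "both",
                            var_retained = 0.9, cca_method = "first",
                            seed = 1L, resolution = 1,
                            min_module_size = 100L, me_alpha = 0.05,
                            mm_threshold = 0.85, gs_threshold = 0.17,
                            target_trait = "stage_N", trait_samples = "case",
                            split_quantile = 0.5, surv_alpha = 0.05) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Keys must match [pipeline_config()] arguments; unknown keys are
#' rejected.
#'
#' @param path JSON file of key-value pairs.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_json <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

run_stage <- function(name, log, expr) {
  log(sprintf("stage %-10s started", name))
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the complete weighted-methylation-network analysis
#'
#' Executes cleaning, differential methylation, CCA network construction,
#' module detection, trait association, key-site screening and survival
#' evaluation in order, writing every intermediate artifact (plain TSV/JSON)
#' plus a run manifest and log into `out_dir`. Any stage error aborts with
#' the stage name.
#'
#' @param beta_path,annotation_path,clinical_path,prior_path Input files in
#'   the formats of [read_beta_matrix()], [read_clinical()],
#'   [read_prior_network()].
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the manifest and principal stage results.
#' @export
run_all <- function(beta_path, annotation_path, clinical_path, prior_path,
                    out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
    message("[methccanet] ", msg)
  }

  inputs <- run_stage("read", log, {
    for (p in c(beta_path, annotation_path, clinical_path, prior_path))
      if (!file.exists(p)) stop("input file not found: ", p)
    bm <- read_beta_matrix(beta_path, annotation_path)
    list(beta = bm$beta, annotation = bm$annotation,
         clin = read_clinical(clinical_path),
         prior = read_prior_network(prior_path))
  })
  annotation <- inputs$annotation

  aligned <- run_stage("align", log,
                       align_samples(inputs$beta, inputs$clin))
  beta <- aligned$beta
  clin <- aligned$clin
  log(sprintf("aligned %d samples (%d case / %d control)",
              ncol(beta), sum(clin$group == "case"),
              sum(clin$group != "case")))

  outliers <- character(0)
  if (!is.na(config$cut_quantile)) {
    outliers <- run_stage("outliers", log, {
      case_ids <- clin$sample_id[clin$group == "case"]
      if (length(case_ids) >= 3L) {
        detect_outlier_samples(beta[, case_ids, drop = FALSE],
                               config$cut_quantile)
      } else character(0)
    })
    if (length(outliers) > 0L) {
      keep <- !clin$sample_id %in% outliers
      clin <- clin[keep, , drop = FALSE]
      beta <- beta[, clin$sample_id, drop = FALSE]
    }
    log(sprintf("removed %d outlier sample(s)", length(outliers)))
  }

  beta <- run_stage("clean", log,
                    suppressMessages(clean_sites(beta, config$zero_policy)))
  log(sprintf("%d sites retained after cleaning", nrow(beta)))

  dmp <- run_stage("dmp", log, {
    res <- test_sites(beta, clin$group, scale = config$test_scale,
                      annotation = annotation)
    sel <- select_dmps(res, config$fc_threshold, config$p_threshold,
                       config$use_adjusted, config$fc_measure)
    genes <- sites_to_genes(sel, annotation)
    utils::write.table(res, file.path(out_dir, "dmp_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(genes, file.path(out_dir, "dmgs.txt"))
    list(results = res, dmps = sel, dmgs = genes)
  })
  log(sprintf("%d DMPs in %d DMGs", nrow(dmp$dmps), length(dmp$dmgs)))

  net <- run_stage("network", log, {
    restricted <- restrict_prior_network(inputs$prior, dmp$dmgs,
                                         config$dmg_policy)
    genes <- unique(c(restricted$edges$gene_a, restricted$edges$gene_b))
    blocks <- list()
    for (g in genes) {
      blk <- tryCatch(reduce_gene_features(beta, annotation, g,
                                           config$var_retained),
                      error = function(e) NULL)
      if (!is.null(blk)) blocks[[g]] <- blk
    }
    if (length(blocks) < length(genes))
      log(sprintf("%d gene(s) without usable feature block dropped",
                  length(genes) - length(blocks)))
    built <- suppressWarnings(
      build_weighted_network(restricted, blocks, config$cca_method))
    write_weighted_network(built,
                           tsv_path = file.path(out_dir, "network_edges.tsv"),
                           graphml_path = file.path(out_dir, "network.graphml"))
    built
  })
  log(sprintf("weighted network: %d genes, %d edges; largest component %d genes",
              length(net$nodes), nrow(net$edges), length(analysis_genes(net))))

  partition <- run_stage("modules", log, {
    p <- detect_modules(net, seed = config$seed,
                        resolution = config$resolution)
    p <- filter_small_modules(p, config$min_module_size)
    utils::write.table(
      data.frame(gene = names(p$assignment), module = p$assignment),
      file.path(out_dir, "modules.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(sizes = p$sizes, modularity_q = p$modularity_q,
           seed = p$seed, resolution = p$resolution),
      file.path(out_dir, "partition.json"), auto_unbox = TRUE, digits = NA)
    p
  })
  log(sprintf("%d module(s) retained, Q = %.4f",
              length(partition$sizes), partition$modularity_q))

  traits <- run_stage("traits", log, {
    sig <- significant_sites(beta, clin$group, config$me_alpha,
                             scale = config$test_scale)
    use <- if (config$trait_samples == "case") clin$group == "case" else
      rep(TRUE, nrow(clin))
    beta_t <- beta[, use, drop = FALSE]
    clin_t <- clin[use, , drop = FALSE]
    mes <- list()
    mod_sites <- list()
    for (m in sort(unique(partition$assignment))) {
      genes_m <- names(partition$assignment)[partition$assignment == m]
      sites_m <- intersect(
        annotation$site_id[annotation$gene_symbol %in% genes_m], sig)
      if (length(sites_m) == 0L) {
        log(sprintf("module %d has no significant sites; skipped", m))
        next
      }
      mod_sites[[as.character(m)]] <- sites_m
      mes[[as.character(m)]] <- compute_me(beta_t, sites_m)
    }
    if (length(mes) == 0L) stop("no module has significant sites")
    assoc <- associate_traits(mes, clin_t)
    utils::write.table(assoc, file.path(out_dir, "module_trait.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(sig = sig, mes = mes, mod_sites = mod_sites, assoc = assoc,
         beta_t = beta_t, clin_t = clin_t)
  })
  log(sprintf("%d significant sites; %d module eigengene(s)",
              length(traits$sig), length(traits$mes)))

  keys <- run_stage("key_sites", log, {
    sub <- traits$assoc[traits$assoc$trait == config$target_trait &
                          !is.na(traits$assoc$rho), , drop = FALSE]
    if (nrow(sub) == 0L)
      stop("no module association available for trait ", config$target_trait)
    target_module <- sub$module[which.max(abs(sub$rho))]
    screened <- screen_key_sites(
      traits$beta_t, traits$mod_sites[[target_module]],
      traits$mes[[target_module]],
      traits$clin_t[[config$target_trait]],
      config$mm_threshold, config$gs_threshold,
      annotation = annotation)
    utils::write.table(cbind(module = target_module, screened),
                       file.path(out_dir, "key_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(target_module = target_module, screened = screened,
         key_sites = screened$site_id[screened$passes])
  })
  log(sprintf("target module %s: %d key site(s) pass |MM| > %.2f & |GS| > %.2f",
              keys$target_module, length(keys$key_sites),
              config$mm_threshold, config$gs_threshold))

  surv <- run_stage("survival", log, {
    tab <- key_site_survival(keys$key_sites, beta, clin,
                             quantile = config$split_quantile,
                             alpha = config$surv_alpha,
                             annotation = annotation)
    utils::write.table(tab, file.path(out_dir, "survival_key_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tab
  })
  log(sprintf("%d key site(s) flagged prognostic at p < %.2f",
              sum(surv$flagged, na.rm = TRUE), config$surv_alpha))

  manifest <- list(
    package = "methccanet",
    version = as.character(utils::packageVersion("methccanet")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = unclass(config),
    counts = list(
      samples_aligned = ncol(aligned$beta),
      outliers_removed = length(outliers),
      samples_final = ncol(beta),
      sites_raw = nrow(inputs$beta),
      sites_clean = nrow(beta),
      dmps = nrow(dmp$dmps),
      dmgs = length(dmp$dmgs),
      network_genes = length(net$nodes),
      network_edges = nrow(net$edges),
      largest_component = length(analysis_genes(net)),
      modules = length(partition$sizes),
      module_sizes = partition$sizes,
      modularity_q = partition$modularity_q,
      significant_sites = length(traits$sig),
      target_module = keys$target_module,
      key_sites = length(keys$key_sites),
      flagged_survival = sum(surv$flagged, na.rm = TRUE)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(out_dir = out_dir, manifest = manifest, dmp = dmp,
                 network = net, partition = partition, traits = traits,
                 key_sites = keys, survival = surv))
}
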
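#' Logit (M-value) transform of beta values
#'
#' @param beta Beta values in \[0, 1\].
#' @param eps Guard applied at 0/1 before the logit (default 1e-6).
#' @return `log2(beta / (1 - beta))` with `beta` clamped to
#'   `[eps, 1 - eps]`.
#' @export
beta_to_mvalue <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Per-site two-group differential methylation test
#'
#' Welch's unequal-variance t-test is applied to every site, on the beta
#' scale by default or on M-values. Group means, the beta difference
#' `delta_beta = mean_case - mean_control` and `log_fc = log2(mean_case /
#' mean_control)` are always reported on the beta scale. Sites where both
#' groups have zero variance receive `t = 0`, `p = 1` (with a warning).
#'
#' @param beta Cleaned sites x samples beta matrix.
#' @param groups Character/factor vector over columns of `beta` with the
#'   case and control labels.
#' @param case,control Labels identifying the two groups (default
#'   `"case"`/`"control"`).
#' @param scale `"beta"` (default) or `"mvalue"` test scale.
#' @param annotation Optional annotation data.frame used to attach gene
#'   symbols to the result.
#' @return Data.frame in input site order with columns `site_id`,
#'   `gene_symbol`, `mean_case`, `mean_control`, `delta_beta`, `log_fc`,
#'   `t_stat`, `df`, `p_value`, `p_adj` (Benjamini-Hochberg).
#' @export
test_sites <- function(beta, groups, case = "case", control = "control",
                       scale = c("beta", "mvalue"), annotation = NULL) {
  scale <- match.arg(scale)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(beta))
  i1 <- which(groups == case)
  i2 <- which(groups == control)
  if (length(i1) < 2L || length(i2) < 2L)
    stop("each group needs >= 2 samples")
  x <- if (scale == "beta") beta else beta_to_mvalue(beta)
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, i2, drop = FALSE])
  v1 <- rowSums((x[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((x[, i2, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " site(s) with zero variance in both groups; p set to 1")
    t_stat[degenerate] <- 0
    df[degenerate] <- n1 + n2 - 2
    p[degenerate] <- 1
  }
  bc <- rowMeans(beta[, i1, drop = FALSE])
  bn <- rowMeans(beta[, i2, drop = FALSE])
  res <- data.frame(site_id = rownames(beta),
                    gene_symbol = NA_character_,
                    mean_case = bc, mean_control = bn,
                    delta_beta = bc - bn,
                    log_fc = log2(bc / bn),
                    t_stat = t_stat, df = df,
                    p_value = p, p_adj = adjust_bh(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(annotation))
    res$gene_symbol <- annotation$gene_symbol[match(res$site_id,
                                                    annotation$site_id)]
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")` preserving input
#' order; adjusted values are clipped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values in the original order (empty in, empty out).
#' @export
adjust_bh <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Select differentially methylated positions
#'
#' A site is flagged when its fold-change gate and p-value gate both pass
#' (strict inequalities). With `fc_measure = "ratio"` (default) the gate is
#' `|log2 FC| > |log2(fc_threshold)|` where FC is the ratio of group mean
#' betas; with `"delta"` it is `|delta_beta| > fc_threshold`, reading the
#' threshold directly as a mean beta difference (the convention of
#' limma-style logFC computed on a beta matrix). The p gate uses the raw
#' p-value by default, or BH-adjusted values with `use_adjusted = TRUE`.
#'
#' @param results Data.frame from [test_sites()].
#' @param fc_threshold Fold-change threshold (default 0.235).
#' @param p_threshold P-value threshold (default 0.05).
#' @param use_adjusted Gate on `p_adj` instead of `p_value`.
#' @param fc_measure `"ratio"` (default) or `"delta"`.
#' @return The flagged subset of `results` with an `is_dmp` column.
#' @export
select_dmps <- function(results, fc_threshold = 0.235, p_threshold = 0.05,
                        use_adjusted = FALSE,
                        fc_measure = c("ratio", "delta")) {
  fc_measure <- match.arg(fc_measure)
  fc_pass <- if (fc_measure == "ratio") {
    abs(results$log_fc) > abs(log2(fc_threshold))
  } else {
    abs(results$delta_beta) > fc_threshold
  }
  p <- if (use_adjusted) results$p_adj else results$p_value
  flag <- fc_pass & p < p_threshold
  flag[is.na(flag)] <- FALSE
  out <- results[flag, , drop = FALSE]
  out$is_dmp <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Map differentially methylated positions to genes
#'
#' @param dmps Data.frame of flagged sites (from [select_dmps()]).
#' @param annotation Site annotation data.frame (`site_id`, `gene_symbol`).
#' @return Character vector of unique gene symbols; sites absent from the
#'   annotation are skipped with a warning.
#' @export
sites_to_genes <- function(dmps, annotation) {
  if (nrow(dmps) == 0L) return(character(0))
  genes <- annotation$gene_symbol[match(dmps$site_id, annotation$site_id)]
  miss <- is.na(genes)
  if (any(miss))
    warning(sum(miss), " flagged site(s) missing from annotation; excluded")
  unique(genes[!miss])
}
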
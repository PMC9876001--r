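#' Sites with a significant case/control difference
#'
#' Re-runs the per-site two-group test and returns the ids of sites with
#' raw `p < alpha`. This defines the reduced "background" used for module
#' eigengenes and key-site screening, keeping trait association focused on
#' sites that actually separate the groups; `alpha = 1` keeps every site.
#'
#' @param beta Cleaned, aligned sites x samples beta matrix.
#' @param groups Case/control labels over columns.
#' @param alpha Raw p-value cutoff (default 0.05).
#' @param ... Passed to [test_sites()].
#' @return Character vector of site ids.
#' @export
significant_sites <- function(beta, groups, alpha = 0.05, ...) {
  if (alpha >= 1) return(rownames(beta))
  res <- test_sites(beta, groups, ...)
  res$site_id[res$p_value < alpha]
}

#' Module eigengene: first principal component of a module's sites
#'
#' The sample x site submatrix is column-centered and decomposed; the first
#' principal-component score vector summarizes the module per sample. Its
#' sign is fixed so that the correlation with the module's mean beta across
#' sites is non-negative (higher eigengene = higher methylation).
#'
#' @param beta Sites x samples beta matrix.
#' @param sites Site ids belonging to the module.
#' @return A `module_eigengene`: list with `scores` (named per-sample
#'   vector, centered), `explained_variance` (fraction for PC1), `n_sites`,
#'   `sign_flipped`.
#' @export
compute_me <- function(beta, sites) {
  sites <- intersect(sites, rownames(beta))
  if (length(sites) == 0L) stop("module has no sites in the beta matrix")
  x <- t(beta[sites, , drop = FALSE])
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  scores <- pr$x[, 1L]
  ev <- pr$sdev[1L]^2 / sum(pr$sdev^2)
  mean_beta <- colMeans(beta[sites, , drop = FALSE])
  flipped <- FALSE
  r <- suppressWarnings(stats::cor(scores, mean_beta))
  if (!is.na(r) && r < 0) {
    scores <- -scores
    flipped <- TRUE
  }
  structure(list(scores = scores, explained_variance = ev,
                 n_sites = length(sites), sign_flipped = flipped),
            class = "module_eigengene")
}

#' Spearman association between module eigengenes and clinical traits
#'
#' For every module x trait pair the Spearman rank correlation (average
#' ranks for ties) and its asymptotic p-value are computed on pairwise
#' complete observations. Constant traits give `NA` with a warning.
#'
#' @param mes Named list of `module_eigengene`s (names = module labels).
#' @param clin Clinical data.frame aligned, in order, with the eigengene
#'   samples.
#' @param traits Clinical columns to associate (default `event`, `age`,
#'   `stage_M`, `stage_N`, `stage_T`, restricted to those present).
#' @param adjust Apply BH adjustment across all cells (`p_adj` column).
#' @return Data.frame with columns `module`, `trait`, `rho`, `p`, `n`
#'   (class `association_matrix`).
#' @export
associate_traits <- function(mes, clin,
                             traits = c("event", "age", "stage_M",
                                        "stage_N", "stage_T"),
                             adjust = FALSE) {
  traits <- intersect(traits, colnames(clin))
  if (length(traits) == 0L) stop("none of the requested traits are present")
  rows <- list()
  for (mod in names(mes)) {
    scores <- mes[[mod]]$scores
    if (length(scores) != nrow(clin))
      stop("eigengene and clinical table cover different samples")
    for (tr in traits) {
      y <- clin[[tr]]
      ok <- !is.na(y) & !is.na(scores)
      n <- sum(ok)
      if (n < 3L || stats::sd(y[ok]) == 0) {
        warning("trait ", tr, " constant or too few observations; rho = NA")
        rho <- NA_real_; p <- NA_real_
      } else {
        ct <- suppressWarnings(
          stats::cor.test(scores[ok], y[ok], method = "spearman",
                          exact = FALSE))
        rho <- unname(ct$estimate); p <- ct$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        module = mod, trait = tr, rho = rho, p = p, n = n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- adjust_bh(out$p)
  rownames(out) <- NULL
  class(out) <- c("association_matrix", "data.frame")
  out
}

#' Reshape an association result to a modules x traits matrix
#'
#' @param assoc Result of [associate_traits()].
#' @param value `"rho"` (default) or `"p"`.
#' @return Numeric matrix, rows = modules, columns = traits.
#' @export
association_matrix <- function(assoc, value = "rho") {
  mods <- unique(assoc$module)
  trs <- unique(assoc$trait)
  m <- matrix(NA_real_, length(mods), length(trs),
              dimnames = list(mods, trs))
  m[cbind(match(assoc$module, mods), match(assoc$trait, trs))] <- assoc[[value]]
  m
}

#' Screen key methylation sites by module membership and trait significance
#'
#' Module membership (MM) is the Pearson correlation between a site's beta
#' profile and the module eigengene (the co-expression-network convention);
#' trait (gene) significance (GS) is the Spearman correlation between the
#' site's beta and the (ordinal) trait. A site passes when `|MM| >
#' mm_threshold` and `|GS| > gs_threshold`, both strictly. Constant sites
#' get `NA` and fail.
#'
#' @param beta Sites x samples beta matrix.
#' @param sites Site ids of the module to screen.
#' @param me The module's `module_eigengene` (same samples as `beta`
#'   columns).
#' @param trait Numeric trait vector over the same samples.
#' @param mm_threshold,gs_threshold Screening thresholds (defaults 0.85 and
#'   0.17).
#' @param mm_method,gs_method Correlation types (defaults `"pearson"` /
#'   `"spearman"`).
#' @param annotation Optional annotation to attach gene symbols.
#' @return Data.frame `site_id`, `gene_symbol`, `mm`, `gs`, `passes`.
#' @export
screen_key_sites <- function(beta, sites, me, trait,
                             mm_threshold = 0.85, gs_threshold = 0.17,
                             mm_method = "pearson", gs_method = "spearman",
                             annotation = NULL) {
  sites <- intersect(sites, rownames(beta))
  x <- beta[sites, , drop = FALSE]
  stopifnot(ncol(x) == length(me$scores), ncol(x) == length(trait))
  mm <- gs <- rep(NA_real_, length(sites))
  for (i in seq_along(sites)) {
    b <- x[i, ]
    if (stats::sd(b) == 0) next
    mm[i] <- stats::cor(b, me$scores, method = mm_method)
    gs[i] <- suppressWarnings(
      stats::cor(b, trait, method = gs_method, use = "pairwise.complete.obs"))
  }
  passes <- !is.na(mm) & !is.na(gs) &
    abs(mm) > mm_threshold & abs(gs) > gs_threshold
  out <- data.frame(site_id = sites, gene_symbol = NA_character_,
                    mm = mm, gs = gs, passes = passes,
                    stringsAsFactors = FALSE)
  if (!is.null(annotation))
    out$gene_symbol <- annotation$gene_symbol[match(sites, annotation$site_id)]
  out
}

#' Spearman correlation between a site's methylation and gene expression
#'
#' @param site_beta Beta values of one site over samples.
#' @param expression Expression values over the same samples (n >= 5).
#' @return List with `rho` and `p` (asymptotic).
#' @export
correlate_meth_expr <- function(site_beta, expression) {
  stopifnot(length(site_beta) == length(expression))
  if (length(site_beta) < 5L) stop("need at least 5 samples")
  ct <- suppressWarnings(
    stats::cor.test(site_beta, expression, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
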
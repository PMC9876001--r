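#' Remove zero-beta and incomplete methylation sites
#'
#' Failed probes on beta arrays show up as exact zeros; the default
#' `"any-zero"` policy drops a site if any sample carries a missing value or
#' a beta of exactly 0. The `"all-zero"` policy drops only sites that are
#' zero in every sample (missing-value rows are dropped under both
#' policies).
#'
#' @param beta Sites x samples beta matrix.
#' @param policy `"any-zero"` (default) or `"all-zero"`.
#' @return The filtered matrix; the number of dropped sites is reported via
#'   `message()`.
#' @export
clean_sites <- function(beta, policy = c("any-zero", "all-zero")) {
  policy <- match.arg(policy)
  has_na <- rowSums(is.na(beta)) > 0L
  zero <- beta == 0
  drop <- if (policy == "any-zero") {
    has_na | rowSums(zero, na.rm = TRUE) > 0L
  } else {
    has_na | rowSums(zero, na.rm = TRUE) == ncol(beta)
  }
  if (all(drop)) stop("clean_sites: all sites dropped")
  message(sprintf("clean_sites: dropped %d of %d sites (policy %s)",
                  sum(drop), nrow(beta), policy))
  beta[!drop, , drop = FALSE]
}

#' Flag outlier samples by hierarchical clustering
#'
#' Samples are clustered on Euclidean distance of their beta profiles with
#' average linkage (the convention of sample-tree QC in co-methylation
#' pipelines); the tree is cut at the given quantile of merge heights and
#' every sample outside the largest resulting cluster is reported as an
#' outlier. `cut_height_quantile = 1` never cuts the tree and returns no
#' outliers.
#'
#' @param beta Sites x samples beta matrix (>= 3 samples).
#' @param cut_height_quantile Quantile of merge heights at which to cut
#'   (default 0.95).
#' @return Character vector of outlier sample ids (possibly empty).
#' @export
detect_outlier_samples <- function(beta, cut_height_quantile = 0.95) {
  if (ncol(beta) < 3L) stop("detect_outlier_samples needs >= 3 samples")
  hc <- stats::hclust(stats::dist(t(beta)), method = "average")
  cut_h <- stats::quantile(hc$height, cut_height_quantile, names = FALSE)
  cl <- stats::cutree(hc, h = cut_h)
  sizes <- table(cl)
  main <- as.integer(names(sizes)[which.max(sizes)])
  colnames(beta)[cl != main]
}

#' Align a beta matrix and clinical table on common samples
#'
#' Both objects are restricted, in identical order, to the intersection of
#' their sample ids; samples missing any of the `required` clinical fields
#' are dropped (and reported), mirroring removal of clinically incomplete
#' samples before association analysis.
#'
#' @param beta Sites x samples beta matrix.
#' @param clin Clinical data.frame with a `sample_id` column.
#' @param required Clinical columns that must be non-missing (defaults to
#'   all fields used downstream that are present in `clin`).
#' @return List with aligned `beta` and `clin`.
#' @export
align_samples <- function(beta, clin,
                          required = c("group", "event", "time", "age",
                                       "stage_T", "stage_N", "stage_M")) {
  required <- intersect(required, colnames(clin))
  common <- intersect(colnames(beta), clin$sample_id)
  if (length(common) == 0L) stop("no samples shared by beta matrix and clinical table")
  clin <- clin[match(common, clin$sample_id), , drop = FALSE]
  if (length(required) > 0L) {
    complete <- rowSums(is.na(clin[required])) == 0L
    if (!all(complete))
      message(sprintf("align_samples: dropped %d sample(s) with missing clinical data",
                      sum(!complete)))
    clin <- clin[complete, , drop = FALSE]
  }
  if (nrow(clin) == 0L) stop("no samples left after removing incomplete clinical rows")
  beta <- beta[, clin$sample_id, drop = FALSE]
  rownames(clin) <- NULL
  list(beta = beta, clin = clin)
}
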
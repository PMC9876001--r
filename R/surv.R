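#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times, with
#' right censoring handled through the risk sets.
#'
#' @param times Non-negative follow-up times.
#' @param events 0/1 event indicators (1 = event).
#' @param group Optional label stored with the fit.
#' @return A `km_fit`: data.frame with one row per distinct observed time
#'   (`time`, `n_risk`, `n_event`, `n_censor`, `surv`), plus attributes
#'   `group` and `n`.
#' @export
km_estimate <- function(times, events, group = NA_character_) {
  stopifnot(length(times) == length(events), length(times) >= 1L)
  if (any(times < 0)) stop("negative follow-up time")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  tt <- sort(unique(times))
  n_risk <- vapply(tt, function(t) sum(times >= t), 0)
  n_event <- vapply(tt, function(t) sum(times == t & events == 1), 0)
  n_censor <- vapply(tt, function(t) sum(times == t & events == 0), 0)
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = tt, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, surv = surv)
  attr(out, "group") <- group
  attr(out, "n") <- length(times)
  class(out) <- c("km_fit", "data.frame")
  out
}

#' Split samples into high/low methylation groups at one site
#'
#' `"high"` when beta exceeds the cut value (default the median; ties go to
#' `"low"`), the usual convention for methylation Kaplan-Meier plots.
#'
#' @param site_beta Beta values of one site (>= 4 samples).
#' @param quantile Cut quantile (default 0.5 = median split).
#' @return Character vector of `"high"`/`"low"` labels.
#' @export
split_by_site <- function(site_beta, quantile = 0.5) {
  if (length(site_beta) < 4L) stop("need >= 4 samples to split")
  if (stats::sd(site_beta) == 0) stop("constant beta values: no split possible")
  cut <- stats::quantile(site_beta, quantile, names = FALSE)
  ifelse(site_beta > cut, "high", "low")
}

#' Two-sample log-rank test
#'
#' At each distinct pooled event time the expected events in group A are
#' `e_A = n_A d / n` with hypergeometric variance
#' `n_A n_B d (n - d) / (n^2 (n - 1))` (no continuity correction, matching
#' the default of standard survival software). The statistic
#' `(O_A - E_A)^2 / V` is referred to a chi-square with 1 df.
#'
#' @param times_a,events_a Follow-up and 0/1 event indicator, group A.
#' @param times_b,events_b Same for group B.
#' @return A `logrank_result`: list with `chi_square`, `df`, `p_value`,
#'   `observed`, `expected` (named per group), `n`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  stopifnot(length(times_a) >= 1L, length(times_b) >= 1L)
  times <- c(times_a, times_b)
  events <- c(events_a, events_b)
  grp_a <- rep(c(TRUE, FALSE), c(length(times_a), length(times_b)))
  if (sum(events) == 0) {
    warning("no events in either group; log-rank undefined, p = 1")
    return(structure(list(chi_square = 0, df = 1L, p_value = 1,
                          observed = c(A = 0, B = 0),
                          expected = c(A = 0, B = 0),
                          n = c(A = length(times_a), B = length(times_b))),
                     class = "logrank_result"))
  }
  ev_times <- sort(unique(times[events == 1]))
  o_a <- e_a <- v <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & grp_a)
    d <- sum(times == t & events == 1)
    d_a <- sum(times == t & events == 1 & grp_a)
    o_a <- o_a + d_a
    e_a <- e_a + n_a * d / n
    if (n > 1)
      v <- v + d * (n - d) / (n - 1) * (n_a / n) * (1 - n_a / n)
  }
  chi <- if (v > 0) (o_a - e_a)^2 / v else 0
  total <- sum(events)
  structure(list(chi_square = chi, df = 1L,
                 p_value = stats::pchisq(chi, 1L, lower.tail = FALSE),
                 observed = c(A = o_a, B = total - o_a),
                 expected = c(A = e_a, B = total - e_a),
                 n = c(A = length(times_a), B = length(times_b))),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chi-square = %.4f (df %d), p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  cat(sprintf("observed A/B: %g/%g, expected A/B: %.2f/%.2f\n",
              x$observed["A"], x$observed["B"],
              x$expected["A"], x$expected["B"]))
  invisible(x)
}

#' Survival screen of key methylation sites
#'
#' Each key site splits the cohort into high/low methylation groups
#' ([split_by_site()]) which are compared with the log-rank test; the table
#' is sorted by p-value and sites with `p < alpha` are flagged as
#' prognostic. Sites missing from the beta matrix (or unsplittable) yield an
#' `NA` row with a warning.
#'
#' @param site_ids Character vector of key site ids.
#' @param beta Sites x samples beta matrix.
#' @param clin Clinical data.frame aligned with the beta columns (`time`,
#'   `event`).
#' @param quantile Split quantile (default 0.5).
#' @param alpha Flagging threshold (default 0.05).
#' @param annotation Optional annotation to attach gene symbols.
#' @return Data.frame `site_id`, `gene_symbol`, `n_high`, `n_low`,
#'   `chi_square`, `p_value`, `flagged`, sorted by p.
#' @export
key_site_survival <- function(site_ids, beta, clin, quantile = 0.5,
                              alpha = 0.05, annotation = NULL) {
  stopifnot(ncol(beta) == nrow(clin))
  empty <- data.frame(site_id = character(0), gene_symbol = character(0),
                      n_high = integer(0), n_low = integer(0),
                      chi_square = numeric(0), p_value = numeric(0),
                      flagged = logical(0))
  if (length(site_ids) == 0L) return(empty)
  rows <- lapply(site_ids, function(s) {
    na_row <- data.frame(site_id = s, gene_symbol = NA_character_,
                         n_high = NA_integer_, n_low = NA_integer_,
                         chi_square = NA_real_, p_value = NA_real_,
                         flagged = FALSE, stringsAsFactors = FALSE)
    if (!s %in% rownames(beta)) {
      warning("site ", s, " absent from beta matrix")
      return(na_row)
    }
    lab <- tryCatch(split_by_site(beta[s, ], quantile = quantile),
                    error = function(e) {
                      warning("site ", s, ": ", conditionMessage(e))
                      NULL
                    })
    if (is.null(lab)) return(na_row)
    hi <- lab == "high"
    lr <- suppressWarnings(
      logrank_test(clin$time[hi], clin$event[hi],
                   clin$time[!hi], clin$event[!hi]))
    data.frame(site_id = s, gene_symbol = NA_character_,
               n_high = sum(hi), n_low = sum(!hi),
               chi_square = lr$chi_square, p_value = lr$p_value,
               flagged = lr$p_value < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(annotation) && nrow(out) > 0L)
    out$gene_symbol <- annotation$gene_symbol[match(out$site_id,
                                                    annotation$site_id)]
  out[order(out$p_value), , drop = FALSE]
}
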
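#' Per-sample summaries of sampled lifetimes
#'
#' Averages each sample's randomly selected pixels per channel, giving one
#' representative NADH and PPIX lifetime per tissue sample. These
#' per-sample means are the unit of all downstream group statistics (the
#' sampled pixels within a sample are strongly correlated, so pooling them
#' would overstate the effective n).
#'
#' @param cohort_table a [build_cohort_table()] result
#' @return data.frame with one row per sample: ids, labels,
#'   `mean_tau_nadh_ns`, `mean_tau_ppix_ns`, `n_points`
#' @export
summarize_samples <- function(cohort_table) {
  stopifnot(is.data.frame(cohort_table))
  ids <- unique(cohort_table$sample_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    rows <- cohort_table[cohort_table$sample_id == id, ]
    if (nrow(rows) == 0L) return(NULL)
    data.frame(rows[1, c("patient_id", "sample_id", "diagnosis", "grade",
                         "tissue", "ala")],
               mean_tau_nadh_ns = mean(rows$tau_nadh_ns),
               mean_tau_ppix_ns = mean(rows$tau_ppix_ns),
               n_points = nrow(rows), stringsAsFactors = FALSE)
  }))
  bad <- !is.finite(out$mean_tau_nadh_ns) | !is.finite(out$mean_tau_ppix_ns)
  if (any(bad)) {
    warning("excluding samples with non-finite means: ",
            paste(out$sample_id[bad], collapse = ", "))
    out <- out[!bad, ]
  }
  rownames(out) <- NULL
  out
}

group_key_column <- function(key) {
  switch(key, tissue = "tissue", grade = "grade", ala = "ala",
         stop("grouping key must be one of 'tissue', 'grade', 'ala'"))
}

#' Group medians and quartiles of per-sample lifetimes
#'
#' Median and 25/75% quantiles (linear interpolation between order
#' statistics, quantile type 7) of the per-sample mean lifetimes within
#' each level of the grouping key.
#'
#' @param summaries a [summarize_samples()] result (or, with
#'   `pooled = TRUE`, a [build_cohort_table()] result whose individual
#'   pixel values are pooled — a sensitivity-analysis alternative that
#'   ignores the within-sample correlation)
#' @param key grouping key: `"tissue"`, `"grade"` or `"ala"`
#' @param pooled if `TRUE`, quantiles are computed over pooled pixel
#'   values instead of per-sample means
#' @return data.frame with one row per group: `group`, `n_samples`, and
#'   per channel `median`, `q25`, `q75` (ns)
#' @export
summarize_groups <- function(summaries, key = c("tissue", "grade", "ala"),
                             pooled = FALSE) {
  key <- match.arg(key)
  col <- group_key_column(key)
  ncol_ <- if (pooled) "tau_nadh_ns" else "mean_tau_nadh_ns"
  pcol_ <- if (pooled) "tau_ppix_ns" else "mean_tau_ppix_ns"
  groups <- unique(summaries[[col]])
  out <- do.call(rbind, lapply(groups, function(gr) {
    x <- summaries[summaries[[col]] == gr, ]
    q <- function(v) quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    qn <- q(x[[ncol_]]); qp <- q(x[[pcol_]])
    data.frame(group = gr,
               n_samples = if (pooled) length(unique(x$sample_id))
                           else nrow(x),
               nadh_median_ns = qn[2], nadh_q25_ns = qn[1], nadh_q75_ns = qn[3],
               ppix_median_ns = qp[2], ppix_q25_ns = qp[1], ppix_q75_ns = qp[3],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum test for a location difference between two independent groups,
#' chosen over parametric tests because several groups hold very few
#' samples. U is computed from midranks; the two-tailed p-value comes from
#' full enumeration of all group assignments when `n1 + n2 <= 12` and the
#' pooled data are tie-free, otherwise from the normal approximation with
#' tie correction and continuity correction. Swapping the groups leaves p
#' unchanged, and p depends on the data only through ranks.
#'
#' @param x,y numeric value vectors of the two groups
#' @return object of class `mwu_test`: `U` (for `x`), `p_value`, `method`
#'   (`"exact"` or `"normal_approx"`), `n1`, `n2`
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L,
            all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  if (all(pooled == pooled[1])) {
    res <- list(U = U, p_value = 1, method = "exact", n1 = n1, n2 = n2)
  } else if (N <= 12L && !has_ties) {
    # enumerate all C(N, n1) assignments of the ranks to group 1
    sets <- combn(N, n1)
    Us <- colSums(matrix(r[as.vector(sets)], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    res <- list(U = U, p_value = p, method = "exact", n1 = n1, n2 = n2)
  } else {
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
    res <- list(U = U, p_value = p, method = "normal_approx",
                n1 = n1, n2 = n2)
  }
  structure(res, class = "mwu_test")
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (two-tailed, %s): U = %g, n = (%d, %d), p = %.4g\n",
              x$method, x$U, x$n1, x$n2, x$p_value))
  invisible(x)
}

#' All pairwise Mann-Whitney comparisons between groups
#'
#' Tests every unordered pair of groups of the chosen key on the
#' per-sample means of one channel, flagging significance at alpha = 0.05.
#' No multiple-testing correction is applied (a documented limitation of
#' the replicated procedure); pairs involving a single-sample group are
#' tested but flagged `low_n`.
#'
#' @param summaries a [summarize_samples()] result
#' @param key grouping key: `"tissue"`, `"grade"` or `"ala"`
#' @param channel `"ppix"` or `"nadh"`
#' @param alpha significance level (default 0.05)
#' @return data.frame with one row per pair: groups, ns, `U`, `p_value`,
#'   `method`, `significant`, `low_n`
#' @export
pairwise_comparisons <- function(summaries, key = c("tissue", "grade", "ala"),
                                 channel = c("ppix", "nadh"), alpha = 0.05) {
  key <- match.arg(key)
  channel <- match.arg(channel)
  col <- group_key_column(key)
  vcol <- if (channel == "ppix") "mean_tau_ppix_ns" else "mean_tau_nadh_ns"
  groups <- sort(unique(summaries[[col]]))
  if (length(groups) < 2L) stop("need at least two groups to compare")
  pairs <- combn(groups, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    v1 <- summaries[summaries[[col]] == g1, vcol]
    v2 <- summaries[summaries[[col]] == g2, vcol]
    tst <- mann_whitney_u(v1, v2)
    data.frame(group1 = g1, group2 = g2, channel = channel,
               n1 = tst$n1, n2 = tst$n2, U = tst$U, p_value = tst$p_value,
               method = tst$method, significant = tst$p_value < alpha,
               low_n = tst$n1 < 2 || tst$n2 < 2, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
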
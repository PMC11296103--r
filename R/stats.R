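# Paired nonparametric statistics: Kolmogorov-Smirnov normality screen,
# Wilcoxon signed-rank (exact for small n without ties, normal approximation
# with continuity and tie correction otherwise), Cliff's delta effect size,
# Benjamini-Hochberg FDR adjustment, and the cohort comparison wrapper.

#' One-sample Kolmogorov-Smirnov normality check
#'
#' KS statistic of the sample against a normal with the sample mean and SD
#' (parameters estimated from the data, as in common practice; the p-value
#' is therefore approximate and used only as a reporting screen).
#'
#' @param x numeric sample, n >= 3, non-degenerate.
#' @return p-value.
#' @export
ks_normality <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3) stop("ks_normality needs n >= 3", call. = FALSE)
  if (sd(x) == 0) stop("ks_normality: sample is constant (zero variance)",
                       call. = FALSE)
  suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))$p.value
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences are `post - pre`. Zero differences are dropped (Wilcoxon's
#' original policy, default) or kept in the ranking and removed from the
#' statistic (Pratt). The exact two-sided p-value is used when there are no
#' ties among nonzero |differences| and n <= `exact_max`; otherwise a
#' normal approximation with continuity and tie correction.
#'
#' @param pre,post paired numeric vectors of equal length.
#' @param zero_policy `"drop"` or `"pratt"`.
#' @param exact_max largest n for the exact null distribution (25).
#' @return list with `statistic` (V, rank sum of positive differences),
#'   `p_value`, `n` (pairs used), `method`.
#' @export
wilcoxon_signed_rank <- function(pre, post, zero_policy = c("drop", "pratt"),
                                 exact_max = 25) {
  zero_policy <- match.arg(zero_policy)
  if (length(pre) != length(post)) stop("paired samples of unequal length",
                                        call. = FALSE)
  ok <- !(is.na(pre) | is.na(post))
  d <- post[ok] - pre[ok]
  if (zero_policy == "drop") d_rank <- d[d != 0] else d_rank <- d
  if (!length(d_rank) || all(d_rank == 0)) {
    return(list(statistic = NA_real_, p_value = 1, n = 0,
                method = "no nonzero differences"))
  }
  r <- rank(abs(d_rank))
  nz <- d_rank != 0
  V <- sum(r[d_rank > 0])
  n <- sum(nz)
  ties <- any(duplicated(abs(d_rank[nz])))
  if (zero_policy == "drop" && !ties && n <= exact_max) {
    # exact: V ~ signed-rank null over 2^n sign assignments
    p_lo <- psignrank(V, n)
    p_hi <- 1 - psignrank(V - 1, n)
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(statistic = V, p_value = p, n = n, method = "exact"))
  }
  # normal approximation; zeros (Pratt) stay in the ranks but drop from V
  mu <- sum(r[nz]) / 2
  tie_tab <- table(r[nz])
  sigma2 <- sum(r[nz]^2) / 4
  z <- (V - mu - 0.5 * sign(V - mu)) / sqrt(sigma2)
  list(statistic = V, p_value = 2 * pnorm(-abs(z)), n = n,
       method = "normal approximation")
}

#' Cliff's delta effect size
#'
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n_x n_y)` over all cross
#' pairs; in `[-1, 1]`, 0 for identical samples, antisymmetric in its
#' arguments, invariant under strictly monotone transforms.
#'
#' @param x,y numeric samples (nonempty).
#' @return delta.
#' @export
cliffs_delta <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("cliffs_delta: empty sample",
                                     call. = FALSE)
  mean(sign(outer(x, y, "-")))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement; adjusted values
#' are `>=` raw values and non-decreasing after sorting.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
fdr_adjust <- function(pvals) {
  stopifnot(all(is.na(pvals) | (pvals >= 0 & pvals <= 1)))
  m <- length(pvals)
  if (m <= 1) return(pvals)
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * pvals[o]))[ro]
}

format_median_range <- function(x, digits = 2) {
  x <- x[!is.na(x)]
  sprintf("%.*f [%.*f-%.*f]", digits, median(x), digits, min(x),
          digits, max(x))
}

#' Paired pre/post comparison of cohort endpoints
#'
#' For every endpoint: complete-case paired samples, median [range] per arm,
#' Wilcoxon signed-rank p, Cliff's delta computed between the post and pre
#' arms (so a decrease yields a negative delta), and Benjamini-Hochberg
#' adjustment across the endpoint family passed in this invocation.
#'
#' @param metrics data.frame with a `subject` column and, per endpoint `e`,
#'   columns `<e>_pre` and `<e>_post`.
#' @param endpoints character vector of endpoint names.
#' @param digits digits of the median [range] strings.
#' @return data.frame of class `paired_cohort_result`, one row per
#'   endpoint; excluded (incomplete) subjects are reported in the
#'   `n_excluded` column.
#' @export
compare_cohort <- function(metrics, endpoints, digits = 2) {
  rows <- lapply(endpoints, function(e) {
    pre <- metrics[[paste0(e, "_pre")]]
    post <- metrics[[paste0(e, "_post")]]
    if (is.null(pre) || is.null(post)) {
      stop("metrics table lacks columns for endpoint '", e, "'",
           call. = FALSE)
    }
    ok <- !(is.na(pre) | is.na(post))
    w <- wilcoxon_signed_rank(pre[ok], post[ok])
    data.frame(
      endpoint = e, n = sum(ok), n_excluded = sum(!ok),
      pre = format_median_range(pre[ok], digits),
      post = format_median_range(post[ok], digits),
      median_pre = median(pre[ok]), median_post = median(post[ok]),
      statistic = w$statistic, p_value = w$p_value,
      cliffs_delta = cliffs_delta(post[ok], pre[ok]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_adjusted_p <- fdr_adjust(out$p_value)
  class(out) <- c("paired_cohort_result", "data.frame")
  out
}

#' @export
print.paired_cohort_result <- function(x, ...) {
  df <- as.data.frame(x)
  for (k in seq_len(nrow(df))) {
    cat(sprintf("%s (n=%d): %s vs. %s, p = %.3g, d = %.2f (FDR p = %.3g)\n",
                df$endpoint[k], df$n[k], df$pre[k], df$post[k],
                df$p_value[k], df$cliffs_delta[k], df$fdr_adjusted_p[k]))
  }
  invisible(x)
}

#' Unpaired subgroup contrast of a per-subject metric
#'
#' Rank-sum comparison of a metric (e.g. percentage change in burden)
#' between two subject subgroups, with Cliff's delta.
#'
#' @param values per-subject metric.
#' @param group logical or two-level factor defining the subgroups.
#' @return list with `p_value`, `cliffs_delta`, group medians and sizes.
#' @export
compare_subgroups <- function(values, group) {
  g <- as.factor(group)
  if (nlevels(g) != 2) stop("group must have exactly two levels", call. = FALSE)
  a <- values[g == levels(g)[1]]
  b <- values[g == levels(g)[2]]
  wt <- suppressWarnings(wilcox.test(a, b))
  list(p_value = wt$p.value, cliffs_delta = cliffs_delta(a, b),
       median_1 = median(a, na.rm = TRUE), median_2 = median(b, na.rm = TRUE),
       n_1 = sum(!is.na(a)), n_2 = sum(!is.na(b)))
}
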
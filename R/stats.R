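#' Chi-square test of equality of two proportions
#'
#' Pearson chi-square on the 2x2 table `k1/n1` vs `k2/n2` with expecteds
#' from the pooled proportion, df = 1. Yates' continuity subtraction of 0.5
#' is applied only when `correction = TRUE`; the default is off, which
#' reproduces standard uncorrected worked values.
#'
#' @param k1,n1,k2,n2 Successes and totals per group.
#' @param correction Apply Yates' continuity correction.
#' @return An object of class `nc_test` (see [tidy.nc_test()]).
#' @examples
#' chi2_proportions(31, 73, 5, 49) # chi-square = 14.67
#' @export
chi2_proportions <- function(k1, n1, k2, n2, correction = FALSE) {
  stopifnot(k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2, n1 > 0, n2 > 0)
  p_pool <- (k1 + k2) / (n1 + n2)
  if (p_pool == 0 || p_pool == 1) {
    stop("degenerate table: pooled proportion is 0 or 1, expected cell zero",
         call. = FALSE)
  }
  obs <- c(k1, n1 - k1, k2, n2 - k2)
  exp_ <- c(n1 * p_pool, n1 * (1 - p_pool), n2 * p_pool, n2 * (1 - p_pool))
  adj <- if (correction) pmax(0, abs(obs - exp_) - 0.5) else abs(obs - exp_)
  stat <- sum(adj^2 / exp_)
  new_nc_test("chi-squared test of proportions", stat, df = 1,
              p = stats::pchisq(stat, 1, lower.tail = FALSE),
              n = c(n1, n2), correction = if (correction) "yates" else "none")
}

#' Two-sample Kuiper test on circular data
#'
#' Kuiper statistic `V = D+ + D-` between the empirical distribution
#' functions of two angle samples. On the circle `V` is invariant under a
#' common rotation of both samples, making it the appropriate two-sample
#' test for preferred-phase distributions. The p-value is obtained by
#' permutation of the sample labels.
#'
#' @param angles1,angles2 Angle samples in radians (>= 5 each).
#' @param n_perm Number of label permutations.
#' @param seed Optional integer seed.
#' @return An `nc_test` with the statistic `V` and permutation p-value.
#' @export
kuiper_two_sample <- function(angles1, angles2, n_perm = 1000, seed = NULL) {
  if (length(angles1) < 5L || length(angles2) < 5L) {
    stop("need at least 5 angles per sample", call. = FALSE)
  }
  a1 <- angles1 %% (2 * pi)
  a2 <- angles2 %% (2 * pi)
  v_stat <- function(x, y) {
    pts <- sort(unique(c(x, y)))
    f1 <- stats::ecdf(x)(pts)
    f2 <- stats::ecdf(y)(pts)
    max(f1 - f2) + max(f2 - f1)
  }
  v <- v_stat(a1, a2)
  pooled <- c(a1, a2)
  n1 <- length(a1)
  p <- with_seed(seed, {
    exceed <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), n1)
      v_stat(pooled[idx], pooled[-idx]) >= v
    }, logical(1))
    (1 + sum(exceed)) / (n_perm + 1)
  })
  new_nc_test("Kuiper two-sample test", v, df = NA_real_, p = p,
              n = c(length(a1), length(a2)),
              correction = sprintf("permutation (%d)", n_perm))
}

#' Interquartile-range outlier rule
#'
#' Removes values whose distance from the 25th or 75th percentile exceeds
#' 1.5 times the interquartile range. Quartiles use linear interpolation
#' between order statistics; removal is single-pass (quartiles are not
#' re-estimated after removal), which makes the rule idempotent on its own
#' output. Vectors shorter than 4 are returned unchanged with a notice.
#'
#' @param values Numeric vector.
#' @param k Fence multiplier (1.5 by convention).
#' @return List with `kept` (values retained, original order) and `removed`
#'   (indices of removed values).
#' @export
remove_outliers_iqr <- function(values, k = 1.5) {
  if (length(values) < 4L) {
    message("fewer than 4 values; outlier rule not applied")
    return(list(kept = values, removed = integer(0)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, na.rm = TRUE)
  iqr <- q[2] - q[1]
  out <- values < q[1] - k * iqr | values > q[2] + k * iqr
  out[is.na(out)] <- FALSE
  list(kept = values[!out], removed = which(out))
}

# -- thin wrappers over the vetted base-R nonparametric tests ---------------

new_nc_test <- function(method, statistic, df, p, n, correction = "none") {
  structure(list(method = method, statistic = unname(statistic),
                 df = unname(df), p = unname(p), n = n,
                 correction = correction),
            class = "nc_test")
}

#' @export
print.nc_test <- function(x, ...) {
  cat("<nc_test> ", x$method, "\n  statistic = ", signif(x$statistic, 6),
      if (!is.na(x$df)) paste0(", df = ", x$df) else "",
      ", p = ", signif(x$p, 4), "\n  n = ", paste(x$n, collapse = ", "),
      "; correction: ", x$correction, "\n", sep = "")
  invisible(x)
}

#' Nonparametric test wrappers
#'
#' Thin wrappers around the base-R implementations of the nonparametric
#' tests used throughout the pipeline, returning a uniform `nc_test` result:
#' Wilcoxon signed-rank (paired), Wilcoxon rank-sum, Friedman (with optional
#' Bonferroni-corrected signed-rank post hocs against a reference column)
#' and Kruskal-Wallis.
#'
#' @param x,y Paired (`signed_rank`) or independent (`rank_sum`) samples.
#' @param mat Subjects x conditions matrix for the Friedman test.
#' @param values,groups Observations and group labels for Kruskal-Wallis.
#' @param posthoc_ref Column index used as the post hoc reference, or `NULL`
#'   to skip post hocs.
#' @return An `nc_test`; `friedman_rm()` additionally carries a `posthoc`
#'   tibble (`comparison`, `p_raw`, `p_bonferroni`) when requested.
#' @name test-wrappers
NULL

#' @rdname test-wrappers
#' @export
wilcoxon_signed_rank <- function(x, y) {
  h <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                           exact = FALSE))
  new_nc_test("Wilcoxon signed-rank test", h$statistic, NA_real_, h$p.value,
              length(x))
}

#' @rdname test-wrappers
#' @export
wilcoxon_rank_sum <- function(x, y) {
  h <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
  new_nc_test("Wilcoxon rank-sum test", h$statistic, NA_real_, h$p.value,
              c(length(x), length(y)))
}

#' @rdname test-wrappers
#' @export
friedman_rm <- function(mat, posthoc_ref = 1L) {
  h <- stats::friedman.test(as.matrix(mat))
  out <- new_nc_test("Friedman test", h$statistic, h$parameter, h$p.value,
                     nrow(mat))
  if (!is.null(posthoc_ref)) {
    others <- setdiff(seq_len(ncol(mat)), posthoc_ref)
    m <- length(others)
    p_raw <- vapply(others, function(j) {
      suppressWarnings(stats::wilcox.test(mat[, posthoc_ref], mat[, j],
                                          paired = TRUE,
                                          exact = FALSE))$p.value
    }, numeric(1))
    out$posthoc <- tibble::tibble(
      comparison = paste0(posthoc_ref, " vs ", others),
      p_raw = p_raw, p_bonferroni = pmin(1, p_raw * m))
  }
  out
}

#' @rdname test-wrappers
#' @export
kruskal <- function(values, groups) {
  h <- stats::kruskal.test(values, factor(groups))
  new_nc_test("Kruskal-Wallis test", h$statistic, h$parameter, h$p.value,
              as.integer(table(groups)))
}
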
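#' Two-sided Wilcoxon Mann-Whitney U test
#'
#' Wraps [stats::wilcox.test()]: exact for small tie-free samples
#' (n <= 8 enforced exact), tie-corrected normal approximation otherwise.
#'
#' @param x,y Non-empty numeric samples.
#' @return One-row data frame of class `comparison_result`: `test_name`,
#'   `statistic` (U), `p_value`, `n1`, `n2`, `paired`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(10, 11, 12))$p_value  # 0.1
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  exact <- length(x) <= 8L && length(y) <= 8L &&
    !any(duplicated(c(x, y)))
  w <- suppressWarnings(wilcox.test(x, y, exact = if (exact) TRUE else NULL,
                                    correct = !exact))
  comparison_result("mann_whitney_u", unname(w$statistic), w$p.value,
                    length(x), length(y), paired = FALSE)
}

#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (Wilcoxon convention). Exact p for
#' n <= 12 non-tied differences; if all differences are zero, p = 1 is
#' returned with the `degenerate` attribute set.
#'
#' @param pre,post Equal-length numeric vectors (n >= 2).
#' @return A `comparison_result` row.
#' @examples
#' wilcoxon_signed_rank(1:6, 1:6 + 1)$p_value  # 0.03125
#' @export
wilcoxon_signed_rank <- function(pre, post) {
  if (length(pre) != length(post) || length(pre) < 2L) {
    stop("pre and post must have equal length >= 2", call. = FALSE)
  }
  d <- post - pre
  d <- d[d != 0]
  if (length(d) == 0L) {
    out <- comparison_result("wilcoxon_signed_rank", 0, 1,
                             length(pre), length(post), paired = TRUE)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  if (length(d) <= 12L) {
    ## exact two-sided p by enumerating all sign assignments (handles
    ## ties in |d| via average ranks, which wilcox.test's exact path
    ## refuses)
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    m <- length(d)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    w_all <- as.numeric(signs %*% r)
    p <- min(1, 2 * min(mean(w_all >= w_obs), mean(w_all <= w_obs)))
    return(comparison_result("wilcoxon_signed_rank", w_obs, p,
                             length(pre), length(post), paired = TRUE))
  }
  w <- suppressWarnings(wilcox.test(d, correct = TRUE))
  comparison_result("wilcoxon_signed_rank", unname(w$statistic), w$p.value,
                    length(pre), length(post), paired = TRUE)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction by default (the convention that
#' reproduces the printed neuron-count comparison); Yates correction
#' optional.
#'
#' @param table 2x2 numeric matrix of non-negative counts (rows = groups,
#'   columns = outcome yes/no).
#' @param continuity_correction Apply Yates correction.
#' @return A `comparison_result` row.
#' @examples
#' chi2_2x2(matrix(c(17, 7, 47, 75), 2))$p_value  # ~0.0035
#' @export
chi2_2x2 <- function(table, continuity_correction = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("table must be 2x2", call. = FALSE)
  if (any(table < 0) || sum(table) < 1) {
    stop("counts must be non-negative with a positive total", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column margin", call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(table, correct = continuity_correction))
  comparison_result("chi2_2x2", unname(ct$statistic), ct$p.value,
                    sum(table[1L, ]), sum(table[2L, ]), paired = FALSE)
}

#' Two-sided paired Student t test
#'
#' @param pre,post Equal-length numeric vectors (n >= 2) whose differences
#'   have nonzero variance (a constant shift is degenerate and raises an
#'   error).
#' @return A `comparison_result` row.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post) || length(pre) < 2L) {
    stop("pre and post must have equal length >= 2", call. = FALSE)
  }
  if (sd(post - pre) == 0) {
    stop("differences have zero variance; paired t statistic is undefined",
         call. = FALSE)
  }
  tt <- t.test(post, pre, paired = TRUE)
  comparison_result("paired_t", unname(tt$statistic), tt$p.value,
                    length(pre), length(post), paired = TRUE)
}

comparison_result <- function(test_name, statistic, p_value, n1, n2, paired) {
  structure(data.frame(test_name = test_name, statistic = statistic,
                       p_value = p_value, n1 = n1, n2 = n2,
                       paired = paired, stringsAsFactors = FALSE),
            class = c("comparison_result", "data.frame"))
}

#' Box-plot or bar descriptor of a sample
#'
#' Follows the reporting convention: n >= 10 gives a box-plot descriptor
#' (median, quartiles by linear interpolation, whiskers at the most
#' extreme values within 1.5 x IQR of the quartiles, outliers listed);
#' n < 10 gives mean +/- SD.
#'
#' @param values Non-empty numeric vector.
#' @param n Sample size governing the choice (defaults to
#'   `length(values)`).
#' @return A list, either `type = "box"` with `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, `outliers`, or `type = "bar"` with
#'   `mean`, `sd`, each with `n`.
#' @examples
#' summarize_values(1:11)$median
#' @export
summarize_values <- function(values, n = length(values)) {
  if (length(values) == 0L) stop("'values' must be non-empty", call. = FALSE)
  if (n < 10) {
    return(list(type = "bar", mean = mean(values), sd = sd(values), n = n))
  }
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3L] - q[1L]
  lo_fence <- q[1L] - 1.5 * iqr
  hi_fence <- q[3L] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(type = "box", median = q[2L], q1 = q[1L], q3 = q[3L],
       whisker_low = min(values[inside]), whisker_high = max(values[inside]),
       outliers = sort(values[!inside]), n = n)
}
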
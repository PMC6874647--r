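new_test_result <- function(test_name, statistic, p_value, direction,
                            n_group_a, n_group_b, null_summary = NULL) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(
    list(
      test_name = test_name, statistic = statistic, p_value = p_value,
      direction = direction, n_group_a = n_group_a, n_group_b = n_group_b,
      null_summary = null_summary
    ),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, p = %.4g (%s)\n",
              x$test_name, x$statistic, x$p_value, x$direction))
  invisible(x)
}

#' Turn a test result into a one-row tibble
#'
#' @param x A `test_result`.
#' @param ... Unused.
#' @return One-row tibble with the statistic, p-value, direction, group
#'   sizes, and (when the test has an empirical null) the null mean/sd and
#'   empirical p-value.
#' @export
tidy.test_result <- function(x, ...) {
  out <- tibble::tibble(
    test = x$test_name,
    statistic = x$statistic,
    p_value = x$p_value,
    direction = x$direction,
    n_group_a = x$n_group_a,
    n_group_b = x$n_group_b
  )
  if (!is.null(x$null_summary)) {
    out$null_mean <- x$null_summary$mean
    out$null_sd <- x$null_summary$sd
    if (!is.null(x$null_summary$empirical_p)) {
      out$empirical_p <- x$null_summary$empirical_p
    }
  }
  out
}

#' One-tailed Welch two-sample t-test
#'
#' Welch's unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, and a one-tailed p-value for the stated alternative. Used for
#' the somatic mutation-frequency comparison between predicted driver genes
#' and non-driver genes.
#'
#' @param group_a,group_b Numeric vectors, each of length at least 2.
#' @param alternative `"a_greater"` (mean of `group_a` exceeds that of
#'   `group_b`) or `"a_less"`.
#' @return A `test_result` with fields `statistic` (t), `p_value`, and
#'   `df` recorded in `null_summary`-free form via attribute `df`.
#' @examples
#' welch_t_test_one_tailed(c(3, 4, 5), c(1, 2, 3), "a_greater")
#' @export
welch_t_test_one_tailed <- function(group_a, group_b,
                                    alternative = c("a_greater", "a_less")) {
  alternative <- match.arg(alternative)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  va <- stats::var(group_a)
  vb <- stats::var(group_b)
  na <- length(group_a)
  nb <- length(group_b)
  if (va + vb == 0) {
    if (mean(group_a) == mean(group_b)) {
      warning("both groups constant and equal; p = 0.5", call. = FALSE)
      res <- new_test_result("welch_t", 0, 0.5, alternative, na, nb)
      attr(res, "df") <- na + nb - 2
      return(res)
    }
    stop("zero variance in both groups with unequal means", call. = FALSE)
  }
  se2 <- va / na + vb / nb
  t_stat <- (mean(group_a) - mean(group_b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- if (alternative == "a_greater") {
    stats::pt(t_stat, df, lower.tail = FALSE)
  } else {
    stats::pt(t_stat, df, lower.tail = TRUE)
  }
  res <- new_test_result("welch_t", t_stat, p, alternative, na, nb)
  attr(res, "df") <- df
  res
}

# Exact null distribution of the rank sum of group A under H0, by
# enumerating all label assignments. Only called for small tie-free inputs.
mw_exact_p <- function(group_a, group_b, alternative) {
  pooled <- c(group_a, group_b)
  na <- length(group_a)
  r <- rank(pooled)
  obs <- sum(r[seq_len(na)])
  combos <- utils::combn(length(pooled), na)
  sums <- colSums(matrix(r[combos], nrow = na))
  if (alternative == "a_greater") {
    mean(sums >= obs)
  } else {
    mean(sums <= obs)
  }
}

#' One-tailed Mann-Whitney U test
#'
#' Rank-sum test with midrank tie handling. For small tie-free inputs
#' (`n_a + n_b <= 12`) the p-value is exact, computed by enumerating all
#' label assignments; otherwise the tie-corrected normal approximation with
#' continuity correction is used. Used for the per-tool pathogenicity-score
#' enrichment comparisons.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param alternative `"a_greater"` (values of `group_a` stochastically
#'   larger) or `"a_less"`.
#' @return A `test_result`; the statistic is the U of `group_a`.
#' @examples
#' mann_whitney_one_tailed(c(4, 5, 6), c(1, 2, 3), "a_greater")
#' @export
mann_whitney_one_tailed <- function(group_a, group_b,
                                    alternative = c("a_greater", "a_less")) {
  alternative <- match.arg(alternative)
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  na <- length(group_a)
  nb <- length(group_b)
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L

  if (!has_ties && na + nb <= 12L) {
    p <- mw_exact_p(group_a, group_b, alternative)
    method <- "exact"
  } else {
    n <- na + nb
    mu <- na * nb / 2
    tie_counts <- table(pooled)
    tie_term <- sum(tie_counts^3 - tie_counts) / (n * (n - 1))
    sigma2 <- na * nb / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) {
      p <- 0.5
    } else {
      # continuity-corrected z toward the null
      z <- if (alternative == "a_greater") {
        (u_a - mu - 0.5) / sqrt(sigma2)
      } else {
        (u_a - mu + 0.5) / sqrt(sigma2)
      }
      p <- if (alternative == "a_greater") {
        stats::pnorm(z, lower.tail = FALSE)
      } else {
        stats::pnorm(z, lower.tail = TRUE)
      }
    }
    method <- "normal_approx"
  }
  res <- new_test_result("mann_whitney_u", u_a, p, alternative, na, nb)
  attr(res, "method") <- method
  res
}
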
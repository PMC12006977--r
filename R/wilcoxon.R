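#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided exact test for paired data with small n. Zero differences are
#' dropped (reducing the effective n) and tied absolute differences receive
#' average ranks. The statistic is `W`, the sum of ranks of positive
#' differences; its exact null distribution over all `2^n` equiprobable
#' sign assignments is obtained by convolution over the (half-integer)
#' ranks, which enumerates the same distribution as brute force without the
#' exponential cost. The null is symmetric about `n(n+1)/4`, and the
#' two-sided p-value is `P(|W - mu| >= |w_obs - mu|)`.
#'
#' @param x First sample, or the paired differences if `y` is `NULL`.
#' @param y Optional second sample; the test is on `x - y`.
#' @return A list of class `wilcoxon_result`: `statistic` (W),
#'   `n_effective`, `p_two_sided`, `method` (`"exact"`), and `degenerate`
#'   (`TRUE` when every difference is zero, in which case `p = 1`).
#' @export
#' @examples
#' wilcoxon_signed_rank_exact(c(2, 3, 1.5, 4), c(1, 1, 1, 1))
wilcoxon_signed_rank_exact <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  if (!is.null(y) && length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  if (any(!is.finite(d))) stop("differences must be finite", call. = FALSE)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(structure(list(statistic = 0, n_effective = 0L, p_two_sided = 1,
                          method = "exact", degenerate = TRUE),
                     class = "wilcoxon_result"))
  if (n > 25) stop("exact enumeration supported for n <= 25", call. = FALSE)
  r <- rank(abs(d))           # average ranks for ties; may be half-integers
  W <- sum(r[d > 0])
  r2 <- as.integer(round(2 * r))   # doubled ranks are integers
  # counts[w + 1] = number of sign assignments with doubled statistic w
  counts <- c(1, numeric(sum(r2)))
  for (rr in r2) {
    shifted <- c(numeric(rr), counts[seq_len(length(counts) - rr)])
    counts <- counts + shifted
  }
  w2 <- round(2 * W)
  mu2 <- sum(r2) / 2
  extreme <- abs(seq_along(counts) - 1 - mu2) >= abs(w2 - mu2) - 1e-9
  p <- sum(counts[extreme]) / 2^n
  structure(list(statistic = W, n_effective = as.integer(n),
                 p_two_sided = min(p, 1), method = "exact",
                 degenerate = FALSE),
            class = "wilcoxon_result")
}
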
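#' Jarque-Bera normality test
#'
#' Tests departure from normality through sample skewness `S` and excess
#' kurtosis `K`: `JB = n/6 * (S^2 + K^2/4)`, referred to its asymptotic
#' chi-squared distribution with 2 degrees of freedom. The chi-squared
#' reference is anticonservative for small n; a caveat is attached below
#' n = 30.
#'
#' @param x Numeric sample, n >= 4.
#' @return An object of class `htest` with `statistic`, `p.value`, and the
#'   sample skewness/kurtosis as `parameter`s.
#' @examples
#' normality_test(rnorm(50))
#' @export
normality_test <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4) stop("need n >= 4 for the Jarque-Bera test")
  if (!all(is.finite(x))) stop("sample must be finite")
  if (stats::var(x) == 0) stop("degenerate sample: zero variance")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  S <- m3 / m2^1.5
  K <- m4 / m2^2 - 3
  jb <- n / 6 * (S^2 + K^2 / 4)
  p <- stats::pchisq(jb, df = 2, lower.tail = FALSE)
  method <- "Jarque-Bera normality test"
  if (n < 30) method <- paste(method,
                              "(chi-squared reference; small-sample caveat)")
  structure(list(statistic = c(JB = jb), parameter = c(skewness = S,
                                                       ex_kurtosis = K),
                 p.value = p, method = method,
                 data.name = deparse(substitute(x))),
            class = "htest")
}

#' Compare two pooled samples with normality-routed tests
#'
#' Both samples are screened with the Jarque-Bera test at level `alpha`;
#' only when both are compatible with normality is the unpaired two-sided
#' t test used, otherwise the two-sided Wilcoxon-Mann-Whitney rank-sum test
#' (exact null when the smaller sample has at most `exact_n_max`
#' observations and there are no ties; normal approximation with tie
#' correction otherwise). Samples too small or too degenerate for the
#' normality screen are routed to the rank-sum branch.
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @param alpha Normality screening level.
#' @param exact_n_max Largest min(n) for which the exact rank-sum null is
#'   used.
#' @param force Optionally force a branch: `"t"` or `"ranksum"`.
#' @return List with `p`, `test_used` (`"t"` or `"ranksum"`), `statistic`,
#'   and the two normality p-values (NA when not computable).
#' @examples
#' compare_samples(c(1, 2, 3), c(4, 5, 6), force = "ranksum")$p  # 0.1
#' @export
compare_samples <- function(a, b, alpha = 0.05, exact_n_max = 8,
                            force = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("need at least two observations per sample")
  pnorm_a <- tryCatch(normality_test(a)$p.value, error = function(e) NA_real_)
  pnorm_b <- tryCatch(normality_test(b)$p.value, error = function(e) NA_real_)
  use_t <- !is.na(pnorm_a) && !is.na(pnorm_b) &&
    pnorm_a > alpha && pnorm_b > alpha
  if (!is.null(force)) use_t <- match.arg(force, c("t", "ranksum")) == "t"
  if (use_t) {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    list(p = ht$p.value, test_used = "t", statistic = unname(ht$statistic),
         normality_p = c(a = pnorm_a, b = pnorm_b))
  } else {
    exact <- min(length(a), length(b)) <= exact_n_max &&
      !any(duplicated(c(a, b)))
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = !exact))
    list(p = ht$p.value, test_used = "ranksum",
         statistic = unname(ht$statistic),
         normality_p = c(a = pnorm_a, b = pnorm_b))
  }
}

#' Bonferroni adjustment for multiple comparisons
#'
#' @param p Raw p-values in `[0, 1]`.
#' @param m Number of comparisons in the family; must be at least
#'   `length(p)`.
#' @return Adjusted p-values `pmin(1, m * p)`.
#' @examples
#' bonferroni(0.02, 3)  # 0.06
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("m must be at least the number of p-values")
  stats::p.adjust(p, method = "bonferroni", n = m)
}

#' Pairwise condition comparisons with Bonferroni control
#'
#' Runs [compare_samples()] for every pair of named samples and adjusts the
#' p-values over the family.
#'
#' @param samples Named list of numeric vectors (one pooled sample per
#'   condition).
#' @param alpha Significance level applied to the adjusted p-values.
#' @return Data frame: pair, test used, raw and adjusted p, significance
#'   decision.
#' @export
compare_conditions <- function(samples, alpha = 0.05) {
  stopifnot(length(samples) >= 2, !is.null(names(samples)))
  nm <- names(samples)
  pairs <- utils::combn(nm, 2)
  res <- apply(pairs, 2, function(pr) {
    cs <- compare_samples(samples[[pr[1]]], samples[[pr[2]]])
    data.frame(a = pr[1], b = pr[2], test_used = cs$test_used, p_raw = cs$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- bonferroni(res$p_raw, m = nrow(res))
  res$significant <- res$p_adj <= alpha
  res
}
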
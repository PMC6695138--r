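# Exact inference for 2x2 tables: two-sided Fisher p-value, conditional
# maximum-likelihood odds ratio, and 95% CI by test inversion on the
# noncentral hypergeometric distribution.

#' Construct a 2x2 contingency table
#'
#' Row 1 is group 1 (with / without the trait), row 2 group 2. Counts must
#' be non-negative with at least one positive margin.
#'
#' @param a,b,c,d Cell counts: `a` = group 1 with trait, `b` = group 1
#'   without, `c` = group 2 with, `d` = group 2 without.
#' @return An integer matrix of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(is.na(x)) || any(x < 0) || any(x != floor(x)))
    config_error("two_by_two: counts must be non-negative integers")
  if (sum(x) == 0) config_error("two_by_two: all-zero table")
  structure(matrix(as.integer(x), 2L, 2L, byrow = TRUE,
                   dimnames = list(group = c("g1", "g2"),
                                   trait = c("yes", "no"))),
            class = c("two_by_two", "matrix", "array"))
}

# Noncentral hypergeometric log-densities over the support of cell `a`,
# given margins (m = a+b, n = c+d, k = a+c) and log odds ratio `lpsi`.
.nchg_logdens <- function(m, n, k, lpsi) {
  lo <- max(0L, k - n); hi <- min(k, m)
  x <- lo:hi
  lw <- lchoose(m, x) + lchoose(n, k - x) + x * lpsi
  lw - max(lw) - log(sum(exp(lw - max(lw))))
}

.nchg_mean <- function(m, n, k, lpsi) {
  ld <- .nchg_logdens(m, n, k, lpsi)
  x <- max(0L, k - n):min(k, m)
  sum(x * exp(ld))
}

# P(X <= a) and P(X >= a) under the noncentral hypergeometric law.
.nchg_tail <- function(m, n, k, a, lpsi, lower = TRUE) {
  ld <- .nchg_logdens(m, n, k, lpsi)
  x <- max(0L, k - n):min(k, m)
  if (lower) sum(exp(ld[x <= a])) else sum(exp(ld[x >= a]))
}

.solve_lpsi <- function(f, lower = -75, upper = 75) {
  stats::uniroot(f, c(lower, upper), tol = 1e-10)$root
}

#' Fisher exact test with conditional-MLE odds ratio
#'
#' Exact inference for a 2x2 table with all margins fixed. The two-sided
#' p-value sums the hypergeometric probabilities of every table no more
#' likely than the observed one (minimum-likelihood rule, with a relative
#' tolerance of 1e-7 on the comparison). The odds-ratio estimate is the
#' conditional MLE: the value maximizing the noncentral hypergeometric
#' likelihood of the observed count given the margins — not the sample
#' cross-product ratio, which is biased away from 1 in small tables. The
#' confidence bounds invert the exact one-sided tail tests at level
#' `(1 - conf_level) / 2`; when the observed count sits at an attainable
#' extreme of its support the corresponding bound is 0 or `Inf`, as is the
#' estimate itself.
#'
#' @param table A [two_by_two()] table (or any 2x2 matrix of counts).
#' @param conf_level Confidence level for the odds-ratio interval.
#' @return A list of class `exact_test_result`: `p_value`, `estimate`
#'   (conditional-MLE odds ratio), `conf_int` (length 2), `conf_level`,
#'   `table`.
#' @examples
#' fisher_exact(two_by_two(22, 1, 11, 9))
#' @export
fisher_exact <- function(table, conf_level = 0.95) {
  if (!inherits(table, "two_by_two"))
    table <- two_by_two(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
  a <- table[1, 1]
  m <- sum(table[1, ]); n <- sum(table[2, ]); k <- sum(table[, 1])
  lo <- max(0L, k - n); hi <- min(k, m)

  # two-sided p: minimum-likelihood rule at the central (psi = 1) law
  d <- stats::dhyper(lo:hi, m, n, k)
  p <- min(1, sum(d[d <= d[a - lo + 1L] * (1 + 1e-7)]))

  # conditional MLE of the odds ratio
  est <- if (a == lo && a == hi) NA_real_
  else if (a == lo) 0
  else if (a == hi) Inf
  else exp(.solve_lpsi(function(l) .nchg_mean(m, n, k, l) - a))

  alpha <- (1 - conf_level) / 2
  ci_lo <- if (a == lo) 0
  else exp(.solve_lpsi(function(l) .nchg_tail(m, n, k, a, l, lower = FALSE) - alpha))
  ci_hi <- if (a == hi) Inf
  else exp(.solve_lpsi(function(l) .nchg_tail(m, n, k, a, l, lower = TRUE) - alpha))

  structure(list(p_value = p, estimate = est, conf_int = c(ci_lo, ci_hi),
                 conf_level = conf_level, table = table),
            class = "exact_test_result")
}

#' @export
print.exact_test_result <- function(x, ...) {
  cat("Exact 2x2 test\n")
  cat(sprintf("  p (two-sided)     : %.4g\n", x$p_value))
  cat(sprintf("  odds ratio (CMLE) : %.4g\n", x$estimate))
  cat(sprintf("  %g%% CI            : [%.4g, %.4g]\n",
              100 * x$conf_level, x$conf_int[1], x$conf_int[2]))
  invisible(x)
}

#' Grid-search oracle for the conditional-MLE odds ratio
#'
#' Maximizes the noncentral hypergeometric log-likelihood by dense grid
#' search over log odds ratio in `[-15, 15]`, refined twice around the best
#' point. Deliberately independent of the root-finding path in
#' [fisher_exact()]; intended as a verification device in tests, not for
#' analysis use.
#'
#' @param table A [two_by_two()] table.
#' @return The grid-search odds-ratio estimate (0 or `Inf` at the support
#'   boundary).
#' @export
cmle_oracle <- function(table) {
  if (!inherits(table, "two_by_two"))
    table <- two_by_two(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
  a <- table[1, 1]
  m <- sum(table[1, ]); n <- sum(table[2, ]); k <- sum(table[, 1])
  lo <- max(0L, k - n); hi <- min(k, m)
  if (a == lo && a == hi) return(NA_real_)
  if (a == lo) return(0)
  if (a == hi) return(Inf)
  ll <- function(l) .nchg_logdens(m, n, k, l)[a - lo + 1L]
  centre <- 0; half <- 15
  for (pass in 1:3) {
    grid <- seq(centre - half, centre + half, length.out = 2001L)
    vals <- vapply(grid, ll, numeric(1))
    centre <- grid[which.max(vals)]
    half <- half / 50
  }
  exp(centre)
}

#' Cohort minor-allele frequency of carriers
#'
#' Converts carrier counts into an allele frequency over `2 * samples`
#' chromosomes: heterozygous carriers contribute one allele each,
#' homozygous carriers two.
#'
#' @param het Number of heterozygous carriers.
#' @param samples Number of individuals screened.
#' @param hom Number of homozygous-alternate carriers (default 0; the
#'   all-heterozygote convention used when zygosity is uniform).
#' @return The allele frequency as a proportion.
#' @examples
#' carrier_maf(5, 23)        # five heterozygotes among 23 individuals
#' @export
carrier_maf <- function(het, samples, hom = 0) {
  if (!is_count(het) || !is_count(hom) || !is_count(samples) || samples == 0)
    config_error("carrier_maf: counts must be non-negative, samples > 0")
  if (het + hom > samples)
    config_error("carrier_maf: carriers exceed samples")
  (het + 2 * hom) / (2 * samples)
}

#' Ancestry 2x2 tables of true-positive burden
#'
#' Reconstructs, from labeled calls and a cohort table, the two contrasts
#' conventionally used to compare validated variant burden between two
#' ancestry groups: individuals with at least one TP versus none, and
#' individuals with multiple (>= 2) TPs versus fewer. Row 1 is the first
#' group in `groups`.
#'
#' @param labeled Calls labeled by [label_calls()].
#' @param cohort `data.frame` with `sample` and `group` columns covering
#'   all screened individuals (including those without any call).
#' @param groups The two group labels to contrast; defaults to the two
#'   levels present in `cohort`.
#' @return A list with `any_tp` and `multiple_tp` ([two_by_two()] tables)
#'   and `counts`, a per-group breakdown for auditing the reconstruction.
#' @export
tp_burden_tables <- function(labeled, cohort, groups = NULL) {
  groups <- groups %||% unique(cohort$group)
  if (length(groups) != 2L)
    config_error("tp_burden_tables: exactly two groups required")
  tp <- labeled[labeled$label == "TP", , drop = FALSE]
  ntp <- table(factor(tp$sample, levels = cohort$sample))
  per_group <- lapply(groups, function(g) {
    s <- cohort$sample[cohort$group == g]
    c(n = length(s), any = sum(ntp[s] >= 1), multi = sum(ntp[s] >= 2))
  })
  names(per_group) <- groups
  g1 <- per_group[[1L]]; g2 <- per_group[[2L]]
  list(
    any_tp = two_by_two(g1["any"], g1["n"] - g1["any"],
                        g2["any"], g2["n"] - g2["any"]),
    multiple_tp = two_by_two(g1["multi"], g1["n"] - g1["multi"],
                             g2["multi"], g2["n"] - g2["multi"]),
    counts = do.call(rbind, per_group))
}
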
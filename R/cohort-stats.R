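# Frequency tables over clone representatives and cohort statistics:
# Fisher's exact test (2x2, analytic; r x c, Monte Carlo with fixed
# margins), Kruskal-Wallis, Dunn's post hoc with Bonferroni correction,
# and the Cochran-Mantel-Haenszel test over stratified 2x2 tables.

test_result <- function(test_name, statistic, p_value, ...) {
  structure(c(list(test_name = test_name, statistic = statistic,
                   p_value = p_value), list(...)),
            class = "stereorep_test")
}

#' @export
print.stereorep_test <- function(x, ...) {
  cat(x$test_name, ": ",
      if (!is.null(x$statistic) && !is.na(x$statistic))
        paste0("statistic = ", format(x$statistic, digits = 5), ", ") else "",
      "p = ", format(x$p_value, digits = 5), "\n", sep = "")
  invisible(x)
}

#' Per-group frequency table
#'
#' Counts and percentages of stereotype assignments, computed at clone
#' level (pass representative records only). Percentages are
#' `100 * count / total_clones`, rounded half away from zero at the
#' requested precision, and always recomputable exactly from the integer
#' counts.
#'
#' @param assignments Data frame with `subset_id` (`NA` = not stereotyped)
#'   and `population_label` columns, one row per clone representative.
#' @param total_clones Denominator: total number of clonal families
#'   (must be at least the number of stereotyped assignments).
#' @param grouping One of `"by_subset"`, `"by_population"`,
#'   `"by_subset_and_population"`, `"by_cd5_status"`.
#' @param decimals Decimal places for the reported percentages.
#' @return Data frame (class `frequency_report`) with `group` (or
#'   `subset_id`/`population_label` pair), `count`, `percent`; attributes
#'   `total`, `decimals`, `grouping`.
#' @export
frequency_table <- function(assignments, total_clones,
                            grouping = c("by_subset", "by_population",
                                         "by_subset_and_population",
                                         "by_cd5_status"),
                            decimals = 2L) {
  grouping <- match.arg(grouping)
  stopifnot(decimals >= 0)
  if (total_clones == 0) stop("total_clones must be positive")
  cbs <- assignments[!is.na(assignments$subset_id), , drop = FALSE]
  if (total_clones < nrow(cbs))
    stop("total_clones (", total_clones, ") smaller than number of ",
         "stereotyped assignments (", nrow(cbs), ")")
  tab <- switch(grouping,
    by_subset = {
      t <- table(cbs$subset_id)
      data.frame(group = names(t), count = as.integer(t),
                 stringsAsFactors = FALSE)
    },
    by_population = {
      t <- table(cbs$population_label)
      data.frame(group = names(t), count = as.integer(t),
                 stringsAsFactors = FALSE)
    },
    by_subset_and_population = {
      t <- table(cbs$subset_id, cbs$population_label)
      d <- as.data.frame(t, stringsAsFactors = FALSE)
      names(d) <- c("subset_id", "population_label", "count")
      d$count <- as.integer(d$count)
      d
    },
    by_cd5_status = {
      sel <- cbs$population_label %in% c("CD5pos", "CD5neg")
      t <- table(factor(cbs$population_label[sel],
                        levels = c("CD5pos", "CD5neg")))
      data.frame(group = names(t), count = as.integer(t),
                 stringsAsFactors = FALSE)
    })
  tab$percent <- round_half_away(100 * tab$count / total_clones, decimals)
  structure(tab, class = c("frequency_report", "data.frame"),
            total = total_clones, decimals = decimals, grouping = grouping)
}

#' Percentage of a count over a total, report-rounded
#'
#' Convenience for reproducing printed report arithmetic:
#' `subset_percent(142, 117027, 2)` is `0.12`.
#'
#' @param count,total Nonnegative integers, `total > 0`.
#' @param decimals Decimal places.
#' @return `100 * count / total` rounded half away from zero.
#' @export
subset_percent <- function(count, total, decimals = 2L) {
  if (total <= 0) stop("total must be positive")
  round_half_away(100 * count / total, decimals)
}

check_2x2 <- function(m) {
  if (!is.matrix(m) || any(dim(m) != 2L))
    stop("a 2x2 matrix is required")
  if (any(m < 0) || any(m != round(m))) stop("counts must be nonnegative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate table: a margin is zero")
  invisible(m)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing, over all tables with the observed
#' margins, the hypergeometric probabilities not exceeding that of the
#' observed table.
#'
#' @param table 2x2 matrix of nonnegative integer counts with all margins
#'   positive.
#' @return A `stereorep_test` with `p_value` (statistic not applicable).
#' @export
fisher_exact_2x2 <- function(table) {
  check_2x2(table)
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ]); c1 <- sum(table[, 1])
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(table[1, 1], r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  test_result("fisher_exact", NA_real_, min(p, 1))
}

# log multivariate hypergeometric probability of an r x c table given its
# margins (the null distribution Fisher's test conditions on)
log_table_prob <- function(m) {
  sum(lgamma(rowSums(m) + 1)) + sum(lgamma(colSums(m) + 1)) -
    lgamma(sum(m) + 1) - sum(lgamma(m + 1))
}

#' Fisher's exact test with Monte Carlo simulated p-value
#'
#' For an r x c table, simulates tables with the observed margins from the
#' null (multivariate hypergeometric) distribution and estimates the
#' two-sided p-value as `(1 + #{simulated tables at most as probable as
#' the observed}) / (1 + iterations)` — the +1 correction keeps the
#' estimate unbiased and never reports 0. Bit-reproducible for a fixed
#' seed.
#'
#' @param table r x c matrix of nonnegative integers, all row and column
#'   sums positive.
#' @param iterations Number of simulated tables (>= 1000).
#' @param seed Integer seed (global RNG state is restored afterwards).
#' @return A `stereorep_test` with `p_value`, `mc_iterations`, `seed`.
#' @export
fisher_exact_mc <- function(table, iterations = 10000L, seed = 1L) {
  if (!is.matrix(table) || any(table < 0) || any(table != round(table)))
    stop("a matrix of nonnegative integer counts is required")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0))
    stop("degenerate table: a margin is zero")
  if (iterations < 1000) stop("iterations must be >= 1000")
  lp_obs <- log_table_prob(table)
  const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(sum(table) + 1)
  hits <- with_seed(seed, {
    sims <- stats::r2dtable(iterations, rs, cs)
    lp <- vapply(sims, function(t) const - sum(lgamma(t + 1)), numeric(1))
    sum(lp <= lp_obs + 1e-7)
  })
  test_result("fisher_mc", NA_real_, (1 + hits) / (1 + iterations),
              mc_iterations = as.integer(iterations), seed = as.integer(seed))
}

rank_groups <- function(groups) {
  stopifnot(length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("every group must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  r <- rank(x)
  ties <- table(x)
  list(x = x, g = g, r = r, N = length(x),
       tie_term = sum(ties^3 - ties))
}

#' Kruskal-Wallis rank-sum test
#'
#' H statistic with tie correction; p-value from the chi-square
#' approximation with k - 1 degrees of freedom. When all observations are
#' identical, H = 0 and p = 1.
#'
#' @param groups List of (>= 2) non-empty numeric vectors.
#' @return A `stereorep_test` with `statistic` (H), `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  rk <- rank_groups(groups)
  N <- rk$N
  Rj <- tapply(rk$r, rk$g, sum)
  nj <- tabulate(rk$g)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  C <- 1 - rk$tie_term / (N^3 - N)
  if (C <= 0) {
    H <- 0; p <- 1
  } else {
    H <- H / C
    p <- stats::pchisq(H, df = length(groups) - 1, lower.tail = FALSE)
  }
  test_result("kruskal_wallis", H, p, df = length(groups) - 1)
}

#' Dunn's post hoc test with Bonferroni correction
#'
#' Pairwise z statistics on mean ranks (large-sample normal approximation
#' with tie correction); each two-sided p-value is multiplied by the
#' number of comparisons and capped at 1.
#'
#' @param groups List of (>= 3) non-empty numeric vectors.
#' @return Data frame with one row per pair: `group1`, `group2`, `z`,
#'   `p_value`, `p_adjusted`.
#' @export
dunn_bonferroni <- function(groups) {
  stopifnot(length(groups) >= 3)
  rk <- rank_groups(groups)
  N <- rk$N
  nj <- tabulate(rk$g)
  meanR <- tapply(rk$r, rk$g, mean)
  sigma2 <- N * (N + 1) / 12 - rk$tie_term / (12 * (N - 1))
  k <- length(groups)
  m <- k * (k - 1) / 2
  labels <- if (is.null(names(groups))) as.character(seq_len(k))
            else names(groups)
  out <- list()
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    se <- sqrt(sigma2 * (1 / nj[i] + 1 / nj[j]))
    z <- if (se <= 0) 0 else (meanR[[i]] - meanR[[j]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    out[[length(out) + 1L]] <- data.frame(
      group1 = labels[i], group2 = labels[j], z = z, p_value = p,
      p_adjusted = min(1, p * m), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Cochran-Mantel-Haenszel test over stratified 2x2 tables
#'
#' Mantel-Haenszel chi-square (1 df) pooling the per-stratum deviations of
#' the top-left cell from its conditional expectation. Continuity
#' correction off by default. Strata with a zero margin or fewer than two
#' observations contribute nothing; an error is raised if every stratum is
#' degenerate.
#'
#' @param strata List of 2x2 matrices of nonnegative integer counts.
#' @param correct Apply the 0.5 continuity correction.
#' @return A `stereorep_test` with `statistic`, `p_value`, `df = 1`.
#' @export
cmh_test <- function(strata, correct = FALSE) {
  stopifnot(length(strata) >= 1)
  num <- 0; den <- 0; used <- 0L
  for (m in strata) {
    if (!is.matrix(m) || any(dim(m) != 2L)) stop("strata must be 2x2 matrices")
    n <- sum(m)
    if (n < 2 || any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
    c1 <- sum(m[, 1]); c2 <- sum(m[, 2])
    num <- num + m[1, 1] - r1 * c1 / n
    den <- den + r1 * r2 * c1 * c2 / (n^2 * (n - 1))
    used <- used + 1L
  }
  if (used == 0L || den <= 0)
    stop("all strata degenerate: CMH statistic undefined")
  stat <- (abs(num) - if (correct) 0.5 else 0)^2 / den
  if (correct && abs(num) < 0.5) stat <- 0
  test_result("cmh", stat, stats::pchisq(stat, df = 1, lower.tail = FALSE),
              df = 1, n_strata = used)
}

#' Compare per-subset distributions of two cohorts
#'
#' Builds the subsets x cohorts contingency table from two aligned count
#' vectors (subsets absent from both cohorts are dropped) and applies
#' Fisher's exact test with Monte Carlo simulated p-value.
#'
#' @param cohort_a_counts,cohort_b_counts Named integer vectors over the
#'   same subset labels.
#' @param iterations,seed Passed to [fisher_exact_mc()].
#' @return A `stereorep_test`.
#' @export
compare_subset_distributions <- function(cohort_a_counts, cohort_b_counts,
                                         iterations = 10000L, seed = 1L) {
  if (is.null(names(cohort_a_counts)) || is.null(names(cohort_b_counts)) ||
      !setequal(names(cohort_a_counts), names(cohort_b_counts)))
    stop("both cohorts must be named over the same subset label set")
  b <- cohort_b_counts[names(cohort_a_counts)]
  tab <- cbind(a = cohort_a_counts, b = b)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  fisher_exact_mc(tab, iterations = iterations, seed = seed)
}
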
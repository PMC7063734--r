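# Frequency arithmetic and the cohort statistics, cross-checked against
# independent oracles (enumeration, base-R reference implementations).

test_that("subset_percent reproduces printed report arithmetic", {
  expect_equal(subset_percent(142, 117027, 2), 0.12)
  expect_equal(subset_percent(10, 117027, 3), 0.009)
  expect_equal(subset_percent(6, 117027, 3), 0.005)
  expect_equal(subset_percent(0, 117027, 2), 0.0)
  expect_error(subset_percent(1, 0), "positive")
})

test_that("frequency_table counts stereotyped clones and rounds as declared", {
  reps <- data.frame(
    subset_id = c("#12", "#12", "#28A", NA, NA, "#12"),
    population_label = c("FM", "GC", "FM", "FM", "MZ", "CD5pos"),
    stringsAsFactors = FALSE)
  ft <- frequency_table(reps, total_clones = 200, grouping = "by_subset",
                        decimals = 2)
  expect_equal(ft$count[ft$group == "#12"], 3L)
  expect_equal(ft$percent[ft$group == "#12"], 1.5)
  # percentages recompute exactly from counts and total
  expect_equal(ft$percent,
               round_half_away(100 * ft$count / attr(ft, "total"),
                               attr(ft, "decimals")))
  expect_equal(sum(ft$count), 4L)

  bypop <- frequency_table(reps, 200, "by_population", 2)
  expect_equal(sum(bypop$count), 4L)
  expect_error(frequency_table(reps, 0), "positive")
  expect_error(frequency_table(reps, 2), "smaller")
})

test_that("half-away-from-zero rounding is used, not banker's rounding", {
  expect_equal(round_half_away(0.125, 2), 0.13)
  expect_equal(round_half_away(-0.125, 2), -0.13)
  expect_equal(round_half_away(2.5, 0), 3)
})

test_that("fisher_exact_2x2 matches hand enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))$p_value, 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p_value, 1 / 3)
  expect_equal(fisher_exact_2x2(matrix(c(0, 5, 5, 0), 2))$p_value, 2 / 252)
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 2), 2)), "margin")
})

test_that("fisher_exact_2x2 agrees with the reference implementation", {
  set.seed(17)
  for (i in 1:50) {
    m <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(fisher_exact_2x2(m)$p_value,
                 stats::fisher.test(m)$p.value, tolerance = 1e-10)
  }
})

test_that("fisher_exact_mc is seed-deterministic and sane on extremes", {
  m <- matrix(c(8, 2, 3, 9), 2)
  a <- fisher_exact_mc(m, iterations = 2000, seed = 42)
  b <- fisher_exact_mc(m, iterations = 2000, seed = 42)
  expect_identical(a$p_value, b$p_value)
  expect_error(fisher_exact_mc(m, iterations = 10), "1000")

  # independence-perfect table (outer-product margins) is the modal table
  r <- c(10, 20, 30); cc <- c(12, 24, 24)
  perfect <- outer(r, cc) / 60
  expect_true(all(perfect == round(perfect)))
  p <- fisher_exact_mc(perfect, iterations = 2000, seed = 7)$p_value
  expect_gte(p, 0.99)
})

test_that("kruskal_wallis matches the hand-ranked example and the reference", {
  kw0 <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p_value, 1)

  kw <- kruskal_wallis(list(c(1, 2, 3), c(10, 11, 12), c(20, 21, 22)))
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$p_value, pchisq(7.2, 2, lower.tail = FALSE))

  expect_error(kruskal_wallis(list(1:3, numeric())), "non-empty")

  set.seed(19)
  for (i in 1:20) {
    groups <- lapply(1:sample(2:5, 1), function(k)
      sample(1:8, sample(3:12, 1), replace = TRUE))  # ties on purpose
    got <- kruskal_wallis(groups)
    ref <- stats::kruskal.test(groups)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("dunn_bonferroni has the Bonferroni properties", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  d0 <- dunn_bonferroni(same)
  expect_true(all(d0$p_adjusted == 1))

  set.seed(23)
  groups <- lapply(1:4, function(k) rnorm(8, mean = k))
  d <- dunn_bonferroni(groups)
  expect_equal(nrow(d), 6L)  # k(k-1)/2
  expect_true(all(d$p_adjusted >= d$p_value))
  expect_true(all(d$p_adjusted <= 1))
  # strongly separated extreme groups should reject
  expect_lt(d$p_adjusted[d$group1 == "1" & d$group2 == "4"], 0.05)
})

test_that("cmh_test matches the single-stratum formula and the reference", {
  null_strata <- replicate(3, matrix(c(50, 50, 50, 50), 2), simplify = FALSE)
  res <- cmh_test(null_strata)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  expect_equal(cmh_test(list(matrix(c(10, 10, 10, 10), 2)))$statistic, 0)

  s <- matrix(c(12, 5, 7, 14), 2)
  one <- cmh_test(list(s))
  two <- cmh_test(list(s, s))
  # duplicating a stratum doubles numerator and denominator consistently
  n <- sum(s)
  num1 <- s[1, 1] - sum(s[1, ]) * sum(s[, 1]) / n
  den1 <- prod(rowSums(s)) * prod(colSums(s)) / (n^2 * (n - 1))
  expect_equal(one$statistic, num1^2 / den1)
  expect_equal(two$statistic, (2 * num1)^2 / (2 * den1))

  set.seed(29)
  strata <- replicate(4, matrix(rpois(4, 15) + 1, 2), simplify = FALSE)
  got <- cmh_test(strata)
  ref <- stats::mantelhaen.test(
    array(unlist(strata), dim = c(2, 2, 4)), correct = FALSE)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)

  expect_error(cmh_test(list(matrix(c(0, 0, 1, 1), 2))), "degenerate")
})

test_that("compare_subset_distributions wraps the Monte Carlo Fisher test", {
  a <- c("#1" = 30, "#12" = 40, "#28A" = 30)
  same <- compare_subset_distributions(a, a, iterations = 2000, seed = 3)
  expect_gte(same$p_value, 0.99)

  b <- c("#1" = 0, "#12" = 0, "#28A" = 100)
  disjoint <- compare_subset_distributions(
    c("#1" = 100, "#12" = 100, "#28A" = 0), b,
    iterations = 2000, seed = 3)
  expect_lte(disjoint$p_value, 0.01)

  r1 <- compare_subset_distributions(a, b, iterations = 2000, seed = 5)
  r2 <- compare_subset_distributions(a, b, iterations = 2000, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  expect_error(compare_subset_distributions(a, c(x = 1)), "label")
})
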
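# Table of paired stage counts (combined rows x planar columns) used by the
# Bowker-statistic checks: 4 discordant symmetric pairs.
stage_table_6x6 <- function() {
  labs <- c("P-1", "P-2", "P-3", "T-4", "T-5", "T-6")
  m <- matrix(0, 6, 6, dimnames = list(combined = labs, planar = labs))
  diag(m) <- c(1, 12, 4, 5, 4, 7)
  m["P-2", "P-1"] <- 2
  m["P-2", "T-6"] <- 1
  m["P-3", "T-4"] <- 2
  m["P-3", "T-5"] <- 1
  m
}

test_that("McNemar-Bowker matches direct summation and handles zero pairs", {
  tab <- stage_table_6x6()
  r <- mcnemar(tab)
  # direct summation oracle over discordant symmetric pairs
  stat <- 0; df <- 0
  for (i in 1:5) for (j in (i + 1):6) {
    s <- tab[i, j] + tab[j, i]
    if (s > 0) { stat <- stat + (tab[i, j] - tab[j, i])^2 / s; df <- df + 1 }
  }
  expect_lt(abs(r$statistic - stat), 1e-9)
  expect_equal(r$statistic, 6) # (2^2/2 + 1 + 2^2/2 + 1)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, pchisq(6, 4, lower.tail = FALSE))

  # with no empty symmetric pairs, agrees with stats::mcnemar.test
  set.seed(3)
  full <- matrix(rpois(16, 5) + 1, 4, 4)
  expect_lt(abs(mcnemar(full)$statistic -
                  unname(mcnemar.test(full)$statistic)), 1e-9)

  # all mass on the diagonal -> statistic 0
  expect_equal(mcnemar(diag(c(3, 5, 2)))$statistic, 0)
  expect_error(mcnemar(matrix(1, 2, 3)), "square")
})

test_that("2x2 McNemar: symmetric discordance gives exact p = 1", {
  tab <- matrix(c(10, 5, 5, 10), 2, 2)
  ex <- mcnemar(tab, exact = TRUE)
  expect_equal(ex$p_value, 1)
  uncor <- mcnemar(tab, correct = FALSE)
  expect_equal(uncor$statistic, 0)
  # hand value with continuity correction: (|b-c|-1)^2/(b+c)
  expect_lt(abs(mcnemar(matrix(c(10, 2, 9, 10), 2, 2))$statistic -
                  (abs(9 - 2) - 1)^2 / 11), 1e-9)
})

test_that("Kruskal-Wallis H matches the tie-corrected hand formula", {
  set.seed(11)
  groups <- list(round(rnorm(6), 1), round(rnorm(7), 1), round(rnorm(5), 1))
  r <- kruskal_wallis(groups)
  x <- unlist(groups); g <- rep(1:3, lengths(groups)); n <- length(x)
  rk <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(rk, g, sum)^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(x)
  h <- h / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_lt(abs(r$statistic - h), 1e-9)

  expect_equal(kruskal_wallis(list(rep(1, 5), rep(1, 4)))$statistic, 0)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "size zero")
  expect_error(kruskal_wallis(list(1:3)), "two groups")
})

test_that("Dunn-Bonferroni post hoc never shrinks p and caps at 1", {
  set.seed(5)
  groups <- list(a = rnorm(8), b = rnorm(8, 2), c = rnorm(8, 4))
  ph <- dunn_bonferroni(groups)
  expect_equal(nrow(ph), 3)
  expect_true(all(ph$p_bonferroni >= ph$p_raw - 1e-15))
  expect_true(all(ph$p_bonferroni <= 1))
  expect_lt(ph$p_bonferroni[ph$group_a == "a" & ph$group_b == "c"], 0.05)
})

test_that("Mann-Whitney U matches brute-force counting and permutation p", {
  set.seed(7)
  a <- rnorm(6); b <- rnorm(5)
  r <- mann_whitney(a, b, exact = TRUE)
  u <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  expect_lt(abs(r$statistic - u), 1e-9)

  # exhaustive permutation oracle for the exact two-sided p (no ties)
  pooled <- c(a, b)
  combos <- combn(11, 6)
  us <- apply(combos, 2, function(ix)
    sum(outer(pooled[ix], pooled[-ix], ">")))
  mu <- length(a) * length(b) / 2
  p_perm <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
  expect_lt(abs(r$p_value - p_perm), 1e-9)

  # self-comparison is null: p = 1 within numerical tolerance
  expect_gt(mann_whitney(a, a)$p_value, 0.999)
  expect_error(mann_whitney(a, numeric(0)), "non-empty")
})

test_that("Spearman correlation equals the rank correlation", {
  expect_equal(spearman(1:8, c(2, 3, 5, 8, 9, 12, 20, 31))$estimate, 1)
  expect_equal(spearman(1:8, 8:1)$estimate, -1)
  set.seed(13)
  x <- rnorm(10); y <- rnorm(10)
  expect_lt(abs(spearman(x, y)$estimate - cor(rank(x), rank(y))), 1e-9)
  expect_error(spearman(1:4, 1:5), "equal length")
  expect_error(spearman(1:2, 2:1), "at least 3")
})

test_that("linear-by-linear trend: algebraic identities hold", {
  # symmetric table with zero score correlation
  sym <- matrix(c(5, 0, 5, 0, 10, 0, 5, 0, 5), 3, 3)
  expect_lt(abs(linear_by_linear(sym)$statistic), 1e-12)

  # 2x2: M^2 = (N-1)/N * Pearson chi-squared
  tab <- matrix(c(12, 5, 3, 14), 2, 2)
  n <- sum(tab)
  chi <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
  expect_lt(abs(linear_by_linear(tab)$statistic -
                  (n - 1) / n * unname(chi)), 1e-9)

  # perfectly monotone 5x2 table at N = 41 is strongly significant
  mono <- cbind(c(8, 8, 8, 0, 0), c(0, 0, 1, 8, 8))
  r <- linear_by_linear(mono)
  expect_equal(sum(mono), 41)
  expect_lt(r$p_value, 0.01)
  expect_error(linear_by_linear(matrix(c(1, 0), 1, 2)), "at least 2")
})

test_that("weighted kappa matches a direct O/E computation and the bands", {
  a <- c(1, 2, 3, 4, 5, 1, 2, 3)
  b <- c(1, 2, 3, 4, 5, 1, 2, 3)
  perfect <- weighted_kappa(a, b)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$band, "almost perfect")

  set.seed(2)
  x <- sample(1:5, 40, replace = TRUE)
  y <- pmin(5, pmax(1, x + sample(-1:1, 40, replace = TRUE)))
  for (scheme in c("linear", "quadratic")) {
    got <- weighted_kappa(x, y, scheme)$kappa
    # direct summation oracle
    k <- 5
    obs <- table(factor(x, 1:5), factor(y, 1:5)) / 40
    ex <- outer(rowSums(obs), colSums(obs))
    w <- abs(outer(1:5, 1:5, `-`)) / (k - 1)
    if (scheme == "quadratic") w <- w^2
    expect_lt(abs(got - (1 - sum(w * obs) / sum(w * ex))), 1e-9)
  }
  expect_error(weighted_kappa(1:3, 1:4), "equal length")
  expect_error(weighted_kappa(c("a", "a"), c("b", "b")), "share no")
})

test_that("independent ratings give kappa near zero", {
  set.seed(99)
  a <- sample(1:5, 5000, replace = TRUE)
  b <- sample(1:5, 5000, replace = TRUE)
  expect_lt(abs(weighted_kappa(a, b)$kappa), 0.05)
})

test_that("kappa agreement bands follow the conventional cuts", {
  expect_equal(kappa_band(0.896), "almost perfect")
  expect_equal(kappa_band(-0.3), "poor")
})

test_that("the normality gate selects the display form", {
  set.seed(21)
  skewed <- exp(rnorm(60, sd = 1.2))
  s <- summarize_numeric(skewed)
  expect_lt(s$shapiro_p, 0.05)
  expect_equal(s$display, "median_iqr")

  picks <- vapply(1:50, function(i) {
    set.seed(1000 + i)
    summarize_numeric(rnorm(200))$display
  }, character(1))
  expect_gte(mean(picks == "mean_sd"), 0.9)

  const <- summarize_numeric(rep(3.2, 10))
  expect_match(const$flag, "degenerate")
  expect_equal(const$display, "median_iqr")
  tiny <- summarize_numeric(c(1, 2))
  expect_match(tiny$flag, "n < 3")
})
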
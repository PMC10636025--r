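## Nonparametric statistical battery used for the cohort analyses. Standard
## tests are delegated to the stats package where it provides them; the
## McNemar-Bowker generalisation (with zero-pair handling), Dunn's post-hoc
## z-tests, the linear-by-linear trend statistic and weighted kappa are
## computed here.

test_result <- function(method, statistic, p_value, df = NA_real_,
                        estimate = NULL, posthoc = NULL, ...) {
  structure(list(method = method, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value),
                 estimate = estimate, posthoc = posthoc, ...),
            class = "lymph_test")
}

#' @export
print.lymph_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g\n", x$method, x$statistic,
              if (is.finite(x$df)) sprintf(" (df = %g)", x$df) else "",
              x$p_value))
  invisible(x)
}

#' McNemar test for paired categorical readings
#'
#' For a 2x2 table the classic McNemar chi-squared statistic is computed
#' (continuity-corrected by default), with an optional exact binomial p
#' based on the discordant pairs. For a K x K table the McNemar-Bowker
#' generalisation is used: the sum of `(n_ij - n_ji)^2 / (n_ij + n_ji)`
#' over discordant symmetric pairs; pairs with `n_ij + n_ji = 0` carry no
#' information and are skipped, with the degrees of freedom reduced
#' accordingly.
#'
#' @param table square integer matrix of paired counts.
#' @param correct apply the continuity correction in the 2x2 case.
#' @param exact use the exact binomial p-value in the 2x2 case.
#' @return A test-result list (`statistic`, `df`, `p_value`, `method`).
#' @export
mcnemar <- function(table, correct = TRUE, exact = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) != ncol(table))
    stop("table must be square", call. = FALSE)
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  k <- nrow(table)
  if (k == 2) {
    b <- table[1, 2]
    c_ <- table[2, 1]
    if (exact) {
      p <- if (b + c_ == 0) 1 else binom.test(b, b + c_, 0.5)$p.value
      stat <- if (b + c_ == 0) 0 else (abs(b - c_))^2 / (b + c_)
      return(test_result("McNemar exact (binomial)", stat, p, df = NA_real_,
                         discordant = b + c_))
    }
    stat <- if (b + c_ == 0) 0 else
      (abs(b - c_) - if (correct) 1 else 0)^2 / (b + c_)
    stat <- max(stat, 0)
    p <- if (b + c_ == 0) 1 else pchisq(stat, 1, lower.tail = FALSE)
    return(test_result(
      paste0("McNemar chi-squared",
             if (correct) " (continuity corrected)" else ""),
      stat, p, df = 1))
  }
  stat <- 0
  df <- 0L
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      s <- table[i, j] + table[j, i]
      if (s == 0) next
      stat <- stat + (table[i, j] - table[j, i])^2 / s
      df <- df + 1L
    }
  }
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  test_result("McNemar-Bowker chi-squared", stat, p, df = df)
}

#' Kruskal-Wallis rank-sum test over a list of groups
#'
#' Tie-corrected H statistic via [stats::kruskal.test()].
#'
#' @param groups list of numeric vectors, each non-empty, at least two
#'   groups.
#' @return A test-result list.
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1) # all observations tied: no rank variation
    return(test_result("Kruskal-Wallis rank sum", 0, 1,
                       df = length(groups) - 1))
  kt <- kruskal.test(x, g)
  test_result("Kruskal-Wallis rank sum", kt$statistic, kt$p.value,
              df = kt$parameter)
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of at least two groups", call. = FALSE)
  if (any(lengths(groups) == 0))
    stop("group(s) of size zero: ",
         paste(which(lengths(groups) == 0), collapse = ", "), call. = FALSE)
  invisible(groups)
}

#' Dunn's post-hoc pairwise z-tests with Bonferroni adjustment
#'
#' Mid-rank based pairwise comparisons after a Kruskal-Wallis test, with
#' the usual tie correction; p-values are Bonferroni-adjusted over all
#' pairs (adjusted p is never below the raw p and caps at 1).
#'
#' @param groups list of numeric vectors (named or not).
#' @return data.frame with one row per pair: `group_a`, `group_b`, `z`,
#'   `p_raw`, `p_bonferroni`.
#' @export
dunn_bonferroni <- function(groups) {
  check_groups(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(r, g, mean)
  ni <- lengths(groups)
  pairs <- utils::combn(seq_along(groups), 2)
  out <- data.frame(group_a = nm[pairs[1, ]], group_b = nm[pairs[2, ]],
                    z = NA_real_, p_raw = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni[i] + 1 / ni[j]))
    z <- (mean_rank[[i]] - mean_rank[[j]]) / se
    out$z[k] <- z
    out$p_raw[k] <- 2 * pnorm(-abs(z))
  }
  out$p_bonferroni <- pmin(1, out$p_raw * nrow(out))
  out
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided, mid-ranks for ties, via [stats::wilcox.test()]. The
#' exact/asymptotic switch is explicit, never silent.
#'
#' @param a,b non-empty numeric samples.
#' @param exact logical or `NULL` (the stats default: exact for small
#'   untied samples).
#' @param correct continuity correction in the normal approximation.
#' @return A test-result list (`statistic` is the U statistic).
#' @export
mann_whitney <- function(a, b, exact = NULL, correct = TRUE) {
  if (!length(a) || !length(b))
    stop("both samples must be non-empty", call. = FALSE)
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = correct))
  test_result("Mann-Whitney U", wt$statistic, wt$p.value)
}

#' Spearman rank correlation
#'
#' Mid-ranks for ties; two-sided p from the asymptotic t approximation.
#'
#' @param x,y numeric vectors of equal length, at least 3.
#' @return A test-result list with `estimate` = rho.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3)
    stop("need at least 3 paired observations", call. = FALSE)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  test_result("Spearman rank correlation", ct$statistic, ct$p.value,
              estimate = unname(ct$estimate))
}

#' Linear-by-linear association (Mantel-Haenszel trend) test
#'
#' For a two-way table of ordered categories with row and column scores,
#' the statistic is `M^2 = (N - 1) r^2` where `r` is the Pearson
#' correlation of the scores weighted by the cell counts; p comes from the
#' chi-squared distribution with 1 df.
#'
#' @param table matrix of non-negative counts.
#' @param row_scores,col_scores numeric scores for the ordered categories;
#'   default consecutive integers.
#' @return A test-result list with `estimate` = the score correlation r.
#' @export
linear_by_linear <- function(table, row_scores = seq_len(nrow(table)),
                             col_scores = seq_len(ncol(table))) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- sum(table)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  stopifnot(length(row_scores) == nrow(table),
            length(col_scores) == ncol(table))
  p <- table / n
  mu_r <- sum(rowSums(p) * row_scores)
  mu_c <- sum(colSums(p) * col_scores)
  var_r <- sum(rowSums(p) * (row_scores - mu_r)^2)
  var_c <- sum(colSums(p) * (col_scores - mu_c)^2)
  cov_rc <- sum(outer(row_scores - mu_r, col_scores - mu_c) * p)
  r <- if (var_r > 0 && var_c > 0) cov_rc / sqrt(var_r * var_c) else 0
  m2 <- (n - 1) * r^2
  test_result("Linear-by-linear association", m2,
              pchisq(m2, 1, lower.tail = FALSE), df = 1, estimate = r)
}

#' Weighted kappa for two ordinal rating vectors
#'
#' `kappa = 1 - sum(w * O) / sum(w * E)` with linear (default) or quadratic
#' disagreement weights over a shared ordered category set, plus the
#' conventional agreement band for the point estimate: poor (up to 0.20),
#' fair (0.21-0.40), moderate (0.41-0.60), substantial (0.61-0.80), almost
#' perfect (0.81-1.00); negative values fall in the poor band.
#'
#' @param ratings_a,ratings_b equal-length vectors of ordinal ratings.
#' @param scheme `"linear"` or `"quadratic"` weights.
#' @param categories ordered category levels; defaults to the sorted union
#'   of both vectors. The two raters must share at least this set; vectors
#'   with no categories in common raise an error.
#' @return List of class `kappa_result`: `kappa`, `scheme`, `band`, `n`.
#' @export
weighted_kappa <- function(ratings_a, ratings_b,
                           scheme = c("linear", "quadratic"),
                           categories = NULL) {
  scheme <- match.arg(scheme)
  if (length(ratings_a) != length(ratings_b))
    stop("rating vectors must have equal length", call. = FALSE)
  if (!length(ratings_a)) stop("ratings are empty", call. = FALSE)
  if (!length(intersect(unique(ratings_a), unique(ratings_b))))
    stop("raters share no categories", call. = FALSE)
  if (is.null(categories))
    categories <- sort(unique(c(ratings_a, ratings_b)))
  if (!all(c(ratings_a, ratings_b) %in% categories))
    stop("ratings outside the declared category set", call. = FALSE)
  a <- factor(ratings_a, levels = categories)
  b <- factor(ratings_b, levels = categories)
  k <- length(categories)
  obs <- table(a, b) / length(a)
  exp_ <- outer(rowSums(obs), colSums(obs))
  d <- abs(outer(seq_len(k), seq_len(k), `-`))
  w <- if (scheme == "linear") d / (k - 1) else (d / (k - 1))^2
  denom <- sum(w * exp_)
  kap <- if (denom == 0) 1 else 1 - sum(w * obs) / denom
  structure(list(kappa = kap, scheme = scheme, band = kappa_band(kap),
                 n = length(a)),
            class = "kappa_result")
}

#' Agreement band for a kappa value
#'
#' @param kappa numeric kappa in \[-1, 1\].
#' @return One of `"poor"`, `"fair"`, `"moderate"`, `"substantial"`,
#'   `"almost perfect"`.
#' @export
kappa_band <- function(kappa) {
  stopifnot(is.numeric(kappa), kappa >= -1, kappa <= 1 + 1e-12)
  if (kappa <= 0.20) "poor"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost perfect"
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("weighted kappa (%s) = %.3f [%s], n = %d\n",
              x$scheme, x$kappa, x$band, x$n))
  invisible(x)
}

#' Normality-gated numeric summary
#'
#' Computes both the mean/SD and the median/IQR of a sample and selects the
#' display form with a Shapiro-Wilk normality gate at alpha = 0.05:
#' mean (SD) when normality is accepted, median (IQR) when rejected. Both
#' forms are always retained; the gate only selects which one is displayed.
#' Samples of fewer than 3 values, or degenerate (constant) samples, skip
#' the gate and are flagged.
#'
#' @param values numeric vector.
#' @param alpha significance level of the normality gate.
#' @return List: `n`, `mean`, `sd`, `median`, `q1`, `q3`, `shapiro_p`,
#'   `display` (`"mean_sd"` or `"median_iqr"`), `flag`.
#' @export
summarize_numeric <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  out <- list(n = n, mean = mean(values), sd = sd(values),
              median = median(values),
              q1 = unname(quantile(values, 0.25)),
              q3 = unname(quantile(values, 0.75)),
              shapiro_p = NA_real_, display = "median_iqr", flag = NULL)
  if (n < 3) {
    out$flag <- "n < 3: normality gate not applicable"
    return(out)
  }
  if (length(unique(values)) == 1) {
    out$flag <- "degenerate (constant) sample"
    return(out)
  }
  sw <- shapiro.test(values)
  out$shapiro_p <- sw$p.value
  out$display <- if (sw$p.value >= alpha) "mean_sd" else "median_iqr"
  out
}
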
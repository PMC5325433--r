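test_that("Kaplan-Meier estimate matches hand product-limit results", {
  no_events <- km_estimate(c(3, 5, 9), c(0, 0, 0))
  expect_true(all(no_events$surv == 1))
  both <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(both$surv, c(0.5, 0))
  # with no censoring, S(t) = 1 - ECDF at event times
  set.seed(31)
  t <- round(rexp(40, 0.1), 3)
  km <- km_estimate(t, rep(1, 40))
  expect_equal(km$surv, 1 - ecdf(t)(km$time))
  expect_true(all(diff(km$surv) <= 0) && all(km$surv >= 0 & km$surv <= 1))
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("Gehan-Wilcoxon statistic is zero for identical groups", {
  set.seed(32)
  t <- rexp(15); e <- rbinom(15, 1, 0.7)
  res <- gehan_wilcoxon_test(c(t, t), c(e, e), rep(c("a", "b"), each = 15))
  expect_equal(res$statistic, 0, tolerance = 1e-10)
  expect_error(gehan_wilcoxon_test(t, e, rep("a", 15)), "two groups")
})

test_that("chi-square approximation tracks the exact permutation p at small n", {
  set.seed(33)
  for (rep in 1:4) {
    t <- round(rexp(10, 0.2), 2)
    e <- rbinom(10, 1, 0.8)
    g <- rep(c("a", "b"), each = 5)
    res <- gehan_wilcoxon_test(t, e, g)  # n <= 12 -> exact permutation
    expect_false(is.null(res$p_permutation))
    expect_equal(res$p_value, res$p_permutation)
    expect_lt(abs(res$p_chisq - res$p_permutation), 0.15)
  }
})

test_that("Gehan test power on separated hazards exceeds null power", {
  set.seed(34)
  reject <- function(h2) {
    mean(replicate(60, {
      t <- c(rexp(40, 0.01), rexp(40, h2))
      cen <- rexp(80, 0.002)
      gehan_wilcoxon_test(pmin(t, cen), as.integer(t <= cen),
                          rep(c("a", "b"), each = 40))$p_value < 0.05
    }))
  }
  expect_gt(reject(0.04), reject(0.01))
})

test_that("Cox fit recovers a null covariate and errors on separation", {
  set.seed(35)
  d <- data.frame(time = rexp(200, 0.1), event = 1,
                  x = rnorm(200))
  fit <- cox_fit(d, "x")
  expect_lt(abs(fit$table$coef), 3 * fit$table$se)
  expect_true(fit$table$ci_low <= fit$table$hr &
                fit$table$hr <= fit$table$ci_high)
  # monotone likelihood (perfect separation in time) -> diagnostic error
  sep <- data.frame(time = c(1:5, 11:15), event = 1,
                    x = rep(c(1, 0), each = 5))
  expect_error(cox_fit(sep, "x"), "Cox fit failed")
})

test_that("Cox score test at beta = 0 equals the log-rank statistic", {
  set.seed(36)
  d <- data.frame(time = rexp(60, 0.1),
                  event = rbinom(60, 1, 0.8),
                  x = rep(0:1, 30))
  sc <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                        ties = "breslow")$score
  lr <- survival::survdiff(survival::Surv(time, event) ~ x, data = d)$chisq
  expect_equal(sc, lr, tolerance = 1e-6)
})

test_that("Cox estimates are equivariant to covariate rescaling", {
  set.seed(37)
  d <- data.frame(time = rexp(100, 0.1), event = rbinom(100, 1, 0.9),
                  x = rnorm(100))
  d$x10 <- d$x * 10
  f1 <- cox_fit(d, "x")$table
  f2 <- cox_fit(d, "x10")$table
  expect_equal(f1$coef, f2$coef * 10, tolerance = 1e-6)
})

test_that("univariate and multivariate Cox tables cover the requested variables", {
  set.seed(38)
  d <- data.frame(time = rexp(120, 0.05), event = rbinom(120, 1, 0.7),
                  a = sample(0:2, 120, TRUE), b = rnorm(120))
  uni <- cox_fit(d, c("a", "b"), univariate = TRUE)
  multi <- cox_fit(d, c("a", "b"))
  expect_equal(uni$table$variable, c("a", "b"))
  expect_equal(multi$table$variable, c("a", "b"))
  expect_true(is.finite(multi$loglik))
  expect_true(all(multi$table$hr > 0))
})

test_that("Fisher 2x2 equals hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2))$p_value,
               fisher_enum_p(matrix(c(3, 1, 1, 3), 2)))
  set.seed(39)
  for (rep in 1:10) {
    tab <- matrix(rpois(4, 5), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p_value, fisher_enum_p(tab),
                 tolerance = 1e-9)
  }
  # zero margin -> p = 1
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2))$p_value, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("doubling a 2x2 table never increases the Fisher p-value", {
  set.seed(40)
  for (rep in 1:8) {
    tab <- matrix(rpois(4, 4) + 1, 2)
    expect_lte(fisher_exact_2x2(2 * tab)$p_value,
               fisher_exact_2x2(tab)$p_value + 1e-9)
  }
})

test_that("Pearson chi-square matches the hand formula on printed stage counts", {
  # Stage IIA-B / IIIA-C / IV counts, Group 1 vs Group 2
  tab <- rbind(g1 = c(1, 24, 5), g2 = c(3, 13, 14))
  res <- chi_square_rxc(tab)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - exp_tab)^2 / exp_tab))
  expect_equal(res$df, 2)
  expect_true(res$low_expected)       # expected IIA-B cells < 5
  expect_false(is.null(res$p_monte_carlo))
})

test_that("chi-square edge cases: expected table gives 0, MC p approaches enumeration", {
  tab <- matrix(c(10, 20, 20, 40), 2)   # equals its expected table
  res <- chi_square_rxc(tab)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(chi_square_rxc(matrix(c(0, 0, 1, 2), 2)), "margins")
  # tiny 2x2: Monte-Carlo exact p vs full enumeration over the margins
  tiny <- matrix(c(5, 1, 1, 5), 2)
  res2 <- chi_square_rxc(tiny, monte_carlo_B = 2e4, seed = 7)
  r1 <- 6; c1 <- 6; n <- 12
  chi_of <- function(a) {
    t2 <- matrix(c(a, r1 - a, c1 - a, n - r1 - c1 + a), 2)
    e <- outer(rowSums(t2), colSums(t2)) / n
    sum((t2 - e)^2 / e)
  }
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_enum <- sum(probs[sapply(support, chi_of) >= chi_of(5) - 1e-9])
  expect_lt(abs(res2$p_monte_carlo - p_enum), 0.02)
})

test_that("Monte-Carlo chi-square p is reproducible for a given seed", {
  tab <- matrix(c(4, 1, 2, 6), 2)
  p1 <- chi_square_rxc(tab, monte_carlo_B = 5000, seed = 11)$p_monte_carlo
  p2 <- chi_square_rxc(tab, monte_carlo_B = 5000, seed = 11)$p_monte_carlo
  expect_identical(p1, p2)
})

test_that("Mann-Whitney U handles separation, identity and ties", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  expect_equal(mann_whitney_u(c(2, 4, 6), c(2, 4, 6))$p_value, 1)
  # agrees with wilcox.test in the no-tie exact regime
  set.seed(41)
  x <- rnorm(5); y <- rnorm(6)
  ours <- mann_whitney_u(x, y)
  ref <- wilcox.test(x, y, exact = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney normal approximation tracks exact enumeration", {
  set.seed(42)
  for (rep in 1:6) {
    x <- sample(1:8, 5, replace = TRUE)  # ties likely
    y <- sample(2:9, 6, replace = TRUE)
    p_exact <- mann_whitney_u(x, y, exact = TRUE)$p_value
    p_enum <- mw_enum_p(x, y)
    expect_equal(p_exact, p_enum, tolerance = 1e-12)
    p_norm <- mann_whitney_u(x, y, exact = FALSE)$p_value
    expect_lt(abs(p_norm - p_exact), 0.12)
  }
})
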
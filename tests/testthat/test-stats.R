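# statistical contracts, cross-checked against independent oracles

test_that("Welch t matches the hand-evaluated formulas and base R", {
  r <- welch_t_test(c(1, 2, 3), c(2, 4, 6))
  # hand oracle: se^2 = 1/3 + 4/3, t = -2/sqrt(5/3), WS df
  expect_equal(r$statistic, -2 / sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(r$statistic, -1.549, tolerance = 1e-3)
  expect_equal(r$df, (5 / 3)^2 / ((1 / 3)^2 / 2 + (4 / 3)^2 / 2), tolerance = 1e-12)
  expect_equal(r$df, 2.941, tolerance = 1e-3)
  # dual route: base R t.test as oracle over random cases
  set.seed(30)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 2))
    o <- t.test(x, y)
    m <- welch_t_test(x, y)
    expect_equal(m$statistic, unname(o$statistic), tolerance = 1e-10)
    expect_equal(m$df, unname(o$parameter), tolerance = 1e-10)
    expect_equal(m$p_value, o$p.value, tolerance = 1e-10)
  }
})

test_that("Welch t degenerate and symmetry behaviour", {
  x <- c(1, 2, 3)
  expect_equal(welch_t_test(x, x)$statistic, 0)
  expect_equal(welch_t_test(x, x)$p_value, 1)
  expect_equal(welch_t_test(c(2, 2), c(2, 2))$p_value, 1)
  expect_equal(welch_t_test(c(3, 3), c(1, 1))$p_value, 0)
  expect_error(welch_t_test(1, c(1, 2)), ">= 2")
  set.seed(5)
  a <- rnorm(8); b <- rnorm(6, 1)
  expect_equal(welch_t_test(a, b)$p_value, welch_t_test(b, a)$p_value)
})

test_that("one-way ANOVA omnibus matches the lm oracle; ladder behaves at limits", {
  set.seed(14)
  g <- list(a = rnorm(6), b = rnorm(7, 1), c = rnorm(5, 2))
  r <- one_way_anova_nk(g)
  d <- data.frame(y = unlist(g), f = rep(names(g), lengths(g)))
  o <- anova(lm(y ~ f, d))
  expect_equal(r$omnibus$statistic, o$`F value`[1], tolerance = 1e-10)
  expect_equal(r$omnibus$p_value, o$`Pr(>F)`[1], tolerance = 1e-10)
  # identical groups: F = 0 and nothing significant
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  rs <- one_way_anova_nk(same)
  expect_equal(rs$omnibus$statistic, 0)
  expect_false(any(rs$pairs$significant))
  # one group shifted far out: all its pairs significant
  far <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8) + 10)
  rf <- one_way_anova_nk(far)
  pc <- rf$pairs[rf$pairs$group1 == "c" | rf$pairs$group2 == "c", ]
  expect_true(all(pc$significant))
})

test_that("Newman-Keuls is stepwise: a retained stretch blocks inner pairs", {
  set.seed(8)
  # 4 groups with two middle groups nearly equal
  g <- list(a = rnorm(8, 0, 1), b = rnorm(8, 0.1, 1),
            c = rnorm(8, 0.2, 1), d = rnorm(8, 8, 1))
  r <- one_way_anova_nk(g)
  inner <- r$pairs[r$pairs$group1 %in% c("a", "b", "c") &
                   r$pairs$group2 %in% c("a", "b", "c"), ]
  # if the a..c stretch is retained, no inner pair may be declared significant
  span_abc <- r$pairs[(r$pairs$group1 == "a" & r$pairs$group2 == "c") |
                      (r$pairs$group1 == "c" & r$pairs$group2 == "a"), ]
  if (nrow(span_abc) && !span_abc$significant[1])
    expect_false(any(inner$significant))
  # tukey variant uses the full-range critical value (p never smaller)
  rt <- one_way_anova_nk(g, method = "tukey")
  key <- paste(r$pairs$group1, r$pairs$group2)
  expect_true(all(rt$pairs$p_value[match(key, paste(rt$pairs$group1, rt$pairs$group2))] >=
                  r$pairs$p_value - 1e-12))
})

test_that("two-way ANOVA on balanced data matches the classical decomposition", {
  set.seed(21)
  d <- expand.grid(A = c("a1", "a2", "a3"), B = c("b1", "b2"), rep = 1:4)
  d$y <- rnorm(nrow(d)) + as.numeric(d$A == "a2") * 0.8
  r <- two_way_anova_posthoc(d, "y", "A", "B")
  o <- anova(lm(y ~ A * B, d))
  expect_equal(r$anova$sum_sq[1:3], o$`Sum Sq`[1:3], tolerance = 1e-10)
  expect_equal(r$anova$p_value[1:3], o$`Pr(>F)`[1:3], tolerance = 1e-10)
  # all-identical cells: F = 0 and no significant post-hoc
  d0 <- d; d0$y <- 5
  r0 <- two_way_anova_posthoc(d0, "y", "A", "B", posthoc = "sidak")
  expect_equal(r0$anova$statistic[1:3], c(0, 0, 0))
  expect_false(any(r0$posthoc$significant))
  # missing cells are rejected with the cell named
  expect_error(two_way_anova_posthoc(d[!(d$A == "a1" & d$B == "b2"), ],
                                     "y", "A", "B"), "a1, b2")
})

test_that("Sidak adjustment satisfies the k = 1 identity and monotonicity", {
  expect_equal(sidak_adjust(0.05, 1), 0.05)
  expect_equal(sidak_adjust(0.02, 3), 1 - (1 - 0.02)^3)
  p <- runif(20)
  expect_true(all(sidak_adjust(p, 4) >= p))
})

test_that("Dunnett p agrees with a Monte-Carlo oracle of the max-|t| null", {
  k <- 3; n <- 6; df <- (k + 1) * n - (k + 1)
  set.seed(77)
  # simulate the many-to-one max-|t| distribution directly
  reps <- 8000
  maxt <- replicate(reps, {
    g <- matrix(rnorm((k + 1) * n), n)
    mse <- mean(apply(g, 2, var))
    max(abs((colMeans(g[, -1, drop = FALSE]) - mean(g[, 1])) / sqrt(mse * 2 / n)))
  })
  for (tq in c(1.5, 2.2, 2.9)) {
    mc <- mean(maxt > tq)
    expect_lt(abs(dunnett_p(tq, k, df, n, n) - mc), 0.03)  # MC oracle, absolute
  }
  # k = 1 reduces to the plain two-sided t p-value
  expect_equal(dunnett_p(2, 1, 10), 2 * pt(-2, 10), tolerance = 1e-12)
})

test_that("adjusted post-hoc p-values never undercut raw p-values", {
  set.seed(31)
  d <- expand.grid(A = c("ctl", "t1", "t2", "t3"), B = c("b1", "b2"), rep = 1:5)
  d$y <- rnorm(nrow(d)) + ifelse(d$A == "t2", 1, 0)
  r <- two_way_anova_posthoc(d, "y", "A", "B", posthoc = "dunnett",
                             control_level = "ctl")
  df_e <- r$anova$df[4]
  raw <- 2 * pt(-abs(r$posthoc$statistic), df_e)
  expect_true(all(r$posthoc$p_adjusted >= raw - 1e-6))
  expect_true(all(r$posthoc$p_adjusted >= 0 & r$posthoc$p_adjusted <= 1))
})

test_that("Pearson correlation handles exact lines and validates input", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, 2 * x + 1)$p, 0)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_error(pearson_r(x, rep(3, 10)), "zero variance")
  expect_error(pearson_r(1:2, 2:1), ">= 3")
  set.seed(9)
  a <- rnorm(20); b <- rnorm(20)
  o <- cor.test(a, b)
  m <- pearson_r(a, b)
  expect_equal(m$r, unname(o$estimate), tolerance = 1e-12)
  expect_equal(m$p, o$p.value, tolerance = 1e-10)
})
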
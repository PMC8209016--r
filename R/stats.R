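# Statistical contracts used throughout: Welch t, one-way ANOVA with the
# Newman-Keuls studentized-range ladder (Tukey HSD as alternative), two-way
# ANOVA (type-II sums of squares) with Dunnett or Sidak post-hocs, and
# Pearson correlation.

test_result <- function(statistic, df, p_value, test_name, comparison = NA_character_) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 test_name = test_name, comparison = comparison),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s%s> statistic = %.4g, df = %s, p = %.4g\n", x$test_name,
              if (is.na(x$comparison)) "" else paste0(": ", x$comparison),
              x$statistic,
              paste(signif(x$df, 5), collapse = ", "), x$p_value))
  invisible(x)
}

#' Welch's unequal-variance t-test
#'
#' Two-sample t statistic with the Welch-Satterthwaite degrees of freedom.
#' Two-tailed by default. Degenerate zero-variance inputs are handled
#' explicitly: equal means give t = 0, p = 1; unequal means give p = 0.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param tails 2 (default) or 1.
#' @param comparison optional label carried into the result.
#' @return a `test_result` (statistic, df, p_value).
#' @export
welch_t_test <- function(x, y, tails = 2, comparison = NA_character_) {
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs >= 2 values")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("samples must be finite")
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    eq <- mean(x) == mean(y)
    return(test_result(if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                       n1 + n2 - 2, if (eq) 1 else 0, "Welch t", comparison))
  }
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- if (tails == 2) 2 * stats::pt(-abs(t), df) else stats::pt(-abs(t), df)
  test_result(t, df, min(p, 1), "Welch t", comparison)
}

#' Pearson correlation with a two-tailed t-transform p-value
#'
#' @param x,y paired numeric vectors, n >= 3, both non-constant.
#' @return list with `r`, `p`, `n`, `df`.
#' @export
pearson_r <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need >= 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in one variable")
  r <- stats::cor(x, y)
  df <- n - 2
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(r) * sqrt(df / (1 - r^2)), df)
  list(r = r, p = p, n = n, df = df)
}

#' One-way ANOVA with Newman-Keuls (or Tukey) pairwise decisions
#'
#' Omnibus F test over k groups followed by the stepwise studentized-range
#' procedure: pairs are tested at the critical value for the number of
#' ordered means they span, processed from the widest stretch inward, and a
#' non-significant stretch blocks all pairs inside it. `method = "tukey"`
#' uses the full-range critical value for every pair instead (the
#' recommended, non-liberal alternative).
#'
#' @param values numeric vector, or a named list of group samples (in which
#'   case `group` is ignored).
#' @param group grouping factor aligned with `values`.
#' @param alpha familywise level for the ladder decisions.
#' @param method `"newman-keuls"` (default) or `"tukey"`.
#' @return list with `omnibus` (`test_result` for F), `pairs` (data.frame
#'   `group1`, `group2`, `q`, `p_value`, `significant`) and `method`.
#' @export
one_way_anova_nk <- function(values, group = NULL, alpha = 0.05,
                             method = c("newman-keuls", "tukey")) {
  method <- match.arg(method)
  if (is.list(values)) {
    group <- rep(names(values) %||% seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  group <- factor(group)
  k <- nlevels(group)
  if (k < 2L) stop("need >= 2 groups")
  ns <- tapply(values, group, length)
  if (any(ns < 2L)) stop("each group needs >= 2 values")
  means <- tapply(values, group, mean)
  n <- length(values)
  grand <- mean(values)
  ss_b <- sum(ns * (means - grand)^2)
  ss_w <- sum((values - means[group])^2)
  df_b <- k - 1; df_w <- n - k
  mse <- ss_w / df_w
  f <- if (ss_b == 0) 0 else (ss_b / df_b) / mse
  p_f <- if (mse == 0) { if (ss_b == 0) 1 else 0 } else stats::pf(f, df_b, df_w, lower.tail = FALSE)
  omnibus <- test_result(f, c(df_b, df_w), p_f, "one-way ANOVA F")

  ord <- order(means)
  lev <- levels(group)[ord]
  mo <- means[ord]; no <- ns[ord]
  pairs <- list()
  blocked <- matrix(FALSE, k, k)
  for (span in k:2) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      q <- abs(mo[j] - mo[i]) / sqrt(mse / 2 * (1 / no[i] + 1 / no[j]))
      r_crit <- if (method == "tukey") k else span
      p <- if (mse == 0) { if (mo[j] == mo[i]) 1 else 0 }
           else stats::ptukey(q, r_crit, df_w, lower.tail = FALSE)
      sig <- !blocked[i, j] && p <= alpha
      if (!sig) {
        # a retained stretch blocks everything inside it
        for (a in i:j) for (b in i:j) blocked[a, b] <- TRUE
      }
      pairs[[length(pairs) + 1L]] <- data.frame(
        group1 = lev[i], group2 = lev[j], q = q, p_value = p,
        significant = sig, stringsAsFactors = FALSE)
    }
  }
  list(omnibus = omnibus, pairs = do.call(rbind, pairs), method = method)
}

#' Sidak adjustment
#' @param p raw p-value(s).
#' @param k number of comparisons in the family.
#' @return adjusted p-values `1 - (1 - p)^k`.
#' @export
sidak_adjust <- function(p, k) pmin(1, 1 - (1 - p)^k)

#' Two-sided Dunnett many-to-one adjusted p-value
#'
#' Probability that the maximum absolute statistic of `k` correlated
#' many-to-one t contrasts exceeds `t`, under the multivariate t
#' distribution with the Dunnett correlation structure
#' `rho_ij = sqrt(lambda_i lambda_j)`, `lambda_i = n_i / (n_i + n0)`.
#'
#' @param t observed |t| statistic.
#' @param k number of treatment-vs-control comparisons in the family.
#' @param df error degrees of freedom.
#' @param n_treat,n_control group sizes (scalar `n_treat` recycled).
#' @return adjusted p-value.
#' @export
dunnett_p <- function(t, k, df, n_treat = NULL, n_control = NULL) {
  if (k == 1L) return(2 * stats::pt(-abs(t), df))
  lam <- if (is.null(n_treat) || is.null(n_control)) rep(0.5, k)
         else rep_len(n_treat, k) / (rep_len(n_treat, k) + n_control)
  R <- sqrt(outer(lam, lam)); diag(R) <- 1
  # pmvt draws quasi-MC points from the ambient RNG; pin it so identical
  # inputs always give identical p-values
  pr <- with_seed(1L, mvtnorm::pmvt(lower = rep(-abs(t), k), upper = rep(abs(t), k),
                                    df = as.integer(round(df)), corr = R,
                                    algorithm = mvtnorm::GenzBretz(abseps = 1e-5)))
  max(0, 1 - as.numeric(pr))
}

#' Two-way ANOVA with Dunnett or Sidak post-hoc comparisons
#'
#' Main effects and interaction are tested with type-II sums of squares
#' (which reduce to the classical decomposition for balanced layouts).
#' Post-hoc comparisons act on the levels of `factor_a` within each level
#' of `factor_b`, using the full-model mean-square error: Dunnett
#' many-to-one against `control_level`, or Sidak-adjusted all-pairs.
#' Incomplete layouts (empty cells) are rejected with the missing cells
#' listed.
#'
#' @param data data.frame.
#' @param value,factor_a,factor_b column names.
#' @param posthoc `"none"`, `"dunnett"` or `"sidak"`.
#' @param control_level control level of `factor_a` for Dunnett.
#' @param alpha significance level.
#' @return list with `anova` (data.frame: term, df, sum_sq, mean_sq,
#'   statistic, p_value) and `posthoc` (data.frame or `NULL`).
#' @export
two_way_anova_posthoc <- function(data, value, factor_a, factor_b,
                                  posthoc = c("none", "dunnett", "sidak"),
                                  control_level = NULL, alpha = 0.05) {
  posthoc <- match.arg(posthoc)
  y <- data[[value]]
  A <- factor(data[[factor_a]]); B <- factor(data[[factor_b]])
  if (anyNA(y) || anyNA(A) || anyNA(B)) stop("missing values in the layout")
  tab <- table(A, B)
  if (any(tab == 0)) {
    miss <- which(tab == 0, arr.ind = TRUE)
    stop("incomplete layout; empty cells: ",
         paste(sprintf("(%s, %s)", rownames(tab)[miss[, 1]],
                       colnames(tab)[miss[, 2]]), collapse = ", "))
  }
  rss <- function(fm) sum(stats::residuals(fm)^2)
  d <- data.frame(y = y, A = A, B = B)
  m_full <- stats::lm(y ~ A * B, d)
  m_ab <- stats::lm(y ~ A + B, d)
  m_a <- stats::lm(y ~ A, d)
  m_b <- stats::lm(y ~ B, d)
  ss_a <- rss(m_b) - rss(m_ab)
  ss_b <- rss(m_a) - rss(m_ab)
  ss_i <- rss(m_ab) - rss(m_full)
  ss_e <- rss(m_full)
  df_a <- nlevels(A) - 1L; df_b <- nlevels(B) - 1L
  df_i <- df_a * df_b
  df_e <- nrow(d) - nlevels(A) * nlevels(B)
  if (df_e < 1L) stop("no residual degrees of freedom (need replication within cells)")
  mse <- ss_e / df_e
  # constant response: every F is 0 by convention, not floating-point noise
  degenerate <- stats::var(y) == 0
  fstat <- function(ss, df) {
    if (degenerate) return(0)
    if (mse == 0) { if (ss <= 1e-12) 0 else Inf } else (ss / df) / mse
  }
  pval <- function(f, df) {
    if (degenerate) return(1)
    if (is.infinite(f)) 0 else if (mse == 0) 1 else stats::pf(f, df, df_e, lower.tail = FALSE)
  }
  fa <- fstat(ss_a, df_a); fb <- fstat(ss_b, df_b); fi <- fstat(ss_i, df_i)
  an <- data.frame(
    term = c(factor_a, factor_b, paste0(factor_a, ":", factor_b), "residuals"),
    df = c(df_a, df_b, df_i, df_e),
    sum_sq = c(ss_a, ss_b, ss_i, ss_e),
    mean_sq = c(ss_a / df_a, ss_b / df_b, ss_i / df_i, mse),
    statistic = c(fa, fb, fi, NA),
    p_value = c(pval(fa, df_a), pval(fb, df_b), pval(fi, df_i), NA),
    stringsAsFactors = FALSE)

  ph <- NULL
  if (posthoc != "none") {
    cells <- stats::aggregate(y ~ A + B, d, mean)
    ns <- stats::aggregate(y ~ A + B, d, length)
    rows <- list()
    for (bl in levels(B)) {
      ca <- cells[cells$B == bl, ]; na <- ns[ns$B == bl, ]
      if (posthoc == "dunnett") {
        if (is.null(control_level) || !control_level %in% levels(A))
          stop("Dunnett requires a valid `control_level` of ", factor_a)
        ctrl <- ca$y[ca$A == control_level]
        n0 <- na$y[na$A == control_level]
        others <- setdiff(levels(A), control_level)
        kk <- length(others)
        for (al in others) {
          ni <- na$y[na$A == al]
          se <- sqrt(mse * (1 / ni + 1 / n0))
          tstat <- if (se == 0) 0 else (ca$y[ca$A == al] - ctrl) / se
          padj <- if (se == 0) 1 else dunnett_p(tstat, kk, df_e, ni, n0)
          rows[[length(rows) + 1L]] <- data.frame(
            level_b = bl, comparison = paste(al, "vs", control_level),
            estimate = ca$y[ca$A == al] - ctrl, statistic = tstat,
            p_adjusted = padj, significant = padj < alpha,
            stringsAsFactors = FALSE)
        }
      } else {
        cmb <- utils::combn(levels(A), 2)
        kk <- ncol(cmb)
        for (ci in seq_len(kk)) {
          a1 <- cmb[1, ci]; a2 <- cmb[2, ci]
          n1 <- na$y[na$A == a1]; n2 <- na$y[na$A == a2]
          se <- sqrt(mse * (1 / n1 + 1 / n2))
          tstat <- if (se == 0) 0 else (ca$y[ca$A == a2] - ca$y[ca$A == a1]) / se
          praw <- if (se == 0) 1 else 2 * stats::pt(-abs(tstat), df_e)
          rows[[length(rows) + 1L]] <- data.frame(
            level_b = bl, comparison = paste(a2, "vs", a1),
            estimate = ca$y[ca$A == a2] - ca$y[ca$A == a1], statistic = tstat,
            p_adjusted = sidak_adjust(praw, kk), significant = sidak_adjust(praw, kk) < alpha,
            stringsAsFactors = FALSE)
        }
      }
    }
    ph <- do.call(rbind, rows)
  }
  list(anova = an, posthoc = ph, method = posthoc)
}
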
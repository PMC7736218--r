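## The statistical toolbox: repeated-measures correlation, paired and
## one-sample t tests with Cohen's d and a JZS Bayes factor, one-way
## repeated-measures ANOVA with partial eta squared, Pearson correlation,
## and Bonferroni adjustment. Statistics are assembled from explicit sums
## of squares / textbook formulas; the test suite cross-checks them
## against the corresponding base-R fitting routines.

#' Repeated-measures correlation
#'
#' Common within-subject linear association: a least-squares fit of y on x
#' with subject-specific intercepts and one shared slope.
#' \code{r_m = sign(slope) * sqrt(SS_measure / (SS_measure + SS_error))}
#' with \code{df = N - k - 1} (N observations, k subjects) and the p value
#' from the F ratio on (1, df).
#'
#' @param subject subject identifier per observation.
#' @param x,y paired observations.
#' @return list of class \code{RmCorrResult}: \code{r_m}, \code{df},
#'   \code{p_value}, \code{common_slope}, \code{per_subject_intercepts},
#'   \code{per_subject_slopes} (descriptive, per-subject OLS slopes),
#'   \code{n_obs}, \code{n_subjects}.
#' @examples
#' d <- data.frame(s = rep(1:3, each = 4), x = rep(1:4, 3))
#' d$y <- d$x + d$s * 10
#' rmCorr(d$s, d$x, d$y)$r_m  # 1
#' @export
rmCorr <- function(subject, x, y) {
  keep <- is.finite(x) & is.finite(y)
  subject <- as.character(subject[keep]); x <- x[keep]; y <- y[keep]
  sp <- split(seq_along(x), subject)
  ## subjects with constant x contribute no slope information
  inf <- vapply(sp, function(i) stats::sd(x[i]) > 0, TRUE)
  if (!any(inf)) stop("x is constant within every subject")
  xc <- x; yc <- y
  for (i in sp) { xc[i] <- x[i] - mean(x[i]); yc[i] <- y[i] - mean(y[i]) }
  k <- length(sp)
  N <- length(x)
  slope <- sum(xc * yc) / sum(xc^2)
  ssM <- slope^2 * sum(xc^2)
  ssE <- sum(yc^2) - ssM
  df <- N - k - 1
  if (df < 1) stop("not enough observations for the residual df")
  rm_ <- sign(slope) * sqrt(ssM / (ssM + ssE))
  Fv <- ssM / (ssE / df)
  p <- stats::pf(Fv, 1, df, lower.tail = FALSE)
  ints <- vapply(sp, function(i) mean(y[i]) - slope * mean(x[i]), 0)
  slopes <- vapply(sp, function(i)
    if (stats::sd(x[i]) > 0)
      sum((x[i] - mean(x[i])) * (y[i] - mean(y[i]))) /
        sum((x[i] - mean(x[i]))^2)
    else NA_real_, 0)
  structure(list(r_m = rm_, df = df, p_value = p, common_slope = slope,
                 per_subject_intercepts = ints, per_subject_slopes = slopes,
                 n_obs = N, n_subjects = k),
            class = "RmCorrResult")
}

#' @export
print.RmCorrResult <- function(x, ...) {
  cat("Repeated-measures correlation: r_m =", signif(x$r_m, 3),
      ", df =", x$df, ", p =", signif(x$p_value, 3), "\n")
  invisible(x)
}

.effectLabel <- function(d) {
  a <- abs(d)
  if (a < 0.2) "negligible" else if (a < 0.5) "small"
  else if (a < 0.8) "medium" else "large"
}

.tResult <- function(t, df, d, n, bf = TRUE) {
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  structure(list(statistic = t, df = df, p_value = p, effect_size = d,
                 effect_label = .effectLabel(d),
                 bf10 = if (bf) jzsBf10(t, n) else NA_real_),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat("statistic =", signif(x$statistic, 4), ", df =",
      paste(signif(x$df, 4), collapse = ","), ", p =",
      signif(x$p_value, 3), ", effect size =", signif(x$effect_size, 3),
      paste0("(", x$effect_label, ")"),
      if (is.finite(x$bf10)) paste(", BF10 =", signif(x$bf10, 3)), "\n")
  invisible(x)
}

#' Paired t test with Cohen's d and JZS Bayes factor
#'
#' Standard t on the paired differences, two-sided p,
#' \code{d = mean(diff) / sd(diff)}.
#'
#' @param x,y paired samples.
#' @param bf compute the JZS Bayes factor.
#' @return a \code{TestResult} list: \code{statistic}, \code{df},
#'   \code{p_value}, \code{effect_size}, \code{effect_label}, \code{bf10}.
#' @export
pairedT <- function(x, y, bf = TRUE) {
  stopifnot(length(x) == length(y))
  oneSampleT(x - y, 0, bf = bf)
}

#' @rdname pairedT
#' @param mu0 null value for the one-sample test.
#' @export
oneSampleT <- function(x, mu0 = 0, bf = TRUE) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) stop("need at least two finite values")
  dif <- x - mu0
  if (stats::sd(dif) == 0) {
    if (all(dif == 0)) return(.tResult(0, n - 1, 0, n, bf = FALSE))
    stop("zero variance in the differences")
  }
  t <- mean(dif) / (stats::sd(dif) / sqrt(n))
  .tResult(t, n - 1, mean(dif) / stats::sd(dif), n, bf = bf)
}

#' JZS Bayes factor for a one-sample (or paired) t statistic
#'
#' Default-prior (Jeffreys-Zellner-Siow) Bayes factor in favor of the
#' alternative: Cauchy prior with scale \code{cauchyScale} on the
#' standardized effect, evaluated by adaptive quadrature over the
#' Cauchy-mixing variance.
#'
#' @param t t statistic.
#' @param n sample size (pairs for a paired test).
#' @param cauchyScale prior scale (default sqrt(2)/2).
#' @return BF10 (> 1 favors the alternative).
#' @examples
#' jzsBf10(0, 20) < 1
#' @export
jzsBf10 <- function(t, n, cauchyScale = sqrt(2) / 2) {
  if (n < 2) stop("need n >= 2")
  if (cauchyScale == 0) return(1)
  nu <- n - 1
  ## marginal likelihood under H1, integrating over g with the scaled
  ## inverse-chi^2(1) prior induced by the Cauchy on the effect size
  logLik0 <- -(nu + 1) / 2 * log1p(t^2 / nu)
  r2 <- cauchyScale^2
  integrand <- function(g) {
    logf <- -0.5 * log1p(n * g) -
      (nu + 1) / 2 * log1p(t^2 / ((1 + n * g) * nu)) -
      logLik0 +
      -1.5 * log(g) - r2 / (2 * g) + 0.5 * log(r2 / (2 * pi))
    exp(logf)
  }
  q <- try(stats::integrate(integrand, 0, Inf, rel.tol = 1e-9,
                            abs.tol = 0, subdivisions = 500L),
           silent = TRUE)
  if (inherits(q, "try-error") || q$message != "OK")
    stop("Bayes factor integral did not converge")
  q$value
}

#' One-way repeated-measures ANOVA
#'
#' Complete subject x level table; \code{F = MS_level / MS_(subject x
#' level)} and partial eta squared
#' \code{SS_level / (SS_level + SS_error)}. No sphericity correction is
#' applied (uncorrected df are reported).
#'
#' @param values numeric matrix, subjects in rows, levels in columns (or a
#'   data.frame coerced to one).
#' @return a \code{TestResult} with \code{statistic} (F), \code{df}
#'   (length 2), \code{p_value}, \code{effect_size} (partial eta squared).
#' @examples
#' m <- matrix(rnorm(54), 18, 3)
#' oneWayRmAnova(m)$df  # c(2, 34)
#' @export
oneWayRmAnova <- function(values) {
  m <- as.matrix(values)
  if (anyNA(m)) stop("missing cells are not allowed (no imputation)")
  ns <- nrow(m); nl <- ncol(m)
  if (nl < 2) stop("need at least two levels")
  grand <- mean(m)
  ssLevel <- ns * sum((colMeans(m) - grand)^2)
  ssSubject <- nl * sum((rowMeans(m) - grand)^2)
  ssTotal <- sum((m - grand)^2)
  ssError <- ssTotal - ssLevel - ssSubject
  dfL <- nl - 1
  dfE <- (ns - 1) * (nl - 1)
  if (ssLevel < .Machine$double.eps * sum(m^2)) {
    ## identical level means: no treatment variance at all
    Fv <- 0; p <- 1; peta <- 0
  } else {
    Fv <- (ssLevel / dfL) / (ssError / dfE)
    p <- stats::pf(Fv, dfL, dfE, lower.tail = FALSE)
    peta <- ssLevel / (ssLevel + ssError)
  }
  structure(list(statistic = Fv, df = c(dfL, dfE), p_value = p,
                 effect_size = peta,
                 effect_label = if (peta < 0.06) "small"
                                else if (peta < 0.14) "medium" else "large",
                 bf10 = NA_real_),
            class = "TestResult")
}

#' Pearson correlation with t-based p value
#'
#' @param x,y numeric vectors, n >= 3, nonzero variance.
#' @return a \code{TestResult} with \code{statistic} (r's t), \code{df},
#'   \code{p_value}, \code{effect_size} (r itself).
#' @export
pearsonTest <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least three observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  df <- n - 2
  t <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  structure(list(statistic = t, df = df, p_value = p, effect_size = r,
                 effect_label = .effectLabel(r), r = r, bf10 = NA_real_),
            class = "TestResult")
}

#' Bonferroni adjustment
#'
#' \code{min(1, m * p)} elementwise, for a family of \code{m} comparisons.
#'
#' @param p p values in [0, 1].
#' @param m family size; must be at least \code{length(p)}.
#' @return adjusted p values.
#' @examples
#' bonferroni(c(0.01, 0.5), m = 3)
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  if (m < length(p)) stop("family size m must be >= number of p values")
  stats::p.adjust(p, method = "bonferroni", n = m)
}
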
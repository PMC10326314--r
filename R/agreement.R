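# Method-comparison statistics: Bland-Altman, Pearson, normality-driven
# paired-test selection, ICC(2,1), and table/plot reporting.

.check_pairs <- function(values_a, values_b, n_min = 3) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) != length(b)) stop("paired series must have equal length")
  if (anyNA(a) || anyNA(b)) stop("missing values in paired measurements")
  if (length(a) < n_min) stop("need at least ", n_min, " pairs")
  list(a = a, b = b)
}

#' Bland-Altman analysis of two measurement methods
#'
#' Differences d_i = a_i - b_i; reported are the mean difference (bias), the
#' sample standard deviation of the differences, the limits of agreement
#' bias +/- k sd (k = 1.96 for 95%), and the t-based confidence interval of
#' the bias.
#'
#' @param values_a,values_b paired measurements (mm), length >= 3.
#' @param loa_k multiplier for the limits of agreement.
#' @param ci_level confidence level for the bias CI.
#' @return list of class \code{"BlandAltman"}: \code{bias_mm}, \code{sd_mm},
#'   \code{loa_low}, \code{loa_high}, \code{bias_ci} (length 2), \code{n},
#'   \code{differences}, \code{means}.
#' @examples
#' blandAltman(c(10, 20, 30), c(12, 21, 33))  # bias -2, sd 1
#' @export
blandAltman <- function(values_a, values_b, loa_k = 1.96, ci_level = 0.95) {
  p <- .check_pairs(values_a, values_b)
  d <- p$a - p$b
  n <- length(d)
  bias <- mean(d)
  s <- stats::sd(d)
  if (s == 0) warning("all differences identical: degenerate limits of agreement")
  tq <- stats::qt((1 + ci_level) / 2, df = n - 1)
  res <- list(bias_mm = bias, sd_mm = s,
              loa_low = bias - loa_k * s, loa_high = bias + loa_k * s,
              bias_ci = bias + c(-1, 1) * tq * s / sqrt(n),
              n = n, differences = d, means = (p$a + p$b) / 2)
  class(res) <- "BlandAltman"
  res
}

#' @export
print.BlandAltman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.2f +/- %.2f mm, LoA [%.2f, %.2f], bias CI [%.2f, %.2f]\n",
              x$n, x$bias_mm, x$sd_mm, x$loa_low, x$loa_high,
              x$bias_ci[1], x$bias_ci[2]))
  invisible(x)
}

#' Paired comparison with normality-driven test selection
#'
#' Shapiro-Wilk is run on the paired differences; when normality is not
#' rejected (p >= alpha) a two-sided paired t-test is used, otherwise a
#' two-sided Wilcoxon signed-rank test (zero differences dropped, exact null
#' distribution for n <= 25, normal approximation with continuity correction
#' above). Levene's test on the two samples is reported alongside but does
#' not drive the selection.
#'
#' @param values_a,values_b paired measurements, length >= 3.
#' @param alpha significance level for the Shapiro-Wilk decision.
#' @return list: \code{test} ("paired t-test" or "Wilcoxon signed-rank"),
#'   \code{p_value}, \code{shapiro_p}, \code{levene_statistic},
#'   \code{levene_p}, \code{degenerate} (all differences zero).
#' @export
pairedCompare <- function(values_a, values_b, alpha = 0.05) {
  p <- .check_pairs(values_a, values_b)
  d <- p$a - p$b
  lev <- tryCatch({
    df <- data.frame(value = c(p$a, p$b),
                     grp = factor(rep(c("a", "b"), each = length(p$a))))
    lt <- car::leveneTest(value ~ grp, data = df)
    c(lt[1, "F value"], lt[1, "Pr(>F)"])
  }, error = function(e) c(NA_real_, NA_real_))
  if (stats::sd(d) == 0) {
    # identical series: nothing to test; by convention p = 1 on the t branch
    return(list(test = "paired t-test", p_value = 1,
                shapiro_p = NA_real_, levene_statistic = lev[1],
                levene_p = lev[2], degenerate = TRUE))
  }
  sw <- stats::shapiro.test(d)
  if (sw$p.value >= alpha) {
    tt <- stats::t.test(d)
    list(test = "paired t-test", p_value = tt$p.value,
         shapiro_p = sw$p.value, levene_statistic = lev[1], levene_p = lev[2],
         degenerate = FALSE)
  } else {
    dz <- d[d != 0]
    if (length(dz) == 0)
      return(list(test = "Wilcoxon signed-rank", p_value = NA_real_,
                  shapiro_p = sw$p.value, levene_statistic = lev[1],
                  levene_p = lev[2], degenerate = TRUE))
    exact <- length(dz) <= 25 && !any(duplicated(abs(dz)))
    wt <- suppressWarnings(stats::wilcox.test(dz, exact = exact,
                                              correct = TRUE))
    list(test = "Wilcoxon signed-rank", p_value = wt$p.value,
         shapiro_p = sw$p.value, levene_statistic = lev[1], levene_p = lev[2],
         degenerate = FALSE)
  }
}

#' Pearson correlation with qualitative rating
#'
#' Sample correlation with two-sided t-distribution p-value, plus a
#' qualitative label on the conventional scale (weak < 0.35 <= moderate
#' < 0.67 <= strong < 0.9 <= very strong).
#'
#' @param values_a,values_b paired measurements, length >= 3, each with
#'   nonzero variance.
#' @param thresholds ascending cut points for the labels.
#' @return list: \code{r}, \code{p_value}, \code{label}.
#' @export
pearsonCorrelation <- function(values_a, values_b,
                               thresholds = c(0.35, 0.67, 0.9)) {
  p <- .check_pairs(values_a, values_b)
  if (stats::sd(p$a) == 0 || stats::sd(p$b) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(p$a, p$b, method = "pearson")
  labs <- c("weak", "moderate", "strong", "very strong")
  lab <- labs[findInterval(abs(ct$estimate), thresholds) + 1]
  list(r = unname(ct$estimate), p_value = ct$p.value, label = unname(lab))
}

#' ICC(2,1): single-rating absolute-agreement two-way random-effects
#'
#' Two-way ANOVA decomposition of an n subjects x k raters matrix into
#' subject (MSR), rater (MSC) and error (MSE) mean squares, with
#' \deqn{ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)).}
#' The confidence interval is the F-based interval for the single-rating
#' absolute-agreement two-way random-effects model (McGraw & Wong). The
#' label follows the conventional reliability cut points
#' (< 0.5 poor, 0.5-0.75 moderate, 0.75-0.9 good, > 0.9 excellent).
#'
#' @param ratings complete numeric matrix, n subjects x k raters, n >= 2,
#'   k >= 2.
#' @param ci_level confidence level.
#' @param thresholds ascending label cut points.
#' @return list: \code{icc}, \code{ci_low}, \code{ci_high}, \code{label},
#'   \code{ms} (the three mean squares).
#' @export
icc21 <- function(ratings, ci_level = 0.95, thresholds = c(0.5, 0.75, 0.9)) {
  x <- as.matrix(ratings)
  if (anyNA(x)) stop("ratings matrix must be complete")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  # F-based CI (single-rating, absolute-agreement, two-way random)
  alpha <- 1 - ci_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  labs <- c("poor", "moderate", "good", "excellent")
  list(icc = icc, ci_low = ci_low, ci_high = ci_high,
       label = labs[findInterval(icc, thresholds) + 1],
       ms = c(MSR = msr, MSC = msc, MSE = mse))
}

.fmt_p <- function(p, cut = 0.05) {
  ifelse(is.na(p), "NA",
         ifelse(p < cut, sprintf("<%.2f", cut), sprintf("%.2f", p)))
}

#' Method-comparison summary table
#'
#' One row per comparison with the columns "mean deviation +/- sd; p" and
#' "Pearson r; p": the standard compact rendering of paired-modality
#' agreement. Deviations are rounded to one decimal (mm), correlations to
#' two; p-values below 0.05 are printed as "<0.05".
#'
#' @param comparisons named list; each element is a list with elements
#'   \code{a} and \code{b} (paired vectors), e.g.
#'   \code{list("d_max vs. d_XR" = list(a = dmax, b = dxr))}.
#' @param path optional CSV output path.
#' @return data.frame with columns \code{comparison}, \code{deviation},
#'   \code{correlation} plus the raw numbers.
#' @export
agreementTable <- function(comparisons, path = NULL) {
  if (length(comparisons) == 0) stop("at least one comparison required")
  rows <- lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    ba <- blandAltman(cmp$a, cmp$b)
    pc <- pairedCompare(cmp$a, cmp$b)
    pr <- pearsonCorrelation(cmp$a, cmp$b)
    data.frame(
      comparison = nm,
      deviation = sprintf("%.1f ± %.1f; %s", ba$bias_mm, ba$sd_mm,
                          .fmt_p(pc$p_value)),
      correlation = sprintf("%.2f; %s", pr$r, .fmt_p(pr$p_value)),
      bias_mm = ba$bias_mm, sd_mm = ba$sd_mm, p_diff = pc$p_value,
      test = pc$test, r = pr$r, p_r = pr$p_value,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Bland-Altman and scatter plots
#'
#' \code{plotBlandAltman} draws the paired differences against the pair
#' means with zero line, bias line, limits of agreement and the bias
#' confidence band. \code{plotScatter} draws the paired values with the
#' identity line and a least-squares fit.
#'
#' @param ba a \code{\link{blandAltman}} result.
#' @param title plot title.
#' @return a \code{ggplot} object.
#' @export
plotBlandAltman <- function(ba, title = "Bland-Altman") {
  df <- data.frame(mean = ba$means, diff = ba$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = ba$bias_ci[1], ymax = ba$bias_ci[2],
                      fill = "orange", alpha = 0.25) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        color = "darkgreen") +
    ggplot2::geom_hline(yintercept = ba$bias_mm, color = "orange") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed", color = "orange") +
    ggplot2::geom_point() +
    ggplot2::labs(title = title, x = "mean of methods (mm)",
                  y = "difference (mm)")
}

#' @rdname plotBlandAltman
#' @param values_a,values_b paired measurements.
#' @export
plotScatter <- function(values_a, values_b, title = "Method comparison") {
  p <- .check_pairs(values_a, values_b)
  df <- data.frame(a = p$a, b = p$b)
  ggplot2::ggplot(df, ggplot2::aes(x = b, y = a)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "darkgreen") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "orange") +
    ggplot2::geom_point() +
    ggplot2::labs(title = title, x = "method B (mm)", y = "method A (mm)")
}
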
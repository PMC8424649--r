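#' Fit an expansion rate to one time course
#'
#' Ordinary least-squares regression of the metric on day. The slope is the
#' expansion rate in metric units (repeat units, or index units) per day.
#' On exactly collinear input the fit is exact (`r_squared = 1`,
#' `slope_se = 0`).
#'
#' @param course A [time_course()].
#' @return An object of class `expansion_rate`: list with `genotype`,
#'   `replicate`, `metric`, `slope`, `intercept`, `slope_se`, `r_squared`,
#'   `n_points`.
#' @export
fit_expansion_rate <- function(course) {
  stopifnot(inherits(course, "time_course"))
  d <- course$points
  if (length(unique(d$day)) < 2L)
    stop("cannot fit a slope with < 2 distinct days", call. = FALSE)
  fit <- stats::lm(value ~ day, data = d)
  cf <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((d$value - mean(d$value))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  se <- sm$coefficients["day", "Std. Error"]
  if (!is.finite(se)) se <- if (ss_res < 1e-12) 0 else NA_real_
  structure(list(genotype = course$genotype, replicate = course$replicate,
                 metric = course$metric,
                 slope = unname(cf["day"]), intercept = unname(cf["(Intercept)"]),
                 slope_se = se, r_squared = r2, n_points = nrow(d)),
            class = "expansion_rate")
}

#' Trapezoidal area under a time course
#'
#' @param course A [time_course()].
#' @return Area of metric versus day over the observed range (metric units x
#'   days).
#' @export
auc <- function(course) {
  stopifnot(inherits(course, "time_course"))
  d <- course$points
  sum(diff(d$day) * (utils::head(d$value, -1) + utils::tail(d$value, -1)) / 2)
}

# shared container for the group-comparison statistics
new_group_comparison <- function(statistic, df, p_raw, method,
                                 flags = character()) {
  structure(list(statistic = statistic, df = df,
                 p_raw = p_raw, p_adjusted = NA_real_,
                 method = method, flags = flags),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, df = (%s), p = %.4g%s\n",
              x$method, x$statistic, paste(x$df, collapse = ", "), x$p_raw,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop(">= 2 groups required", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes < 2L))
    stop("every group needs >= 2 values", call. = FALSE)
  if (sum(sizes) - length(groups) < 1L)
    stop("no residual degrees of freedom", call. = FALSE)
  lapply(groups, as.numeric)
}

#' One-way ANOVA over groups of values
#'
#' Classical fixed-effects one-way ANOVA, as used to compare per-replicate
#' expansion-rate slopes (and AUCs) between genotypes: F with (k - 1, N - k)
#' degrees of freedom. With zero within-group variance but unequal means the
#' F statistic is infinite and the p value is floored at 1e-300 with a
#' `"degenerate"` flag.
#'
#' @param groups A list (length >= 2) of numeric vectors, each of length
#'   >= 2.
#' @return A `group_comparison` with `method = "oneway_anova"`.
#' @export
anova_oneway <- function(groups) {
  groups <- check_groups(groups)
  values <- unlist(groups, use.names = FALSE)
  k <- length(groups); n <- length(values)
  gm <- mean(values)
  ss_between <- sum(lengths(groups) *
                      (vapply(groups, mean, numeric(1)) - gm)^2)
  ss_within <- sum(vapply(groups, function(x) sum((x - mean(x))^2),
                          numeric(1)))
  df1 <- k - 1L; df2 <- n - k
  if (ss_within == 0) {
    if (ss_between < 1e-24)
      return(new_group_comparison(0, c(df1, df2), 1, "oneway_anova"))
    return(new_group_comparison(Inf, c(df1, df2), 1e-300, "oneway_anova",
                                flags = "degenerate"))
  }
  f <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  new_group_comparison(f, c(df1, df2), max(p, 1e-300), "oneway_anova")
}

#' Brown-Forsythe homogeneity-of-variance test
#'
#' The median-centred Levene test: a one-way ANOVA on the absolute
#' deviations of each value from its group median. Used as the routine check
#' of the equal-variance assumption behind the slope/AUC ANOVAs.
#'
#' @inheritParams anova_oneway
#' @return A `group_comparison` with `method = "brown_forsythe"`.
#' @export
brown_forsythe <- function(groups) {
  groups <- check_groups(groups)
  z <- lapply(groups, function(x) abs(x - stats::median(x)))
  out <- anova_oneway(z)
  out$method <- "brown_forsythe"
  out
}

#' Independent-samples t test
#'
#' Two-sided Student t test (equal-variance pooled by default) for two-group
#' comparisons. Degenerate inputs are handled explicitly: zero pooled
#' variance with equal means gives `t = 0, p = 1`; zero pooled variance with
#' unequal means is flagged and reported as infinite.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param var_equal Pool the variance (classical Student t, the default) or
#'   use Welch's correction.
#' @return A `group_comparison` with `method = "t_test"`.
#' @export
t_test_independent <- function(a, b, var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs >= 2 values", call. = FALSE)
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2L)
  df <- length(a) + length(b) - 2L
  # same near-zero-variance guard stats::t.test applies before erroring
  stderr_est <- sqrt(pooled_var * (1 / length(a) + 1 / length(b)))
  degenerate <- stderr_est < 10 * .Machine$double.eps *
    max(abs(mean(a)), abs(mean(b)), 1e-12)
  if (var_equal && degenerate) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(new_group_comparison(0, df, 1, "t_test"))
    return(new_group_comparison(sign(mean(a) - mean(b)) * Inf, df, 1e-300,
                                "t_test", flags = "degenerate"))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  new_group_comparison(unname(ht$statistic), unname(ht$parameter),
                       ht$p.value, "t_test")
}

#' False-discovery-rate adjustment
#'
#' Benjamini-Hochberg step-up adjustment (the default) or the two-stage
#' Benjamini-Krieger-Yekutieli procedure, with rejection flags at the target
#' FDR `q` (5% by default, the level used throughout the expansion-rate
#' comparisons).
#'
#' @param p_values Numeric vector of raw p values in \[0, 1\].
#' @param q Target false discovery rate.
#' @param method `"BH"` (default) or `"BKY"` (two-stage).
#' @return A list with `p_adjusted` (same length/order as input) and
#'   `reject` (logical).
#' @export
fdr_adjust <- function(p_values, q = 0.05, method = c("BH", "BKY")) {
  method <- match.arg(method)
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  if (method == "BH") {
    adj <- stats::p.adjust(p, method = "BH")
    return(list(p_adjusted = adj, reject = adj <= q))
  }
  # two-stage BKY: stage 1 at q' = q/(1+q) estimates the number of true
  # nulls, stage 2 re-runs BH at q * m / m0-hat
  m <- length(p)
  q1 <- q / (1 + q)
  r1 <- sum(stats::p.adjust(p, method = "BH") <= q1)
  if (r1 == 0L)
    return(list(p_adjusted = rep(1, m), reject = rep(FALSE, m)))
  if (r1 == m)
    return(list(p_adjusted = stats::p.adjust(p, method = "BH"),
                reject = rep(TRUE, m)))
  m0 <- m - r1
  adj <- pmin(1, stats::p.adjust(p, method = "BH") * m0 / m)
  list(p_adjusted = adj, reject = adj <= q1)
}

#' Compare expansion rates between genotypes
#'
#' Convenience front-end reproducing the kinetics statistics: fits
#' per-replicate slopes (or AUCs), runs the global one-way ANOVA across
#' genotypes, all pairwise t tests with FDR adjustment, and the
#' Brown-Forsythe variance check.
#'
#' @param courses A list of [time_course()] objects (one metric).
#' @param statistic `"slope"` (per-replicate OLS slope, default) or `"auc"`
#'   (per-replicate trapezoidal area).
#' @param q Target FDR for the pairwise comparisons.
#' @param fdr_method Passed to [fdr_adjust()].
#' @return A list with `rates` (data.frame of per-replicate fits), `anova`
#'   and `brown_forsythe` (`group_comparison`s), and `pairwise` (data.frame:
#'   contrast, statistic, df, p_raw, p_adj, reject).
#' @export
compare_expansion_rates <- function(courses, statistic = c("slope", "auc"),
                                    q = 0.05, fdr_method = "BH") {
  statistic <- match.arg(statistic)
  stopifnot(length(courses) > 0)
  rates <- do.call(rbind, lapply(courses, function(cs) {
    fit <- fit_expansion_rate(cs)
    data.frame(genotype = cs$genotype, replicate = cs$replicate,
               metric = cs$metric, slope = fit$slope,
               slope_se = fit$slope_se, r_squared = fit$r_squared,
               n_points = fit$n_points, auc = auc(cs),
               stringsAsFactors = FALSE)
  }))
  value_col <- if (statistic == "slope") "slope" else "auc"
  groups <- split(rates[[value_col]], rates$genotype)
  global <- anova_oneway(groups)
  bf <- brown_forsythe(groups)
  gn <- names(groups)
  pairs <- utils::combn(gn, 2L, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    tt <- t_test_independent(groups[[pr[1L]]], groups[[pr[2L]]])
    data.frame(contrast = paste(pr, collapse = " vs "),
               statistic = tt$statistic, df = tt$df, p_raw = tt$p_raw,
               stringsAsFactors = FALSE)
  }))
  fdr <- fdr_adjust(pw$p_raw, q = q, method = fdr_method)
  pw$p_adj <- fdr$p_adjusted
  pw$reject <- fdr$reject
  list(rates = rates, anova = global, brown_forsythe = bf, pairwise = pw)
}

#' 95% confidence band of an OLS time-course fit
#'
#' Pointwise confidence band of the fitted mean at given days, the shading
#' convention used when plotting per-genotype expansion time courses.
#'
#' @param course A [time_course()].
#' @param days Days at which to evaluate the band (default: observed days).
#' @param level Confidence level.
#' @return Data.frame with `day`, `fit`, `lwr`, `upr`.
#' @export
confidence_band <- function(course, days = NULL, level = 0.95) {
  stopifnot(inherits(course, "time_course"))
  if (is.null(days)) days <- course$points$day
  fit <- stats::lm(value ~ day, data = course$points)
  pr <- stats::predict(fit, newdata = data.frame(day = days),
                       interval = "confidence", level = level)
  data.frame(day = days, fit = pr[, "fit"], lwr = pr[, "lwr"],
             upr = pr[, "upr"])
}
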
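# Repeatability and group statistics. The ICC mean-squares forms and the
# Holm step-down are written out explicitly (they are part of the reported
# method); ANOVA, t-tests and OLS ride on base R.

# Two-way crossed mean squares of an n x k complete matrix:
# rows = units (cells/locations), columns = repeated measurements.
.twoWayMeanSquares <- function(data) {
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop("ICC input must be complete (no missing cells)")
  n <- nrow(data); k <- ncol(data)
  if (n < 3L || k < 2L) stop("ICC needs at least 3 units and 2 measurements")
  grand <- mean(data)
  rowm <- rowMeans(data); colm <- colMeans(data)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sse <- sum((data - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + grand)^2)
  list(n = n, k = k,
       msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

#' Intraclass correlation coefficients (two-way mixed effects, single measure)
#'
#' `iccConsistency` implements the consistency form
#' `(MSR - MSE) / (MSR + (k - 1) MSE)`; `iccAgreement` the absolute-agreement
#' form `(MSR - MSE) / (MSR + (k - 1) MSE + k (MSC - MSE) / n)`, where MSR,
#' MSC and MSE are the between-unit, between-measurement and residual mean
#' squares of the two-way decomposition. Both return the single-measure
#' coefficient with the F-test p-value (`MSR/MSE` on `n - 1`,
#' `(n - 1)(k - 1)` df) attached as attribute `"p_value"`.
#'
#' @param data complete n x k matrix (units x repeated measurements), n >= 3,
#'   k >= 2.
#' @return ICC value (<= 1) with attribute `p_value`.
#' @examples
#' iccConsistency(matrix(c(1, 2, 3, 2, 3, 4), ncol = 2))  # 1 (offset only)
#' iccAgreement(matrix(c(1, 2, 3, 2, 3, 4), ncol = 2))    # 2/3
#' @export
iccConsistency <- function(data) {
  ms <- .twoWayMeanSquares(data)
  .iccReturn((ms$msr - ms$mse) / (ms$msr + (ms$k - 1) * ms$mse), ms)
}

#' @rdname iccConsistency
#' @export
iccAgreement <- function(data) {
  ms <- .twoWayMeanSquares(data)
  val <- (ms$msr - ms$mse) /
    (ms$msr + (ms$k - 1) * ms$mse + ms$k * (ms$msc - ms$mse) / ms$n)
  .iccReturn(val, ms)
}

.iccReturn <- function(val, ms) {
  p <- if (ms$mse == 0) 0 else
    pf(ms$msr / ms$mse, ms$n - 1, (ms$n - 1) * (ms$k - 1), lower.tail = FALSE)
  structure(val, p_value = p)
}

#' Agreement category of an ICC value
#'
#' Below 0.5: poor; 0.5 to 0.75: moderate; 0.75 to 0.9: good; 0.9 and above:
#' excellent (lower bounds inclusive). A non-significant ICC (`pValue` >
#' `alpha`) is classed `"ns"`.
#'
#' @param value ICC value (<= 1).
#' @param pValue optional F-test p-value of the ICC.
#' @param alpha significance level for the `"ns"` class.
#' @return One of `"poor"`, `"moderate"`, `"good"`, `"excellent"`, `"ns"`.
#' @export
classifyIcc <- function(value, pValue = NULL, alpha = 0.05) {
  if (any(value > 1 + 1e-12)) stop("ICC values cannot exceed 1")
  cls <- ifelse(value < 0.5, "poor",
         ifelse(value < 0.75, "moderate",
         ifelse(value < 0.9, "good", "excellent")))
  if (!is.null(pValue)) cls[pValue > alpha] <- "ns"
  cls
}

#' Absolute and percent paired differences
#'
#' For matched measurements `x1`, `x2` (same units, e.g. two visits):
#' per-unit absolute difference `|x1 - x2|` and percent difference
#' `100 |x1 - x2| / ((x1 + x2) / 2)`; reports mean and sample SD of each.
#' Units with a zero pair mean are excluded from the percent statistics with
#' a warning. Symmetric in its arguments.
#'
#' @param x1,x2 numeric vectors of equal length >= 2.
#' @return data.frame row: `mean_abs_diff`, `sd_abs_diff`, `mean_pct_diff`,
#'   `sd_pct_diff`, `n`.
#' @export
pairedDifferenceStats <- function(x1, x2) {
  stopifnot(length(x1) == length(x2), length(x1) >= 2L)
  d <- abs(x1 - x2)
  pm <- (x1 + x2) / 2
  ok <- pm != 0
  if (!all(ok))
    warning(sum(!ok), " unit(s) with zero pair mean excluded from percent differences")
  pct <- 100 * d[ok] / pm[ok]
  data.frame(mean_abs_diff = mean(d), sd_abs_diff = sd(d),
             mean_pct_diff = mean(pct), sd_pct_diff = sd(pct),
             n = length(x1))
}

#' One-way fixed-factor ANOVA
#'
#' @param values numeric response.
#' @param groups group labels (>= 2 groups, each with >= 2 values).
#' @return data.frame row: `effect`, `F`, `df_between`, `df_within`,
#'   `p_value`.
#' @export
oneWayAnova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 values")
  tab <- suppressWarnings(anova(lm(values ~ groups)))
  Fval <- tab$`F value`[1L]
  pval <- tab$`Pr(>F)`[1L]
  if (tab$`Sum Sq`[1L] < 1e-12) {  # no between-group variance at all
    Fval <- 0
    pval <- 1
  }
  data.frame(effect = "group", F = Fval,
             df_between = tab$Df[1L], df_within = tab$Df[2L],
             p_value = pval)
}

#' Repeated-measures ANOVA
#'
#' Within-subject effect of a repeated condition (e.g. spectral channel),
#' an optional between-subject factor (e.g. eccentricity) and their
#' interaction, via the standard within-subject sum-of-squares decomposition
#' (`aov` with an `Error(subject/within)` stratum). Subjects missing any
#' within-factor level are dropped (count reported via `message`).
#'
#' @param data long-format data.frame.
#' @param value,subject,within column names of the response, the subject id
#'   and the within-subject factor.
#' @param between optional column name of a between-subject factor.
#' @return data.frame with one row per effect: `effect`, `F`, `df_between`,
#'   `df_within`, `p_value`.
#' @export
rmAnova <- function(data, value, subject, within, between = NULL) {
  df <- data.frame(y = data[[value]], subj = factor(data[[subject]]),
                   w = factor(data[[within]]))
  if (!is.null(between)) df$b <- factor(data[[between]])
  lv <- levels(df$w)
  counts <- table(df$subj, df$w)
  complete <- rownames(counts)[apply(counts >= 1L, 1L, all)]
  dropped <- setdiff(levels(df$subj), complete)
  if (length(dropped))
    message(length(dropped),
            " subject(s) without all conditions dropped from RM-ANOVA")
  df <- droplevels(df[df$subj %in% complete, , drop = FALSE])
  if (nlevels(df$subj) < 2L) stop("need at least 2 complete subjects")
  form <- if (is.null(between)) y ~ w + Error(subj / w)
          else y ~ w * b + Error(subj / w)
  fit <- aov(form, data = df)
  sm <- summary(fit)
  out <- list()
  for (stratum in sm) {
    tab <- stratum[[1L]]
    terms <- rownames(tab)
    resid_row <- grepl("^Residuals", trimws(terms))
    df_err <- tab$Df[resid_row][1L]
    for (j in which(!resid_row)) {
      nm <- trimws(terms[j])
      nm <- switch(nm, w = within, b = between,
                   `w:b` = paste(within, between, sep = ":"), nm)
      Fval <- tab$`F value`[j]
      pval <- tab$`Pr(>F)`[j]
      if (tab$`Sum Sq`[j] < 1e-12) {  # no effect variance at all
        Fval <- 0
        pval <- 1
      }
      out[[length(out) + 1L]] <- data.frame(
        effect = nm, F = Fval, df_between = tab$Df[j],
        df_within = df_err, p_value = pval)
    }
  }
  do.call(rbind, out)
}

#' Pooled-variance unpaired t-test
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return data.frame row: `t`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
tTestUnpaired <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  ht <- t.test(x, y, var.equal = TRUE)
  data.frame(t = unname(ht$statistic), df = unname(ht$parameter),
             p_value = ht$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Holm-Bonferroni step-down correction
#'
#' Sorts the m p-values ascending and compares the i-th smallest against
#' `alpha / (m - i + 1)`, rejecting until the first failure; adjusted
#' p-values are the running maximum of `(m - i + 1) * p_(i)`, capped at 1.
#' With four eccentricity levels there are six pairwise comparisons, so the
#' smallest p-value faces `alpha / 6` (0.008 at three decimals for
#' `alpha = 0.05`).
#'
#' @param pValues raw p-values in `[0, 1]`.
#' @param alpha family-wise error rate.
#' @return list with `thresholds` (in ascending-p order), `reject` and
#'   `adjusted_p` (in the original order), and `alpha`.
#' @export
holmBonferroni <- function(pValues, alpha = 0.05) {
  m <- length(pValues)
  if (m == 0L) stop("empty p-value list")
  if (any(pValues < 0 | pValues > 1)) stop("p-values must lie in [0, 1]")
  ord <- order(pValues)
  thresholds <- alpha / (m - seq_len(m) + 1)
  sorted <- pValues[ord]
  pass <- sorted <= thresholds
  first_fail <- which(!pass)[1L]
  reject_sorted <- if (is.na(first_fail)) rep(TRUE, m)
                   else seq_len(m) < first_fail
  adj_sorted <- pmin(1, cummax((m - seq_len(m) + 1) * sorted))
  reject <- adjusted <- rep(NA, m)
  reject[ord] <- reject_sorted
  adjusted[ord] <- adj_sorted
  list(thresholds = thresholds, reject = as.logical(reject),
       adjusted_p = as.numeric(adjusted), alpha = alpha)
}

#' Two-group sample size (normal approximation)
#'
#' `n = ceiling(2 (z_{1 - alpha/side} + z_{power})^2 (sigma / delta)^2)`
#' per group, for detecting a mean difference `delta` between two groups of
#' common SD `sigma`.
#'
#' @param delta group mean difference to detect (non-zero).
#' @param sigma per-group standard deviation (> 0).
#' @param power target power (default 0.8).
#' @param alpha significance level (default 0.05).
#' @param sided 1 or 2.
#' @return Integer sample size per group.
#' @examples
#' sampleSizeTwoGroup(0.013, 0.005)  # 3 per group, two-sided
#' @export
sampleSizeTwoGroup <- function(delta, sigma, power = 0.8, alpha = 0.05,
                               sided = 2L) {
  if (delta == 0) stop("delta must be non-zero")
  if (sigma <= 0) stop("sigma must be positive")
  if (power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1)
    stop("power and alpha must lie in (0, 1)")
  if (!sided %in% c(1L, 2L)) stop("sided must be 1 or 2")
  z <- qnorm(1 - alpha / sided) + qnorm(power)
  as.integer(ceiling(2 * z^2 * (sigma / delta)^2))
}

#' Ordinary least-squares linear trend
#'
#' @param x,y numeric vectors; `x` must contain at least 2 distinct values.
#' @return data.frame row: `slope`, `intercept`, `r` (signed Pearson
#'   correlation).
#' @export
linearTrend <- function(x, y) {
  if (length(unique(x)) < 2L) stop("x must contain at least 2 distinct values")
  fit <- lm(y ~ x)
  r <- if (sd(y) == 0) 0 else unname(cor(x, y))
  data.frame(slope = unname(coef(fit)[2L]),
             intercept = unname(coef(fit)[1L]), r = r)
}

#' Repeatability report across two matched measurement sets
#'
#' Matches two per-cell (or per-location) result tables on a key, then for
#' each parameter reports the single-measure ICC (agreement by default, as
#' used for scan/visit repeatability; consistency for mask-sensitivity
#' comparisons), its agreement class (with non-significant ICCs marked
#' `"ns"`), and the mean and SD of the absolute and percent differences.
#'
#' @param a,b data.frames of matched measurements.
#' @param parameters parameter columns to report (default the standard set
#'   `tau_m_ps`, `tau1_ps`, `tau2_ps`, `a1`, `g`, `s`, intersected with the
#'   available columns).
#' @param matchOn key column (default `"label"`).
#' @param model `"agreement"` or `"consistency"`.
#' @return data.frame with one row per parameter: `parameter`, `icc_value`,
#'   `icc_model`, `icc_p`, `icc_class`, difference statistics, `n_units`.
#' @export
repeatabilityReport <- function(a, b,
                                parameters = c("tau_m_ps", "tau1_ps",
                                               "tau2_ps", "a1", "g", "s"),
                                matchOn = "label", model = "agreement") {
  stopifnot(model %in% c("agreement", "consistency"))
  parameters <- intersect(parameters, intersect(colnames(a), colnames(b)))
  if (!length(parameters)) stop("no shared parameter columns to compare")
  merged <- merge(a[, c(matchOn, parameters)], b[, c(matchOn, parameters)],
                  by = matchOn, suffixes = c(".a", ".b"))
  rows <- lapply(parameters, function(p) {
    x1 <- merged[[paste0(p, ".a")]]
    x2 <- merged[[paste0(p, ".b")]]
    ok <- is.finite(x1) & is.finite(x2)
    x1 <- x1[ok]; x2 <- x2[ok]
    if (length(x1) < 3L)
      return(data.frame(parameter = p, icc_value = NA_real_,
                        icc_model = model, icc_p = NA_real_,
                        icc_class = NA_character_, mean_abs_diff = NA_real_,
                        sd_abs_diff = NA_real_, mean_pct_diff = NA_real_,
                        sd_pct_diff = NA_real_, n_units = length(x1)))
    mat <- cbind(x1, x2)
    icc <- if (model == "agreement") iccAgreement(mat) else iccConsistency(mat)
    dstats <- suppressWarnings(pairedDifferenceStats(x1, x2))
    data.frame(parameter = p, icc_value = as.numeric(icc),
               icc_model = model, icc_p = attr(icc, "p_value"),
               icc_class = classifyIcc(as.numeric(icc),
                                       attr(icc, "p_value")),
               mean_abs_diff = dstats$mean_abs_diff,
               sd_abs_diff = dstats$sd_abs_diff,
               mean_pct_diff = dstats$mean_pct_diff,
               sd_pct_diff = dstats$sd_pct_diff,
               n_units = length(x1))
  })
  do.call(rbind, rows)
}
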
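# Evaluation statistics over collections of dispensing runs, plus the small
# worked-example calculators used to characterise the device.

#' Percent accuracy of dispensing
#'
#' Mean percent difference between the number dispensed and the target.
#' Display convention for headline values is the nearest integer percent; the
#' raw value is returned.
#'
#' @param dispensed_mean Mean number dispensed.
#' @param target Target count (>= 1).
#' @return Percent deviation (raw).
#' @examples
#' accuracy_pct(262, 250)  # +4.8, displays +5%
#' accuracy_pct(233, 250)  # -6.8, displays -7%
#' @export
accuracy_pct <- function(dispensed_mean, target) {
  if (any(target < 1)) stop("target must be >= 1")
  100 * (dispensed_mean - target) / target
}

#' Photograph-count disagreement rate
#'
#' @param n_disagree Counts requiring third-person reconciliation.
#' @param n_total Total photographs counted.
#' @return Percent (raw; display to one decimal).
#' @examples
#' disagreement_rate(275, 477)  # 57.65 -> displays 57.6-57.7%
#' @export
disagreement_rate <- function(n_disagree, n_total) {
  if (any(n_total < 1)) stop("n_total must be >= 1")
  if (any(n_disagree < 0) || any(n_disagree > n_total))
    stop("n_disagree must be in [0, n_total]")
  100 * n_disagree / n_total
}

#' Two-sided normal tail probability at a z threshold
#'
#' The probability that pure Gaussian noise exceeds `z` standard deviations in
#' either direction -- the rationale for the recommended detection threshold
#' (z = 3.5 gives ~1 random trigger per 2100 samples).
#'
#' @param z Threshold in standard deviations (>= 0), vectorised.
#' @return `2 * (1 - Phi(z))`.
#' @examples
#' signif(z_error_probability(3.5), 2)  # 0.00047
#' @export
z_error_probability <- function(z) {
  if (any(z < 0)) stop("z must be non-negative")
  2 * stats::pnorm(z, lower.tail = FALSE)
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance (default) or Welch two-sided t-test computed from group
#' means, SDs and sizes only.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries (`n >= 2`, `sd >= 0`).
#' @param welch Use the Welch (unequal variance) variant.
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_ttest <- function(mean1, sd1, n1, mean2, sd2, n2, welch = FALSE) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("sds must be non-negative")
  if (sd1 == 0 && sd2 == 0 && mean1 == mean2)
    return(list(t = 0, df = n1 + n2 - 2, p = 1))
  v1 <- sd1^2; v2 <- sd2^2
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    tval <- (mean1 - mean2) / sqrt(se2)
  } else {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    tval <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

runs_to_dispensed <- function(x, target = NULL) {
  if (is.numeric(x)) return(list(dispensed = x, target = target))
  tab <- runs_table(x)
  list(dispensed = tab$dispensed[tab$complete],
       target = if (is.null(target)) tab$target[1] else target,
       tab = tab)
}

#' Accuracy and precision summary of dispensing runs
#'
#' Mean percent error with a t-based 95% CI half-width, the integer-count mode
#' (all tied maxima reported), the proportions of runs within +/-2 and +/-5 of
#' the target, a Shapiro-Wilk normality p-value, and the skew direction of the
#' dispensed counts.
#'
#' @param x Numeric vector of dispensed counts, or a `dispense_chain` / list
#'   of `dispense_run`s (incomplete runs excluded).
#' @param target Target count; taken from the runs when omitted.
#' @return An object of class `eval_summary`. With a single run the CI and
#'   Shapiro-Wilk entries are `NA` (unavailable, not fabricated).
#' @export
summarize_runs <- function(x, target = NULL) {
  d <- runs_to_dispensed(x, target)
  disp <- d$dispensed
  target <- d$target
  if (is.null(target)) stop("target must be supplied for a plain numeric vector")
  n <- length(disp)
  if (n < 1) stop("at least one (complete) run required")
  err <- accuracy_pct(disp, target)
  ci <- if (n >= 2 && stats::sd(err) > 0)
    stats::qt(0.975, n - 1) * stats::sd(err) / sqrt(n)
  else if (n >= 2) 0 else NA_real_
  tab <- table(disp)
  mode_vals <- as.integer(names(tab)[tab == max(tab)])
  shapiro_p <- if (n >= 3 && n <= 5000 && stats::sd(disp) > 0)
    stats::shapiro.test(disp)$p.value else NA_real_
  m3 <- mean((disp - mean(disp))^3)
  s <- stats::sd(disp)
  skew <- if (n < 3 || is.na(s) || s == 0) 0 else m3 / s^3
  structure(list(n_runs = n,
                 target = target,
                 mean_dispensed = mean(disp),
                 mean_pct_error = mean(err),
                 ci95_halfwidth = ci,
                 mode = mode_vals,
                 mode_n = max(tab),
                 prop_98_102 = mean(abs(disp - target) <= 2),
                 prop_95_105 = mean(abs(disp - target) <= 5),
                 shapiro_p = shapiro_p,
                 skewness = skew,
                 skew_direction = if (skew < 0) "left"
                                  else if (skew > 0) "right" else "none"),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("dispensing summary over %d runs (target %d):\n", x$n_runs, x$target))
  cat(sprintf("  accuracy: %+.2f%% (95%% CI +/- %.2f), mean dispensed %.2f\n",
              x$mean_pct_error, x$ci95_halfwidth, x$mean_dispensed))
  cat(sprintf("  mode: %s (%d runs); within +/-2: %.1f%%; within +/-5: %.1f%%\n",
              paste(x$mode, collapse = "/"), x$mode_n,
              100 * x$prop_98_102, 100 * x$prop_95_105))
  cat(sprintf("  Shapiro-Wilk p = %.3g; skew %s (%.2f)\n",
              x$shapiro_p, x$skew_direction, x$skewness))
  invisible(x)
}

# sd recovered from a 95% CI half-width of the mean: sd = ci * sqrt(n) / crit,
# where crit is the t quantile (this package's own CI convention) or the
# normal quantile (as produced by spreadsheet CONFIDENCE-style summaries).
sd_from_ci <- function(ci, n, ci_quantile = c("t", "normal")) {
  ci_quantile <- match.arg(ci_quantile)
  crit <- if (ci_quantile == "t") stats::qt(0.975, n - 1)
          else stats::qnorm(0.975)
  ci * sqrt(n) / crit
}

#' One-way ANOVA with Tukey HSD letters
#'
#' Accepts either raw per-group values or published group summaries
#' (`n`, `mean`, and 95% CI half-width of the mean). For summaries, the
#' between-group sum of squares comes from the group sizes and means and the
#' within-group variance is recovered from the CI half-widths via the t
#' quantile (`sd = ci * sqrt(n) / t(0.975, n-1)`). Pairwise comparisons use
#' the studentized-range (Tukey HSD) distribution; by default significance is
#' judged at a Bonferroni-adjusted alpha (`alpha / n_pairs`), with plain HSD
#' available via `bonferroni = FALSE`. Groups sharing a letter are not
#' significantly different.
#'
#' @param x Either a data.frame with columns `label`, `n`, `mean`, `ci`
#'   (summary route) or a data.frame with columns `label`, `value` /
#'   a named list of numeric vectors (raw route).
#' @param alpha Family significance level.
#' @param bonferroni Evaluate HSD comparisons at `alpha / n_pairs`.
#' @param ci_quantile Quantile convention behind the supplied CI half-widths:
#'   `"t"` (this package's convention) or `"normal"` (spreadsheet
#'   CONFIDENCE-style summaries, as in many published tables).
#' @return An object of class `apc_anova`: `table` (Source/SS/df/MS/F/P),
#'   `groups` (label, n, mean, letters), `pairwise` (labels, q, p, significant),
#'   `alpha_effective`.
#' @examples
#' raw <- data.frame(label = rep(c("A", "B"), each = 5),
#'                   value = c(1:5, 4:8))
#' zscore_anova(raw)$table
#' @export
zscore_anova <- function(x, alpha = 0.05, bonferroni = TRUE,
                         ci_quantile = c("t", "normal")) {
  ci_quantile <- match.arg(ci_quantile)
  if (is.list(x) && !is.data.frame(x)) {
    x <- data.frame(label = rep(names(x), lengths(x)),
                    value = unlist(x, use.names = FALSE))
  }
  stopifnot(is.data.frame(x))
  if (all(c("n", "mean") %in% names(x))) {
    g <- x
    if (!"label" %in% names(g)) g$label <- as.character(seq_len(nrow(g)))
    if (nrow(g) < 2) stop("at least two groups required")
    usable <- g$n >= 2 & !is.na(g$ci)
    if (any(!usable))
      warning("groups with n = 1 or missing CI excluded from within-group SS recovery")
    gm <- sum(g$n * g$mean) / sum(g$n)
    ss_b <- sum(g$n * (g$mean - gm)^2)
    df_b <- nrow(g) - 1
    sds <- rep(NA_real_, nrow(g))
    sds[usable] <- sd_from_ci(g$ci[usable], g$n[usable], ci_quantile)
    ss_w <- sum((g$n[usable] - 1) * sds[usable]^2)
    df_w <- sum(g$n) - nrow(g)
    means <- g$mean; ns <- g$n; labels <- as.character(g$label)
  } else if (all(c("label", "value") %in% names(x))) {
    f <- factor(x$label)
    if (nlevels(f) < 2) stop("at least two groups required")
    fit <- stats::aov(value ~ f, data = data.frame(value = x$value, f = f))
    a <- stats::anova(fit)
    ss_b <- a$`Sum Sq`[1]; df_b <- a$Df[1]
    ss_w <- a$`Sum Sq`[2]; df_w <- a$Df[2]
    means <- tapply(x$value, f, mean)
    ns <- as.integer(table(f))
    labels <- levels(f)
  } else {
    stop("x must have columns (label, n, mean, ci) or (label, value)")
  }
  ms_b <- ss_b / df_b
  ms_w <- ss_w / df_w
  fval <- ms_b / ms_w
  p <- stats::pf(fval, df_b, df_w, lower.tail = FALSE)
  k <- length(means)
  pairs <- utils::combn(k, 2)
  npairs <- ncol(pairs)
  alpha_eff <- if (bonferroni) alpha / npairs else alpha
  q <- p_pair <- numeric(npairs)
  for (j in seq_len(npairs)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(ms_w / 2 * (1 / ns[i1] + 1 / ns[i2]))
    q[j] <- abs(means[i1] - means[i2]) / se
    p_pair[j] <- stats::ptukey(q[j], k, df_w, lower.tail = FALSE)
  }
  sig <- matrix(FALSE, k, k)
  for (j in seq_len(npairs))
    sig[pairs[1, j], pairs[2, j]] <- sig[pairs[2, j], pairs[1, j]] <-
      p_pair[j] < alpha_eff
  letters_by_group <- cld_letters(means, sig)
  tab <- data.frame(Source = c("Between Groups", "Within Groups", "Total"),
                    SS = c(ss_b, ss_w, ss_b + ss_w),
                    df = c(df_b, df_w, df_b + df_w),
                    MS = c(ms_b, ms_w, NA),
                    F = c(fval, NA, NA),
                    P = c(p, NA, NA))
  structure(list(table = tab,
                 groups = data.frame(label = labels, n = ns,
                                     mean = as.numeric(means),
                                     letters = letters_by_group),
                 pairwise = data.frame(group1 = labels[pairs[1, ]],
                                       group2 = labels[pairs[2, ]],
                                       q = q, p = p_pair,
                                       significant = p_pair < alpha_eff),
                 alpha_effective = alpha_eff),
            class = "apc_anova")
}

# Compact letter display: groups sorted by mean; every maximal contiguous
# block of mutually non-different groups gets one letter.
cld_letters <- function(means, sig) {
  k <- length(means)
  ord <- order(means)
  ranges <- list()
  for (a in seq_len(k)) {
    b <- a
    while (b < k && !any(sig[ord[a:(b + 1)], ord[a:(b + 1)]]))
      b <- b + 1
    ranges[[length(ranges) + 1]] <- c(a, b)
  }
  ranges <- unique(ranges)
  # drop ranges nested in another
  keep <- vapply(seq_along(ranges), function(i) {
    !any(vapply(seq_along(ranges), function(j) {
      i != j && ranges[[j]][1] <= ranges[[i]][1] && ranges[[j]][2] >= ranges[[i]][2]
    }, logical(1)))
  }, logical(1))
  ranges <- ranges[keep]
  out <- character(k)
  for (r in seq_along(ranges)) {
    idx <- ord[ranges[[r]][1]:ranges[[r]][2]]
    out[idx] <- paste0(out[idx], letters[r])
  }
  out
}

#' @export
print.apc_anova <- function(x, ...) {
  cat("One-way ANOVA\n")
  print(x$table, row.names = FALSE, digits = 7)
  cat(sprintf("Tukey HSD letters (alpha_eff = %.4g):\n", x$alpha_effective))
  print(x$groups, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Correlation between throughput rate and accuracy
#'
#' Pearson correlation between per-run mean larvae-per-second and percent
#' error of the number dispensed.
#'
#' @param x A `dispense_chain` / list of runs, or a data.frame with columns
#'   `mean_lps` and either `pct_error` or (`dispensed`, `target`).
#' @param target Target count when `x` is a list of runs (taken from runs by
#'   default).
#' @return List with `r`, `p`, `n`; `r` is `NA` (with `reason`) when either
#'   variable has zero variance.
#' @export
lps_accuracy_correlation <- function(x, target = NULL) {
  if (is.data.frame(x)) {
    lps <- x$mean_lps
    err <- if ("pct_error" %in% names(x)) x$pct_error
           else accuracy_pct(x$dispensed, if (is.null(target)) x$target else target)
  } else {
    tab <- runs_table(x)
    tab <- tab[tab$complete, ]
    lps <- tab$mean_lps
    err <- accuracy_pct(tab$dispensed, if (is.null(target)) tab$target else target)
  }
  if (length(lps) < 3) stop("at least three runs required")
  if (stats::sd(lps) == 0 || stats::sd(err) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(lps),
                reason = "zero variance"))
  ct <- stats::cor.test(lps, err, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(lps))
}
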
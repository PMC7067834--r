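#' Mean relative difference between paired fine/coarse measurements
#'
#' `mean(100 * (fine_i - coarse_i) / fine_i)` over samples: the average of
#' per-sample relative differences (not the ratio of the means), positive
#' when the fine-resolution measurement is larger.
#'
#' @param fine,coarse equal-length numeric vectors of paired per-sample
#'   values; all `fine` values must be nonzero.
#' @return the difference in percent.
#' @export
relative_diff <- function(fine, coarse) {
  if (length(fine) != length(coarse) || length(fine) < 1)
    stop("fine and coarse must be paired vectors of equal length >= 1")
  if (any(fine == 0)) stop("relative difference undefined: zero fine value")
  mean(100 * (fine - coarse) / fine)
}

#' Paired two-group test with a normality/variance decision rule
#'
#' Tests whether a parameter differs between the two resolutions: a
#' Kolmogorov-Smirnov normality check on each group (against a normal with
#' estimated mean and sd -- a Lilliefors-style usage, so the normality p is
#' approximate) and an F-test of variance homogeneity decide the test: when
#' all pass (p > 0.05) a paired t-test is used, otherwise the Wilcoxon
#' signed rank test. The decision trace is returned so every branch is
#' logged.
#'
#' @param fine,coarse paired numeric vectors, n >= 3.
#' @return list: `test` ("paired t" or "wilcoxon signed rank"), `statistic`,
#'   `p_value`, `normality_p` (per group), `variance_p`, `degenerate` flag
#'   (all differences zero reports p = 1), `decision` (text trace).
#' @export
paired_test <- function(fine, coarse) {
  if (length(fine) != length(coarse) || length(fine) < 3)
    stop("need at least 3 pairs")
  d <- fine - coarse
  if (all(d == 0)) {
    return(list(test = "wilcoxon signed rank", statistic = NA_real_,
                p_value = 1, normality_p = c(NA_real_, NA_real_),
                variance_p = NA_real_, degenerate = TRUE,
                decision = "all paired differences zero: degenerate, p = 1"))
  }
  ks_p <- function(x) {
    if (sd(x) == 0) return(0)
    suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x))$p.value)
  }
  np <- c(ks_p(fine), ks_p(coarse))
  vp <- if (sd(fine) == 0 || sd(coarse) == 0) 0 else
    var.test(fine, coarse)$p.value
  use_t <- all(np > 0.05) && vp > 0.05
  if (sd(d) == 0) {
    # exactly constant nonzero shift: the paired t statistic diverges
    return(list(test = "paired t", statistic = sign(mean(d)) * Inf,
                p_value = 0, normality_p = np, variance_p = vp,
                degenerate = TRUE,
                decision = "constant nonzero paired difference: t diverges, p = 0"))
  }
  if (use_t) {
    tt <- t.test(fine, coarse, paired = TRUE)
    res <- list(test = "paired t", statistic = unname(tt$statistic),
                p_value = tt$p.value)
    why <- sprintf("normality p = {%.3f, %.3f} and variance p = %.3f all > 0.05 -> paired t",
                   np[1], np[2], vp)
  } else {
    wt <- suppressWarnings(wilcox.test(fine, coarse, paired = TRUE))
    res <- list(test = "wilcoxon signed rank",
                statistic = unname(wt$statistic), p_value = wt$p.value)
    why <- sprintf("normality p = {%.3f, %.3f}, variance p = %.3f: condition failed -> wilcoxon",
                   np[1], np[2], vp)
  }
  c(res, list(normality_p = np, variance_p = vp, degenerate = FALSE,
              decision = why))
}

#' Spearman correlation, regression slope and Fisher-z p-value
#'
#' Correlation between paired fine/coarse measurements: squared Spearman rank
#' correlation (R^2), the ordinary least-squares slope of `coarse` on `fine`,
#' and the p-value of the correlation from Fisher's r-to-z transformation.
#' A `good` flag marks R^2 > 0.5 with p < 0.05.
#'
#' @param fine,coarse paired numeric vectors, n >= 3, non-constant.
#' @return list: `r2`, `rho`, `slope`, `p_value`, `good`.
#' @export
correlate_resolutions <- function(fine, coarse) {
  if (length(fine) != length(coarse) || length(fine) < 3)
    stop("need at least 3 pairs")
  if (sd(fine) == 0 || sd(coarse) == 0)
    stop("zero variance: correlation undefined")
  rho <- cor(fine, coarse, method = "spearman")
  slope <- unname(coef(lm(coarse ~ fine))[2])
  n <- length(fine)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    z <- atanh(rho) * sqrt(n - 3)
    p <- 2 * (1 - pnorm(abs(z)))
  }
  list(r2 = rho^2, rho = rho, slope = slope, p_value = p,
       good = rho^2 > 0.5 && p < 0.05)
}

#' Resolution-impact comparison report over a set of parameters
#'
#' Builds the paired fine-vs-coarse report for every shared numeric column of
#' two per-sample parameter tables: mean relative difference (Diff, %), the
#' decision-rule paired test, and (for n >= 3 non-constant parameters) the
#' Spearman R^2, regression slope and Fisher-z p-value.
#'
#' @param fine_df,coarse_df data.frames with one row per sample and one
#'   column per parameter (same columns, same sample order).
#' @return data.frame with columns Parameter, Diff, Test, Statistic, p.value,
#'   Slope, R2, cor.p.value, Good.
#' @export
compare_tables <- function(fine_df, coarse_df) {
  params <- intersect(names(fine_df), names(coarse_df))
  params <- params[vapply(params, function(p)
    is.numeric(fine_df[[p]]) && is.numeric(coarse_df[[p]]), logical(1))]
  if (!length(params)) stop("no shared numeric parameters")
  rows <- lapply(params, function(p) {
    f <- fine_df[[p]]
    cvals <- coarse_df[[p]]
    dif <- if (any(f == 0)) NA_real_ else relative_diff(f, cvals)
    tst <- if (length(f) >= 3) paired_test(f, cvals) else
      list(test = NA_character_, statistic = NA_real_, p_value = NA_real_)
    cr <- if (length(f) >= 3 && sd(f) > 0 && sd(cvals) > 0)
      correlate_resolutions(f, cvals)
    else list(slope = NA_real_, r2 = NA_real_, p_value = NA_real_, good = NA)
    data.frame(Parameter = p, Diff = dif, Test = tst$test,
               Statistic = tst$statistic, p.value = tst$p_value,
               Slope = cr$slope, R2 = cr$r2, cor.p.value = cr$p_value,
               Good = cr$good, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
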
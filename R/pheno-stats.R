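#' Group summary (mean, SE, n)
#'
#' The printed form of a replicate set: mean, standard error of the mean
#' and replicate count.
#'
#' @param mean group mean.
#' @param se standard error of the mean (>= 0).
#' @param n replicate count (>= 2).
#' @return list of class `groupSummary`.
#' @export
groupSummary <- function(mean, se, n) {
  if (!is.numeric(se) || se < 0) stop("se must be >= 0")
  if (!is.numeric(n) || n < 2) stop("n must be >= 2")
  structure(list(mean = mean, se = se, n = n), class = "groupSummary")
}

#' @rdname groupSummary
#' @param x numeric vector of raw replicate values.
#' @export
summarizeSamples <- function(x) {
  if (length(x) < 2L) stop("need at least 2 replicates")
  groupSummary(mean(x), stats::sd(x) / sqrt(length(x)), length(x))
}

#' Pooled two-sample t test from printed summaries
#'
#' `t = (m1 - m2) / sqrt(se1^2 + se2^2)` with `df = n1 + n2 - 2` and a
#' two-sided p from the t distribution. For equal group sizes this is
#' exactly the textbook pooled (Student) t computed from the raw samples,
#' since `sp * sqrt(2/n) = sqrt(se1^2 + se2^2)` when `n1 = n2`.
#'
#' @param g1,g2 [groupSummary()] objects (or raw numeric vectors, which
#'   are summarized first).
#' @return list with `statistic`, `df`, `p`, `method = "pooled-t"`.
#' @examples
#' pooledTSummary(groupSummary(0.351, 0.005, 10),
#'                groupSummary(0.347, 0.010, 10))
#' @export
pooledTSummary <- function(g1, g2) {
  if (is.numeric(g1)) g1 <- summarizeSamples(g1)
  if (is.numeric(g2)) g2 <- summarizeSamples(g2)
  stopifnot(inherits(g1, "groupSummary"), inherits(g2, "groupSummary"))
  denom <- sqrt(g1$se^2 + g2$se^2)
  if (denom == 0) {
    if (g1$mean == g2$mean) {
      t <- 0
    } else {
      stop("both standard errors are zero with unequal means: ",
           "t statistic is infinite")
    }
  } else {
    t <- (g1$mean - g2$mean) / denom
  }
  df <- g1$n + g2$n - 2
  list(statistic = t, df = df,
       p = 2 * stats::pt(-abs(t), df = df), method = "pooled-t")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving with the input (delegates to
#' `stats::p.adjust(method = "BH")`).
#'
#' @param pvalues numeric vector of p values in `[0, 1]`.
#' @return adjusted p values in input order.
#' @export
bhAdjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Larval relative growth rate
#'
#' `RGR = ln(w7 / w2) / 5` in mg per mg per day, from the per-aphid
#' weights at day 2 and day 7 of larval development.
#'
#' @param wDay2,wDay7 weights (mg, > 0); vectorized.
#' @return RGR in mg/mg/day.
#' @export
relativeGrowthRate <- function(wDay2, wDay7) {
  if (any(wDay2 <= 0) || any(wDay7 <= 0))
    stop("weights must be positive")
  log(wDay7 / wDay2) / 5
}

#' Intrinsic rate of increase
#'
#' `r_m = 0.745 * ln(Md) / d`, with `Md` the total progeny per aphid and
#' `d` the days from larviposition to onset of reproduction.
#'
#' @param Md progeny count (>= 1); vectorized.
#' @param d days to first reproduction (> 0).
#' @return r_m in per day.
#' @export
intrinsicRate <- function(Md, d) {
  if (any(Md < 1)) stop("Md must be >= 1")
  if (any(d <= 0)) stop("d must be > 0")
  0.745 * log(Md) / d
}

#' Rank-sum (Mann-Whitney) two-sample test
#'
#' Delegated to `stats::wilcox.test` with the normal approximation and
#' continuity correction. Provided as the explicit alternative to the
#' pooled t test for nonnormal or heteroscedastic data; the choice of
#' test is always the caller's, never switched silently.
#'
#' @param x,y raw samples.
#' @return list with `statistic` (W), `df` (`NA`), `p`, `method`.
#' @export
rankSumTest <- function(x, y) {
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), df = NA_real_,
       p = wt$p.value, method = "mann-whitney")
}

#' Advisory normality and homoscedasticity checks
#'
#' Shapiro-Wilk per group and Bartlett's test across groups, reported as
#' advisory p values only — they never change which test is run.
#'
#' @param x,y raw samples (length >= 3 each for Shapiro-Wilk).
#' @return data.frame with columns `check`, `p`.
#' @export
checkDistributionAssumptions <- function(x, y) {
  data.frame(
    check = c("shapiro_group1", "shapiro_group2", "bartlett"),
    p = c(stats::shapiro.test(x)$p.value,
          stats::shapiro.test(y)$p.value,
          stats::bartlett.test(list(x, y))$p.value))
}

#' Two-stage metabolite screen
#'
#' Stage 1: per-feature two-sample pooled t test of symbiont status
#' (uncorrected) flags candidates at `alpha`. Stage 2: for each candidate,
#' a linear mixed model with status as fixed effect and genotype as random
#' intercept, fitted by REML (`lmerTest::lmer`), whose Satterthwaite fixed-
#' effect p values are then Benjamini-Hochberg adjusted. Features that are
#' constant within both groups are skipped and reported as not applicable.
#' With fewer than two genotypes per status level the mixed stage cannot
#' be fitted; the screen falls back to BH-adjusted stage-1 p values with a
#' warning.
#'
#' @param matrix numeric features x samples matrix (log-scale
#'   abundances), feature ids as rownames.
#' @param design data.frame with columns `sample`, `status` (two levels)
#'   and `genotype`, rows matching the matrix columns.
#' @param alpha stage-1 candidate threshold (default 0.05).
#' @return data.frame with one row per feature: `feature`, `t`, `p_t`
#'   (stage 1), `candidate`, `p_mixed` (stage 2, NA for non-candidates),
#'   `p_adj` (BH over the stage-2 tests), `note`.
#' @seealso [genMetabolomicsMatrix()]
#' @export
metaboliteScreen <- function(matrix, design, alpha = 0.05) {
  stopifnot(is.matrix(matrix), ncol(matrix) == nrow(design))
  if (!all(c("sample", "status", "genotype") %in% names(design)))
    stop("design needs columns sample, status, genotype")
  status <- factor(design$status)
  if (nlevels(status) != 2L)
    stop("status must have exactly 2 levels, got ", nlevels(status))
  g_per_level <- tapply(design$genotype, status,
                        function(g) length(unique(g)))
  mixed_ok <- all(g_per_level >= 2L)
  if (!mixed_ok)
    warning("fewer than 2 genotypes per status level: mixed-model stage ",
            "skipped, falling back to t-only screening")
  i1 <- status == levels(status)[1]
  out <- data.frame(feature = rownames(matrix), t = NA_real_,
                    p_t = NA_real_, candidate = FALSE, p_mixed = NA_real_,
                    p_adj = NA_real_, note = "", stringsAsFactors = FALSE)
  for (f in seq_len(nrow(matrix))) {
    x <- matrix[f, i1]; y <- matrix[f, !i1]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      out$note[f] <- "constant feature: not applicable"
      next
    }
    tt <- stats::t.test(x, y, var.equal = TRUE)
    out$t[f] <- unname(tt$statistic)
    out$p_t[f] <- tt$p.value
    out$candidate[f] <- tt$p.value < alpha
  }
  cand <- which(out$candidate)
  if (length(cand)) {
    p2 <- vapply(cand, function(f) {
      if (!mixed_ok) return(out$p_t[f])
      dat <- data.frame(y = matrix[f, ], status = status,
                        genotype = factor(design$genotype))
      fit <- suppressMessages(suppressWarnings(
        lmerTest::lmer(y ~ status + (1 | genotype), data = dat)))
      stats::coef(summary(fit))[paste0("status", levels(status)[2]),
                                "Pr(>|t|)"]
    }, numeric(1))
    out$p_mixed[cand] <- p2
    out$p_adj[cand] <- bhAdjust(p2)
  }
  attr(out, "mixed_model") <- mixed_ok
  out
}
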
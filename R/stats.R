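## Nonparametric cohort statistics: rank-sum, Kruskal-Wallis with Dunn's
## multiple comparisons, Spearman correlation, univariate ANOVA, one-sample
## t, and the Shapiro-Wilk normality gate.

.stat_result <- function(test, statistic, p, n, pairwise = NULL,
                         alpha = 0.05) {
  structure(list(test = test, statistic = unname(statistic),
                 p = unname(p), n = n, pairwise = pairwise,
                 significant = !is.na(p) && p < alpha),
            class = "disc_stat")
}

#' Two-sided rank-sum (Mann-Whitney/Wilcoxon) test
#'
#' For small samples (`min(n) <= 8`) the p value is computed by exact
#' enumeration of all assignments of the pooled midranks (valid with ties);
#' otherwise the normal approximation with tie correction and continuity
#' correction is used. If every pooled value is identical, p = 1 by
#' convention.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact logical; force (or forbid) the exact enumeration. Default:
#'   exact when `min(length(x), length(y)) <= 8`.
#' @return a `disc_stat` list: `statistic` is the rank sum W of `x`.
#' @export
rank_sum_test <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); N <- nx + ny
  pooled <- c(x, y)
  rk <- rank(pooled)
  W <- sum(rk[seq_len(nx)])
  if (stats::var(pooled) == 0)
    return(.stat_result("rank_sum", W, 1, c(nx, ny)))
  if (is.null(exact)) exact <- min(nx, ny) <= 8
  if (exact) {
    mu <- nx * (N + 1) / 2
    combs <- utils::combn(N, nx)
    Wall <- colSums(matrix(rk[combs], nrow = nx))
    p <- mean(abs(Wall - mu) >= abs(W - mu) - 1e-9)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  }
  .stat_result("rank_sum", W, p, c(nx, ny))
}

#' Kruskal-Wallis test with Dunn's multiple comparison procedure
#'
#' Omnibus Kruskal-Wallis H (tie-corrected, chi-square p) followed by
#' Dunn's pairwise z tests on mean ranks with the classical Bonferroni-style
#' adjustment (unadjusted p times the number of pairs, capped at 1). In the
#' pipeline's decision logic a pair is declared significant only when both
#' its adjusted p and the omnibus p fall below `alpha`.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length as `values` (>= 3 groups, each
#'   with >= 2 observations for the omnibus test).
#' @param alpha significance level.
#' @return a `disc_stat` list; `pairwise` is a data frame with `group1`,
#'   `group2`, `z`, `p_unadj`, `p_adj`, `significant`.
#' @export
kruskal_dunn <- function(values, groups, alpha = 0.05) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  n_g <- table(groups)
  if (any(n_g == 0) || nlevels(groups) < 2)
    stop("each group must be non-empty and >= 2 groups are required")
  kw <- stats::kruskal.test(values, groups)
  N <- length(values)
  rk <- rank(values)
  rbar <- tapply(rk, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   z = NA_real_, p_unadj = NA_real_, p_adj = NA_real_,
                   significant = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    se <- sqrt(s2 * (1 / n_g[[g1]] + 1 / n_g[[g2]]))
    z <- (rbar[[g1]] - rbar[[g2]]) / se
    p_u <- 2 * stats::pnorm(-abs(z))
    pw$z[j] <- z
    pw$p_unadj[j] <- p_u
    pw$p_adj[j] <- min(1, p_u * m)
  }
  pw$significant <- pw$p_adj < alpha & kw$p.value < alpha
  .stat_result("kruskal_dunn", kw$statistic, kw$p.value, as.integer(n_g),
               pairwise = pw, alpha = alpha)
}

#' Spearman rank-order correlation
#'
#' rho is the Pearson correlation of midranks; the p value uses the t
#' approximation `t = rho sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom.
#'
#' @param x,y paired numeric vectors, n >= 3 after removing missing pairs.
#' @return a `disc_stat` list with `statistic` = rho.
#' @export
spearman_cor <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("zero variance in ranks: correlation undefined")
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  out <- .stat_result("spearman", rho, p, n)
  out$rho <- rho
  out
}

#' Univariate analysis of variance (partial sums of squares)
#'
#' Fits a linear model of the response on the given covariates (factors
#' with sum-to-zero contrasts) and reports the partial (Type-III-style) F
#' test for each variable, i.e. the F for dropping that variable from the
#' full model.
#'
#' @param data data frame containing all variables.
#' @param response name of the response column.
#' @param covariates character vector of covariate names.
#' @param factors subset of `covariates` to treat as factors.
#' @return data frame with `variable`, `df`, `F`, `p`.
#' @export
univariate_anova <- function(data, response, covariates,
                             factors = character()) {
  cols <- c(response, covariates)
  if (any(!cols %in% names(data)))
    stop("missing columns: ", paste(setdiff(cols, names(data)), collapse = ", "))
  d <- data[, cols, drop = FALSE]
  if (anyNA(d)) stop("missing values in selected columns")
  for (f in factors) d[[f]] <- factor(d[[f]])
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  form <- stats::as.formula(paste(response, "~",
                                  paste(covariates, collapse = " + ")))
  fit <- stats::lm(form, data = d)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased: ", paste(aliased, collapse = ", "))
  }
  dr <- stats::drop1(fit, scope = form, test = "F")
  dr <- dr[-1, , drop = FALSE]   # drop the <none> row
  data.frame(variable = rownames(dr), df = dr$Df, F = dr$`F value`,
             p = dr$`Pr(>F)`, row.names = NULL, stringsAsFactors = FALSE)
}

#' One-sample t test
#'
#' Classical two-sided one-sample t test against `mu0`. A zero-variance
#' sample equal to `mu0` is reported as t = 0, p = 1 by convention; a
#' zero-variance sample different from `mu0` as p = 0 with a warning.
#'
#' @param values numeric sample, n >= 2.
#' @param mu0 hypothesized mean.
#' @return a `disc_stat` list.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 observations")
  if (stats::sd(values) == 0) {
    if (isTRUE(all.equal(mean(values), mu0)))
      return(.stat_result("one_sample_t", 0, 1, n))
    warning("zero variance with mean != mu0: p = 0 by convention")
    return(.stat_result("one_sample_t", sign(mean(values) - mu0) * Inf, 0, n))
  }
  tt <- stats::t.test(values, mu = mu0)
  .stat_result("one_sample_t", tt$statistic, tt$p.value, n)
}

#' Shapiro-Wilk normality gate
#'
#' Records the Shapiro-Wilk p value; the pipeline proceeds with
#' nonparametric tests when the gate reports non-normality (p < alpha).
#' Outside the valid sample-size range (3..5000) the gate is skipped with a
#' warning.
#'
#' @param values numeric sample.
#' @param alpha significance level.
#' @return list with `p` and logical `non_normal` (NA when skipped).
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000) {
    warning("sample size outside 3..5000: normality gate skipped")
    return(list(p = NA_real_, non_normal = NA))
  }
  if (stats::sd(values) == 0) stop("constant sample: normality test undefined")
  p <- stats::shapiro.test(values)$p.value
  list(p = p, non_normal = p < alpha)
}

#' Modic-change group label for a disc
#'
#' A disc with at least one type I/II endplate, or type I at one endplate
#' and type II at the other, is grouped as `MCI/II`; otherwise the disc is
#' labelled by its single present type (`MCI`, `MCII`), or `MC0` when both
#' endplates are free of Modic changes. Type III (never produced by the
#' phantom generator) is kept as its own label `MCIII` with a warning.
#'
#' @param mc_upper,mc_lower character vectors of per-endplate types
#'   (`"0"`, `"I"`, `"II"`, `"I/II"`, `"III"`).
#' @return character vector of group labels.
#' @export
mc_group <- function(mc_upper, mc_lower) {
  out <- character(length(mc_upper))
  for (i in seq_along(mc_upper)) {
    u <- mc_upper[i]; l <- mc_lower[i]
    if (u == "III" || l == "III") {
      warning("MC type III present: grouped as its own label MCIII")
      out[i] <- "MCIII"
    } else if (u == "I/II" || l == "I/II" ||
               (u == "I" && l == "II") || (u == "II" && l == "I")) {
      out[i] <- "MCI/II"
    } else if (u == "I" || l == "I") {
      out[i] <- "MCI"
    } else if (u == "II" || l == "II") {
      out[i] <- "MCII"
    } else {
      out[i] <- "MC0"
    }
  }
  out
}
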
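test_that("rank-sum test: exact small-sample p values and conventions", {
  # identical pooled values: p = 1 by convention
  expect_gte(rank_sum_test(c(2, 2, 2), c(2, 2))$p, 0.99)
  # fully separated samples: 2 of the 20 assignments are as extreme
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$p, 0.1)
  expect_equal(rs$statistic, 6)   # ranks 1 + 2 + 3
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("exact rank-sum p equals the reference enumeration", {
  set.seed(61)
  for (rep in 1:10) {
    nx <- sample(3:6, 1); ny <- sample(3:7, 1)
    x <- round(rnorm(nx), 1); y <- round(rnorm(ny, 0.5), 1)  # ties likely
    got <- rank_sum_test(x, y)$p
    # tie-free comparison against the classical exact distribution
    if (!anyDuplicated(c(x, y))) {
      want <- wilcox.test(x, y, exact = TRUE)$p.value
      expect_equal(got, want, tolerance = 1e-12)
    }
    # reference enumeration over all labelings (midranks, two-sided)
    rk <- rank(c(x, y)); N <- nx + ny; mu <- nx * (N + 1) / 2
    W <- sum(rk[1:nx])
    cnt <- 0; tot <- 0
    for (idx in utils::combn(N, nx, simplify = FALSE)) {
      tot <- tot + 1
      if (abs(sum(rk[idx]) - mu) >= abs(W - mu) - 1e-9) cnt <- cnt + 1
    }
    expect_equal(got, cnt / tot, tolerance = 1e-12)
  }
  # large samples fall back to the tie-corrected normal approximation
  set.seed(62)
  x <- rnorm(30); y <- rnorm(30, 1)
  expect_equal(rank_sum_test(x, y)$p,
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("Kruskal-Wallis H matches the closed-form rank computation", {
  st <- kruskal_dunn(c(1, 2, 3, 11, 12, 13, 21, 22, 23),
                     rep(c("a", "b", "c"), each = 3))
  # mean ranks 2, 5, 8 with N = 9: H = 12/(N(N+1)) * sum(n_i rbar_i^2) - 3(N+1)
  H <- 12 / (9 * 10) * (3 * 4 + 3 * 25 + 3 * 64) - 3 * 10
  expect_equal(unname(st$statistic), H)
  expect_equal(H, 7.2)
  expect_true(st$significant)
  expect_true(all(c("a", "b", "c") %in%
                    c(st$pairwise$group1, st$pairwise$group2)))
})

test_that("Dunn pairs are gated by the omnibus test", {
  # three identical groups: H ~ 0, nothing significant
  st <- kruskal_dunn(rep(c(5, 6, 7), 3), rep(c("a", "b", "c"), each = 3))
  expect_false(st$significant)
  expect_false(any(st$pairwise$significant))
  # under the null, no pair may be declared significant when the omnibus
  # p exceeds alpha
  set.seed(63)
  for (rep in 1:50) {
    v <- rnorm(30)
    g <- rep(c("a", "b", "c"), each = 10)
    st <- kruskal_dunn(v, g)
    if (st$p > 0.05) expect_false(any(st$pairwise$significant))
  }
  expect_error(kruskal_dunn(1:3, c("a", "a", "a")), ">= 2 groups")
})

test_that("Spearman rho matches rank-then-Pearson and cor.test", {
  expect_equal(spearman_cor(1:10, 1:10)$rho, 1)
  expect_equal(spearman_cor(1:10, 10:1)$rho, -1)
  set.seed(64)
  x <- c(3.1, 5.2, 1.0, 4.4, 2.2)
  y <- c(10, 14, 9, 30, 11)
  st <- spearman_cor(x, y)
  expect_equal(st$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_equal(st$rho, unname(cor.test(x, y, method = "spearman")$estimate),
               tolerance = 1e-12)
  # t-approximation p value
  tt <- st$rho * sqrt(3 / (1 - st$rho^2))
  expect_equal(st$p, 2 * pt(-abs(tt), 3), tolerance = 1e-12)
  expect_error(spearman_cor(rep(1, 5), 1:5), "zero variance")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("univariate ANOVA reproduces a hand-computed balanced table", {
  # balanced 2x3 design, 2 replicates; partial F equals the classical
  # between-groups decomposition computed from explicit sums of squares
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2", "b3"),
                   rep = 1:2, KEEP.OUT.ATTRS = FALSE)
  d$y <- c(10, 14, 12, 16, 14, 18,
           11, 15, 13, 17, 15, 19) + c(0.5, -0.5)
  tab <- univariate_anova(d, "y", c("A", "B"), factors = c("A", "B"))
  # hand computation (balanced, no interaction term in the model)
  gm <- mean(d$y)
  ssA <- sum(tapply(d$y, d$A, function(v) length(v) * (mean(v) - gm)^2))
  ssB <- sum(tapply(d$y, d$B, function(v) length(v) * (mean(v) - gm)^2))
  fit_res <- d$y - (ave(d$y, d$A) + ave(d$y, d$B) - gm)
  sse <- sum(fit_res^2)
  dfe <- nrow(d) - 1 - 1 - 2
  expect_equal(tab$F[tab$variable == "A"], (ssA / 1) / (sse / dfe),
               tolerance = 1e-8)
  expect_equal(tab$F[tab$variable == "B"], (ssB / 2) / (sse / dfe),
               tolerance = 1e-8)
})

test_that("ANOVA recovers a planted single effect and flags aliasing", {
  set.seed(65)
  n <- 80
  d <- data.frame(height = runif(n, 5, 14),
                  grade = sample(1:5, n, TRUE),
                  mc = sample(c(TRUE, FALSE), n, TRUE))
  d$y <- 10 - 2 * d$height + rnorm(n, 0, 0.01)
  tab <- univariate_anova(d, "y", c("height", "grade", "mc"),
                          factors = c("grade", "mc"))
  expect_gt(tab$F[tab$variable == "height"], 1e4)
  expect_gt(min(tab$p[tab$variable != "height"]), 0.001)
  # aliased column: duplicate of height
  d$height2 <- d$height
  expect_error(univariate_anova(d, "y", c("height", "height2")),
               "rank-deficient")
  d$height2[1] <- NA
  expect_error(univariate_anova(d, "y", c("height", "height2")),
               "missing values")
})

test_that("one-sample t follows the textbook formula and conventions", {
  expect_equal(one_sample_t(c(3, 3, 3), mu0 = 3)$p, 1)
  st <- one_sample_t(c(-1, 0, 1), mu0 = 0)
  expect_equal(unname(st$statistic), 0)
  expect_equal(st$p, 1)
  set.seed(66)
  v <- rnorm(10, 0.3)
  st <- one_sample_t(v)
  tt <- mean(v) / (sd(v) / sqrt(10))
  expect_equal(unname(st$statistic), tt, tolerance = 1e-12)
  expect_equal(st$p, 2 * pt(-abs(tt), 9), tolerance = 1e-12)
  expect_warning(p0 <- one_sample_t(c(2, 2, 2), mu0 = 0)$p, "zero variance")
  expect_equal(p0, 0)
})

test_that("normality gate flags gross departures and skips bad sizes", {
  set.seed(67)
  two_point <- sample(c(0, 10), 300, replace = TRUE)
  g <- normality_gate(two_point)
  expect_true(g$non_normal)
  expect_error(normality_gate(rep(1, 10)), "constant")
  expect_warning(g2 <- normality_gate(c(1, 2)), "skipped")
  expect_true(is.na(g2$non_normal))
})

test_that("Modic grouping follows the combined-type rule", {
  expect_equal(mc_group("0", "0"), "MC0")
  expect_equal(mc_group("I", "0"), "MCI")
  expect_equal(mc_group("0", "II"), "MCII")
  expect_equal(mc_group("I/II", "0"), "MCI/II")
  expect_equal(mc_group("I", "II"), "MCI/II")
  expect_equal(mc_group("II", "I"), "MCI/II")
  expect_equal(mc_group(c("0", "II"), c("II", "II")), c("MCII", "MCII"))
  expect_warning(g <- mc_group("III", "0"), "type III")
  expect_equal(g, "MCIII")
})
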
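test_that("two-condition rm-ANOVA reduces to the squared paired t", {
  set.seed(4)
  d <- tidyr::expand_grid(id = factor(1:12), cond = factor(c("a", "b")))
  d$y <- rnorm(24) + as.numeric(d$cond == "b") * 0.6
  fit <- tidy(rm_anova(d, "y", "id", "cond"))
  wide <- tidyr::pivot_wider(d, names_from = "cond", values_from = "y")
  tt <- t.test(wide$a, wide$b, paired = TRUE)
  expect_equal(fit$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fit$p, tt$p.value, tolerance = 1e-10)
  expect_equal(fit$epsilon_gg, 1)
})

test_that("rm-ANOVA matches the aov error-strata oracle on small fixtures", {
  set.seed(10)
  # one factor, 4 participants x 3 levels
  d1 <- tidyr::expand_grid(id = factor(1:4), f1 = factor(1:3))
  d1$y <- round(rnorm(12, 10, 3), 1)
  mine <- tidy(rm_anova(d1, "y", "id", "f1"))
  orc <- aov_oracle(d1, "y", "id", "f1")
  expect_equal(mine$ss_effect, orc$f1$ss, tolerance = 1e-10)
  expect_equal(mine$ss_error, orc$f1$ss_err, tolerance = 1e-10)
  expect_equal(mine$F, orc$f1$F, tolerance = 1e-10)

  # three crossed factors, 5 participants x 2 x 3 x 2
  d3 <- tidyr::expand_grid(id = factor(1:5), a = factor(1:2),
                           b = factor(1:3), c = factor(1:2))
  d3$y <- round(rnorm(nrow(d3), 50, 10), 1)
  mine3 <- tidy(rm_anova(d3, "y", "id", c("a", "b", "c")))
  orc3 <- aov_oracle(d3, "y", "id", c("a", "b", "c"))
  for (eff in names(orc3)) {
    row <- mine3[mine3$effect == eff, ]
    expect_equal(row$ss_effect, orc3[[eff]]$ss, tolerance = 1e-8,
                 info = eff)
    expect_equal(row$ss_error, orc3[[eff]]$ss_err, tolerance = 1e-8,
                 info = eff)
    expect_equal(row$F, orc3[[eff]]$F, tolerance = 1e-8, info = eff)
    expect_equal(row$df_effect, orc3[[eff]]$df, info = eff)
  }
})

test_that("rm-ANOVA sum-of-squares decomposition is exact", {
  set.seed(77)
  for (i in 1:5) {
    d <- tidyr::expand_grid(id = factor(1:8), a = factor(1:3), b = factor(1:4))
    d$y <- rnorm(nrow(d), 100, 20)
    fit <- rm_anova(d, "y", "id", c("a", "b"))
    tab <- tidy(fit)
    g <- glance(fit)
    expect_equal(sum(tab$ss_effect) + sum(tab$ss_error) + g$ss_subject,
                 g$ss_total, tolerance = 1e-8 * g$ss_total)
    expect_true(all(tab$pes >= 0 & tab$pes <= 1))
    expect_true(all(tab$epsilon_gg <= 1 + 1e-12))
    expect_true(all(tab$epsilon_gg >= 1 / tab$df_effect - 1e-12))
  }
})

test_that("rm-ANOVA rejects incomplete or duplicated designs", {
  d <- tidyr::expand_grid(id = factor(1:4), f1 = factor(1:3))
  d$y <- rnorm(12)
  expect_error(rm_anova(d[-1, ], "y", "id", "f1"), "not complete")
  expect_error(rm_anova(rbind(d, d[1, ]), "y", "id", "f1"), "more than one")
})

test_that("Greenhouse-Geisser epsilon has its closed-form landmarks", {
  # compound symmetry is spherical: epsilon 1
  cs <- diag(4) * 3 + matrix(1.5, 4, 4)
  expect_equal(gg_epsilon(cs), 1)
  # two conditions leave a single contrast: epsilon 1 by construction
  expect_equal(gg_epsilon(matrix(c(2, .3, .3, 1), 2)), 1)
  # eigenvalues (4,1,1) on 3 contrasts: (4+1+1)^2 / (3 * 18) = 2/3
  C <- t(stats::contr.poly(4))
  S <- t(C) %*% diag(c(4, 1, 1)) %*% C
  expect_equal(gg_epsilon(S, C), 2 / 3, tolerance = 1e-12)
  expect_error(gg_epsilon(matrix(c(1, 2, 0, 1), 2)), "symmetric")
  expect_error(gg_epsilon(t(C) %*% diag(c(-4, 1, 1)) %*% C), "semi-definite")
})

test_that("epsilon is invariant to orthonormal rotation of the contrast basis", {
  set.seed(6)
  for (i in 1:10) {
    k <- sample(3:6, 1)
    X <- matrix(rnorm(20 * k), 20, k)
    S <- crossprod(X) / 19
    C <- t(stats::contr.poly(k))
    Q <- qr.Q(qr(matrix(rnorm((k - 1)^2), k - 1)))
    expect_equal(gg_epsilon(S, C), gg_epsilon(S, Q %*% C), tolerance = 1e-10)
  }
})

test_that("epsilon from rm_anova matches the classic Box formula", {
  set.seed(31)
  d <- tidyr::expand_grid(id = factor(1:15), f1 = factor(1:4))
  d$y <- rnorm(60) + rep(rnorm(15), each = 4) +
    as.numeric(d$f1) * rep(rnorm(15), each = 4)  # sphericity violation
  fit <- tidy(rm_anova(d, "y", "id", "f1"))
  wide <- as.matrix(tidyr::pivot_wider(d, names_from = "f1",
                                       values_from = "y")[, -1])
  S <- cov(wide)
  k <- ncol(S)
  sbar <- mean(diag(S)); m <- mean(S)
  rowm <- rowMeans(S)
  eps_box <- (k * (sbar - m))^2 /
    ((k - 1) * (sum(S^2) - 2 * k * sum(rowm^2) + k^2 * m^2))
  expect_equal(fit$epsilon_gg, eps_box, tolerance = 1e-10)
})

test_that("Friedman test matches hand-ranked landmarks", {
  # identical columns: statistic zero
  d <- tidyr::expand_grid(id = factor(1:6), cond = factor(1:4))
  d$y <- rep(rnorm(6), each = 4)
  expect_equal(friedman_test(d, "y", "id", "cond")$statistic, 0)
  # perfect ordering, 3 x 3: rank sums (3, 6, 9) give chi-square 6, df 2
  d2 <- tidyr::expand_grid(id = factor(1:3), cond = factor(1:3))
  d2$y <- as.numeric(d2$cond) + rnorm(9, 0, 1e-6)
  res <- friedman_test(d2, "y", "id", "cond")
  expect_equal(res$statistic, 6)
  expect_equal(res$df, 2)
  expect_error(friedman_test(d[d$cond %in% 1:2, ], "y", "id", "cond"),
               "at least 3")
})

test_that("Wilcoxon signed-rank statistic is the smaller tied-rank sum", {
  # |diffs| 1, 2, 3, 1.5 -> ranks 1, 3, 4, 2; negative sum = 2
  res <- wilcoxon_signed_rank(c(1, 2, 3, -1.5))
  expect_equal(res$statistic, 2)
  # brute-force oracle on random vectors with ties and zeros
  set.seed(14)
  for (i in 1:15) {
    d <- round(rnorm(12, 0.3), 1)
    nz <- d[d != 0]
    r <- rank(abs(nz))
    oracle <- min(sum(r[nz > 0]), sum(r[nz < 0]))
    res <- wilcoxon_signed_rank(d)
    expect_equal(res$statistic, oracle)
    # sign flip leaves the statistic unchanged
    expect_equal(wilcoxon_signed_rank(-d)$statistic, oracle)
    # p agrees with the tie-corrected continuity-corrected normal approx
    expect_equal(res$p, suppressWarnings(
      wilcox.test(nz, exact = FALSE, correct = TRUE)$p.value))
  }
  expect_error(wilcoxon_signed_rank(rep(0, 5)), "zero")
})

test_that("Cousineau-Morey standard errors remove participant offsets", {
  # additive participant offsets only: within-participant SEs are zero
  d <- tidyr::expand_grid(id = factor(1:6), cond = factor(1:3))
  d$y <- rep(c(10, 20, 30), 6) + rep(rnorm(6, 0, 5), each = 3)
  se <- cousineau_morey_se(d, "y", "id", "cond")
  expect_equal(se$se, rep(0, 3), tolerance = 1e-12)

  # random fixture vs a manual two-step oracle
  set.seed(2)
  d$y <- rnorm(18)
  se2 <- cousineau_morey_se(d, "y", "id", "cond")
  wide <- as.matrix(tidyr::pivot_wider(d, names_from = "cond",
                                       values_from = "y")[, -1])
  centred <- wide - rowMeans(wide) + mean(wide)
  M <- ncol(wide)
  oracle <- sqrt(M / (M - 1)) * apply(centred, 2, sd) / sqrt(nrow(wide))
  expect_equal(se2$se, unname(oracle), tolerance = 1e-12)

  # two conditions: inflation factor sqrt(2) relative to the centred sd
  d2 <- tidyr::expand_grid(id = factor(1:5), cond = factor(1:2))
  set.seed(3); d2$y <- rnorm(10)
  se3 <- cousineau_morey_se(d2, "y", "id", "cond")
  w2 <- as.matrix(tidyr::pivot_wider(d2, names_from = "cond",
                                     values_from = "y")[, -1])
  c2 <- w2 - rowMeans(w2) + mean(w2)
  expect_equal(se3$se, unname(sqrt(2) * apply(c2, 2, sd) / sqrt(5)),
               tolerance = 1e-12)
})

test_that("t-based confidence intervals have the closed form", {
  ci <- ci_mean(c(1, 2, 3, 4))
  half <- qt(0.975, 3) * sd(1:4) / 2
  expect_equal(ci$mean, 2.5)
  expect_equal(ci$lo, 2.5 - half)
  expect_equal(ci$hi, 2.5 + half)
  expect_equal(round(ci$lo, 4), 0.4457)
  # constant input collapses to a zero-width interval
  ci0 <- ci_mean(rep(7, 6))
  expect_equal(ci0$lo, 7)
  expect_equal(ci0$hi, 7)
})
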
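test_that("Shapiro-Wilk wrapper validates input and keeps its size", {
  expect_error(shapiro_wilk(c(1, 2)), "at least 3")
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  set.seed(1)
  rej <- mean(replicate(1000, shapiro_wilk(rnorm(50))$p < 0.05))
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
  pow <- mean(replicate(200, shapiro_wilk(rexp(50))$p < 0.01))
  expect_gte(pow, 0.95)
})

test_that("Levene's test matches hand-computed sums of squares", {
  # toy 2-group example, worked by hand: groups {0,2,4}, {0,6,12}
  v <- c(0, 2, 4, 0, 6, 12); g <- rep(c("a", "b"), each = 3)
  # |dev from group mean|: {2,0,2}, {6,0,6} -> z-means 4/3 and 4
  # SSB = 3*((4/3-8/3)^2 + (4-8/3)^2) = 32/3
  # SSW = (8/3) + 24 = 80/3;  F = (32/3) / (80/3 / 4) = 1.6
  res <- levene_test(v, g)
  expect_equal(res$F, 1.6, tolerance = 1e-10)
  expect_equal(res$df1, 1); expect_equal(res$df2, 4)
  expect_equal(res$p, pf(1.6, 1, 4, lower.tail = FALSE), tolerance = 1e-10)
  # identical groups: no variance heterogeneity at all
  same <- levene_test(rep(c(1, 2, 3), 2), g)
  expect_equal(same$F, 0); expect_equal(same$p, 1)
  # agreement with the car implementation (center = mean)
  skip_if_not_installed("car")
  set.seed(4)
  v2 <- rnorm(60); g2 <- rep(letters[1:3], each = 20)
  ours <- levene_test(v2, g2)
  theirs <- car::leveneTest(v2, factor(g2), center = mean)
  expect_equal(ours$F, theirs$`F value`[1], tolerance = 1e-10)
  expect_equal(ours$p, theirs$`Pr(>F)`[1], tolerance = 1e-10)
  # power: SD ratio 4, n = 30 per group
  hits <- mean(replicate(100, {
    levene_test(c(rnorm(30, sd = 1), rnorm(30, sd = 4)),
                rep(1:2, each = 30))$p < 0.05
  }))
  expect_gte(hits, 0.9)
})

test_that("Greenhouse-Geisser epsilon has its closed-form limits", {
  for (k in c(3, 5)) {
    S_cs <- diag(k) * 3 + 2            # compound symmetry
    expect_equal(gg_epsilon(S_cs), 1, tolerance = 1e-12)
    v <- seq_len(k) - mean(seq_len(k)) # rank-1 centred deviation
    expect_equal(gg_epsilon(v %o% v), 1 / (k - 1), tolerance = 1e-12)
  }
  # random covariance vs an independent eigen-decomposition oracle
  set.seed(8)
  for (r in 1:5) {
    A <- matrix(rnorm(25), 5)
    S <- crossprod(A)
    J <- diag(5) - 1 / 5
    lam <- eigen(J %*% S %*% J, symmetric = TRUE)$values
    oracle <- sum(lam)^2 / (4 * sum(lam^2))
    expect_equal(gg_epsilon(S), oracle, tolerance = 1e-10)
  }
})

test_that("Mauchly's test agrees with the base-R implementation", {
  expect_equal(mauchly(diag(2), n = 10)$p, 1)   # k = 2: automatic
  expect_equal(mauchly(diag(2), n = 10)$W, 1)
  set.seed(9)
  X <- matrix(rnorm(12 * 4), 12, 4) %*% matrix(rnorm(16), 4)
  ours <- mauchly(cov(X), n = 12)
  base <- stats::mauchly.test(lm(X ~ 1), X = ~1)
  expect_equal(ours$W, unname(base$statistic), tolerance = 1e-10)
  # base R adds a higher-order term to the chi-square approximation;
  # agreement is to a few thousandths in p
  expect_lt(abs(ours$p - base$p.value), 0.005)
  # type-I error under sphericity, power under strong violation
  rej_null <- mean(replicate(300, {
    Y <- matrix(rnorm(12 * 4), 12, 4)
    mauchly(cov(Y), n = 12)$p < 0.05
  }))
  expect_gt(rej_null, 0.02); expect_lt(rej_null, 0.1)
  rej_alt <- mean(replicate(100, {
    Y <- cbind(rnorm(12, sd = 0.2), rnorm(12, sd = 1), rnorm(12, sd = 3),
               z <- rnorm(12, sd = 5))
    mauchly(cov(Y), n = 12)$p < 0.05
  }))
  expect_gte(rej_alt, 0.9)
})

test_that("rm_anova3 matches the brute-force decomposition and aov", {
  set.seed(14)
  n <- 5
  y <- array(rnorm(n * 2 * 5 * 5), dim = c(n, 2, 5, 5)) +
    rnorm(n) +                              # subject effects
    rep(rnorm(5), each = n * 2 * 5)         # band effects
  tab <- table_from_array(y)
  fit <- rm_anova3(tab)
  ss <- brute_rm_anova3(y)
  eff_map <- list(hemisphere = c("A", "SA"), state = c("B", "SB"),
                  band = c("C", "SC"),
                  `hemisphere:state` = c("AB", "SAB"),
                  `hemisphere:band` = c("AC", "SAC"),
                  `state:band` = c("BC", "SBC"),
                  `hemisphere:state:band` = c("ABC", "SABC"))
  for (nm in names(eff_map)) {
    row <- fit[fit$effect == nm, ]
    expect_equal(row$SS_effect, ss[[eff_map[[nm]][1]]], tolerance = 1e-8)
    expect_equal(row$SS_error, ss[[eff_map[[nm]][2]]], tolerance = 1e-8)
    # partial eta squared identity holds exactly
    expect_identical(row$partial_eta_sq,
                     row$SS_effect / (row$SS_effect + row$SS_error))
    expect_true(row$epsilon >= 1 / row$df_num - 1e-12 &&
                  row$epsilon <= 1 + 1e-12)
  }
  # df pattern: effect df = prod(levels - 1), error df = effect df * (n-1)
  expect_equal(fit$df_num, c(1, 4, 4, 4, 4, 16, 16))
  expect_equal(fit$df_den, fit$df_num * (n - 1))
  # cross-check F against stats::aov Error() strata
  d <- tab
  d$S <- factor(d$subject); d$A <- factor(d$hemisphere)
  d$B <- factor(d$state); d$C <- factor(d$band)
  a <- summary(aov(log_power ~ A * B * C + Error(S / (A * B * C)),
                   data = d))
  expect_equal(fit$F[fit$effect == "band"],
               a[["Error: S:C"]][[1]]$`F value`[1], tolerance = 1e-8)
  expect_equal(fit$F[fit$effect == "state:band"],
               a[["Error: S:B:C"]][[1]]$`F value`[1], tolerance = 1e-8)
})

test_that("constant tables give zero SS and flagged undefined F", {
  y <- array(3.7, dim = c(4, 2, 5, 5))
  fit <- rm_anova3(table_from_array(y))
  expect_true(all(fit$SS_effect == 0))
  expect_true(all(is.nan(fit$F)))
  expect_true(attr(fit, "zero_variance"))
})

test_that("an induced state x band interaction is detected and localised", {
  hits_int <- 0; hits_simple <- 0
  n_rep <- 5
  for (seed in seq_len(n_rep)) {
    set.seed(seed)
    y <- array(rnorm(12 * 2 * 5 * 5, sd = 0.3), dim = c(12, 2, 5, 5)) +
      rnorm(12, sd = 0.5)
    y[, , 5, 4] <- y[, , 5, 4] + 0.5     # band D boosted in state S80
    tab <- table_from_array(y)
    fit <- rm_anova3(tab)
    p_int <- fit$p_GG[fit$effect == "state:band"]
    hits_int <- hits_int + (p_int < 0.05)
    se <- simple_effects(tab, factor = "band", within = "state")
    p80 <- se$p[se$level == "S80"]
    p_ai <- se$p[se$level == "AI"]
    hits_simple <- hits_simple + (p80 < 0.05 && p_ai > 0.05)
  }
  expect_equal(hits_int, n_rep)
  expect_gte(hits_simple, n_rep - 1)
  # incomplete slice errors
  tab2 <- table_from_array(array(rnorm(4 * 2 * 5 * 5), c(4, 2, 5, 5)))
  tab2 <- tab2[!(tab2$state == "S80" & tab2$band == "D"), ]
  expect_error(simple_effects(tab2, "band", "state"), "incomplete|missing")
})

test_that("LSD post hocs reproduce hand-computed paired statistics", {
  # n = 3 subjects, 2 levels: values chosen for clean arithmetic
  tab <- data.frame(subject = rep(c("s1", "s2", "s3"), each = 2),
                    hemisphere = "L", state = rep(c("AI", "AT"), 3),
                    band = "A",
                    log_power = c(1, 3, 2, 5, 3, 7))
  # level means: AI 2, AT 5; diff -3
  # one-way RM error SS: interaction residuals -> MSE and t by hand:
  # y - subj mean - level mean + grand: AI resids (0.5, 0, -0.5),
  # AT (-0.5, 0, 0.5); SS_err = 1, df = 2, MSE = 0.5
  # t = -3 / sqrt(2 * 0.5 / 3) = -3 / sqrt(1/3) = -5.196152
  cmp <- lsd_posthoc(tab, "state")
  expect_equal(nrow(cmp), 1)
  expect_equal(cmp$mean_diff, -3, tolerance = 1e-10)
  expect_equal(cmp$t, -3 / sqrt(1 / 3), tolerance = 1e-10)
  expect_equal(cmp$df, 2)
  expect_equal(cmp$p, 2 * pt(-abs(cmp$t), 2), tolerance = 1e-10)

  # equal means give t = 0, p = 1
  tab0 <- tab; tab0$log_power <- rep(c(1, 2, 3), each = 2)
  cmp0 <- lsd_posthoc(tab0, "state")
  expect_equal(cmp0$t, 0); expect_equal(cmp0$p, 1)

  # |mean difference| ranks match |t| ranks (common denominator)
  set.seed(6)
  y <- array(rnorm(6 * 2 * 5 * 5), dim = c(6, 2, 5, 5))
  cmpb <- lsd_posthoc(table_from_array(y), "band")
  expect_equal(order(abs(cmpb$mean_diff)), order(abs(cmpb$t)))
  # symmetry: p depends only on the unordered pair
  expect_equal(cmpb$p, 2 * pt(-abs(cmpb$t), cmpb$df))
})

test_that("assumption checks cover every cell and pool across cells", {
  set.seed(30)
  y <- array(rnorm(12 * 2 * 5 * 5), dim = c(12, 2, 5, 5))
  chk <- check_assumptions(table_from_array(y))
  expect_equal(nrow(chk$shapiro), 50)
  expect_false(anyNA(chk$shapiro$W))
  expect_true(chk$levene$p > 0 && chk$levene$p <= 1)
  expect_equal(chk$levene$df1, 49)
})
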
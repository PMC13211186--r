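# Statistical pipeline: fixed fixtures against an independent reference
# implementation, hand-computed examples, algebraic identities and
# simulation-based calibration.

test_that("Shapiro-Wilk matches the reference implementation on a fixture", {
  x <- c(62.1, 58.3, 71.0, 64.5, 66.2, 59.8, 70.4, 63.3, 61.7, 68.9)
  r <- shapiro_wilk(x)
  expect_equal(r$statistic, 0.9476496988545547, tolerance = 1e-6)
  expect_equal(r$p_value, 0.6407834759040719, tolerance = 1e-6)
  expect_true(r$statistic > 0 && r$statistic <= 1)

  # affine invariance of W
  r2 <- shapiro_wilk(3.7 * x - 120)
  expect_equal(r2$statistic, r$statistic, tolerance = 1e-9)

  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rep(5, 10)), "identical")
})

test_that("Levene's test matches the reference implementation on a fixture", {
  g <- list(c(18.2, 21.5, 19.8, 23.1), c(24.9, 26.3, 22.8, 28.4),
            c(15.1, 19.7, 17.4, 16.8))
  r <- levene(g)
  expect_equal(r$statistic, 0.18173598553345452, tolerance = 1e-6)
  expect_equal(r$p_value, 0.8368067522779867, tolerance = 1e-6)
  rm_med <- levene(g, center = "median")
  expect_equal(rm_med$statistic, 0.18026905829596476, tolerance = 1e-6)

  # cross-check against car::leveneTest on the same fixture
  y <- unlist(g)
  grp <- factor(rep(seq_along(g), lengths(g)))
  cc <- car::leveneTest(y, grp, center = mean)
  expect_equal(r$statistic, cc$`F value`[1], tolerance = 1e-9)
  expect_equal(r$p_value, cc$`Pr(>F)`[1], tolerance = 1e-9)

  # degenerate case: all absolute deviations equal
  r0 <- levene(list(c(1, 3), c(2, 4)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # exchangeability within groups
  g2 <- lapply(g, function(v) ivmorph:::with_seed(1, sample(v)))
  expect_equal(levene(g2)$statistic, r$statistic, tolerance = 1e-12)

  expect_error(levene(list(c(1, 2))), ">= 2 groups")
  expect_error(levene(list(c(1, 2), 3)), "n >= 2")
})

test_that("paired t reproduces the hand-computed fixture", {
  r <- paired_t(c(1, 2, 3), c(2, 4, 5))  # diffs 1, 2, 2
  expect_equal(r$statistic, 5.0, tolerance = 1e-9)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 0.03774955135062371, tolerance = 1e-9)

  same <- paired_t(c(3, 4, 5), c(3, 4, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  rev <- paired_t(c(2, 4, 5), c(1, 2, 3))
  expect_equal(rev$statistic, -r$statistic, tolerance = 1e-12)
  expect_equal(rev$p_value, r$p_value, tolerance = 1e-12)
  expect_error(paired_t(1:3, 1:4), "length mismatch")
})

test_that("unpaired t reproduces the hand-computed fixture", {
  r <- unpaired_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(r$statistic), 3.674234614174767, tolerance = 1e-9)
  expect_equal(r$df, 4)

  same <- unpaired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  swap <- unpaired_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swap$statistic, -r$statistic, tolerance = 1e-12)
  expect_error(unpaired_t(c(2, 2), c(3, 3)), "infinite t")
  expect_equal(unpaired_t(c(2, 2), c(2, 2))$statistic, 0)
})

test_that("one-way ANOVA matches a hand decomposition", {
  a <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(a$ss_between, 6, tolerance = 1e-12)
  expect_equal(a$ss_within, 6, tolerance = 1e-12)
  expect_equal(a$df_between, 2)
  expect_equal(a$df_within, 6)
  expect_equal(a$F, 3.0, tolerance = 1e-12)
  expect_equal(a$p_value, 0.125, tolerance = 1e-9)

  # independent decomposition oracle on a random fixture
  g <- ivmorph:::with_seed(2, lapply(c(4, 6, 5), function(n) rnorm(n, 0, 2)))
  a2 <- one_way_anova(g)
  y <- unlist(g)
  ssb <- sum(lengths(g) * (vapply(g, mean, numeric(1)) - mean(y))^2)
  ssw <- sum(unlist(lapply(g, function(v) (v - mean(v))^2)))
  expect_equal(a2$ss_between, ssb, tolerance = 1e-9)
  expect_equal(a2$ss_within, ssw, tolerance = 1e-9)
  expect_equal(a2$ss_between + a2$ss_within,
               sum((y - mean(y))^2), tolerance = 1e-9)

  expect_error(one_way_anova(list(rep(1, 3), rep(1, 4))), "identical")
})

test_that("two-group ANOVA F equals the squared unpaired t", {
  a <- c(12.5, 14.1, 13.3); b <- c(15.0, 16.2, 15.8)
  av <- one_way_anova(list(a, b))
  tt <- unpaired_t(a, b)
  expect_equal(av$F, tt$statistic^2, tolerance = 1e-9)
  expect_equal(av$p_value, tt$p_value, tolerance = 1e-9)
})

test_that("the null distribution of F has the expected mean", {
  fs <- vapply(1:1000, function(s) {
    g <- ivmorph:::with_seed(1000 + s,
                             lapply(1:3, function(i) rnorm(50)))
    one_way_anova(g)$F
  }, numeric(1))
  expect_lt(abs(mean(fs) - 1), 0.1)
})

test_that("LSD post hoc uses the pooled error and the significance gate", {
  # means 2 vs 4, MSE = 1, n = 3 each, within df = 6 -> |t| = 2.449
  g1 <- c(1, 2, 3); g2 <- c(3, 4, 5); g3 <- c(2, 3, 4)
  av <- one_way_anova(list(a = g1, b = g2, c = g3))
  expect_equal(av$ms_within, 1, tolerance = 1e-12)
  lsd <- lsd_posthoc(av, alpha = 0.05)
  ab <- lsd[lsd$group_i == "a" & lsd$group_j == "b", ]
  expect_equal(ab$t, -2.449489742783178, tolerance = 1e-9)
  expect_equal(ab$df, 6)
  # ANOVA p = 0.125 >= alpha: pairs emitted but gated
  expect_true(all(lsd$gated))
  expect_false(any(lsd$significant))

  # with two groups LSD equals the pooled unpaired t
  av2 <- one_way_anova(list(a = c(1, 2, 3), b = c(6, 7, 9)))
  lsd2 <- lsd_posthoc(av2)
  tt <- unpaired_t(c(1, 2, 3), c(6, 7, 9))
  expect_equal(lsd2$t, tt$statistic, tolerance = 1e-9)
  expect_equal(lsd2$p_value, tt$p_value, tolerance = 1e-9)
  expect_false(lsd2$gated[1])

  # cross-check t and p against emmeans pairwise contrasts (no adjustment)
  y <- c(g1, g2, g3)
  grp <- factor(rep(c("a", "b", "c"), each = 3))
  fit <- stats::lm(y ~ grp)
  em <- as.data.frame(emmeans::contrast(emmeans::emmeans(fit, "grp"),
                                        "pairwise", adjust = "none"))
  expect_equal(sort(abs(lsd$t)), sort(abs(em$t.ratio)), tolerance = 1e-9)
  expect_equal(sort(lsd$p_value), sort(em$p.value), tolerance = 1e-9)
})

test_that("negating the data negates t statistics and preserves p", {
  a <- c(10.2, 11.5, 9.8); b <- c(12.0, 13.1, 12.4)
  r1 <- unpaired_t(a, b); r2 <- unpaired_t(-a, -b)
  expect_equal(r2$statistic, -r1$statistic, tolerance = 1e-12)
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-12)
  p1 <- paired_t(a, b); p2 <- paired_t(-a, -b)
  expect_equal(p2$statistic, -p1$statistic, tolerance = 1e-12)
  expect_equal(p2$p_value, p1$p_value, tolerance = 1e-12)
})

test_that("run_analysis picks the branch by group count", {
  mk_dishes <- function(groups, shift = 0) {
    do.call(rbind, lapply(seq_along(groups), function(i) {
      data.frame(dish_id = paste0(groups[i], "_d", 1:3), group = groups[i],
                 n_oocytes = 30,
                 mean_delta_um = c(10.1, 11.8, 9.4) + (i - 1) * shift,
                 gvbd_rate_percent = c(70, 76.7, 73.3) - (i - 1) * shift)
    }))
  }
  two <- run_analysis(mk_dishes(c("ctrl", "DHP"), shift = 5))
  expect_equal(two$mean_delta_um$omnibus$test, "unpaired_t")
  expect_null(two$mean_delta_um$posthoc)

  six <- run_analysis(mk_dishes(paste0("g", 1:6), shift = 3))
  expect_s3_class(six$mean_delta_um$omnibus, "ivm_anova")
  expect_equal(nrow(six$mean_delta_um$posthoc), 15)  # C(6, 2)

  short <- mk_dishes(c("a", "b"))[-(1:2), ]
  expect_error(run_analysis(short), "< 2 dishes: a")
})

test_that("a 3x-SD group shift is detected in most simulated experiments", {
  # dish-level Delta with a true shift of 3 SD in one of three groups,
  # n = 3 dishes per group
  rejections <- vapply(1:500, function(s) {
    g <- ivmorph:::with_seed(20000 + s, list(rnorm(3, 10, 2), rnorm(3, 10, 2),
                                             rnorm(3, 16, 2)))
    one_way_anova(g)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.8)
})
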
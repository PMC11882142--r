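rm_long <- function(Y, within = "level") {
  d <- expand.grid(subject = paste0("s", seq_len(nrow(Y))),
                   level = paste0("l", seq_len(ncol(Y))))
  d$y <- as.vector(Y)
  names(d)[2] <- within
  d
}

test_that("one-way RM ANOVA: degenerate, textbook and two-level identities", {
  # all levels identical per subject -> F = 0
  Y <- matrix(rep(c(1, 2, 3, 4), 3), 4, 3)
  tab <- one_way_rm_anova(rm_long(Y), "y", "subject", "level")
  expect_equal(tab$F, 0)

  # 4-subject x 3-level table vs brute-force sum-of-squares decomposition
  Y <- matrix(c(30, 14, 24, 38,
                28, 18, 20, 34,
                16, 10, 18, 20), 4, 3)
  tab <- one_way_rm_anova(rm_long(Y), "y", "subject", "level")
  grand <- mean(Y)
  ss_level <- nrow(Y) * sum((colMeans(Y) - grand)^2)
  ss_err <- sum((Y - outer(rowMeans(Y), rep(1, 3)) -
                   outer(rep(1, 4), colMeans(Y)) + grand)^2)
  F_oracle <- (ss_level / 2) / (ss_err / 6)
  expect_equal(tab$F, F_oracle, tolerance = 1e-12)
  expect_equal(tab$df_num, 2)
  expect_equal(tab$df_den, 6)
  expect_equal(tab$ss, ss_level, tolerance = 1e-10)

  # two levels: F equals the squared paired t statistic
  set.seed(30)
  Y <- matrix(rnorm(16), 8, 2)
  tab2 <- one_way_rm_anova(rm_long(Y), "y", "subject", "level")
  tt <- t.test(Y[, 1], Y[, 2], paired = TRUE)
  expect_equal(tab2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(tab2$p, tt$p.value, tolerance = 1e-10)
})

test_that("one-way RM ANOVA matches the aov split-plot stratum", {
  set.seed(31)
  d <- expand.grid(subject = paste0("s", 1:8), session = paste0("P", 1:4))
  d$y <- rnorm(nrow(d)) + as.integer(d$session) * 0.5 + rep(rnorm(8), 4)
  tab <- one_way_rm_anova(d, "y", "subject", "session")
  a <- summary(aov(y ~ session + Error(subject / session), data = d))
  stratum <- a[["Error: subject:session"]][[1]]
  expect_equal(tab$F, stratum[["F value"]][1], tolerance = 1e-10)
  expect_equal(tab$p_uncorrected, stratum[["Pr(>F)"]][1], tolerance = 1e-10)
  expect_equal(tab$ss, stratum[["Sum Sq"]][1], tolerance = 1e-8)
})

test_that("mixed ANOVA (1 between x 1 within) matches car::Anova Type III", {
  library(car)
  set.seed(32)
  d <- expand.grid(subject = paste0("s", 1:9), session = paste0("P", 1:5))
  d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= 4, "g1", "g2")
  d$y <- rnorm(nrow(d)) + (d$group == "g2") + as.integer(d$session) * 0.3
  tab <- mixed_anova(d, "y", "subject", within = "session", between = "group")

  wide <- reshape(d, idvar = c("subject", "group"), timevar = "session",
                  direction = "wide")
  mod <- lm(as.matrix(wide[, paste0("y.P", 1:5)]) ~ group, data = wide,
            contrasts = list(group = "contr.sum"))
  av <- summary(Anova(mod, idata = data.frame(session = factor(paste0("P", 1:5))),
                      idesign = ~session, type = 3), multivariate = FALSE)
  ref <- av$univariate.tests
  for (eff in c("group", "session", "group:session")) {
    expect_equal(tab$F[tab$effect == eff], ref[eff, "F value"],
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(tab$p_uncorrected[tab$effect == eff], ref[eff, "Pr(>F)"],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_equal(tab$gg_epsilon[tab$effect == "session"],
               unname(av$pval.adjustments["session", "GG eps"]),
               tolerance = 1e-10)
  expect_equal(tab$mauchly_p[tab$effect == "session"],
               unname(av$sphericity.tests["session", "p-value"]),
               tolerance = 0.01)
})

test_that("mixed ANOVA with two within factors matches car::Anova Type III", {
  library(car)
  set.seed(33)
  d <- expand.grid(subject = paste0("s", 1:8), path = c("ht", "lt"),
                   session = paste0("P", 1:3))
  d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= 3, "g1", "g2")
  d$y <- rnorm(nrow(d)) + (d$path == "ht") * 0.8 +
    as.integer(d$session) * 0.2 + (d$group == "g2") * 0.5
  tab <- mixed_anova(d, "y", "subject", within = c("path", "session"),
                     between = "group")

  d$cell <- paste(d$path, d$session, sep = ".")
  wide <- reshape(d[, c("subject", "group", "cell", "y")],
                  idvar = c("subject", "group"), timevar = "cell",
                  direction = "wide")
  cells <- expand.grid(session = paste0("P", 1:3), path = c("ht", "lt"))
  cells <- cells[order(cells$path, cells$session), ]
  ycols <- paste0("y.", cells$path, ".", cells$session)
  mod <- lm(as.matrix(wide[, ycols]) ~ group, data = wide,
            contrasts = list(group = "contr.sum"))
  idata <- data.frame(path = factor(cells$path),
                      session = factor(cells$session))
  av <- summary(Anova(mod, idata = idata, idesign = ~ path * session,
                      type = 3), multivariate = FALSE)
  ref <- av$univariate.tests
  pairs <- c(group = "group", path = "path", session = "session",
             "path:session" = "path:session",
             "group:path" = "group:path", "group:session" = "group:session",
             "group:path:session" = "group:path:session")
  for (eff in names(pairs)) {
    expect_equal(tab$F[tab$effect == eff], ref[pairs[eff], "F value"],
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("Greenhouse-Geisser correction is bounded and only reduces significance", {
  set.seed(34)
  for (rep in 1:10) {
    k <- sample(3:5, 1)
    Y <- matrix(rnorm(7 * k), 7, k)
    Y[, 1] <- Y[, 1] * 3   # break sphericity sometimes
    tab <- one_way_rm_anova(rm_long(Y), "y", "subject", "level",
                            sphericity_alpha = 1)  # always apply
    expect_gte(tab$gg_epsilon, 1 / (k - 1))
    expect_lte(tab$gg_epsilon, 1)
    expect_lte(tab$df_num_corr, tab$df_num)
    # shrinking both dfs is conservative in the significance region
    if (tab$p_uncorrected <= 0.2) expect_gte(tab$p, tab$p_uncorrected)
  }
})

test_that("Mauchly p-values agree with stats::mauchly.test", {
  set.seed(35)
  Y <- matrix(rnorm(40), 8, 5)
  tab <- one_way_rm_anova(rm_long(Y), "y", "subject", "level")
  mod <- lm(Y ~ 1)
  ref <- mauchly.test(mod, X = ~1,
                      M = ~level, idata = data.frame(level = factor(1:5)))
  expect_equal(tab$mauchly_p, ref$p.value, tolerance = 0.01)
})

test_that("incomplete designs and doubly-assigned subjects are rejected", {
  d <- expand.grid(subject = paste0("s", 1:4), level = paste0("l", 1:3))
  d$y <- rnorm(12)
  expect_error(one_way_rm_anova(d[-1, ], "y", "subject", "level"), "complete")
  d$group <- ifelse(d$level == "l1", "a", "b")  # subjects straddle groups
  expect_error(mixed_anova(d, "y", "subject", "level", between = "group"),
               "more than one group")
})

test_that("Tukey follow-up matches TukeyHSD-style studentized-range p-values", {
  set.seed(36)
  Y <- matrix(rnorm(24), 8, 3)
  Y[, 3] <- Y[, 3] + 2
  out <- tukey_rm(rm_long(Y), "y", "subject", "level")
  expect_equal(nrow(out), 3)
  # oracle: direct q statistic from the RM error term
  n <- 8
  ms_e <- sum((Y - outer(rowMeans(Y), rep(1, 3)) -
                 outer(rep(1, n), colMeans(Y)) + mean(Y))^2) / (2 * (n - 1))
  q13 <- abs(mean(Y[, 3]) - mean(Y[, 1])) / sqrt(ms_e / n)
  i <- out$level_1 == "l1" & out$level_2 == "l3"
  expect_equal(out$q[i], q13, tolerance = 1e-10)
  expect_equal(out$p_adj[i],
               ptukey(q13, nmeans = 3, df = 14, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(out$p_adj[i], 0.05)
})

test_that("basic tests match closed forms and enumeration", {
  # KS on identical samples
  x <- c(1.2, 3.4, 5.6, 7.8)
  expect_equal(ks_test_2s(x, x)$statistic, 0)

  # chi-square closed form, no continuity correction
  tab <- rbind(c(10, 4), c(5, 13))
  n <- sum(tab)
  closed <- n * (10 * 13 - 4 * 5)^2 / (14 * 18 * 15 * 17)
  expect_equal(chisq_2x2(tab)$statistic, closed, tolerance = 1e-12)

  # exact binomial p by enumeration of tail probabilities
  probs <- dbinom(0:10, 10, 0.5)
  p_enum <- sum(probs[probs <= dbinom(7, 10, 0.5) + 1e-12])
  expect_equal(binom_test_exact(7, 10, 0.5)$p, p_enum, tolerance = 1e-12)

  # unpaired t equals the closed form for Student's t
  set.seed(37)
  a <- rnorm(10); b <- rnorm(12, 1)
  got <- unpaired_t_test(a, b)
  sp2 <- ((9 * var(a) + 11 * var(b)) / 20)
  t_closed <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 10 + 1 / 12))
  expect_equal(got$statistic, t_closed, tolerance = 1e-12)
  expect_equal(got$df, 20)

  expect_error(unpaired_t_test(rep(1, 5), rep(2, 5)), "zero variance")
  expect_error(pearson_cor_test(rep(1, 5), rnorm(5)), "zero-variance")
  r <- pearson_cor_test(a, a * 2 + rnorm(10, 0, 0.1))
  expect_gt(r$statistic, 0.9)
})

test_that("under Gaussian null data the RM ANOVA F test keeps its size", {
  set.seed(38)
  n_rep <- 1500
  p_vals <- replicate(n_rep, {
    Y <- matrix(rnorm(18), 6, 3)
    one_way_rm_anova(rm_long(Y), "y", "subject", "level")$p_uncorrected
  })
  rate <- mean(p_vals < 0.05)
  se2 <- 2 * sqrt(0.05 * 0.95 / n_rep)
  expect_gt(rate, 0.05 - se2)
  expect_lt(rate, 0.05 + se2)
})
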
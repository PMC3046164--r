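test_that("scalar-variability slope separates multiplicative from additive
           noise", {
  # constant-CV multiplicative noise: slope near 1
  slopes_mult <- vapply(1:10, function(s) {
    sv <- scalar_variability_report(simulate_estimates(seed = s))
    mean(vapply(sv$per_condition, `[[`, numeric(1), "slope"))
  }, numeric(1))
  expect_lt(abs(mean(slopes_mult) - 1), 0.15)
  # additive constant-SD noise: slope near 0
  set.seed(42)
  slopes_add <- vapply(1:10, function(s) {
    tab <- expand.grid(subject = 1:11, condition = "c1",
                       numerosity = 10:30, rep = 1:6,
                       stringsAsFactors = FALSE)
    tab$estimate <- pmax(1, tab$numerosity + rnorm(nrow(tab), 0, 3))
    tab$bar_height <- 2.6; tab$trial <- tab$rep
    scalar_variability_report(tab)$per_condition$c1$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes_add)), 0.25)
})

test_that("degenerate zero-variance tables are reported without crashing", {
  tab <- expand.grid(subject = 1:5, condition = "c1", numerosity = 10:20,
                     rep = 1:3, stringsAsFactors = FALSE)
  tab$estimate <- tab$numerosity  # every estimate exact: SE = 0 everywhere
  tab$bar_height <- 2.6; tab$trial <- tab$rep
  sv <- scalar_variability_report(tab)
  p <- sv$per_condition$c1
  expect_true(is.na(p$slope))
  expect_true(all(p$by_numerosity$se == 0))
  expect_equal(p$mean_cv, 0)
})

test_that("single-observation cells are excluded from the CV analysis with a
           warning", {
  tab <- simulate_estimates(10:14, subjects = 3, reps = 2, seed = 2)
  tab <- tab[tab$condition == "first_order", ]
  tab <- tab[!(tab$subject == 1 & tab$numerosity == 10 & tab$trial == 2), ]
  expect_warning(scalar_variability_report(tab), "single observation")
})

test_that("per-numerosity bias tests detect a calibrated observer as unbiased", {
  veridical <- observer_params(c = 1, n = 1, cv = 0.2,
                               condition_gain = c(first_order = 1,
                                                  second_order = 1))
  sv <- scalar_variability_report(simulate_estimates(params = veridical,
                                                     seed = 4))
  bias <- sv$per_condition$first_order$bias
  # at alpha = .05, about 1 of 21 uncorrected tests may fire by chance
  expect_lte(sum(bias$p < 0.05, na.rm = TRUE), 3)
  expect_true(all(bias$p_bonferroni >= bias$p, na.rm = TRUE))
})

test_that("per-subject regression recovers pure and null predictors", {
  set.seed(11)
  phi <- rep(10:30, each = 6)
  hts <- vapply(phi, function(k) mean(sample(c(2.08, 3.12), k, TRUE)),
                numeric(1))
  exact <- data.frame(subject = 1, condition = "first_order",
                      numerosity = phi, bar_height = hts,
                      estimate = phi, trial = 1)
  r <- suppressWarnings(per_subject_regression(exact, 1, "first_order"))
  expect_equal(r$coef$beta[r$coef$term == "num"], 1, tolerance = 1e-8)
  expect_equal(r$coef$beta[r$coef$term == "height"], 0, tolerance = 1e-8)
  expect_equal(r$adj_r_squared, 1, tolerance = 1e-8)
  expect_equal(r$df_residual, 126 - 3)
  # pure-noise estimates: adjusted R^2 averages to ~0
  r2 <- vapply(1:40, function(s) {
    set.seed(s)
    noise <- exact
    noise$estimate <- exp(rnorm(nrow(noise)))
    per_subject_regression(noise, 1, "first_order")$adj_r_squared
  }, numeric(1))
  expect_lt(abs(mean(r2)), 0.05)
})

test_that("per-subject regression recovers known standardized effects", {
  set.seed(21)
  phi <- rep(10:30, each = 6)  # 126 rows, the per-condition trial count
  hts <- vapply(phi, function(k) mean(sample(c(2.08, 3.12), k, TRUE)),
                numeric(1))
  zln <- scale(log(phi))[, 1]
  log_est <- 0.8 * zln + sqrt(1 - 0.8^2) * rnorm(length(phi))
  tab <- data.frame(subject = 7, condition = "second_order",
                    numerosity = phi, bar_height = hts,
                    estimate = exp(log_est), trial = 1)
  r <- per_subject_regression(tab, 7, "second_order")
  b <- r$coef$beta; se <- abs(b / r$coef$t)
  expect_lt(abs(b[1] - 0.8), 3 * se[1])
  expect_lt(abs(b[2] - 0.0), 3 * se[2])
})

test_that("standardized coefficients are invariant to predictor rescaling", {
  tab <- simulate_estimates(10:30, subjects = 1, reps = 6, seed = 3)
  r1 <- per_subject_regression(tab, 1, "first_order")
  tab2 <- tab
  tab2$numerosity <- tab2$numerosity * 7
  tab2$bar_height <- tab2$bar_height * 0.125
  r2 <- per_subject_regression(tab2, 1, "first_order")
  expect_equal(r2$coef$beta, r1$coef$beta, tolerance = 1e-10)
  expect_equal(r2$adj_r_squared, r1$adj_r_squared, tolerance = 1e-10)
})

test_that("per-subject regression rejects degenerate inputs", {
  tab <- simulate_estimates(10:30, subjects = 1, reps = 6, seed = 3)
  short <- tab[tab$condition == "first_order", ][1:5, ]
  expect_error(per_subject_regression(short, 1, "first_order"), ">= 10 rows")
  const <- tab[tab$condition == "first_order", ]
  const$bar_height <- 2.6
  expect_error(per_subject_regression(const, 1, "first_order"),
               "constant predictor: log\\(bar_height\\)")
})

test_that("repeated-measures ANOVA matches the brute-force sums-of-squares
           oracle to 6 decimals", {
  # hand-computable 3-subject 2x2 design
  y <- array(c(2.1, 2.5, 2.3,   2.8, 3.1, 2.9,
               2.4, 2.2, 2.6,   3.3, 3.0, 3.4),
             dim = c(3, 2, 2))
  oracle <- rm_anova_bruteforce(log(y))
  tab <- table_from_array(y, numerosities = c(10, 20))
  got <- rm_anova_2way(tab)
  e <- got$effects
  expect_equal(e$ss, c(oracle$SS_A, oracle$SS_B, oracle$SS_AB),
               tolerance = 1e-6)
  expect_equal(e$ss_error, c(oracle$SS_AS, oracle$SS_BS, oracle$SS_res),
               tolerance = 1e-6)
  expect_equal(e$F[1], oracle$F_A, tolerance = 1e-6)
  expect_equal(e$F[2], oracle$F_B, tolerance = 1e-6)
  expect_equal(e$F[3], oracle$F_AB, tolerance = 1e-6)
  expect_equal(e$partial_eta_sq[1],
               oracle$SS_A / (oracle$SS_A + oracle$SS_AS), tolerance = 1e-6)
})

test_that("repeated-measures ANOVA agrees with aov error strata", {
  tab <- simulate_estimates(10:15, subjects = 5, reps = 3, seed = 13)
  got <- rm_anova_2way(tab)
  cell <- aggregate(estimate ~ subject + condition + numerosity, tab, mean)
  cell$y <- log(cell$estimate)
  cell$subject <- factor(cell$subject)
  cell$condition <- factor(cell$condition)
  cell$numerosity <- factor(cell$numerosity)
  fit <- aov(y ~ condition * numerosity +
               Error(subject / (condition * numerosity)), data = cell)
  sm <- summary(fit)
  f_aov <- c(sm[["Error: subject:condition"]][[1]]["condition", "F value"],
             sm[["Error: subject:numerosity"]][[1]]["numerosity", "F value"],
             sm[["Error: subject:condition:numerosity"]][[1]][
               "condition:numerosity", "F value"])
  expect_equal(got$effects$F, unname(f_aov), tolerance = 1e-8)
})

test_that("the full design yields the (1,10) and (20,200) degrees of freedom", {
  tab <- simulate_estimates(10:30, subjects = 11, reps = 6, seed = 1)
  got <- rm_anova_2way(tab)
  e <- got$effects
  expect_equal(e$df1, c(1, 20, 20))
  expect_equal(e$df2, c(10, 200, 200))
})

test_that("ANOVA F statistics are calibrated under the null", {
  n_seeds <- 300
  stats <- t(vapply(seq_len(n_seeds), function(s) {
    set.seed(1000 + s)
    y <- array(exp(rnorm(11 * 2 * 8, 0, 0.3)), dim = c(11, 2, 8))
    e <- rm_anova_2way(table_from_array(y, numerosities = 10:17))$effects
    c(e$F, e$p)
  }, numeric(6)))
  # E[F(df1, df2)] = df2 / (df2 - 2) under the null
  expect_equal(mean(stats[, 1]), 10 / 8, tolerance = 0.2)     # F(1,10)
  expect_equal(mean(stats[, 2]), 70 / 68, tolerance = 0.1)    # F(7,70)
  expect_equal(mean(stats[, 3]), 70 / 68, tolerance = 0.1)
  # type-I rate at alpha = .05 within 3 binomial SEs
  for (j in 4:6) {
    rate <- mean(stats[, j] < 0.05)
    expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_seeds))
  }
})

test_that("a pure condition gain produces an order effect but no interaction", {
  params <- observer_params(c = 2, n = 0.8, cv = 0.15,
                            condition_gain = c(first_order = 1.2,
                                               second_order = 1.0))
  tab <- simulate_estimates(10:30, subjects = 11, reps = 6,
                            params = params, seed = 6)
  e <- rm_anova_2way(tab)$effects
  expect_gt(e$F[e$effect == "condition"], 10)
  expect_lt(e$F[e$effect == "condition:numerosity"], 2)
})

test_that("ANOVA rejects incomplete designs, naming the missing cells", {
  tab <- simulate_estimates(10:12, subjects = 3, reps = 2, seed = 2)
  tab <- tab[!(tab$subject == 2 & tab$numerosity == 11 &
                 tab$condition == "second_order"), ]
  expect_error(rm_anova_2way(tab), "missing cells.*2 second_order 11")
})

test_that("condition correlation behaves at its anchors", {
  # identical estimates in both conditions: r = 1
  tab <- simulate_estimates(10:30, subjects = 1, reps = 6, seed = 5)
  fo <- tab[tab$condition == "first_order", ]
  dup <- rbind(fo, transform(fo, condition = "second_order"))
  class(dup) <- c("estimate_table", "data.frame")
  expect_equal(condition_correlation(dup, 1)$r, 1, tolerance = 1e-12)
  # independent pure noise: r ~ 0 on average
  rs <- vapply(1:40, function(s) {
    set.seed(s)
    d <- expand.grid(subject = 1, condition = c("a", "b"),
                     numerosity = 10:30, trial = 1:3,
                     stringsAsFactors = FALSE)
    d$estimate <- exp(rnorm(nrow(d)))
    d$bar_height <- 2.6
    condition_correlation(d, 1)$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
  # shared power law with cv = .33: substantially positive
  rs2 <- vapply(1:20, function(s)
    condition_correlation(simulate_estimates(seed = s, subjects = 1), 1)$r,
    numeric(1))
  expect_gt(mean(rs2), 0.5)
  # zero variance: undefined, reported as NA with a warning
  flat <- dup
  flat$estimate[flat$condition == "second_order"] <- 5
  expect_warning(res <- condition_correlation(flat, 1), "zero variance")
  expect_true(is.na(res$r))
})
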
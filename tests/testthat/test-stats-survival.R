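test_that("KM estimator is a proper survival curve and matches survfit", {
  set.seed(10)
  n <- 60
  t <- rexp(n, 0.1); c <- rexp(n, 0.05)
  time <- pmin(t, c); ev <- as.integer(t <= c)
  km <- km_curve(time, ev)
  expect_true(all(diff(km$surv) <= 1e-14))
  expect_lte(km$surv[1], 1)
  sf <- survival::survfit(survival::Surv(time, ev) ~ 1)
  ref <- summary(sf, times = km$time)$surv
  expect_equal(km$surv, ref, tolerance = 1e-12)
  # closure: all events, estimate after last event = 0
  km2 <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km2$surv[length(km2$surv)], 0)
})

test_that("log-rank matches survdiff and a full permutation enumeration", {
  set.seed(12)
  n <- 80
  g <- rep(c("a", "b"), each = n / 2)
  t <- rexp(n, ifelse(g == "a", 0.05, 0.12)); c <- rexp(n, 0.03)
  time <- pmin(t, c); ev <- as.integer(t <= c)
  lr <- km_logrank(time, ev, g)
  ref <- survival::survdiff(survival::Surv(time, ev) ~ g)
  expect_equal(lr$test$statistic, unname(ref$chisq), tolerance = 1e-8)
  # identical groups, merged tied data: statistic exactly 0
  lr0 <- km_logrank(rep(c(1, 2, 3), 2), rep(1, 6), rep(c("a", "b"), 3))
  expect_equal(lr0$test$statistic, 0)
  # fully separated 3 vs 3, all events: the observed statistic is the
  # most extreme over all 20 assignments (permutation p = 2/20)
  obs <- km_logrank(1:6, rep(1, 6), rep(c("a", "b"), each = 3))$test$statistic
  combs <- utils::combn(6, 3)
  stats_all <- apply(combs, 2, function(ix) {
    gg <- rep("b", 6); gg[ix] <- "a"
    km_logrank(1:6, rep(1, 6), gg)$test$statistic
  })
  expect_equal(max(stats_all), obs, tolerance = 1e-10)
  expect_equal(mean(stats_all >= obs - 1e-10), 0.1)
  expect_error(km_logrank(1:4, rep(1, 4), rep("a", 4)), "two groups")
  expect_error(km_logrank(1:4, rep(0, 4), rep(c("a", "b"), 2)), "event")
})

test_that("Cox fit maximizes the partial likelihood (brute-force oracle)", {
  # 6 subjects, binary covariate, no ties
  time <- c(2, 4, 5, 7, 9, 12)
  ev <- c(1, 1, 0, 1, 1, 1)
  x <- c(1, 0, 1, 1, 0, 0)
  fit <- cox_ph(time, ev, cbind(grp = x))
  oracle <- cox_brute_oracle(time, ev, x)
  expect_equal(unname(fit$coef), oracle, tolerance = 1e-6)
  # and equality with the survival package on a larger draw
  set.seed(13)
  n <- 100
  z <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
  t <- rexp(n, 0.05 * exp(0.4 * z[, 1] - 0.6 * z[, 2])); c <- rexp(n, 0.02)
  tt <- pmin(t, c); evt <- as.integer(t <= c)
  mine <- cox_ph(tt, evt, z)
  ref <- survival::coxph(survival::Surv(tt, evt) ~ z, ties = "efron")
  expect_equal(unname(mine$coef), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(mine$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
})

test_that("Cox handles constant covariates, duplication, and separation", {
  set.seed(14)
  n <- 60
  x <- rnorm(n)
  t <- rexp(n, 0.05 * exp(0.5 * x))
  expect_message(f0 <- cox_ph(t, rep(1, n), cbind(k = rep(2, n), x = x)),
                 "constant")
  expect_equal(f0$dropped, "k")
  # duplicating every row halves SEs by sqrt(2)
  f1 <- cox_ph(t, rep(1, n), cbind(x = x))
  f2 <- cox_ph(rep(t, 2), rep(1, 2 * n), cbind(x = rep(x, 2)))
  expect_equal(unname(f2$se / f1$se), 1 / sqrt(2), tolerance = 0.02)
  # perfect separation: the low-covariate subject always survives longest
  xs <- c(rep(1, 5), rep(-1, 5))
  ts <- c(1:5, 101:105)
  expect_warning(fs <- cox_ph(ts, rep(1, 10), cbind(x = xs)), "monotone")
  expect_false(fs$converged)
})

test_that("Cox recovers a planted log-hazard within 2 SE in most replicates", {
  hits <- 0
  for (s in 1:60) {
    set.seed(1000 + s)
    n <- 300
    x <- rnorm(n)
    t <- rexp(n, 0.04 * exp(0.7 * x)); c <- rexp(n, 0.02)
    f <- cox_ph(pmin(t, c), as.integer(t <= c), cbind(x = x))
    if (abs(f$coef - 0.7) <= 2 * f$se) hits <- hits + 1
  }
  expect_gte(hits, 54)  # >= 90%
})

test_that("univariate screening feeds the joint model correctly", {
  set.seed(15)
  n <- 200
  x <- cbind(planted = rnorm(n), matrix(rnorm(n * 4), n,
                                        dimnames = list(NULL, paste0("n", 1:4))))
  t <- rexp(n, 0.05 * exp(0.9 * x[, 1])); c <- rexp(n, 0.02)
  scr <- multivariable_screen(pmin(t, c), as.integer(t <= c), x)
  expect_true("planted" %in% scr$selected)
  expect_true("planted" %in% names(scr$fit$coef))
  all_in <- multivariable_screen(pmin(t, c), as.integer(t <= c), x, alpha = 1)
  expect_equal(sort(all_in$selected), sort(colnames(x)))
  expect_message(none <- multivariable_screen(pmin(t, c), as.integer(t <= c),
                                              x, alpha = 0), "no candidate")
  expect_null(none$fit)
})

test_that("time-dependent AUC reduces to the static AUC without censoring", {
  set.seed(16)
  n <- 120
  score <- rnorm(n)
  t <- rexp(n, 0.05 * exp(0.8 * score))
  ev <- rep(1, n)
  horizon <- median(t)
  td <- time_dependent_auc(score, t, ev, horizon)
  static <- roc_youden(score, as.integer(t <= horizon))$auc
  expect_equal(td, static, tolerance = 1e-12)
  # oracle score: -time ranks cases perfectly
  expect_equal(time_dependent_auc(-t, t, ev, horizon), 1)
  expect_error(time_dependent_auc(score, t + 100, ev, 1), "events")
})

test_that("time-dependent AUC under censoring tracks a large-sample pair oracle", {
  # population value by brute force on a huge uncensored draw
  set.seed(17)
  big <- 1e5
  sb <- rnorm(big)
  tb <- rexp(big, 0.05 * exp(0.8 * sb))
  horizon <- 10
  truth <- roc_youden(sb, as.integer(tb <= horizon))$auc
  aucs <- vapply(1:20, function(s) {
    set.seed(200 + s)
    n <- 400
    sc <- rnorm(n)
    t <- rexp(n, 0.05 * exp(0.8 * sc)); c <- rexp(n, 0.04)
    time_dependent_auc(sc, pmin(t, c), as.integer(t <= c), horizon)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - truth), 0.03)
})
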
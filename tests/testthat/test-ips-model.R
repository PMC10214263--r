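# Direct synthetic survival design matching the dual-selection setting:
# 8 features, 5 with planted log-HR, 3 pure noise.
make_selection_data <- function(seed, n = 253, beta = rep(c(0.7, 0), c(5, 3))) {
  set.seed(seed)
  p <- length(beta)
  x <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("g", seq_len(p))))
  t <- rexp(n, 0.02 * exp(drop(x %*% beta)))
  c <- rexp(n, 0.01)
  list(x = x, time = pmin(t, c), event = as.integer(t <= c),
       planted = paste0("g", seq_len(sum(beta != 0))))
}

test_that("lasso Cox honours the penalty limits and path nesting", {
  d <- make_selection_data(50)
  inf <- lasso_cox_select(d$x, d$time, d$event, penalty = Inf)
  expect_length(inf$chosen, 0)
  zero <- lasso_cox_select(d$x, d$time, d$event, penalty = 0)
  expect_setequal(zero$chosen, colnames(d$x))
  fit <- lasso_cox_select(d$x, d$time, d$event, penalty = "cv", seed = 1)
  # active set at the strongest penalty nests inside the weakest one
  sets <- fit$active_sets
  expect_true(all(sets[[1]] %in% sets[[length(sets)]]))
  expect_true(all(d$planted %in% zero$chosen))
  # all-constant feature dropped with a warning
  xc <- cbind(d$x, const = 1)
  expect_warning(lasso_cox_select(xc, d$time, d$event, penalty = 0), "constant")
})

test_that("survival-forest importance separates planted from noise features", {
  d <- make_selection_data(51)
  r <- rsf_importance(d$x, d$time, d$event, seed = 1)
  expect_gt(min(r$importance[d$planted]), max(r$importance[paste0("g", 6:8)]))
  expect_length(rsf_importance(d$x, d$time, d$event, threshold = Inf,
                               seed = 1)$chosen, 0)
  expect_error(rsf_importance(d$x, d$time, d$event, threshold = -1), "threshold")
  # deterministic for a fixed seed
  r2 <- rsf_importance(d$x, d$time, d$event, seed = 1)
  expect_identical(r$importance, r2$importance)
})

test_that("null features have importance near zero on average", {
  imps <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 120
    x <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("f", 1:4)))
    t <- rexp(n, 0.03); c <- rexp(n, 0.015)
    mean(rsf_importance(x, pmin(t, c), as.integer(t <= c),
                        seed = s)$importance)
  }, numeric(1))
  expect_gte(mean(imps), -0.01)
  expect_lte(mean(imps), 0.01)
})

test_that("feature-set intersection follows set algebra", {
  expect_setequal(select_features(c("a", "b", "c"), c("b", "c", "d")),
                  c("b", "c"))
  expect_setequal(select_features(c("a", "b"), c("a", "b")), c("a", "b"))
  expect_warning(empty <- select_features("a", "b"), "disjoint")
  expect_length(empty, 0)
})

test_that("the IPS is a linear predictor with recoverable coefficients", {
  d <- make_selection_data(52, n = 400)
  m <- fit_ips(d$x[, 1:5], d$time, d$event, stepwise = FALSE)
  # linearity: shifting one marker shifts every score by coef * shift
  s1 <- ips_score(m, d$x[, 1:5])
  shifted <- d$x[, 1:5]; shifted[, "g2"] <- shifted[, "g2"] + 10
  s2 <- ips_score(m, shifted)
  expect_equal(s2 - s1, rep(10 * m$coef[["g2"]], length(s1)),
               tolerance = 1e-10)
  # single marker: score proportional to it
  m1 <- fit_ips(d$x[, 1, drop = FALSE], d$time, d$event)
  expect_equal(cor(ips_score(m1, d$x[, 1, drop = FALSE]), d$x[, 1]), 1)
  # coefficients within 2 SE of the planted values
  ref <- survival::coxph(survival::Surv(d$time, d$event) ~ d$x[, 1:5])
  se <- sqrt(diag(vcov(ref)))
  expect_true(all(abs(m$coef - 0.7) <= 2.5 * se))
})

test_that("Youden dichotomization matches outcomes and degenerates sanely", {
  # perfectly separating score
  time <- c(rep(5, 20), rep(80, 20))
  ev <- rep(1, 40)
  score <- c(rnorm(20, 10), rnorm(20, -10))
  di <- dichotomize(score, time, ev, horizon = 40)
  expect_true(all(di$results$ips_class[1:20] == "High"))
  expect_true(all(di$results$ips_class[21:40] == "Low"))
  expect_warning(dg <- dichotomize(rep(1, 40), time, ev, horizon = 40),
                 "identical")
  expect_length(unique(dg$results$ips_class), 1)
})

test_that("a planted two-population score separates survival strongly", {
  set.seed(53)
  n <- 500
  grp <- rbinom(n, 1, 0.5)
  score <- rnorm(n, 2 * grp)
  t <- rexp(n, 0.02 * exp(1.2 * grp)); c <- rexp(n, 0.01)
  time <- pmin(t, c); ev <- as.integer(t <= c)
  di <- dichotomize(score, time, ev)
  lr <- km_logrank(time, ev, di$results$ips_class)
  expect_lt(lr$test$p_value, 0.001)
})

test_that("biopsy applicability excludes small areas and finds the noise knee", {
  # identity pairs: perfect agreement
  set.seed(54)
  ipsp <- rnorm(40)
  r <- biopsy_applicability(ipsp, ipsp, tumor_area = runif(40, 0.2, 1))
  expect_equal(r$rho, 1)
  expect_equal(r$auc, 1)
  # area below the default threshold is excluded
  area <- c(0.15, rep(0.5, 9))
  r2 <- biopsy_applicability(rnorm(10), rnorm(10), area)
  expect_equal(r2$n_retained, 9)
  # sweep recovers the planted noise knee within one grid step
  grid <- c(0.04, 0.08, 0.16, 0.32)
  hits <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    n <- 120
    a <- runif(n, 0.02, 1)
    p <- rnorm(n)
    b <- p + rnorm(n, 0, ifelse(a < 0.16, 3, 0.3))
    sw <- biopsy_applicability(b, p, a, sweep = grid)
    if (abs(match(sw$best_threshold, grid) - 3) <= 1) hits <- hits + 1
  }
  expect_gte(hits, 15)
  expect_error(biopsy_applicability(1:5, 1:5, rep(0.01, 5)), "3 retained")
})
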
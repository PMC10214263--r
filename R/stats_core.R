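# ---- result container ----------------------------------------------------

new_test_result <- function(method, statistic = NA_real_, p_value = NA_real_,
                            effect = NA_real_, ci = c(NA_real_, NA_real_),
                            extra = list()) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1 + 1e-12))
  structure(c(list(method = method, statistic = unname(statistic),
                   p_value = unname(min(p_value, 1)),
                   effect = unname(effect), ci = unname(ci)), extra),
            class = "ips_test")
}

#' @export
print.ips_test <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic),
      " p =", format.pval(x$p_value), "\n")
  if (!is.na(x$effect)) cat("  effect =", format(x$effect), "\n")
  invisible(x)
}

as_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop("expected a 2x2 table")
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  if (sum(m) <= 0) stop("table total must be positive")
  storage.mode(m) <- "double"
  m
}

# ---- contingency tests ---------------------------------------------------

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Point-probability rule: the two-sided p-value is the sum of
#' hypergeometric probabilities of every table with the observed margins
#' whose probability does not exceed that of the observed table (within a
#' relative tolerance of 1e-7 on the comparison).  This is the convention
#' that reproduces standard clinical-report p-values such as 0.015 for
#' counts [[12,12],[4,22]].
#'
#' @param table 2x2 matrix of counts; rows are groups, columns outcomes.
#' @return An `ips_test` with the p-value and the sample odds ratio
#'   (cross-product ad/bc, `Inf` or `NaN` when a margin cell is zero).
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as_2x2(table)
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  support <- lo:hi
  dens <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  new_test_result("Fisher's exact test (two-sided)", statistic = m[1, 1],
                  p_value = min(p, 1), effect = or)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected statistic N(ad-bc)^2 / (r1 r2 c1 c2) with 1 df; the
#' optional Yates correction subtracts N/2 from |ad-bc|.
#'
#' @param table 2x2 count matrix.
#' @param correction apply Yates continuity correction (default FALSE).
#' @return An `ips_test` (statistic, p, odds-ratio effect).
#' @export
chi_square_2x2 <- function(table, correction = FALSE) {
  m <- as_2x2(table)
  r <- rowSums(m); cl <- colSums(m); n <- sum(m)
  if (any(r == 0) || any(cl == 0)) stop("chi-square undefined: zero margin")
  d <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  num <- if (correction) max(abs(d) - n / 2, 0)^2 else d^2
  stat <- n * num / (r[1] * r[2] * cl[1] * cl[2])
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  new_test_result(paste0("Pearson chi-square", if (correction) " (Yates)"),
                  statistic = stat, p_value = p, effect = or)
}

# ---- rank tests ----------------------------------------------------------

#' Rank-based two-group and k-group tests
#'
#' `mann_whitney` and `wilcoxon_signed_rank` use the exact null
#' distribution when each sample has at most 12 observations and there
#' are no ties (no zero differences for the paired test); otherwise a
#' normal approximation with tie correction is used.  `kruskal_wallis`
#' uses the chi-square approximation with tie correction.
#'
#' @param x numeric vector (first group / first member of pairs). For
#'   `kruskal_wallis`, a list of numeric vectors may be given as `x`.
#' @param y second group (ignored for `kruskal_wallis` when `x` is a list).
#' @param mode one of `"mann_whitney"`, `"kruskal_wallis"`,
#'   `"wilcoxon_signed_rank"`.
#' @return An `ips_test`.
#' @export
rank_test <- function(x, y = NULL,
                      mode = c("mann_whitney", "kruskal_wallis",
                               "wilcoxon_signed_rank")) {
  mode <- match.arg(mode)
  switch(mode,
         mann_whitney = mann_whitney_test(x, y),
         kruskal_wallis = kruskal_wallis_test(x, y),
         wilcoxon_signed_rank = wilcoxon_sr_test(x, y))
}

mann_whitney_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty group")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (nx <= 12 && ny <= 12 && !ties) {
    # exact: dwilcox gives the null pmf of U
    p_le <- stats::pwilcox(u, nx, ny)
    p_ge <- stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE)
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- nx * ny / 2
    tab <- table(r)
    tiecor <- sum(tab^3 - tab) / ((nx + ny) * (nx + ny - 1))
    sigma <- sqrt(nx * ny / 12 * (nx + ny + 1 - tiecor))
    z <- (u - mu) / sigma
    p <- 2 * stats::pnorm(-abs(z))
  }
  new_test_result("Mann-Whitney U", statistic = u, p_value = p,
                  extra = list(exact = nx <= 12 && ny <= 12 && !ties))
}

wilcoxon_sr_test <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  d <- x - y
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) == 0) {
    warning("all paired differences are zero; p defined as 1")
    return(new_test_result("Wilcoxon signed-rank", statistic = 0, p_value = 1))
  }
  n <- length(nz)
  r <- rank(abs(nz))
  v <- sum(r[nz > 0])
  ties <- any(duplicated(abs(nz))) || length(nz) < length(d)
  if (n <= 12 && !ties) {
    p_le <- stats::psignrank(v, n)
    p_ge <- stats::psignrank(v - 1, n, lower.tail = FALSE)
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    tab <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48)
    z <- (v - mu) / sigma
    p <- 2 * stats::pnorm(-abs(z))
  }
  new_test_result("Wilcoxon signed-rank", statistic = v, p_value = p)
}

kruskal_wallis_test <- function(x, y = NULL) {
  groups <- if (is.list(x)) x else list(x, y)
  if (any(lengths(groups) == 0)) stop("empty group")
  if (length(groups) < 2) stop("need at least 2 groups")
  v <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(v)
  r <- rank(v)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  tab <- table(v)
  cf <- 1 - sum(tab^3 - tab) / (n^3 - n)
  h <- h / cf
  p <- stats::pchisq(h, df = length(groups) - 1, lower.tail = FALSE)
  new_test_result("Kruskal-Wallis", statistic = h, p_value = p)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of tie-averaged ranks; the p-value uses
#' t = rho * sqrt((n-2)/(1-rho^2)) with n-2 df (p = 0 at |rho| = 1).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return An `ips_test` with `effect` = rho.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  new_test_result("Spearman rank correlation", statistic = rho * sqrt(n - 2),
                  p_value = p, effect = rho)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in [0,1].
#' @return Adjusted values (monotone, capped at 1), in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) stop("p-values must lie in [0,1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

# ---- survival ------------------------------------------------------------

check_survival <- function(time, event) {
  if (length(time) != length(event)) stop("time and event length mismatch")
  if (any(time <= 0)) stop("survival times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  invisible(NULL)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicator.
#' @return data.frame with columns time, n_risk, n_event, surv (the step
#'   value just after `time`).
#' @export
km_curve <- function(time, event) {
  check_survival(time, event)
  ut <- sort(unique(time[event == 1]))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = ut, n_risk = n_risk, n_event = n_event, surv = surv)
}

#' Log-rank test across groups with per-group KM curves
#'
#' Standard O-E statistic with hypergeometric variance, chi-square with
#' G-1 df.  With two groups the statistic reduces to (O1-E1)^2/V1.
#'
#' @param time,event survival data.
#' @param group group labels (>= 2 distinct values required).
#' @return list with `curves` (named list of KM data.frames) and `test`
#'   (an `ips_test`).
#' @export
km_logrank <- function(time, event, group) {
  check_survival(time, event)
  if (sum(event) < 1) stop("log-rank requires at least one event")
  group <- as.factor(group)
  if (nlevels(group) < 2) stop("log-rank requires at least two groups")
  lev <- levels(group)
  g <- length(lev)
  ut <- sort(unique(time[event == 1]))
  obs <- exp_ <- numeric(g)
  vmat <- matrix(0, g, g)
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(time == t & event == 1)
    ni <- vapply(lev, function(l) sum(at_risk & group == l), numeric(1))
    di <- vapply(lev, function(l) sum(time == t & event == 1 & group == l),
                 numeric(1))
    obs <- obs + di
    exp_ <- exp_ + d * ni / n
    if (n > 1) {
      # multivariate hypergeometric covariance
      for (i in seq_len(g)) for (j in seq_len(g)) {
        delta <- as.numeric(i == j)
        vmat[i, j] <- vmat[i, j] +
          d * (n - d) / (n - 1) * ni[i] * (delta * n - ni[j]) / n^2
      }
    }
  }
  z <- (obs - exp_)[-g]
  vsub <- vmat[-g, -g, drop = FALSE]
  stat <- if (all(abs(z) < 1e-12)) 0 else
    drop(t(z) %*% solve(vsub, z))
  p <- stats::pchisq(stat, df = g - 1, lower.tail = FALSE)
  curves <- lapply(lev, function(l)
    km_curve(time[group == l], event[group == l]))
  names(curves) <- lev
  list(curves = curves,
       test = new_test_result("log-rank", statistic = stat, p_value = p,
                              extra = list(observed = obs, expected = exp_)))
}

# ---- Cox proportional hazards (Efron ties, Newton-Raphson) ---------------

cox_loglik <- function(beta, x, time, event) {
  eta <- drop(x %*% beta)
  w <- exp(eta)
  ut <- sort(unique(time[event == 1]))
  ll <- 0
  grad <- numeric(ncol(x))
  hess <- matrix(0, ncol(x), ncol(x))
  for (t in ut) {
    risk <- which(time >= t)
    dead <- which(time == t & event == 1)
    d <- length(dead)
    s0r <- sum(w[risk])
    s1r <- colSums(x[risk, , drop = FALSE] * w[risk])
    s2r <- crossprod(x[risk, , drop = FALSE] * sqrt(w[risk]))
    s0d <- sum(w[dead])
    s1d <- colSums(x[dead, , drop = FALSE] * w[dead])
    s2d <- crossprod(x[dead, , drop = FALSE] * sqrt(w[dead]))
    ll <- ll + sum(eta[dead])
    for (l in seq_len(d) - 1) {
      f <- l / d
      s0 <- s0r - f * s0d
      s1 <- s1r - f * s1d
      s2 <- s2r - f * s2d
      ll <- ll - log(s0)
      grad <- grad - s1 / s0
      hess <- hess - (s2 / s0 - tcrossprod(s1 / s0))
    }
    grad <- grad + colSums(x[dead, , drop = FALSE])
  }
  list(ll = ll, grad = grad, hess = hess)
}

#' Cox proportional-hazards regression (Efron tie handling)
#'
#' Newton-Raphson maximization of the Efron partial likelihood to a
#' gradient max-norm below `tol`.  Constant covariates are dropped with a
#' note; monotone likelihoods (separation) are flagged rather than
#' reported as huge estimates.
#'
#' @param time,event survival data.
#' @param x covariate matrix (or vector for a single covariate).
#' @param tol convergence tolerance on the gradient max-norm.
#' @param max_iter Newton iteration cap.
#' @return list with coefficients, se, hr, ci (95% Wald), z, p, loglik,
#'   converged flag, and `dropped` (names of constant covariates).
#' @export
cox_ph <- function(time, event, x, tol = 1e-8, max_iter = 50) {
  check_survival(time, event)
  if (sum(event) < 1) stop("Cox model requires at least one event")
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  keep <- apply(x, 2, function(v) stats::sd(v) > 0)
  dropped <- colnames(x)[!keep]
  if (length(dropped))
    message("dropping constant covariate(s): ", paste(dropped, collapse = ", "))
  x <- x[, keep, drop = FALSE]
  if (ncol(x) == 0) {
    return(list(coef = numeric(0), se = numeric(0), hr = numeric(0),
                ci = matrix(numeric(0), 0, 2), z = numeric(0), p = numeric(0),
                loglik = NA_real_, converged = TRUE, dropped = dropped))
  }
  beta <- numeric(ncol(x))
  converged <- FALSE
  flagged <- FALSE
  obj <- cox_loglik(beta, x, time, event)
  for (it in seq_len(max_iter)) {
    if (max(abs(obj$grad)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(-obj$hess, obj$grad), error = function(e) NULL)
    if (is.null(step)) { flagged <- TRUE; break }
    new_beta <- beta + step
    new_obj <- cox_loglik(new_beta, x, time, event)
    halvings <- 0
    while ((!is.finite(new_obj$ll) || new_obj$ll < obj$ll - 1e-12) &&
           halvings < 30) {
      step <- step / 2
      new_beta <- beta + step
      new_obj <- cox_loglik(new_beta, x, time, event)
      halvings <- halvings + 1
    }
    beta <- new_beta
    obj <- new_obj
    if (max(abs(beta)) > 10) { flagged <- TRUE; break }  # monotone likelihood
  }
  if (max(abs(obj$grad)) < tol) converged <- TRUE
  # a "converged" optimum at an extreme coefficient is quasi-separation:
  # the gradient saturates numerically once exp(eta) overwhelms the
  # risk sets, well before the coefficient grows large
  if (converged && length(beta) && max(abs(beta)) > 10) flagged <- TRUE
  if (flagged)
    warning("possible monotone partial likelihood (separation); ",
            "estimates flagged as non-converged")
  se <- sqrt(diag(solve(-obj$hess)))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  ci <- cbind(exp(beta - 1.96 * se), exp(beta + 1.96 * se))
  colnames(ci) <- c("lower95", "upper95")
  rownames(ci) <- colnames(x)
  names(beta) <- names(se) <- names(z) <- names(p) <- colnames(x)
  list(coef = beta, se = se, hr = exp(beta), ci = ci, z = z, p = p,
       loglik = obj$ll, converged = converged && !flagged, dropped = dropped)
}

#' Univariate screening followed by a joint Cox model
#'
#' Fits a univariate Cox model per candidate covariate and refits jointly
#' on those with univariate p <= alpha.
#'
#' @param time,event survival data.
#' @param x candidate covariate matrix (>= 2 columns).
#' @param alpha screening significance level (default 0.05).
#' @return list with `univariate` (data.frame per candidate), `selected`
#'   (names), and `fit` (joint cox_ph fit, or NULL with a notice when no
#'   candidate passes).
#' @export
multivariable_screen <- function(time, event, x, alpha = 0.05) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 candidate covariates")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  uni <- do.call(rbind, lapply(colnames(x), function(nm) {
    f <- cox_ph(time, event, x[, nm, drop = FALSE])
    data.frame(covariate = nm, coef = unname(f$coef), hr = unname(f$hr),
               p = unname(f$p), stringsAsFactors = FALSE)
  }))
  selected <- uni$covariate[uni$p <= alpha]
  fit <- NULL
  if (length(selected) == 0) {
    message("no candidate passed univariate screening at alpha = ", alpha)
  } else {
    fit <- cox_ph(time, event, x[, selected, drop = FALSE])
  }
  list(univariate = uni, selected = selected, fit = fit)
}

# ---- ROC / Youden --------------------------------------------------------

#' Rank-based AUC and Youden-optimal cutoff
#'
#' AUC by the Mann-Whitney rank statistic with tie averaging.  Candidate
#' cutoffs are midpoints between consecutive distinct scores (plus one
#' below the minimum); a case is called positive when score > cutoff.
#' The returned cutoff maximizes Youden's J = sensitivity + specificity
#' - 1, ties broken toward the lower cutoff.
#'
#' @param score numeric risk scores.
#' @param label 0/1 class labels (both classes required).
#' @return list with auc, cutoff, youden (J at the cutoff), sensitivity,
#'   specificity.
#' @export
roc_youden <- function(score, label) {
  if (length(score) != length(label)) stop("score/label length mismatch")
  if (!all(label %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- as.numeric(sum(label == 1)); n0 <- as.numeric(sum(label == 0))
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(score)
  auc <- (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  us <- sort(unique(score))
  cand <- if (length(us) > 1) c(us[1] - 1, (us[-1] + us[-length(us)]) / 2)
          else us - 1
  # cand[i] satisfies: score > cand[i]  <=>  score >= us[i]
  tab1 <- vapply(split(label, score), sum, numeric(1))        # positives per value
  tab0 <- vapply(split(1 - label, score), sum, numeric(1))
  csum1 <- unname(c(0, cumsum(tab1))[seq_along(us)])
  csum0 <- unname(c(0, cumsum(tab0))[seq_along(us)])
  sens <- (n1 - csum1) / n1
  spec <- csum0 / n0
  j <- sens + spec - 1
  best <- which.max(j)  # which.max takes the first (lowest cutoff) on ties
  list(auc = auc, cutoff = cand[best], youden = j[best],
       sensitivity = sens[best], specificity = spec[best])
}

#' Time-dependent AUC (cumulative cases / dynamic controls)
#'
#' Cases are subjects with an event by the horizon, controls those still
#' at risk beyond it; both are weighted by inverse-probability-of-
#' censoring weights from the Kaplan-Meier estimate of the censoring
#' distribution.  With no censoring this reduces to the static AUC of
#' score against the event-by-horizon indicator.
#'
#' @param score risk scores (higher = higher risk).
#' @param time,event survival data.
#' @param horizon evaluation time (months).
#' @return AUC(t) as a single number.
#' @export
time_dependent_auc <- function(score, time, event, horizon) {
  check_survival(time, event)
  cases <- which(time <= horizon & event == 1)
  controls <- which(time > horizon)
  if (length(cases) == 0) stop("no events before the horizon")
  if (length(controls) == 0) stop("no subjects at risk past the horizon")
  # KM of the censoring distribution G(t); weight cases by 1/G(T-), controls by 1/G(horizon)
  cens_km <- km_curve(time, 1 - event)
  G <- function(t) {
    s <- cens_km$surv[cens_km$time <= t]
    if (length(s) == 0) 1 else s[length(s)]
  }
  w_case <- vapply(time[cases], function(t) 1 / max(G(t - 1e-10), 1e-10),
                   numeric(1))
  w_ctrl <- rep(1 / max(G(horizon), 1e-10), length(controls))
  sc <- score[cases]; sn <- score[controls]
  num <- 0; den <- 0
  for (i in seq_along(sc)) {
    conc <- sum(w_ctrl * ((sc[i] > sn) + 0.5 * (sc[i] == sn)))
    num <- num + w_case[i] * conc
    den <- den + w_case[i] * sum(w_ctrl)
  }
  num / den
}

# ---- logistic regression -------------------------------------------------

#' Logistic regression with separation diagnostics
#'
#' Maximum-likelihood fit via iteratively reweighted least squares;
#' complete or quasi-complete separation is detected (fitted
#' probabilities collapsing to 0/1 or exploding coefficients) and
#' flagged instead of reporting divergent estimates.
#'
#' @param outcome 0/1 response (both classes required).
#' @param x covariate matrix or vector; an intercept is always added.
#' @return list with coef, se, or (exp(coef)), z, p, separation flag.
#' @export
logistic_fit <- function(outcome, x = NULL) {
  if (!all(outcome %in% c(0, 1))) stop("outcome must be 0/1")
  if (length(unique(outcome)) < 2) stop("both outcome classes must be present")
  if (is.null(x)) {
    df <- data.frame(y = outcome)
    fml <- y ~ 1
  } else {
    x <- as.matrix(x)
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
    df <- data.frame(y = outcome, x)
    fml <- stats::as.formula(paste("y ~", paste(colnames(x), collapse = "+")))
  }
  fit <- suppressWarnings(stats::glm(fml, data = df, family = stats::binomial()))
  mu <- stats::fitted(fit)
  separation <- any(mu < 1e-8 | mu > 1 - 1e-8) || any(abs(stats::coef(fit)) > 15)
  if (separation)
    warning("complete or quasi-complete separation detected; ",
            "estimates are unreliable")
  sm <- summary(fit)$coefficients
  list(coef = sm[, 1], se = sm[, 2], or = exp(sm[, 1]), z = sm[, 3],
       p = sm[, 4], separation = separation, fit = fit)
}
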
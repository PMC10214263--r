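# Construction of the immunophenotypic score (IPS): dual feature
# selection (L1-penalized Cox intersected with survival-forest
# permutation importance), stepwise multivariate Cox fit, Youden-cutoff
# dichotomization, and biopsy-applicability validation.

#' L1-penalized Cox feature selection
#'
#' Fits the lasso Cox path and returns the active set along it plus a
#' chosen set, either at an explicit penalty or at the
#' cross-validation-minimizing penalty (partial-likelihood deviance,
#' folds fixed by `seed`).
#'
#' @param features samples x features numeric matrix (e.g. H-scores).
#' @param time,event survival data.
#' @param penalty `"cv"` (default) or an explicit lambda; `0` returns
#'   the unpenalized Cox support, `Inf` the empty set.
#' @param nfolds cross-validation folds.
#' @param seed fold-assignment seed.
#' @return list: `chosen` (feature names), `lambda`, `path`
#'   (data.frame lambda x active-set size), `active_sets` (list of
#'   name vectors along the path), `fit` (the glmnet object or NULL).
#' @export
lasso_cox_select <- function(features, time, event, penalty = "cv",
                             nfolds = 10, seed = 1L) {
  check_survival(time, event)
  x <- as.matrix(features)
  if (ncol(x) < 2) stop("need >= 2 features")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  keep <- apply(x, 2, function(v) stats::sd(v) > 0)
  if (any(!keep)) {
    warning("dropping all-constant feature(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  if (sum(event) < 10) warning("fewer than 10 events; selection is unstable")
  y <- survival::Surv(time, event)
  if (identical(penalty, Inf)) {
    return(list(chosen = character(0), lambda = Inf, path = NULL,
                active_sets = list(), fit = NULL))
  }
  if (identical(penalty, 0)) {
    f <- cox_ph(time, event, x)
    chosen <- names(f$coef)[abs(f$coef) > 1e-8]
    return(list(chosen = chosen, lambda = 0, path = NULL,
                active_sets = list(chosen), fit = NULL))
  }
  fit <- glmnet::glmnet(x, y, family = "cox", alpha = 1, thresh = 1e-10)
  active_sets <- apply(as.matrix(fit$beta) != 0, 2, function(col)
    rownames(fit$beta)[col], simplify = FALSE)
  path <- data.frame(lambda = fit$lambda,
                     n_active = vapply(active_sets, length, integer(1)))
  if (identical(penalty, "cv")) {
    set.seed(seed)
    foldid <- sample(rep(seq_len(nfolds), length.out = nrow(x)))
    cv <- glmnet::cv.glmnet(x, y, family = "cox", alpha = 1, foldid = foldid,
                            thresh = 1e-10)
    lambda <- cv$lambda.min
  } else {
    lambda <- penalty
  }
  beta <- as.matrix(glmnet::coef.glmnet(fit, s = lambda))
  chosen <- rownames(beta)[abs(beta[, 1]) > 1e-8]
  list(chosen = chosen, lambda = lambda, path = path,
       active_sets = active_sets, fit = fit)
}

#' Survival-forest permutation importance selection
#'
#' Ensemble of survival trees (log-rank splitting) on bootstrap
#' samples; per-feature out-of-bag permutation importance; features at
#' or above `threshold` are returned.  The importance scale is
#' implementation-dependent, so the default threshold was calibrated on
#' synthetic null features (null importances stay within about
#' +/- 0.007) rather than carried over from other software.
#'
#' @param features samples x features matrix.
#' @param time,event survival data.
#' @param threshold importance cutoff (default 0.01).
#' @param num_trees,min_node_size,mtry forest controls; `mtry` defaults
#'   to floor(sqrt(p)).
#' @param seed forest seed (single-threaded, deterministic).
#' @return list: `chosen`, `importance` (named numeric).
#' @export
rsf_importance <- function(features, time, event, threshold = 0.01,
                           num_trees = 500, min_node_size = 15,
                           mtry = NULL, seed = 1L) {
  check_survival(time, event)
  if (threshold < 0) stop("validation error: threshold must be >= 0")
  x <- as.matrix(features)
  if (ncol(x) < 2) stop("need >= 2 features")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(x))))
  df <- data.frame(.time = time, .status = event, x, check.names = FALSE)
  fit <- ranger::ranger(survival::Surv(.time, .status) ~ ., data = df,
                        num.trees = num_trees, mtry = mtry,
                        min.node.size = min_node_size,
                        splitrule = "logrank",
                        importance = "permutation",
                        seed = seed, num.threads = 1)
  imp <- fit$variable.importance
  list(chosen = names(imp)[imp >= threshold], importance = imp)
}

#' Intersect the two selection routes
#'
#' @param lasso_set,rsf_set character vectors of selected features.
#' @return their intersection; warns when empty.
#' @export
select_features <- function(lasso_set, rsf_set) {
  out <- intersect(lasso_set, rsf_set)
  if (length(out) == 0) warning("lasso and survival-forest sets are disjoint")
  out
}

#' Fit the IPS risk model
#'
#' Multivariate Cox on the selected markers with AIC-based stepwise
#' selection (both directions); the IPS is the raw linear predictor
#' sum(coef * feature) so scored patients do not depend on training-set
#' centering.
#'
#' @param features samples x markers matrix (e.g. H-scores).
#' @param time,event survival data.
#' @param stepwise apply stepwise AIC selection (default TRUE).
#' @param standardize z-score features before fitting (default FALSE;
#'   raw H-scores keep the score interpretable per stain unit).
#' @return `ips_model` list: markers, coef, cutoff (NA until
#'   [dichotomize()]), training summary, scaling info.
#' @export
fit_ips <- function(features, time, event, stepwise = TRUE,
                    standardize = FALSE) {
  check_survival(time, event)
  x <- as.matrix(features)
  if (ncol(x) < 1) stop("need >= 1 selected marker")
  if (is.null(colnames(x))) colnames(x) <- paste0("m", seq_len(ncol(x)))
  center <- rep(0, ncol(x)); scale_ <- rep(1, ncol(x))
  if (standardize) {
    center <- colMeans(x); scale_ <- apply(x, 2, stats::sd)
    scale_[scale_ == 0] <- 1
    x <- scale(x, center, scale_)
  }
  df <- data.frame(.time = time, .status = event, x, check.names = FALSE)
  fml <- stats::as.formula(paste("survival::Surv(.time, .status) ~",
                                 paste(sprintf("`%s`", colnames(x)),
                                       collapse = "+")))
  fit <- survival::coxph(fml, data = df)
  if (stepwise && ncol(x) > 1) {
    fit <- MASS::stepAIC(fit, direction = "both", trace = 0)
  }
  cf <- stats::coef(fit)
  markers <- gsub("`", "", names(cf))
  names(cf) <- markers
  structure(list(markers = markers, coef = cf,
                 center = stats::setNames(center, colnames(x))[markers],
                 scale = stats::setNames(scale_, colnames(x))[markers],
                 cutoff = NA_real_,
                 training = list(n = length(time), events = sum(event))),
            class = "ips_model")
}

#' Score patients with a fitted IPS model
#'
#' @param model an `ips_model`.
#' @param features samples x markers matrix containing the model's
#'   markers.
#' @return named numeric IPS per sample.
#' @export
ips_score <- function(model, features) {
  x <- as.matrix(features)[, model$markers, drop = FALSE]
  x <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  drop(x %*% model$coef)
}

#' Youden-cutoff dichotomization into IPS-Low / IPS-High
#'
#' The classification label is vital status by `horizon` (death before
#' the horizon = positive; censored before it = excluded from cutoff
#' estimation); the cutoff maximizes Youden's J of score against that
#' label.  Patients with score <= cutoff are IPS-Low (better prognosis
#' when high score is hazardous).
#'
#' @param scores named numeric IPS values.
#' @param time,event survival data aligned with `scores`.
#' @param horizon label horizon in months; default = median follow-up.
#' @param model optional `ips_model` to store the cutoff into.
#' @return list: `cutoff`, `results` (data.frame patient_id, ips_score,
#'   ips_class), `roc` (the [roc_youden()] output), `model` (updated
#'   copy when supplied).
#' @export
dichotomize <- function(scores, time, event, horizon = NULL, model = NULL) {
  check_survival(time, event)
  if (is.null(horizon)) horizon <- stats::median(time)
  dead <- time <= horizon & event == 1
  alive <- time > horizon
  use <- dead | alive
  if (!any(dead[use]) || !any(alive[use]))
    stop("both vital statuses must be present at the horizon")
  if (length(unique(scores[use])) == 1) {
    warning("all scores identical; a single class results")
    cutoff <- unique(scores[use])
    roc <- NULL
  } else {
    roc <- roc_youden(scores[use], as.integer(dead[use]))
    cutoff <- roc$cutoff
  }
  cls <- ifelse(scores <= cutoff, "Low", "High")
  ids <- names(scores)
  if (is.null(ids)) ids <- paste0("p", seq_along(scores))
  if (!is.null(model)) model$cutoff <- cutoff
  list(cutoff = cutoff,
       results = data.frame(patient_id = ids, ips_score = unname(scores),
                            ips_class = unname(cls),
                            stringsAsFactors = FALSE),
       roc = roc, model = model)
}

#' Biopsy applicability of the IPS
#'
#' Pairs biopsy IPS with postoperative IPS, excludes pairs whose
#' assessable tumor area falls below the threshold (default 0.16 mm^2,
#' strictly-below exclusion), and reports the Spearman correlation, the
#' AUC of the biopsy score for predicting the postoperative class, and
#' the retained n.  Sweep mode evaluates a threshold grid and reports
#' the AUC-maximizing threshold.
#'
#' @param ips_b,ips_p paired biopsy and postoperative scores.
#' @param tumor_area assessable tumor area per pair (mm^2).
#' @param area_threshold exclusion threshold (mm^2).
#' @param p_class optional postoperative class ("Low"/"High"); computed
#'   from the median of `ips_p` when absent.
#' @param sweep optional numeric grid of thresholds to evaluate.
#' @return list: rho, auc, n_retained, threshold; in sweep mode also
#'   `sweep` (data.frame threshold, rho, auc, n) and `best_threshold`.
#' @export
biopsy_applicability <- function(ips_b, ips_p, tumor_area,
                                 area_threshold = 0.16, p_class = NULL,
                                 sweep = NULL) {
  if (length(ips_b) != length(ips_p) || length(ips_b) != length(tumor_area))
    stop("paired inputs must have equal length")
  if (is.null(p_class))
    p_class <- ifelse(ips_p <= stats::median(ips_p), "Low", "High")
  eval_at <- function(thr) {
    keep <- tumor_area >= thr
    n <- sum(keep)
    if (n < 3) stop("validation error: < 3 retained pairs")
    rho <- spearman_test(ips_b[keep], ips_p[keep])$effect
    auc <- roc_youden(ips_b[keep], as.integer(p_class[keep] == "High"))$auc
    list(rho = rho, auc = auc, n = n)
  }
  main <- eval_at(area_threshold)
  out <- list(rho = main$rho, auc = main$auc, n_retained = main$n,
              threshold = area_threshold)
  if (!is.null(sweep)) {
    grid <- do.call(rbind, lapply(sweep, function(thr) {
      r <- tryCatch(eval_at(thr), error = function(e) NULL)
      if (is.null(r)) return(NULL)
      data.frame(threshold = thr, rho = r$rho, auc = r$auc, n = r$n)
    }))
    out$sweep <- grid
    out$best_threshold <- grid$threshold[which.max(grid$auc)]
  }
  out
}
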
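# Neoadjuvant ICI response evaluation: ORR/TRG tabulation, association
# reporting with the chi-square/Fisher choice rule, IPS x CPS Type A-D
# stratification, biomarker comparison, and recurrence-free survival.

#' Objective response rate
#'
#' (CR + PR) / n over patients with a RECIST category.
#'
#' @param recist character vector of CR/PR/SD/PD (NA allowed; excluded
#'   from the denominator with a message).
#' @return list(orr, responders, n).
#' @export
orr <- function(recist) {
  known <- !is.na(recist)
  if (!any(known)) stop("validation error: no patient with a RECIST category")
  if (any(!known)) message(sum(!known), " patient(s) without RECIST excluded")
  recist <- recist[known]
  bad <- setdiff(unique(recist), c("CR", "PR", "SD", "PD"))
  if (length(bad)) stop("unknown RECIST category: ", paste(bad, collapse = ", "))
  r <- sum(recist %in% c("CR", "PR"))
  list(orr = r / length(recist), responders = r, n = length(recist))
}

#' Binary Becker TRG response
#'
#' 1a/1b (subtotal or total regression) = responder; 2/3 =
#' non-responder; missing values are excluded from denominators and the
#' count is logged.
#'
#' @param trg character vector of 1a/1b/2/3 (NA allowed).
#' @return factor "responder"/"non_responder", NA preserved.
#' @export
trg_binary <- function(trg) {
  known <- !is.na(trg)
  bad <- setdiff(unique(trg[known]), c("1a", "1b", "2", "3"))
  if (length(bad)) stop("validation error: unknown TRG code ",
                        paste(bad, collapse = ", "))
  if (any(!known)) message(sum(!known), " patient(s) without TRG excluded")
  out <- ifelse(trg %in% c("1a", "1b"), "responder",
                ifelse(trg %in% c("2", "3"), "non_responder", NA))
  factor(out, levels = c("responder", "non_responder"))
}

#' IPS x CPS stratification into Types A-D
#'
#' A = (IPS-Low, CPS >= 5); B = (IPS-Low, CPS < 5); C = (IPS-High,
#' CPS >= 5); D = (IPS-High, CPS < 5).
#'
#' @param ips_class "Low"/"High" per patient.
#' @param cps numeric CPS per patient.
#' @return factor with levels A-D.
#' @export
stratify_types <- function(ips_class, cps) {
  if (any(is.na(ips_class)) || any(is.na(cps)))
    stop("validation error: missing input")
  if (!all(ips_class %in% c("Low", "High")))
    stop("validation error: ips_class must be Low/High")
  ge5 <- cps >= 5
  type <- ifelse(ips_class == "Low", ifelse(ge5, "A", "B"),
                 ifelse(ge5, "C", "D"))
  factor(type, levels = c("A", "B", "C", "D"))
}

endpoint_2x2 <- function(outcomes, endpoint) {
  grp <- outcomes$ips_class
  pos <- switch(endpoint,
    response = outcomes$recist %in% c("CR", "PR"),
    trg = outcomes$trg %in% c("1a", "1b"),
    ypt = outcomes$ypT %in% c("T0", "T1"),
    ypn = outcomes$ypN %in% c("N0"),
    yptnm = outcomes$ypTNM %in% c("pCR", "I"),
    stop("unknown endpoint"))
  present <- switch(endpoint,
    response = !is.na(outcomes$recist),
    trg = !is.na(outcomes$trg),
    ypt = !is.na(outcomes$ypT),
    ypn = !is.na(outcomes$ypN),
    yptnm = !is.na(outcomes$ypTNM))
  m <- rbind(c(sum(pos & present & grp == "Low"),
               sum(!pos & present & grp == "Low")),
             c(sum(pos & present & grp == "High"),
               sum(!pos & present & grp == "High")))
  dimnames(m) <- list(c("IPS_Low", "IPS_High"), c("favorable", "unfavorable"))
  m
}

#' Association report across neoadjuvant endpoints
#'
#' For each endpoint (Response CR/PR vs SD/PD, TRG 1a/1b vs 2/3, ypT
#' T0/T1 vs T2/T3, ypN N0 vs N1-3, ypTNM pCR/I vs II/III) the 2x2 table
#' against IPS class is built (patients missing that endpoint are
#' excluded from it only), both the uncorrected chi-square and Fisher's
#' exact test are computed, and the headline p comes from the
#' chi-square when every expected count is at least `min_expected`
#' (default 10), otherwise from Fisher.
#'
#' @param outcomes data.frame with ips_class, recist, trg, ypT, ypN,
#'   ypTNM (endpoint columns optional).
#' @param min_expected expected-count threshold of the test-choice rule.
#' @return data.frame: endpoint, counts, percentages, chisq_p,
#'   fisher_p, test_used, p.
#' @export
association_report <- function(outcomes, min_expected = 10) {
  if (length(unique(outcomes$ips_class)) < 2)
    stop("need both IPS classes")
  endpoints <- c("response", "trg", "ypt", "ypn", "yptnm")
  have <- c(response = "recist", trg = "trg", ypt = "ypT", ypn = "ypN",
            yptnm = "ypTNM")
  endpoints <- endpoints[have[endpoints] %in% names(outcomes)]
  rows <- lapply(endpoints, function(ep) {
    m <- endpoint_2x2(outcomes, ep)
    expd <- outer(rowSums(m), colSums(m)) / sum(m)
    chi <- tryCatch(chi_square_2x2(m), error = function(e) NULL)
    fis <- fisher_exact_2x2(m)
    use_chi <- all(expd >= min_expected) && !is.null(chi)
    data.frame(endpoint = ep,
               low_fav = m[1, 1], low_unfav = m[1, 2],
               high_fav = m[2, 1], high_unfav = m[2, 2],
               low_fav_pct = 100 * m[1, 1] / sum(m[1, ]),
               high_fav_pct = 100 * m[2, 1] / sum(m[2, ]),
               chisq_p = if (is.null(chi)) NA_real_ else chi$p_value,
               fisher_p = fis$p_value,
               test_used = if (use_chi) "chi_square" else "fisher",
               p = if (use_chi) chi$p_value else fis$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare biomarkers for predicting ICI response
#'
#' AUC per biomarker for the binary response label (TRG 1a/1b by
#' default, or RECIST CR/PR), univariate logistic odds ratios, and a
#' joint multivariate logistic model.  Constant biomarkers are excluded
#' with a warning.
#'
#' @param outcomes data.frame with trg and/or recist columns.
#' @param scores named list / data.frame of numeric biomarker values
#'   (e.g. ips_score, cps, inflamed indicator).
#' @param label `"trg"` (default) or `"recist"`.
#' @return list: `auc` (named), `univariate` (data.frame), `joint`
#'   (logistic_fit output or NULL).
#' @export
biomarker_compare <- function(outcomes, scores, label = c("trg", "recist")) {
  label <- match.arg(label)
  y <- if (label == "trg") as.integer(trg_binary(outcomes$trg) == "responder")
       else as.integer(outcomes$recist %in% c("CR", "PR"))
  keep <- !is.na(y)
  y <- y[keep]
  if (length(unique(y)) < 2) stop("response label has a single class")
  sc <- as.data.frame(scores)[keep, , drop = FALSE]
  const <- vapply(sc, function(v) stats::sd(v) == 0, logical(1))
  if (any(const)) {
    warning("excluding constant biomarker(s): ",
            paste(names(sc)[const], collapse = ", "))
    sc <- sc[, !const, drop = FALSE]
  }
  aucs <- vapply(sc, function(v) roc_youden(v, y)$auc, numeric(1))
  uni <- do.call(rbind, lapply(names(sc), function(nm) {
    f <- logistic_fit(y, matrix(sc[[nm]], ncol = 1,
                                dimnames = list(NULL, nm)))
    data.frame(biomarker = nm, or = unname(f$or[2]), p = unname(f$p[2]),
               separation = f$separation, stringsAsFactors = FALSE)
  }))
  joint <- if (ncol(sc) > 1) logistic_fit(y, as.matrix(sc)) else NULL
  list(auc = aucs, univariate = uni, joint = joint)
}

#' Recurrence-free survival by group
#'
#' Kaplan-Meier curves and the log-rank test on RFS.
#'
#' @param outcomes data.frame with rfs_months, rfs_event.
#' @param group grouping labels (default the IPS class).
#' @return [km_logrank()] output.
#' @export
rfs_analysis <- function(outcomes, group = outcomes$ips_class) {
  if (!all(c("rfs_months", "rfs_event") %in% names(outcomes)))
    stop("outcomes lack RFS fields")
  km_logrank(outcomes$rfs_months, outcomes$rfs_event, group)
}
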
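# Cross-cohort ranking of immune-phenotype-associated genes.  Per-cohort
# evidence (logFC, BH-adjusted p, AUC for predicting cluster A, Cox HR)
# is combined into a single weight per gene:
#
#   weight_total = sum_i  logFC_i * 2/(1 + adj_p_i) * |AUC_i - 0.5|
#                         * log2(HR_i) * n_i / N
#
# The weight formula is reconstructed from a typographically damaged
# source rendering ("LogFC×21+adj·pvalue×AUC−0.5×Log2HR×niN"); the
# factors are read as 2/(1+adj_p) and |AUC - 0.5| so that an
# uninformative gene (adj_p = 1, AUC = 0.5 or HR = 1) contributes
# nothing and evidence is averaged over cohorts in proportion to their
# size.

#' Moderated differential expression, cluster A vs rest
#'
#' Wraps limma's moderated t statistics: logFC is the A-vs-rest mean
#' difference on the log2 scale, p-values are BH-adjusted, and genes
#' passing the |logFC| and adjusted-p thresholds are flagged as DEGs.
#' Genes with zero variance in both groups get logFC 0, p 1, and a flag.
#'
#' @param expression genes x samples log2 matrix.
#' @param labels per-sample phenotype labels; `a_level` vs the rest.
#' @param a_level label treated as the activated group (default "A").
#' @param lfc_threshold,p_threshold DEG flag thresholds.
#' @param moderated use limma's empirical-Bayes moderation (default) or
#'   ordinary two-sample t statistics.
#' @return data.frame: gene, logfc, p, adj_p, deg (logical),
#'   zero_variance (logical).
#' @export
differential_expression <- function(expression, labels, a_level = "A",
                                    lfc_threshold = 0.5, p_threshold = 0.05,
                                    moderated = TRUE) {
  grp <- factor(ifelse(labels == a_level, "A", "rest"), levels = c("rest", "A"))
  if (min(table(grp)) < 2) stop("both groups need >= 2 samples")
  v <- apply(expression, 1, stats::var)
  zerovar <- v < 1e-300 | is.na(v)
  design <- stats::model.matrix(~grp)
  if (moderated) {
    fit <- limma::eBayes(limma::lmFit(expression, design))
    logfc <- fit$coefficients[, 2]
    p <- fit$p.value[, 2]
  } else {
    a <- expression[, grp == "A", drop = FALSE]
    r <- expression[, grp == "rest", drop = FALSE]
    logfc <- rowMeans(a) - rowMeans(r)
    p <- vapply(seq_len(nrow(expression)), function(i)
      tryCatch(stats::t.test(a[i, ], r[i, ])$p.value, error = function(e) 1),
      numeric(1))
  }
  logfc[zerovar] <- 0
  p[zerovar] <- 1
  p[is.na(p)] <- 1
  adj <- bh_adjust(p)
  data.frame(gene = rownames(expression), logfc = unname(logfc),
             p = unname(p), adj_p = unname(adj),
             deg = abs(logfc) > lfc_threshold & adj < p_threshold & !zerovar,
             zero_variance = unname(zerovar),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-gene AUC for predicting cluster A membership
#'
#' Rank-based (Mann-Whitney) AUC with tie averaging; all-tied
#' expression gives exactly 0.5.
#'
#' @param expr numeric expression vector for one gene.
#' @param labels per-sample labels; `a_level` is the positive class.
#' @param a_level positive-class label.
#' @return AUC in [0,1].
#' @export
gene_auc <- function(expr, labels, a_level = "A") {
  y <- as.integer(labels == a_level)
  if (length(unique(y)) < 2) stop("validation error: one class absent")
  n1 <- sum(y); n0 <- sum(1 - y)
  r <- rank(expr)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-gene univariate Cox hazard ratio
#'
#' HR per unit of standardized (z-scored) expression from the
#' self-contained Cox fit.
#'
#' @param expr expression vector for one gene.
#' @param time,event survival data.
#' @param standardize z-score expression first (default TRUE).
#' @return list(hr, coef, se, p).
#' @export
gene_cox_hr <- function(expr, time, event, standardize = TRUE) {
  x <- if (standardize && stats::sd(expr) > 0) as.numeric(scale(expr)) else expr
  f <- cox_ph(time, event, matrix(x, ncol = 1, dimnames = list(NULL, "expr")))
  if (length(f$coef) == 0)
    return(list(hr = 1, coef = 0, se = NA_real_, p = 1))
  list(hr = unname(f$hr[1]), coef = unname(f$coef[1]), se = unname(f$se[1]),
       p = unname(f$p[1]))
}

#' Assemble per-cohort gene evidence for the weight formula
#'
#' Runs differential expression per cohort (A vs rest), then computes
#' the per-cohort AUC and Cox HR for the genes in `genes` (default: the
#' union of per-cohort DEGs).  Expression is standardized per cohort
#' before AUC and Cox for cross-cohort comparability.
#'
#' @param cohorts named list; each element needs `expression` (genes x
#'   samples), `metadata` (with os_months, os_event), and a per-sample
#'   `imcluster` label vector (A/B/C) aligned with the expression
#'   columns.
#' @param genes genes to evaluate; NULL = union of per-cohort DEGs.
#' @param exclude_genes genes removed from consideration before ranking
#'   (typically the deconvolution-signature genes, to avoid circularity
#'   between fraction estimation and marker discovery).
#' @param lfc_threshold,p_threshold DEG thresholds passed through.
#' @return data.frame: gene, cohort, logfc, adj_p, auc, hr, n_i, N.
#' @export
build_gene_evidence <- function(cohorts, genes = NULL, exclude_genes = NULL,
                                lfc_threshold = 0.5, p_threshold = 0.05) {
  de <- lapply(cohorts, function(co)
    differential_expression(co$expression, co$imcluster,
                            lfc_threshold = lfc_threshold,
                            p_threshold = p_threshold))
  if (is.null(genes))
    genes <- sort(unique(unlist(lapply(de, function(d) d$gene[d$deg]))))
  genes <- setdiff(genes, exclude_genes)
  if (length(genes) == 0) stop("no DEGs at the given thresholds")
  n_i <- vapply(cohorts, function(co) ncol(co$expression), numeric(1))
  N <- sum(n_i)
  rows <- list()
  for (ci in seq_along(cohorts)) {
    co <- cohorts[[ci]]
    d <- de[[ci]]
    present <- intersect(genes, rownames(co$expression))
    idx <- match(present, d$gene)
    ez <- co$expression[present, , drop = FALSE]
    ez <- t(scale(t(ez)))  # per-cohort per-gene z-score
    ez[is.na(ez)] <- 0
    auc <- vapply(present, function(g) gene_auc(ez[g, ], co$imcluster),
                  numeric(1))
    hr <- vapply(present, function(g)
      gene_cox_hr(ez[g, ], co$metadata$os_months, co$metadata$os_event,
                  standardize = FALSE)$hr, numeric(1))
    rows[[ci]] <- data.frame(gene = present, cohort = names(cohorts)[ci],
                             logfc = d$logfc[idx], adj_p = d$adj_p[idx],
                             auc = auc, hr = hr, n_i = n_i[ci], N = N,
                             stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Cross-cohort evidence weight per gene
#'
#' Per-cohort contribution: logFC * 2/(1+adj_p) * |AUC - 0.5| *
#' log2(HR) * n_i/N; cohorts missing a gene contribute 0; the total is
#' the sum over cohorts.  Ranking (see [rank_top()]) uses
#' |weight_total| by default so that protective and hazardous markers
#' both surface.
#'
#' @param evidence data.frame from [build_gene_evidence()] (columns
#'   gene, cohort, logfc, adj_p, auc, hr, n_i, N).
#' @return data.frame: gene, weight_total, rank, plus a `contributions`
#'   attribute (per gene x cohort).
#' @export
eq1_weight <- function(evidence) {
  req <- c("gene", "cohort", "logfc", "adj_p", "auc", "hr", "n_i", "N")
  if (!all(req %in% names(evidence))) stop("evidence is missing columns")
  if (any(evidence$hr <= 0)) stop("validation error: hr must be positive")
  if (any(evidence$adj_p < 0 | evidence$adj_p > 1))
    stop("validation error: adj_p outside [0,1]")
  if (any(evidence$auc < 0 | evidence$auc > 1))
    stop("validation error: auc outside [0,1]")
  contrib <- evidence$logfc * (2 / (1 + evidence$adj_p)) *
    abs(evidence$auc - 0.5) * log2(evidence$hr) * (evidence$n_i / evidence$N)
  agg <- tapply(contrib, evidence$gene, sum)
  out <- data.frame(gene = names(agg), weight_total = as.numeric(agg),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-abs(out$weight_total), out$gene), ]
  out$rank <- seq_len(nrow(out))
  attr(out, "contributions") <-
    data.frame(gene = evidence$gene, cohort = evidence$cohort,
               contribution = contrib, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Top-m genes by absolute weight
#'
#' @param weights data.frame from [eq1_weight()].
#' @param m number of genes to keep.
#' @param signed rank by signed weight (descending) instead of
#'   |weight|.
#' @return character vector of gene ids, deterministic tie-break by id.
#' @export
rank_top <- function(weights, m, signed = FALSE) {
  if (m > nrow(weights)) stop("m exceeds the number of genes")
  key <- if (signed) -weights$weight_total else -abs(weights$weight_total)
  ord <- order(key, weights$gene)
  weights$gene[ord][seq_len(m)]
}

#' Transcript-protein concordance filter
#'
#' Per-gene Spearman correlation between mRNA and H-score over paired
#' samples; genes ranked by ascending p (ties by descending |rho|, then
#' id) and the top m returned.
#'
#' @param mrna samples x genes (or genes x samples) expression matrix.
#' @param h_score samples x genes H-score matrix, same genes.
#' @param m number of genes to keep (paper-scale default 8).
#' @return data.frame of the top m: gene, rho, p, ordered by rank.
#' @export
concordance_filter <- function(mrna, h_score, m = 8) {
  genes <- colnames(h_score)
  if (!all(genes %in% colnames(mrna)) && all(genes %in% rownames(mrna)))
    mrna <- t(mrna)
  if (!all(genes %in% colnames(mrna))) stop("mrna lacks the staining panel genes")
  common <- intersect(rownames(mrna), rownames(h_score))
  if (length(common) < 3) stop("validation error: < 3 paired samples")
  res <- do.call(rbind, lapply(genes, function(g) {
    t <- spearman_test(mrna[common, g], h_score[common, g])
    data.frame(gene = g, rho = t$effect, p = t$p_value,
               stringsAsFactors = FALSE)
  }))
  res <- res[order(res$p, -abs(res$rho), res$gene), ]
  rownames(res) <- NULL
  utils::head(res, m)
}
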
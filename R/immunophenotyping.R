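# Immune-fraction estimation and resampling consensus clustering into
# the three immune phenotypes (IMclusters), with cluster A defined as
# the immune-activated cluster.

#' Estimate immune-cell fractions by non-negative deconvolution
#'
#' For each sample, solves non-negative least squares of (linear-scale)
#' expression on the signature columns restricted to the signature genes
#' present in the expression matrix, then normalizes the coefficients to
#' sum to 1.  This is a declared linear stand-in for support-vector
#' deconvolution: the pipeline only requires valid fraction estimates.
#'
#' @param expression genes x samples matrix (log2 scale by default; set
#'   `log2_input = FALSE` if already linear).
#' @param signature genes x cell-types non-negative reference matrix
#'   (default [default_signature()]).
#' @param log2_input is `expression` on the log2 scale?
#' @return samples x cell-types fraction matrix, rows summing to 1.
#' @export
estimate_fractions <- function(expression, signature = default_signature(),
                               log2_input = TRUE) {
  if (any(colSums(signature) == 0)) stop("signature has an all-zero column")
  common <- intersect(rownames(signature), rownames(expression))
  if (length(common) < 2)
    stop("validation error: fewer than 2 signature genes found in expression")
  s <- signature[common, , drop = FALSE]
  e <- expression[common, , drop = FALSE]
  if (log2_input) e <- 2^e - 1
  e[e < 0] <- 0
  frac <- t(apply(e, 2, function(v) {
    beta <- pracma::lsqnonneg(s, v)$x
    if (sum(beta) <= 0) rep(1 / ncol(s), ncol(s)) else beta / sum(beta)
  }))
  colnames(frac) <- colnames(signature)
  frac
}

#' Resampling consensus clustering of immune fractions
#'
#' Repeatedly subsamples the samples, clusters each subsample (Ward
#' hierarchical clustering on Euclidean distance, or k-means), and
#' records for every sample pair the fraction of co-sampled draws in
#' which the pair co-clustered.  Fractions are standardized per cell
#' type before clustering.  Final labels for each k come from Ward
#' clustering of 1 - consensus.
#'
#' @param fractions samples x cell-types matrix.
#' @param k_range integer vector of cluster numbers to evaluate.
#' @param reps number of subsample draws (>= 2).
#' @param subsample proportion of samples per draw, in (0, 1].
#' @param backend "hclust_ward" or "kmeans".
#' @param seed integer seed; runs are deterministic given it.
#' @param scale_fractions z-score each cell type before clustering?
#' @return `consensus_result`: list with `k_range`, `consensus` (named
#'   list of samples x samples matrices), `labels` (matrix, one column
#'   per k), `consensus_score` (per-sample mean within-cluster consensus
#'   at each k), `area` (consensus-CDF area per k).
#' @export
consensus_cluster <- function(fractions, k_range = 2:6, reps = 1000,
                              subsample = 0.8,
                              backend = c("hclust_ward", "kmeans"),
                              seed = 1L, scale_fractions = TRUE) {
  backend <- match.arg(backend)
  if (reps < 2) stop("reps must be >= 2")
  if (subsample <= 0 || subsample > 1) stop("subsample must lie in (0, 1]")
  n <- nrow(fractions)
  if (min(k_range) < 2 || max(k_range) > n - 1)
    stop("k_range must lie within [2, samples - 1]")
  s <- max(2L, floor(subsample * n))
  if (max(k_range) > s)
    stop("configuration error: k exceeds the subsampled size")
  z <- if (scale_fractions) scale(fractions) else as.matrix(fractions)
  z[is.na(z)] <- 0
  ids <- rownames(fractions)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))

  set.seed(seed)
  nk <- length(k_range)
  conn <- lapply(seq_len(nk), function(i) matrix(0, n, n))
  cnt <- matrix(0, n, n)
  for (r in seq_len(reps)) {
    idx <- if (subsample >= 1) seq_len(n) else sort(sample.int(n, s))
    cnt[idx, idx] <- cnt[idx, idx] + 1
    zi <- z[idx, , drop = FALSE]
    if (backend == "hclust_ward") {
      hc <- stats::hclust(stats::dist(zi), method = "ward.D2")
      for (ki in seq_len(nk)) {
        cl <- stats::cutree(hc, k_range[ki])
        for (gcl in unique(cl)) {
          ii <- idx[cl == gcl]
          conn[[ki]][ii, ii] <- conn[[ki]][ii, ii] + 1
        }
      }
    } else {
      for (ki in seq_len(nk)) {
        cl <- stats::kmeans(zi, centers = k_range[ki], nstart = 3)$cluster
        for (gcl in unique(cl)) {
          ii <- idx[cl == gcl]
          conn[[ki]][ii, ii] <- conn[[ki]][ii, ii] + 1
        }
      }
    }
  }
  consensus <- lapply(conn, function(m) {
    cm <- m / pmax(cnt, 1)
    cm[cnt == 0] <- 0
    diag(cm) <- 1
    dimnames(cm) <- list(ids, ids)
    cm
  })
  names(consensus) <- paste0("k", k_range)
  labels <- matrix(NA_integer_, n, nk, dimnames = list(ids, paste0("k", k_range)))
  score <- matrix(NA_real_, n, nk, dimnames = list(ids, paste0("k", k_range)))
  area <- numeric(nk)
  grid <- seq(0, 1, by = 0.01)
  for (ki in seq_len(nk)) {
    cm <- consensus[[ki]]
    hc <- stats::hclust(stats::as.dist(1 - cm), method = "ward.D2")
    cl <- stats::cutree(hc, k_range[ki])
    labels[, ki] <- cl
    for (gcl in unique(cl)) {
      mem <- which(cl == gcl)
      score[mem, ki] <- if (length(mem) > 1)
        rowMeans(cm[mem, mem, drop = FALSE]) else 1
    }
    v <- cm[upper.tri(cm)]
    cdf <- stats::ecdf(v)
    area[ki] <- sum(diff(grid) * cdf(grid[-1]))
  }
  structure(list(k_range = k_range, consensus = consensus, labels = labels,
                 consensus_score = score, area = area, backend = backend,
                 reps = reps, subsample = subsample, seed = seed),
            class = "consensus_result")
}

#' Choose the number of clusters from a consensus run
#'
#' Delta-area elbow rule: let A(k) be the area under the consensus-CDF
#' and Delta(k) the relative area gain (Delta(2) = A(2), Delta(k) =
#' (A(k) - A(k-1)) / A(k-1)).  The chosen k is the one after which the
#' relative gain drops the most, i.e. argmax of Delta(k) - Delta(k+1).
#' When no pronounced drop exists (flat curve, `flat_tol`), the smallest
#' k is returned with a warning.  `override` short-circuits the rule.
#'
#' @param result a `consensus_result`.
#' @param override fixed k to return regardless of the rule (e.g. 3).
#' @param flat_tol minimum drop in relative gain regarded as an elbow.
#' @return chosen k (integer).
#' @export
select_k <- function(result, override = NULL, flat_tol = 0.05) {
  if (!inherits(result, "consensus_result")) stop("validation error: need a consensus_result")
  if (!is.null(override)) return(as.integer(override))
  kr <- result$k_range
  if (length(kr) < 2) stop("validation error: need >= 2 values of k")
  a <- result$area
  d <- c(a[1], diff(a) / a[-length(a)])
  drop_after <- d[-length(d)] - d[-1]
  if (max(drop_after) < flat_tol) {
    warning("delta-area curve is flat; returning the smallest k")
    return(as.integer(min(kr)))
  }
  as.integer(kr[which.max(drop_after)])
}

#' Map cluster labels to immune phenotypes A/B/C
#'
#' The cluster with the highest mean activation composite (CD8 T +
#' activated memory CD4 + M1 fractions) is labeled A (immune-activated);
#' the remaining clusters are labeled B, C by descending composite.
#' Ties beyond 1e-12 are broken deterministically by cluster index with
#' a warning.
#'
#' @param labels integer/character cluster labels per sample.
#' @param fractions samples x cell-types matrix with columns including
#'   CD8T, CD4mem_act, M1.
#' @return character vector of "A"/"B"/"C"... per sample, named as
#'   `labels`.
#' @export
assign_imcluster <- function(labels, fractions) {
  labels <- as.character(labels)
  ulab <- sort(unique(labels))
  if (length(ulab) < 2) stop("validation error: need >= 2 clusters")
  comp_cols <- intersect(c("CD8T", "CD4mem_act", "M1"), colnames(fractions))
  if (length(comp_cols) == 0) stop("fractions lack activation components")
  comp <- vapply(ulab, function(l)
    mean(rowSums(fractions[labels == l, comp_cols, drop = FALSE])), numeric(1))
  if (anyDuplicated(signif(comp, 12)))
    warning("activation composite tie; breaking by cluster index")
  ord <- order(-comp, ulab)
  map <- stats::setNames(LETTERS[seq_along(ulab)], ulab[ord])
  out <- unname(map[labels])
  nm <- names(labels)
  if (is.null(nm) && !is.null(rownames(fractions))) nm <- rownames(fractions)
  names(out) <- nm
  out
}
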
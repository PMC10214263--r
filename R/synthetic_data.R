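# Synthetic multi-cohort gastric-cancer TME data with planted ground truth.
# Defaults emulate a five-dataset discovery compendium: three immune
# phenotypes driven by five immune-cell fractions, marker genes with a
# planted cluster-A log-fold-change and survival effect, cohort batch
# offsets, H-scores copula-linked to mRNA, and neoadjuvant outcomes driven
# by IPS class and CPS class on the logit scale.

#' Reference mean immune-fraction profiles of the three planted clusters
#'
#' Rows A (immune-activated), B, C; columns the five cell types. Each
#' row sums to 1.
#'
#' @return 3 x 5 matrix.
#' @export
default_fraction_profiles <- function() {
  m <- rbind(
    A = c(0.35, 0.25, 0.10, 0.20, 0.10),  # immune-activated
    B = c(0.15, 0.10, 0.35, 0.10, 0.30),
    C = c(0.08, 0.07, 0.30, 0.05, 0.50))
  colnames(m) <- c("CD8T", "CD4mem_act", "CD4mem_rest", "M1", "M2")
  m
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator and validates the
#' structural invariants.  Defaults define the reference study
#' conditions used throughout the test-suite: five cohorts totalling 500
#' patients, 2000 background genes plus 30 planted phenotype markers, a
#' planted three-cluster immune structure over five cell-type fractions,
#' exponential survival with log-linear cluster and marker effects, and
#' a Gaussian-copula mRNA/H-score link.
#'
#' @param n_cohorts number of cohorts.
#' @param samples_per_cohort integer vector of per-cohort sample counts.
#' @param n_genes number of background (null) genes.
#' @param n_marker_genes number of planted marker genes.
#' @param cluster_proportions length-3 probabilities of clusters A/B/C.
#' @param fraction_profiles 3 x 5 matrix of mean immune-cell fractions
#'   per planted cluster (rows sum to 1).
#' @param fraction_concentration Dirichlet precision of per-sample
#'   fractions around the cluster profile.
#' @param marker_logfc planted cluster-A-vs-rest mean difference for
#'   marker genes (log2 units).
#' @param marker_hr hazard ratio per SD of the latent risk covariate.
#'   The risk covariate is the negated standardized mean of the
#'   `n_prognostic_markers` prognostic markers: immune-activation
#'   markers are protective, so the immune-activated cluster (which
#'   overexpresses them) has the better prognosis, mirroring the
#'   biology the pipeline assumes.
#' @param n_prognostic_markers how many of the marker genes carry the
#'   survival effect (the first ones; default 5, matching a five-gene
#'   risk panel).
#' @param cluster_hazard additional log-hazard offsets for clusters
#'   A/B/C (default 0: prognosis differences between phenotypes arise
#'   through the marker score alone, keeping the planted survival law
#'   identifiable from its single covariate).
#' @param baseline_hazard exponential baseline event rate (1/month).
#' @param censoring_rate exponential censoring rate (1/month).
#' @param batch_sd SD of per-cohort additive gene offsets.
#' @param gene_sd residual SD of log2 expression.
#' @param concordance_rho target within-cohort Spearman correlation
#'   between marker mRNA and H-score, in [0,1].
#' @param response_model named numeric: logit-scale intercept and
#'   coefficients `ips_low` and `cps_high` for responder probability.
#' @param seed integer master seed; per-stage substreams are derived
#'   from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cohorts = 5,
                       samples_per_cohort = c(120, 100, 90, 110, 80),
                       n_genes = 2000,
                       n_marker_genes = 30,
                       cluster_proportions = c(0.35, 0.35, 0.30),
                       fraction_profiles = default_fraction_profiles(),
                       fraction_concentration = 100,
                       marker_logfc = 1.5,
                       marker_hr = 2.0,
                       n_prognostic_markers = 5,
                       cluster_hazard = c(A = 0, B = 0, C = 0),
                       baseline_hazard = 0.02,
                       censoring_rate = 0.01,
                       batch_sd = 0.3,
                       gene_sd = 1,
                       concordance_rho = 0.8,
                       response_model = c(intercept = -1.79, ips_low = 1.8,
                                          cps_high = 1.7),
                       seed = 1L) {
  cfg <- list(n_cohorts = n_cohorts, samples_per_cohort = samples_per_cohort,
              n_genes = n_genes, n_marker_genes = n_marker_genes,
              cluster_proportions = cluster_proportions,
              fraction_profiles = fraction_profiles,
              fraction_concentration = fraction_concentration,
              marker_logfc = marker_logfc, marker_hr = marker_hr,
              n_prognostic_markers = n_prognostic_markers,
              cluster_hazard = cluster_hazard,
              baseline_hazard = baseline_hazard,
              censoring_rate = censoring_rate, batch_sd = batch_sd,
              gene_sd = gene_sd, concordance_rho = concordance_rho,
              response_model = response_model, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_cohorts < 1 || any(cfg$samples_per_cohort <= 0))
    stop("configuration error: cohort and sample counts must be positive")
  if (length(cfg$samples_per_cohort) != cfg$n_cohorts)
    stop("configuration error: samples_per_cohort length != n_cohorts")
  if (cfg$n_genes <= 0) stop("configuration error: n_genes must be positive")
  if (cfg$n_marker_genes > cfg$n_genes)
    stop("configuration error: n_marker_genes exceeds n_genes")
  if (cfg$n_prognostic_markers > cfg$n_marker_genes)
    stop("configuration error: n_prognostic_markers exceeds n_marker_genes")
  if (abs(sum(cfg$cluster_proportions) - 1) > 1e-12)
    stop("configuration error: cluster_proportions must sum to 1")
  fp <- cfg$fraction_profiles
  if (!all(dim(fp) == c(3, 5)))
    stop("configuration error: fraction_profiles must be 3 x 5")
  if (any(fp < 0) || any(abs(rowSums(fp) - 1) > 1e-12))
    stop("configuration error: fraction_profiles rows must be non-negative and sum to 1")
  if (cfg$concordance_rho < 0 || cfg$concordance_rho > 1)
    stop("configuration error: concordance_rho must lie in [0,1]")
  invisible(cfg)
}

# Derive a deterministic per-stage substream seed from the master seed.
stage_seed <- function(seed, stage) {
  stages <- c(cohorts = 1L, ihc = 2L, neoadjuvant = 3L, clustering = 4L,
              misc = 5L)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, length(stages))
  sub[stages[[stage]]]
}

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Reference signature matrix for the five immune cell types
#'
#' Block-structured non-negative matrix (10 genes per cell type) used
#' both by the generator to embed deconvolvable signal and by
#' [estimate_fractions()] as the default reference.
#'
#' @param genes_per_type signature genes per cell type.
#' @param on,off expression of a signature gene in its own / other types.
#' @return genes x 5 numeric matrix with rownames `sig_<type>_<j>`.
#' @export
default_signature <- function(genes_per_type = 10, on = 100, off = 5) {
  types <- colnames(default_fraction_profiles())
  g <- genes_per_type * length(types)
  m <- matrix(off, g, length(types), dimnames = list(NULL, types))
  rn <- character(g)
  for (i in seq_along(types)) {
    rows <- (i - 1) * genes_per_type + seq_len(genes_per_type)
    m[rows, i] <- on
    rn[rows] <- paste0("sig_", types[i], "_", seq_len(genes_per_type))
  }
  rownames(m) <- rn
  m
}

#' Generate multi-cohort expression, fractions, and survival
#'
#' Samples cluster labels from `cluster_proportions`, per-sample immune
#' fractions from a Dirichlet around the cluster profile, log2
#' expression with the planted marker effect and per-cohort batch
#' offsets, signature-gene expression driven by the true fractions, and
#' exponential survival whose log-hazard is linear in cluster membership
#' and the standardized marker score.
#'
#' @param config a [sim_config()].
#' @return list with `cohorts` (named list; each has `expression`
#'   (genes x samples log2 matrix), `metadata` (sample_id, cohort,
#'   os_months, os_event), `fractions` (samples x 5)), and `truth`
#'   (cluster label per sample, marker gene ids, prognostic marker ids,
#'   and `marker_score`, the planted per-sample risk covariate whose
#'   coefficient in the survival law is log(marker_hr)).
#' @export
generate_cohorts <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "cohorts"))
  types <- colnames(config$fraction_profiles)
  markers <- sprintf("mk%03d", seq_len(config$n_marker_genes))
  null_genes <- sprintf("gn%04d", seq_len(config$n_genes - config$n_marker_genes))
  sig <- default_signature()
  genes <- c(markers, null_genes, rownames(sig))
  base_mean <- stats::rnorm(length(genes), 6, 1.5)
  names(base_mean) <- genes

  cohorts <- vector("list", config$n_cohorts)
  names(cohorts) <- sprintf("cohort%d", seq_len(config$n_cohorts))
  all_labels <- character(0)
  all_ids <- character(0)
  marker_signal <- numeric(0)

  for (ci in seq_len(config$n_cohorts)) {
    n <- config$samples_per_cohort[ci]
    ids <- sprintf("%s_s%03d", names(cohorts)[ci], seq_len(n))
    lab <- sample(c("A", "B", "C"), n, replace = TRUE,
                  prob = config$cluster_proportions)
    frac <- matrix(NA_real_, n, length(types), dimnames = list(ids, types))
    for (l in c("A", "B", "C")) {
      idx <- which(lab == l)
      if (length(idx))
        frac[idx, ] <- rdirichlet(length(idx),
          config$fraction_profiles[l, ] * config$fraction_concentration)
    }
    expr <- matrix(stats::rnorm(length(genes) * n, base_mean, config$gene_sd),
                   nrow = length(genes), dimnames = list(genes, ids))
    is_a <- lab == "A"
    expr[markers, is_a] <- expr[markers, is_a] + config$marker_logfc
    # signature genes track the true fractions on the linear scale
    sig_lin <- sig %*% t(frac)                       # sig genes x samples
    expr[rownames(sig), ] <- log2(1 + sig_lin * 50) +
      matrix(stats::rnorm(nrow(sig) * n, 0, 0.1), nrow(sig))
    batch <- stats::rnorm(length(genes), 0, config$batch_sd)
    expr_obs <- expr + batch
    # latent per-sample marker signal, pre-batch (clean planted truth);
    # carried only by the prognostic subset of the markers
    prog <- markers[seq_len(config$n_prognostic_markers)]
    msig <- colMeans(expr[prog, , drop = FALSE])
    cohorts[[ci]] <- list(expression = expr_obs,
                          fractions = frac,
                          metadata = data.frame(sample_id = ids,
                                                cohort = names(cohorts)[ci],
                                                stringsAsFactors = FALSE))
    all_labels <- c(all_labels, stats::setNames(lab, ids))
    all_ids <- c(all_ids, ids)
    marker_signal <- c(marker_signal, msig)
  }

  # risk covariate: activation markers are protective, so risk is the
  # negated standardized marker signal
  z <- -as.numeric(scale(marker_signal))
  names(z) <- all_ids
  loghaz <- log(config$baseline_hazard) +
    config$cluster_hazard[all_labels] + log(config$marker_hr) * z
  t_event <- stats::rexp(length(all_ids), rate = exp(loghaz))
  t_cens <- pmin(stats::rexp(length(all_ids), rate = config$censoring_rate), 120)
  os <- pmin(t_event, t_cens)
  ev <- as.integer(t_event <= t_cens)
  names(os) <- names(ev) <- all_ids
  for (ci in seq_along(cohorts)) {
    ids <- cohorts[[ci]]$metadata$sample_id
    cohorts[[ci]]$metadata$os_months <- unname(os[ids])
    cohorts[[ci]]$metadata$os_event <- unname(ev[ids])
  }
  truth <- list(cluster = all_labels[all_ids], marker_genes = markers,
                prognostic_markers = markers[seq_len(config$n_prognostic_markers)],
                marker_score = z)
  list(cohorts = cohorts, truth = truth)
}

#' Generate IHC readouts coupled to expression
#'
#' H-scores are linked to marker mRNA by a Gaussian copula at the target
#' Spearman correlation (per cohort); regional CD8 densities, field-level
#' count tables, M1/M2 densities and PD-L1 CPS inputs reflect the planted
#' cluster (cluster A is immune-hot: higher core-of-tumor densities and
#' CPS).
#'
#' @param config a [sim_config()].
#' @param sim output of [generate_cohorts()].
#' @param genes genes to stain; defaults to all planted markers.
#' @param rho per-gene target Spearman correlation, recycled; defaults to
#'   `concordance_rho` for the first 8 genes and 0 for the rest,
#'   mirroring a panel in which only some antibodies track transcript
#'   level.
#' @return list with `h_scores` (samples x genes, in [0,300]),
#'   `densities` (per patient: cd8_ct, cd8_im, m1_ct, m2_ct), `fields`
#'   (long field-count table: patient, marker, region, field, count,
#'   area_mm2), `cps_table` (patient, pd_l1_positive_cells,
#'   viable_tumor_cells, cps).
#' @export
generate_ihc <- function(config, sim, genes = NULL, rho = NULL) {
  validate_sim_config(config)
  if (config$concordance_rho < 0 || config$concordance_rho > 1)
    stop("configuration error: concordance_rho outside [0,1]")
  set.seed(stage_seed(config$seed, "ihc"))
  if (is.null(genes)) genes <- sim$truth$marker_genes
  if (is.null(rho)) {
    rho <- rep(0, length(genes))
    rho[seq_len(min(8, length(genes)))] <- config$concordance_rho
  }
  rho <- rep_len(rho, length(genes))
  if (any(rho < -1 | rho > 1)) stop("configuration error: rho outside [-1,1]")

  ids <- unlist(lapply(sim$cohorts, function(co) co$metadata$sample_id),
                use.names = FALSE)
  h <- matrix(NA_real_, length(ids), length(genes),
              dimnames = list(ids, genes))
  for (co in sim$cohorts) {
    cid <- co$metadata$sample_id
    n <- length(cid)
    for (j in seq_along(genes)) {
      e <- co$expression[genes[j], cid]
      u <- rank(e, ties.method = "average") / (n + 1)
      zm <- stats::qnorm(u)
      zh <- rho[j] * zm + sqrt(max(0, 1 - rho[j]^2)) * stats::rnorm(n)
      # rho = 1 keeps H a strictly monotone transform of mRNA
      h[cid, j] <- 300 * stats::pnorm(zh)
    }
  }

  lab <- sim$truth$cluster[ids]
  dens_mu <- list(A = c(ct = log(150), im = log(80)),
                  B = c(ct = log(40), im = log(60)),
                  C = c(ct = log(8), im = log(10)))
  cd8_ct <- exp(vapply(lab, function(l) dens_mu[[l]]["ct"], numeric(1)) +
                stats::rnorm(length(ids), 0, 0.5))
  cd8_im <- exp(vapply(lab, function(l) dens_mu[[l]]["im"], numeric(1)) +
                stats::rnorm(length(ids), 0, 0.5))
  frac <- do.call(rbind, lapply(sim$cohorts, function(co) co$fractions))[ids, ]
  m1_ct <- 800 * frac[, "M1"] * exp(stats::rnorm(length(ids), 0, 0.3))
  m2_ct <- 800 * frac[, "M2"] * exp(stats::rnorm(length(ids), 0, 0.3))
  densities <- data.frame(patient = ids, cluster = lab, cd8_ct = cd8_ct,
                          cd8_im = cd8_im, m1_ct = m1_ct, m2_ct = m2_ct,
                          stringsAsFactors = FALSE, row.names = NULL)

  # five 200x fields per region; Poisson counts around density * area
  np <- length(ids)
  fields <- data.frame(
    patient = rep(ids, each = 10),
    marker = "CD8",
    region = rep(rep(c("CT", "IM"), each = 5), np),
    field = rep(1:5, 2 * np),
    stringsAsFactors = FALSE)
  dens <- as.vector(apply(cbind(cd8_ct, cd8_im), 1,
                          function(r) rep(r, each = 5)))
  area <- 0.35 * exp(stats::rnorm(10 * np, 0, 0.05))
  fields$area_mm2 <- area
  fields$count <- stats::rpois(10 * np, dens * area)

  cps_mu <- c(A = 15, B = 5, C = 2)
  viable <- stats::rpois(length(ids), 1000)
  pos <- stats::rpois(length(ids), viable * cps_mu[lab] / 100)
  cps_table <- data.frame(patient = ids,
                          pd_l1_positive_cells = pos,
                          viable_tumor_cells = pmax(viable, 1),
                          stringsAsFactors = FALSE)
  cps_table$cps <- pmin(100, 100 * cps_table$pd_l1_positive_cells /
                          cps_table$viable_tumor_cells)
  list(h_scores = h, densities = densities, fields = fields,
       cps_table = cps_table)
}

#' Generate neoadjuvant-ICI outcome tables
#'
#' Responder status is Bernoulli with logit-linear probability in IPS
#' class (Low) and CPS class (>= 5) from `response_model`; RECIST and
#' Becker TRG categories are mapped from (noisy copies of) that latent
#' status, and recurrence-free survival has a lower hazard for
#' responders.
#'
#' @param config a [sim_config()].
#' @param ips_class character vector, "Low"/"High", one per patient.
#' @param cps_class logical (or 0/1): CPS >= 5 flag per patient.
#' @return data.frame with patient_id, ips_class, cps_class, recist,
#'   trg, ypT, ypN, ypTNM, rfs_months, rfs_event, plus attribute
#'   `latent_p` (true responder probability).
#' @export
generate_neoadjuvant <- function(config, ips_class, cps_class) {
  validate_sim_config(config)
  if (length(ips_class) != length(cps_class))
    stop("validation error: ips_class and cps_class lengths differ")
  if (any(is.na(ips_class)) || any(is.na(cps_class)))
    stop("validation error: missing class labels")
  if (!all(ips_class %in% c("Low", "High")))
    stop("validation error: ips_class must be Low/High")
  set.seed(stage_seed(config$seed, "neoadjuvant"))
  n <- length(ips_class)
  b <- config$response_model
  eta <- b[["intercept"]] + b[["ips_low"]] * (ips_class == "Low") +
    b[["cps_high"]] * (as.numeric(cps_class) > 0)
  p <- stats::plogis(eta)
  resp <- stats::rbinom(n, 1, p)
  recist <- ifelse(resp == 1,
                   ifelse(stats::runif(n) < 0.15, "CR", "PR"),
                   ifelse(stats::runif(n) < 0.6, "SD", "PD"))
  # pathological response tracks the radiological one imperfectly
  resp_path <- ifelse(stats::runif(n) < 0.85, resp, 1 - resp)
  trg <- ifelse(resp_path == 1,
                ifelse(stats::runif(n) < 0.4, "1a", "1b"),
                ifelse(stats::runif(n) < 0.5, "2", "3"))
  ypT <- ifelse(resp_path == 1,
                ifelse(stats::runif(n) < 0.7, sample(c("T0", "T1"), n, TRUE), "T2"),
                sample(c("T2", "T3"), n, TRUE))
  ypN <- ifelse(stats::runif(n) < ifelse(resp_path == 1, 0.8, 0.3), "N0",
                sample(c("N1", "N2", "N3"), n, TRUE))
  ypTNM <- ifelse(resp_path == 1 & ypN == "N0",
                  ifelse(trg == "1a", "pCR", "I"),
                  sample(c("II", "III"), n, TRUE))
  rfs_haz <- 0.02 * exp(-1.2 * resp_path)
  t_rec <- stats::rexp(n, rfs_haz)
  t_cens <- pmin(stats::rexp(n, 0.015), 36)
  out <- data.frame(patient_id = sprintf("nici_%03d", seq_len(n)),
                    ips_class = ips_class,
                    cps_class = as.integer(as.numeric(cps_class) > 0),
                    recist = recist, trg = trg, ypT = ypT, ypN = ypN,
                    ypTNM = ypTNM,
                    rfs_months = pmin(t_rec, t_cens),
                    rfs_event = as.integer(t_rec <= t_cens),
                    stringsAsFactors = FALSE)
  attr(out, "latent_p") <- p
  out
}
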
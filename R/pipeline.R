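# End-to-end orchestration: simulate -> cluster -> rank -> concord ->
# select -> fit/score -> respond, with every intermediate written as
# CSV/TSV so any stage can be resumed from disk, and a manifest
# recording the config hash and output checksums.

#' Pipeline configuration
#'
#' @param out_dir output directory (created if absent).
#' @param sim a [sim_config()] driving the synthetic stage.
#' @param reps,k_range,subsample consensus-clustering controls.
#' @param k_override fixed cluster number (default 3, mirroring the
#'   reference analysis; NULL to use the delta-area rule).
#' @param top_m markers kept from the weight ranking.
#' @param concord_m genes kept by the concordance filter.
#' @param rsf_threshold survival-forest importance cutoff.
#' @param youden_horizon months; NULL = median follow-up.
#' @param n_neoadjuvant size of the simulated neoadjuvant cohort.
#' @param seed master seed (overrides `sim$seed` when given).
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, sim = sim_config(), reps = 200,
                            k_range = 2:6, subsample = 0.8, k_override = 3,
                            top_m = 30, concord_m = 8, rsf_threshold = 0.01,
                            youden_horizon = NULL, n_neoadjuvant = 52,
                            seed = NULL) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, sim = sim, reps = reps, k_range = k_range,
                 subsample = subsample, k_override = k_override, top_m = top_m,
                 concord_m = concord_m, rsf_threshold = rsf_threshold,
                 youden_horizon = youden_horizon,
                 n_neoadjuvant = n_neoadjuvant),
            class = "pipeline_config")
}

pipe_path <- function(cfg, ...) file.path(cfg$out_dir, ...)

stage_done <- function(cfg, files) all(file.exists(pipe_path(cfg, files)))

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full pipeline
#'
#' Executes the stages in order, writing per-stage outputs under
#' `out_dir`; stages whose outputs already exist are skipped when
#' `resume = TRUE`, so deleting an intermediate file and re-running
#' regenerates it (identically, given the same config).  All
#' randomness flows from the config seed.
#'
#' @param cfg a [pipeline_config()].
#' @param resume skip stages whose outputs exist (default TRUE).
#' @return the run manifest (list), also written as manifest.json.
#' @export
run_pipeline <- function(cfg, resume = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  co_names <- sprintf("cohort%d", seq_len(cfg$sim$n_cohorts))
  expr_files <- paste0("expression_", co_names, ".tsv")
  sim_files <- c(expr_files, "metadata.csv", "fractions.csv", "h_scores.csv",
                 "truth.csv", "cps.csv")

  # -- stage: simulate ----------------------------------------------------
  t0 <- tic()
  if (!(resume && stage_done(cfg, sim_files))) {
    sim <- generate_cohorts(cfg$sim)
    ihc <- generate_ihc(cfg$sim, sim)
    for (i in seq_along(sim$cohorts))
      write_expression(sim$cohorts[[i]]$expression,
                       pipe_path(cfg, expr_files[i]))
    meta <- do.call(rbind, lapply(sim$cohorts, function(co) co$metadata))
    utils::write.csv(meta, pipe_path(cfg, "metadata.csv"), row.names = FALSE)
    frac <- do.call(rbind, lapply(sim$cohorts, function(co)
      data.frame(sample_id = rownames(co$fractions), co$fractions,
                 stringsAsFactors = FALSE)))
    utils::write.csv(frac, pipe_path(cfg, "fractions.csv"), row.names = FALSE)
    utils::write.csv(data.frame(sample_id = rownames(ihc$h_scores),
                                ihc$h_scores, stringsAsFactors = FALSE),
                     pipe_path(cfg, "h_scores.csv"), row.names = FALSE)
    utils::write.csv(data.frame(sample_id = names(sim$truth$cluster),
                                cluster = unname(sim$truth$cluster),
                                stringsAsFactors = FALSE),
                     pipe_path(cfg, "truth.csv"), row.names = FALSE)
    utils::write.csv(ihc$cps_table, pipe_path(cfg, "cps.csv"),
                     row.names = FALSE)
    log_stage("simulate", "wrote ", length(sim_files), " files, N = ",
              nrow(meta))
  } else log_stage("simulate", "outputs present, skipped")
  timings["simulate"] <- toc(t0)

  meta <- utils::read.csv(pipe_path(cfg, "metadata.csv"),
                          stringsAsFactors = FALSE)
  fr <- utils::read.csv(pipe_path(cfg, "fractions.csv"),
                        stringsAsFactors = FALSE)
  fractions <- as.matrix(fr[, -1]); rownames(fractions) <- fr$sample_id

  # -- stage: cluster -----------------------------------------------------
  t0 <- tic()
  if (!(resume && stage_done(cfg, "imclusters.csv"))) {
    cc <- consensus_cluster(fractions, k_range = cfg$k_range,
                            reps = cfg$reps, subsample = cfg$subsample,
                            seed = stage_seed(cfg$sim$seed, "clustering"))
    k <- select_k(cc, override = cfg$k_override)
    lab <- assign_imcluster(cc$labels[, paste0("k", k)], fractions)
    utils::write.csv(data.frame(sample_id = rownames(fractions),
                                imcluster = lab, stringsAsFactors = FALSE),
                     pipe_path(cfg, "imclusters.csv"), row.names = FALSE)
    log_stage("cluster", "k = ", k, "; sizes ",
              paste(table(lab), collapse = "/"))
  } else log_stage("cluster", "outputs present, skipped")
  timings["cluster"] <- toc(t0)

  clusters <- utils::read.csv(pipe_path(cfg, "imclusters.csv"),
                              stringsAsFactors = FALSE)

  # -- stage: rank --------------------------------------------------------
  t0 <- tic()
  if (!(resume && stage_done(cfg, c("weights.csv", "top_markers.csv")))) {
    cohorts <- lapply(seq_along(co_names), function(i) {
      e <- read_expression(pipe_path(cfg, expr_files[i]))
      ids <- colnames(e)
      list(expression = e,
           metadata = meta[match(ids, meta$sample_id), ],
           imcluster = clusters$imcluster[match(ids, clusters$sample_id)])
    })
    names(cohorts) <- co_names
    ev <- build_gene_evidence(cohorts,
                              exclude_genes = rownames(default_signature()))
    w <- eq1_weight(ev)
    utils::write.csv(w, pipe_path(cfg, "weights.csv"), row.names = FALSE)
    top <- rank_top(w, min(cfg$top_m, nrow(w)))
    utils::write.csv(data.frame(gene = top, stringsAsFactors = FALSE),
                     pipe_path(cfg, "top_markers.csv"), row.names = FALSE)
    log_stage("rank", nrow(w), " genes weighted; top ", length(top), " kept")
  } else log_stage("rank", "outputs present, skipped")
  timings["rank"] <- toc(t0)

  top <- utils::read.csv(pipe_path(cfg, "top_markers.csv"),
                         stringsAsFactors = FALSE)$gene
  hs <- utils::read.csv(pipe_path(cfg, "h_scores.csv"),
                        stringsAsFactors = FALSE, check.names = FALSE)
  h_scores <- as.matrix(hs[, -1]); rownames(h_scores) <- hs$sample_id

  # -- stage: concord -----------------------------------------------------
  t0 <- tic()
  if (!(resume && stage_done(cfg, "concordance.csv"))) {
    panel <- intersect(top, colnames(h_scores))
    mrna <- do.call(cbind, lapply(seq_along(co_names), function(i)
      read_expression(pipe_path(cfg, expr_files[i]))[panel, , drop = FALSE]))
    conc <- concordance_filter(t(mrna), h_scores[, panel, drop = FALSE],
                               m = cfg$concord_m)
    utils::write.csv(conc, pipe_path(cfg, "concordance.csv"),
                     row.names = FALSE)
    log_stage("concord", nrow(conc), " concordant genes kept of ",
              length(panel))
  } else log_stage("concord", "outputs present, skipped")
  timings["concord"] <- toc(t0)

  conc <- utils::read.csv(pipe_path(cfg, "concordance.csv"),
                          stringsAsFactors = FALSE)

  # -- stage: select + fit + score ---------------------------------------
  t0 <- tic()
  if (!(resume && stage_done(cfg, c("ips_model.json", "scores.csv")))) {
    feats <- h_scores[meta$sample_id, conc$gene, drop = FALSE]
    las <- lasso_cox_select(feats, meta$os_months, meta$os_event,
                            seed = cfg$sim$seed)
    rsf <- rsf_importance(feats, meta$os_months, meta$os_event,
                          threshold = cfg$rsf_threshold, seed = cfg$sim$seed)
    sel <- select_features(las$chosen, rsf$chosen)
    if (length(sel) == 0) {
      # degenerate intersection: fall back to the lasso route alone
      sel <- if (length(las$chosen)) las$chosen else conc$gene
      log_stage("select", "empty intersection; falling back to ",
                length(sel), " lasso-selected marker(s)")
    }
    model <- fit_ips(feats[, sel, drop = FALSE], meta$os_months,
                     meta$os_event)
    sc <- ips_score(model, feats)
    di <- dichotomize(sc, meta$os_months, meta$os_event,
                      horizon = cfg$youden_horizon, model = model)
    model <- di$model
    jsonlite::write_json(
      list(markers = model$markers, coef = as.list(model$coef),
           cutoff = model$cutoff, training = model$training,
           seed = cfg$sim$seed),
      pipe_path(cfg, "ips_model.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(di$results, pipe_path(cfg, "scores.csv"),
                     row.names = FALSE)
    log_stage("fit", length(sel), " markers in the IPS; cutoff ",
              signif(model$cutoff, 4))
  } else log_stage("fit", "outputs present, skipped")
  timings["fit"] <- toc(t0)

  scores <- utils::read.csv(pipe_path(cfg, "scores.csv"),
                            stringsAsFactors = FALSE)

  # -- stage: respond -----------------------------------------------------
  t0 <- tic()
  if (!(resume && stage_done(cfg, c("nici_outcomes.csv", "report.csv")))) {
    cps_tab <- utils::read.csv(pipe_path(cfg, "cps.csv"),
                               stringsAsFactors = FALSE)
    set.seed(stage_seed(cfg$sim$seed, "misc"))
    pick <- sample(nrow(scores), min(cfg$n_neoadjuvant, nrow(scores)))
    ips_cls <- scores$ips_class[pick]
    cps_val <- cps_tab$cps[match(scores$patient_id[pick], cps_tab$patient)]
    outc <- generate_neoadjuvant(cfg$sim, ips_cls, cps_val >= 5)
    utils::write.csv(outc, pipe_path(cfg, "nici_outcomes.csv"),
                     row.names = FALSE)
    rep_ <- association_report(outc)
    utils::write.csv(rep_, pipe_path(cfg, "report.csv"), row.names = FALSE)
    n_excl <- sum(is.na(outc$trg))
    log_stage("respond", nrow(outc), " patients; ", n_excl,
              " missing TRG excluded from that endpoint")
  } else log_stage("respond", "outputs present, skipped")
  timings["respond"] <- toc(t0)

  # -- manifest -----------------------------------------------------------
  outputs <- setdiff(list.files(cfg$out_dir), "manifest.json")
  sums <- tools::md5sum(pipe_path(cfg, outputs))
  names(sums) <- outputs
  cfg_file <- tempfile()
  dput(unclass(cfg[setdiff(names(cfg), "out_dir")]), cfg_file)
  manifest <- list(package_version = as.character(utils::packageVersion("ipstme")),
                   config_hash = unname(tools::md5sum(cfg_file)),
                   seed = cfg$sim$seed,
                   stage_seconds = as.list(round(timings, 3)),
                   outputs = as.list(sums))
  unlink(cfg_file)
  jsonlite::write_json(manifest[c("package_version", "config_hash", "seed",
                                  "outputs")],
                       pipe_path(cfg, "manifest.json"), auto_unbox = TRUE)
  manifest
}
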
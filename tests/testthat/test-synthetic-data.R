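test_that("configuration invariants are enforced", {
  expect_error(sim_config(cluster_proportions = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(sim_config(samples_per_cohort = c(-5, 10), n_cohorts = 2),
               "positive")
  expect_error(sim_config(n_marker_genes = 50, n_genes = 40), "exceeds")
  bad_fp <- default_fraction_profiles(); bad_fp[1, 1] <- bad_fp[1, 1] + 0.1
  expect_error(sim_config(fraction_profiles = bad_fp), "sum to 1")
  expect_error(sim_config(concordance_rho = 1.4), "concordance_rho")
})

test_that("identical config and seed give bitwise-identical datasets", {
  cfg <- small_config(seed = 42)
  a <- generate_cohorts(cfg); b <- generate_cohorts(cfg)
  expect_identical(a, b)
  ia <- generate_ihc(cfg, a); ib <- generate_ihc(cfg, b)
  expect_identical(ia, ib)
  oa <- generate_neoadjuvant(cfg, rep(c("Low", "High"), 26), rep(c(TRUE, FALSE), 26))
  ob <- generate_neoadjuvant(cfg, rep(c("Low", "High"), 26), rep(c(TRUE, FALSE), 26))
  expect_identical(oa, ob)
})

test_that("null configuration plants no marker effect", {
  cfg <- small_config(seed = 3, marker_logfc = 0, marker_hr = 1,
                      cluster_hazard = c(A = 0, B = 0, C = 0))
  sim <- generate_cohorts(cfg)
  expr <- do.call(cbind, lapply(sim$cohorts, function(co) co$expression))
  lab <- sim$truth$cluster[colnames(expr)]
  for (g in sim$truth$marker_genes[1:5]) {
    a <- expr[g, lab == "A"]; r <- expr[g, lab != "A"]
    se <- sqrt(var(a) / length(a) + var(r) / length(r))
    expect_lt(abs(mean(a) - mean(r)), 3 * se)
  }
})

test_that("a planted logFC of 2 is detectable at 50 samples per cohort", {
  cfg <- sim_config(n_cohorts = 2, samples_per_cohort = c(50, 50),
                    n_genes = 100, marker_logfc = 2, seed = 1)
  sim <- generate_cohorts(cfg)
  co <- sim$cohorts[[1]]
  lab <- sim$truth$cluster[co$metadata$sample_id]
  g <- co$expression[sim$truth$marker_genes[1], ]
  expect_lt(t.test(g[lab == "A"], g[lab != "A"])$p.value, 0.01)
})

test_that("empirical marker logFC converges to the planted value", {
  cfg <- sim_config(n_cohorts = 1, samples_per_cohort = 500, n_genes = 200,
                    seed = 8)
  sim <- generate_cohorts(cfg)
  co <- sim$cohorts[[1]]
  lab <- sim$truth$cluster[co$metadata$sample_id]
  lfc <- rowMeans(co$expression[sim$truth$marker_genes, lab == "A"]) -
    rowMeans(co$expression[sim$truth$marker_genes, lab != "A"])
  expect_lt(abs(mean(lfc) - cfg$marker_logfc), 0.1)
})

test_that("H-score concordance targets the configured Spearman correlation", {
  cfg <- sim_config(n_cohorts = 1, samples_per_cohort = 150, n_genes = 60,
                    seed = 5)
  sim <- generate_cohorts(cfg)
  ids <- sim$cohorts[[1]]$metadata$sample_id
  # rho = 1: exact monotone transform
  ihc1 <- generate_ihc(cfg, sim, genes = "mk001", rho = 1)
  e <- sim$cohorts[[1]]$expression["mk001", ids]
  expect_equal(cor(rank(e), rank(ihc1$h_scores[ids, "mk001"])), 1)
  # rho = 0.8 within +/- 0.1; rho = 0 small
  ihc <- generate_ihc(cfg, sim, genes = c("mk001", "mk002"), rho = c(0.8, 0))
  r1 <- cor(rank(e), rank(ihc$h_scores[ids, "mk001"]))
  e2 <- sim$cohorts[[1]]$expression["mk002", ids]
  r2 <- cor(rank(e2), rank(ihc$h_scores[ids, "mk002"]))
  expect_lt(abs(r1 - 0.8), 0.1)
  expect_lt(abs(r2), 0.2)
  expect_true(all(ihc$h_scores >= 0 & ihc$h_scores <= 300))
  expect_error(generate_ihc(cfg, sim, genes = "mk001", rho = 2), "rho")
})

test_that("cluster A is immune-hot in the simulated pathology readouts", {
  cfg <- small_config(seed = 6)
  sim <- generate_cohorts(cfg)
  ihc <- generate_ihc(cfg, sim)
  d <- ihc$densities
  expect_gt(median(d$cd8_ct[d$cluster == "A"]), median(d$cd8_ct[d$cluster == "C"]))
  cpsA <- ihc$cps_table$cps[d$cluster == "A"]
  cpsC <- ihc$cps_table$cps[d$cluster == "C"]
  expect_gt(mean(cpsA >= 5), mean(cpsC >= 5))
})

test_that("planted survival effect is recovered by a univariate Cox model", {
  hits <- 0
  for (s in 1:40) {
    cfg <- sim_config(n_cohorts = 1, samples_per_cohort = 250, n_genes = 40,
                      n_marker_genes = 10, seed = 700 + s)
    sim <- generate_cohorts(cfg)
    meta <- sim$cohorts[[1]]$metadata
    f <- cox_ph(meta$os_months, meta$os_event,
                cbind(z = sim$truth$marker_score[meta$sample_id]))
    if (abs(f$coef - log(cfg$marker_hr)) <= 2 * f$se) hits <- hits + 1
  }
  expect_gte(hits, 36)  # >= 90%
})

test_that("neoadjuvant outcomes follow the planted logistic response model", {
  # null model: no ORR difference on average
  cfg0 <- small_config(response_model = c(intercept = 0, ips_low = 0,
                                          cps_high = 0))
  diffs <- vapply(1:100, function(s) {
    cfg0$seed <- 5000 + s
    o <- generate_neoadjuvant(cfg0, rep(c("Low", "High"), each = 26),
                              rep(c(TRUE, FALSE), 26))
    orr(o$recist[o$ips_class == "Low"])$orr -
      orr(o$recist[o$ips_class == "High"])$orr
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.05)
  # strong planted effect: ordering recovered in nearly all replicates
  cfg1 <- small_config(response_model = c(intercept = -0.9, ips_low = 1.8,
                                          cps_high = 0))
  ord <- vapply(1:1000, function(s) {
    cfg1$seed <- 9000 + s
    o <- generate_neoadjuvant(cfg1, rep(c("Low", "High"), each = 26),
                              rep(c(TRUE, FALSE), 26))
    orr(o$recist[o$ips_class == "Low"])$orr >
      orr(o$recist[o$ips_class == "High"])$orr
  }, logical(1))
  expect_gte(mean(ord), 0.95)
  expect_error(generate_neoadjuvant(cfg1, c("Low", NA), c(TRUE, TRUE)),
               "missing")
})
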
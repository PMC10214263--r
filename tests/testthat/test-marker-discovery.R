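make_two_group <- function(n_per = 50, n_genes = 200, n_planted = 5,
                           lfc = 2, seed = 1) {
  set.seed(seed)
  e <- matrix(rnorm(n_genes * 2 * n_per), n_genes,
              dimnames = list(sprintf("g%03d", 1:n_genes),
                              sprintf("s%03d", 1:(2 * n_per))))
  lab <- rep(c("A", "B"), each = n_per)
  e[seq_len(n_planted), lab == "A"] <- e[seq_len(n_planted), lab == "A"] + lfc
  list(expr = e, lab = lab, planted = rownames(e)[seq_len(n_planted)])
}

test_that("differential expression estimates the planted logFC without bias", {
  # With unit residual SD and 50 samples per group the mean-difference
  # SE is sqrt(2/50) ~ 0.2, so [1.7, 2.3] is a +/- 1.5 SE window with
  # coverage ~ 0.866; the replicate bound below is three binomial SDs
  # under that coverage.
  hits <- 0
  ests <- numeric(100)
  for (s in 1:100) {
    d <- make_two_group(seed = s)
    de <- differential_expression(d$expr, d$lab)
    ests[s] <- de$logfc[de$gene == d$planted[1]]
    if (ests[s] >= 1.7 && ests[s] <= 2.3) hits <- hits + 1
  }
  expect_gte(hits, 76)
  expect_lt(abs(mean(ests) - 2), 3 * 0.2 / sqrt(100))
})

test_that("differential expression controls the FDR on null genes", {
  set.seed(40)
  e <- matrix(rnorm(1000 * 60), 1000,
              dimnames = list(sprintf("g%04d", 1:1000), NULL))
  colnames(e) <- sprintf("s%02d", 1:60)
  de <- differential_expression(e, rep(c("A", "B"), each = 30),
                                lfc_threshold = 0)
  frac_sig <- mean(de$adj_p < 0.05)
  expect_lte(frac_sig, 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("label swap negates every logFC and zero-variance genes are flagged", {
  d <- make_two_group(seed = 2, n_genes = 50)
  d$expr[50, ] <- 3  # constant gene
  de1 <- differential_expression(d$expr, d$lab, a_level = "A")
  de2 <- differential_expression(d$expr, d$lab, a_level = "B")
  expect_equal(de1$logfc, -de2$logfc, tolerance = 1e-10)
  expect_true(de1$zero_variance[de1$gene == "g050"])
  expect_equal(de1$p[de1$gene == "g050"], 1)
  expect_equal(de1$logfc[de1$gene == "g050"], 0)
})

test_that("gene AUC behaves at its extremes and under the null", {
  lab <- rep(c("A", "B"), each = 10)
  expect_equal(gene_auc(c(rep(5, 10), rep(1, 10)), lab), 1)
  expect_equal(gene_auc(rep(2, 20), lab), 0.5)
  set.seed(41)
  m <- mean(replicate(500, gene_auc(rnorm(200), rep(c("A", "B"), 100))))
  expect_lt(abs(m - 0.5), 0.02)
  expect_error(gene_auc(rnorm(5), rep("A", 5)), "class")
})

test_that("gene-level Cox HR inverts under negation and recovers planted effects", {
  set.seed(42)
  n <- 200
  g <- rnorm(n)
  t <- rexp(n, 0.05 * exp(0.7 * g)); c <- rexp(n, 0.02)
  time <- pmin(t, c); ev <- as.integer(t <= c)
  h1 <- gene_cox_hr(g, time, ev)
  h2 <- gene_cox_hr(-g, time, ev)
  expect_equal(h1$hr, 1 / h2$hr, tolerance = 1e-8)
  expect_lt(abs(h1$coef - 0.7), 2 * h1$se + 0.2)
})

test_that("the cross-cohort weight follows the five-factor product", {
  ev1 <- data.frame(gene = "g1", cohort = "c1", logfc = 1, adj_p = 0,
                    auc = 1, hr = 4, n_i = 100, N = 100)
  w1 <- eq1_weight(ev1)
  expect_equal(w1$weight_total, 1 * 2 * 0.5 * 2 * 1)  # = 2.0
  # annihilators: AUC = 0.5 or HR = 1
  ev2 <- ev1; ev2$auc <- 0.5
  expect_equal(eq1_weight(ev2)$weight_total, 0)
  ev3 <- ev1; ev3$hr <- 1
  expect_equal(eq1_weight(ev3)$weight_total, 0)
  # additivity over cohorts: contributions 1.2 and -0.4 sum to 0.8
  evm <- data.frame(gene = "g1", cohort = c("c1", "c2"),
                    logfc = c(1.2, -0.4), adj_p = 0, auc = 1, hr = 4,
                    n_i = c(50, 50), N = 100)
  contr <- attr(eq1_weight(evm), "contributions")$contribution
  expect_equal(sum(contr), eq1_weight(evm)$weight_total, tolerance = 1e-10)
  expect_equal(eq1_weight(evm)$weight_total, (1.2 - 0.4) * 2 * 0.5 * 2 * 0.5)
  expect_error(eq1_weight(transform(ev1, hr = -1)), "positive")
})

test_that("weight is linear in logFC and invariant to cohort-size rescaling", {
  base <- data.frame(gene = "g", cohort = c("a", "b"), logfc = c(0.8, 1.1),
                     adj_p = c(0.01, 0.2), auc = c(0.9, 0.7),
                     hr = c(2.5, 1.6), n_i = c(120, 80), N = 200)
  w <- eq1_weight(base)$weight_total
  tripled <- transform(base, logfc = logfc * 3)
  expect_equal(eq1_weight(tripled)$weight_total, 3 * w, tolerance = 1e-10)
  scaled <- transform(base, n_i = n_i * 7, N = N * 7)
  expect_equal(eq1_weight(scaled)$weight_total, w, tolerance = 1e-12)
})

test_that("rank_top orders by absolute weight with a lexicographic tie-break", {
  w <- data.frame(gene = c("b", "a", "c"), weight_total = c(-3, 1, 1))
  expect_equal(rank_top(w, 3), c("b", "a", "c"))
  expect_equal(rank_top(w, 3, signed = TRUE), c("a", "c", "b"))
  tied <- data.frame(gene = c("z", "m", "a"), weight_total = c(2, 2, 2))
  expect_equal(rank_top(tied, 3), c("a", "m", "z"))
  expect_error(rank_top(w, 5), "exceeds")
})

test_that("concordance filter ranks a perfectly coupled gene first", {
  set.seed(43)
  n <- 60
  mrna <- cbind(good = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  rownames(mrna) <- sprintf("s%02d", 1:n)
  h <- cbind(good = 300 * plogis(mrna[, "good"]), noise1 = runif(n, 0, 300),
             noise2 = runif(n, 0, 300))
  rownames(h) <- rownames(mrna)
  res <- concordance_filter(mrna, h, m = 2)
  expect_equal(res$gene[1], "good")
  expect_equal(res$rho[1], 1)
  expect_equal(nrow(concordance_filter(mrna, h, m = 0)), 0)
  expect_error(concordance_filter(mrna[1:2, ], h[1:2, ], m = 1), "3 paired")
})

test_that("pipeline ranking is deterministic for fixed inputs", {
  d <- make_two_group(seed = 4, n_genes = 80)
  de1 <- differential_expression(d$expr, d$lab)
  de2 <- differential_expression(d$expr, d$lab)
  expect_identical(de1, de2)
})
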
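test_that("hedges_g matches the closed form with its small-sample factor", {
  # arms engineered to have means 2 and 1 and pooled SD exactly 1
  a <- c(2.5, 1.5, 2.5, 1.5, 2.5, 1.5, 2.5, 1.5, 3.1, 0.9)
  b <- a - 1
  s2p <- (9 * var(a) + 9 * var(b)) / 18
  a <- 2 + (a - 2) / sqrt(s2p); b <- 1 + (b - 1) / sqrt(s2p)
  e <- hedges_g(a, b)
  J <- 1 - 3 / 71
  expect_equal(e$y, J * 1, tolerance = 1e-10)
  expect_equal(e$y, 0.9577, tolerance = 1e-4)
  expect_equal(e$v, 20 / 100 + e$y^2 / 40, tolerance = 1e-12)
  expect_equal(e$v, 0.2229, tolerance = 1e-3)

  # identical arms: g = 0, t = 0 so p = 1
  x <- c(1, 2, 3, 4)
  e0 <- hedges_g(x, x)
  expect_equal(e0$y, 0)
  expect_equal(e0$p_study, 1)

  # antisymmetry
  set.seed(5)
  u <- rnorm(8); w <- rnorm(12, 1)
  e1 <- hedges_g(u, w); e2 <- hedges_g(w, u)
  expect_equal(e1$y, -e2$y)
  expect_equal(e1$v, e2$v)

  # degenerate gene (zero pooled SD) flagged
  expect_warning(out <- hedges_g(c(1, 1, 1), c(1, 1, 1)), "degenerate")
  expect_null(out)
})

test_that("Cochran's Q, its chi-square p and I2 match hand computation", {
  h <- cochran_q(c(0.5, 0.7), c(0.04, 0.04))
  expect_equal(h$Q, 0.5, tolerance = 1e-12)
  expect_equal(h$p_Q, pchisq(0.5, 1, lower.tail = FALSE))
  expect_equal(h$p_Q, 0.4795, tolerance = 1e-4)
  expect_equal(h$I2, 0)

  h2 <- cochran_q(c(0, 1), c(0.04, 0.04))
  expect_equal(h2$Q, 12.5, tolerance = 1e-12)
  expect_equal(h2$p_Q, 4.07e-4, tolerance = 1e-2)
  expect_equal(h2$I2, 92)

  expect_equal(cochran_q(c(0.3, 0.3, 0.3), c(0.1, 0.2, 0.3))$Q, 0)
  expect_error(cochran_q(0.5, 0.04),
               class = "lncmeta_insufficient_studies")
})

test_that("fixed-effects pooling matches hand computation and limits", {
  p <- pool_fixed(c(0.5, 0.7), c(0.04, 0.04))
  expect_equal(p$smd_pooled, 0.6, tolerance = 1e-12)
  expect_equal(p$ci_low, 0.3228, tolerance = 1e-4)
  expect_equal(p$ci_high, 0.8772, tolerance = 1e-4)

  # dominant weight limit
  p2 <- pool_fixed(c(0.9, -2), c(1e-8, 10))
  expect_equal(p2$smd_pooled, 0.9, tolerance = 1e-4)

  # CI width shrinks as k grows at fixed v
  w3 <- pool_fixed(rep(0.5, 3), rep(0.2, 3))
  w6 <- pool_fixed(rep(0.5, 6), rep(0.2, 6))
  expect_lt(w6$ci_high - w6$ci_low, w3$ci_high - w3$ci_low)
})

test_that("DerSimonian-Laird pooling matches hand computation", {
  p <- pool_random(c(0, 1), c(0.04, 0.04))
  expect_equal(p$tau2, 0.46, tolerance = 1e-12)
  expect_equal(p$smd_pooled, 0.5, tolerance = 1e-12)
  expect_equal(p$ci_low, -0.48, tolerance = 1e-3)
  expect_equal(p$ci_high, 1.48, tolerance = 1e-3)
  expect_false(p$ci_low > 0 || p$ci_high < 0)  # CI includes zero

  # Q <= df collapses to fixed effects exactly
  y <- c(0.31, 0.29); v <- c(0.1, 0.12)
  expect_equal(pool_random(y, v)[-1], pool_fixed(y, v))
  expect_gte(pool_random(c(-2, 0, 3), c(0.1, 0.2, 0.1))$tau2, 0)
})

test_that("pooled estimates agree with metafor on random instances", {
  skip_if_not_installed("metafor")
  set.seed(11)
  for (r in 1:25) {
    k <- sample(2:12, 1)
    y <- rnorm(k); v <- runif(k, 0.02, 0.5)
    fe <- pool_fixed(y, v)
    mf <- metafor::rma(yi = y, vi = v, method = "FE")
    expect_equal(fe$smd_pooled, as.numeric(mf$beta), tolerance = 1e-10)
    expect_equal(fe$p_meta, as.numeric(mf$pval), tolerance = 1e-10)
    re <- pool_random(y, v)
    mr <- metafor::rma(yi = y, vi = v, method = "DL")
    expect_equal(re$tau2, mr$tau2, tolerance = 1e-10)
    expect_equal(re$smd_pooled, as.numeric(mr$beta), tolerance = 1e-10)
    q <- cochran_q(y, v)
    expect_equal(q$Q, as.numeric(mr$QE), tolerance = 1e-10)
    expect_equal(q$p_Q, as.numeric(mr$QEp), tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the manual step-up and its properties", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(6)
  p <- runif(50)^2
  adj <- bh_fdr(p)
  expect_equal(adj, bh_manual(p))
  expect_true(all(adj >= p) && all(adj <= 1))
  expect_equal(order(adj[order(p)]), 1:50)  # order preserving
  expect_error(bh_fdr(c(0.5, 1.2)), class = "lncmeta_input_error")
})

test_that("run_meta applies the joint heterogeneity switching rule", {
  sim <- small_sim(n_studies = 5, n_genes = 400, frac_de = 0.3,
                   tau2 = 0.3, seed = 77)
  res <- run_meta(sim$studies)
  expect_true(all(res$model %in% c("FEM", "REM")))
  # REM exactly when I2 > 50 AND p_Q < 0.01, both strict
  expect_equal(res$model == "REM", res$I2 > 50 & res$p_Q < 0.01)
  # DE call invariant: CI excludes zero AND fdr < 0.05
  expect_equal(res$de_call,
               (res$ci_low > 0 | res$ci_high < 0) & res$fdr < 0.05)
  expect_true(all(res$ci_low <= res$smd_pooled &
                    res$smd_pooled <= res$ci_high))
  expect_true(all(res$direction[res$de_call] %in% c("up", "down")))
  expect_true(all(res$direction[!res$de_call] == "none"))
  expect_true(all(res$I2 >= 0 & res$I2 <= 100))
  expect_true(all(res$tau2 >= 0))
})

test_that("run_meta reports genes present in fewer than two studies", {
  sim <- small_sim(n_studies = 3, n_genes = 60, seed = 12)
  # restrict gene g1 to a single study
  sim$studies[[2]]$counts <- sim$studies[[2]]$counts[-1, ]
  sim$studies[[3]]$counts <- sim$studies[[3]]$counts[-1, ]
  res <- run_meta(sim$studies)
  row <- res[res$gene_id == "gene00001", ]
  expect_false(row$de_call)
  expect_equal(row$reason, "insufficient_studies")
  expect_equal(row$k, 1)
})

test_that("subgroup runs keep per-study effects and study counts additive", {
  sim <- small_sim(n_studies = 6, n_genes = 150, seed = 31)
  whole <- run_meta(sim$studies)
  g1 <- run_meta(sim$studies[1:3])
  g2 <- run_meta(sim$studies[4:6])
  expect_equal(whole$k, g1$k + g2$k)
  # pooled union effect equals inverse-variance combination of the parts
  # only when models agree; check the FEM-only genes
  both_fem <- whole$model == "FEM" & g1$model == "FEM" & g2$model == "FEM"
  expect_gt(sum(both_fem), 0)
})

test_that("meta p-values are calibrated on a null simulation", {
  sim <- small_sim(n_studies = 5, n_genes = 1500, frac_de = 0, tau2 = 0,
                   seed = 99)
  res <- run_meta(sim$studies)
  expect_lte(mean(res$I2 > 50 & res$p_Q < 0.01), 0.01 + 0.01)
  expect_lte(mean(res$de_call), 0.05)
})
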
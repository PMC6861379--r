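test_that("outlier samples are removed by dendrogram cut, idempotently", {
  set.seed(41)
  base <- matrix(rnorm(50 * 20), 50, 20,
                 dimnames = list(NULL, paste0("s", 1:20)))
  cfg <- network_config(outlier_cut_height = 50, outlier_min_cluster = 5)
  none <- remove_outlier_samples(base, cfg)
  expect_equal(none$removed, character(0))

  out <- base
  out[, 20] <- out[, 20] * 100  # one sample far from the tight cluster
  got <- remove_outlier_samples(out, cfg)
  expect_equal(got$removed, "s20")
  again <- remove_outlier_samples(got$expression, cfg)
  expect_equal(again$removed, character(0))

  expect_equal(remove_outlier_samples(base, network_config())$removed,
               character(0))  # NULL cut height disables removal
})

test_that("soft-threshold pick reaches the scale-free target on modular data", {
  d <- generate_coexpression_data(60, 200, 3, within_cor = 0.8,
                                  trait_cor = 0.5, seed = 3)
  sft <- pick_soft_threshold(d$expression, network_config())
  expect_true(sft$beta %in% 1:20)
  expect_gte(max(sft$fit_table$rsq_signed, na.rm = TRUE), 0.8)
  # mean connectivity is non-increasing in the power (adjacency <= 1)
  expect_true(all(diff(sft$fit_table$mean_k) <= 1e-12))
})

test_that("TOM matches closed forms and the brute-force oracle", {
  # complete graph on 3 nodes
  a3 <- matrix(1, 3, 3)
  expect_equal(tom_matrix(a3)[1, 2], (1 + 1) / (2 + 1 - 1))

  # single nonzero off-diagonal pair: TOM_ij = a_ij
  a <- diag(4); a[1, 2] <- a[2, 1] <- 0.37
  expect_equal(tom_matrix(a)[1, 2], 0.37, tolerance = 1e-15)

  set.seed(42)
  for (r in 1:5) {
    x <- matrix(rnorm(20 * 30), 20, 30)
    A <- abs(cor(t(x)))^sample(2:8, 1)
    diag(A) <- 1
    tom <- tom_matrix(A)
    expect_lt(max(abs(tom - tom_brute(A))), 1e-12)
    expect_true(isSymmetric(tom, tol = 1e-12))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
  bad <- matrix(runif(16), 4, 4)
  expect_error(tom_matrix(bad), class = "lncmeta_input_error")
})

test_that("module detection separates correlated blocks", {
  set.seed(43)
  n <- 30
  e1 <- rnorm(n); e2 <- rnorm(n)
  expr <- rbind(
    t(replicate(40, e1 + rnorm(n, sd = 0.01))),
    t(replicate(40, e2 + rnorm(n, sd = 0.01))))
  rownames(expr) <- paste0("g", 1:80)
  tom <- tom_matrix(adjacency_matrix(expr, 6))
  lab <- detect_modules(tom, expr, network_config(min_module_size = 30))
  expect_equal(sort(unique(lab)), 1:2)
  expect_equal(length(unique(lab[1:40])), 1)
  expect_equal(length(unique(lab[41:80])), 1)

  # min_module_size larger than the gene count leaves everything unassigned
  expect_warning(
    lab0 <- detect_modules(tom, expr, network_config(min_module_size = 100)),
    "unassigned")
  expect_true(all(lab0 == 0L))
})

test_that("module recovery on the standard benchmark is accurate", {
  skip_if_not_installed("mclust")
  d <- generate_coexpression_data(60, 200, 3, within_cor = 0.8,
                                  trait_cor = 0.5, seed = 3)
  sft <- pick_soft_threshold(d$expression, network_config())
  tom <- tom_matrix(adjacency_matrix(d$expression, sft$beta))
  lab <- detect_modules(tom, d$expression, network_config())
  ari <- mclust::adjustedRandIndex(lab, d$truth$module_labels)
  expect_gte(ari, 0.8)
})

test_that("module significance statistics satisfy their identities", {
  set.seed(44)
  n <- 40
  e1 <- rnorm(n)
  expr <- rbind(t(replicate(10, e1)),          # identical genes
                matrix(rnorm(20 * n), 20, n))
  rownames(expr) <- paste0("g", 1:30)
  labels <- setNames(rep(c(1L, 2L), c(10, 20)), rownames(expr))
  trait <- as.integer(expr[15, ] > median(expr[15, ]))
  ms <- module_significance(expr, labels, data.frame(disease = trait))
  # identical genes carry |kME| = 1 with their own eigengene
  expect_equal(abs(ms$kME[1:10, 1]), rep(1, 10), tolerance = 1e-10,
               ignore_attr = TRUE)
  # a trait equal to a binarized gene makes that gene's GS = 1
  expr2 <- rbind(expr, gbin = trait)
  labels2 <- c(labels, gbin = 2L)
  ms2 <- module_significance(expr2, labels2, data.frame(disease = trait))
  expect_equal(unname(ms2$GS["gbin", 1]), 1, tolerance = 1e-12)
  # eigengenes have unit variance; |kME| bounded; GS in [0, 1]
  expect_equal(apply(ms$eigengenes, 1, sd), c(ME1 = 1, ME2 = 1))
  expect_true(all(abs(ms$kME) <= 1 + 1e-12))
  expect_true(all(ms$GS >= 0 & ms$GS <= 1))
  # label permutation leaves module-trait statistics invariant
  relab <- labels; relab[labels == 1L] <- 2L; relab[labels == 2L] <- 1L
  ms3 <- module_significance(expr, relab, data.frame(disease = trait))
  expect_equal(sort(abs(as.vector(ms$module_trait_r))),
               sort(abs(as.vector(ms3$module_trait_r))), tolerance = 1e-10)
})

test_that("the trait-linked module attains the top module-trait correlation", {
  hits <- vapply(1:40, function(r) {
    d <- generate_coexpression_data(100, 120, 3, within_cor = 0.8,
                                    trait_cor = 0.5, seed = 500 + r)
    ms <- module_significance(d$expression, d$truth$module_labels,
                              data.frame(disease = d$trait))
    which.max(abs(ms$module_trait_r[, 1])) == 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
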
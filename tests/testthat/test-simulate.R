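test_that("the count generator is deterministic and honors its config", {
  cfg <- simulation_config(n_studies = 3, n_cases = c(5, 6, 7),
                           n_controls = c(5, 4, 3), n_genes = 100,
                           seed = 55)
  s1 <- generate_multistudy_counts(cfg)
  s2 <- generate_multistudy_counts(cfg)
  expect_identical(s1, s2)

  expect_equal(length(s1$studies), 3)
  for (j in 1:3) {
    st <- s1$studies[[j]]
    expect_equal(dim(st$counts), c(100, cfg$n_cases[j] + cfg$n_controls[j]))
    expect_true(all(st$counts >= 0 & st$counts == round(st$counts)))
    expect_equal(sum(st$design$group == "case"), cfg$n_cases[j])
    expect_equal(st$design$sample_id, colnames(st$counts))
  }

  # no effects planted when frac_de = 0
  s0 <- generate_multistudy_counts(
    simulation_config(n_studies = 2, n_genes = 50, frac_de = 0, seed = 9))
  expect_false(any(s0$truth$de_flags))
  expect_true(all(s0$truth$true_effects == 0))
})

test_that("invalid simulation configs are rejected", {
  expect_error(simulation_config(n_genes = 0),
               class = "lncmeta_config_error")
  expect_error(simulation_config(frac_de = 1.2),
               class = "lncmeta_config_error")
  expect_error(simulation_config(tau2 = -0.1),
               class = "lncmeta_config_error")
  expect_error(simulation_config(nb_dispersion = 0),
               class = "lncmeta_config_error")
  expect_error(simulation_config(n_studies = 3, n_cases = c(2, 2)),
               class = "lncmeta_config_error")
})

test_that("control-arm means track the planted relative abundances", {
  cfg <- simulation_config(n_studies = 1, n_cases = 2, n_controls = 150,
                           n_genes = 200, frac_de = 0, tau2 = 0,
                           lib_size_range = c(1e6, 1e6), seed = 13)
  sim <- generate_multistudy_counts(cfg)
  ctrl <- sim$studies[[1]]$counts[, sim$studies[[1]]$design$group ==
                                    "control"]
  est_q <- rowMeans(ctrl) / 1e6
  # relative error of the empirical mean against q_g, within MC error
  rel <- (est_q - sim$truth$q) / sim$truth$q
  expect_lt(stats::median(abs(rel)), 0.1)
})

test_that("tissue atlas plants dominance and labels consistently", {
  ta <- generate_tissue_atlas(60, c("a", "b", "c"), frac_specific = 1,
                              seed = 2)
  expect_true(all(!is.na(ta$truth$specific_tissue)))
  for (g in 1:60) {
    t <- ta$truth$specific_tissue[g]
    expect_gte(ta$atlas[g, t], 10 * max(ta$atlas[g, colnames(ta$atlas) != t]))
  }
  ta0 <- generate_tissue_atlas(20, c("a", "b", "c"), frac_specific = 0,
                               seed = 2)
  expect_true(all(is.na(ta0$truth$specific_tissue)))
  expect_error(generate_tissue_atlas(10, "onlyone"),
               class = "lncmeta_config_error")
})

test_that("co-expression generator approaches the correlation limit", {
  d <- generate_coexpression_data(80, 30, 3, within_cor = 0.995,
                                  trait_cor = 0.3, seed = 3)
  lab <- d$truth$module_labels
  for (m in 1:3) {
    sub <- d$expression[lab == m, ]
    cc <- cor(t(sub))
    expect_gt(min(cc[upper.tri(cc)]), 0.95)
  }
  expect_error(generate_coexpression_data(50, 10, 0),
               class = "lncmeta_config_error")
  expect_error(generate_coexpression_data(50, 10, 2, within_cor = 1),
               class = "lncmeta_config_error")
})

test_that("gene-set generator plants enrichment and writes valid GMT", {
  labels <- setNames(rep(c(1L, 2L, 0L), c(50, 50, 100)),
                     sprintf("g%03d", 1:200))
  gs <- generate_gene_sets(labels, n_sets = 8, enrichment_strength = 1,
                           set_size = 20, seed = 5)
  expect_equal(length(gs$sets), 8)
  expect_equal(length(gs$truth$enriched_sets), 2)
  planted <- gs$sets[[gs$truth$enriched_sets[1]]]
  expect_true(all(planted %in% names(labels)[labels == 1L]))

  # maximal ORA odds among sets for the fully planted set
  res <- ora(names(labels)[labels == 1L], gs$sets, names(labels),
             min_set = 5)
  expect_equal(res$set_id[1], gs$truth$enriched_sets[1])

  # empty collection round-trips as a valid (empty) GMT
  gs0 <- generate_gene_sets(labels, n_sets = 0, seed = 5)
  expect_equal(length(gs0$sets), 0)
  tmp <- tempfile(fileext = ".gmt")
  write_gmt(gs0$sets, tmp)
  expect_equal(length(read_gmt(tmp)$sets), 0)
  expect_error(generate_gene_sets(integer(0), 3),
               class = "lncmeta_config_error")
})
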
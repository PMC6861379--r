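# Ground-truth simulators for the whole pipeline.
#
# The count generator follows the data model assumed by the meta-analysis:
# study j, sample s, gene g has counts NB(mean = lib_s * q_g *
# 2^(x_s * lambda_gj), dispersion phi) with x_s the case indicator. The
# user-facing effect size delta is the TRUE STANDARDIZED effect (SMD
# units); it is converted to the log2-scale shift lambda_gj =
# (delta_g + b_gj) * sigma_gj where b_gj ~ N(0, tau2) is the between-study
# deviation and sigma_gj = sqrt(mean_s 1/mu_gs + trigamma(1/phi)) / ln 2
# approximates the SD of log2 expression under the gamma-Poisson law
# (trigamma(1/phi) is the exact log-variance of the gamma mixing component;
# the 1/mu term is the Poisson delta-method part). The per-study true SMD
# is therefore delta_g + b_gj by construction and recovery is analytically
# checkable from delta, phi and n alone.

# Per-arm sizes of the 20 studies of the motivating multi-study MS design
# (first 10 blood, last 10 brain).
.default_cases <- c(6, 6, 6, 3, 12, 6, 6, 10, 5, 58,
                    5, 10, 5, 24, 20, 5, 5, 5, 5, 5)
.default_controls <- c(4, 4, 4, 4, 8, 8, 8, 6, 3, 234,
                       5, 11, 5, 18, 5, 5, 5, 5, 5, 5)
.default_tissues <- rep(c("blood", "brain"), each = 10)

#' Simulation configuration for multi-study count data
#'
#' @param n_studies Number of studies (default 20, the reference design).
#' @param n_cases,n_controls Per-study arm sizes. Defaults echo the
#'   reference design's 20 studies (cases 3-58, controls 3-234, unequal);
#'   for other \code{n_studies} the first rows are recycled.
#' @param tissue_class Per-study tissue label; default splits studies into
#'   blood then brain halves.
#' @param n_genes Number of genes (default 2000).
#' @param frac_de Fraction of genes with a nonzero effect (default 0.1).
#' @param delta True standardized effect size (SMD units, applied on the
#'   log2 scale; default 0.6). Sign per DE gene is +1 with probability
#'   \code{frac_up}.
#' @param frac_up Fraction of DE genes upregulated (default 0.5).
#' @param tau2 Between-study variance of the standardized effect
#'   (default 0.2).
#' @param nb_dispersion Negative-binomial dispersion phi (default 0.1).
#' @param lib_size_range Range of per-sample library sizes, drawn
#'   log-uniform (default 5e5 to 5e6).
#' @param n_modules Number of latent co-expression modules embedded in the
#'   counts (default 0 = none); module 1's latent factor is tied to the
#'   case/control trait with correlation \code{module_trait_cor}.
#' @param module_cor Target within-module pairwise correlation of log
#'   expression (default 0.6).
#' @param module_trait_cor Correlation between module 1's latent factor and
#'   case status (default 0.5).
#' @param seed Integer seed; identical configs give identical output.
#' @return List of class \code{lncmeta_simconfig}.
#' @export
simulation_config <- function(n_studies = 20,
                              n_cases = NULL, n_controls = NULL,
                              tissue_class = NULL,
                              n_genes = 2000, frac_de = 0.1, delta = 0.6,
                              frac_up = 0.5, tau2 = 0.2,
                              nb_dispersion = 0.1,
                              lib_size_range = c(5e5, 5e6),
                              n_modules = 0, module_cor = 0.6,
                              module_trait_cor = 0.5, seed = 1L) {
  if (is.null(n_cases))
    n_cases <- rep_len(.default_cases, n_studies)
  if (is.null(n_controls))
    n_controls <- rep_len(.default_controls, n_studies)
  if (is.null(tissue_class))
    tissue_class <- if (n_studies == 20) .default_tissues else
      rep(c("blood", "brain"), c(ceiling(n_studies / 2),
                                 floor(n_studies / 2)))
  cfg <- list(n_studies = n_studies, n_cases = n_cases,
              n_controls = n_controls, tissue_class = tissue_class,
              n_genes = n_genes, frac_de = frac_de, delta = delta,
              frac_up = frac_up, tau2 = tau2, nb_dispersion = nb_dispersion,
              lib_size_range = lib_size_range, n_modules = n_modules,
              module_cor = module_cor, module_trait_cor = module_trait_cor,
              seed = as.integer(seed))
  .assert(n_studies >= 1 && n_genes >= 1 &&
            all(cfg$n_cases >= 1) && all(cfg$n_controls >= 1),
          "sample and gene counts must be positive",
          class = "lncmeta_config_error")
  .assert(frac_de >= 0 && frac_de <= 1, "frac_de must lie in [0, 1]",
          class = "lncmeta_config_error")
  .assert(tau2 >= 0, "tau2 must be >= 0", class = "lncmeta_config_error")
  .assert(nb_dispersion > 0, "nb_dispersion must be > 0",
          class = "lncmeta_config_error")
  .assert(length(cfg$n_cases) == n_studies &&
            length(cfg$n_controls) == n_studies &&
            length(cfg$tissue_class) == n_studies,
          "per-study vectors must have length n_studies",
          class = "lncmeta_config_error")
  structure(cfg, class = "lncmeta_simconfig")
}

#' Generate multi-study negative-binomial count data with known truth
#'
#' See the package vignette for the generative model. Returns one study
#' object per study (counts plus design) and the ground truth: DE flags,
#' realized per-study standardized effects and log2 shifts, and (when
#' \code{n_modules > 0}) planted module labels.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return List with \code{studies} (each: \code{counts} genes x samples,
#'   \code{design} data frame sample_id/group/study_id/tissue_class) and
#'   \code{truth} (list: \code{de_flags}, \code{true_smd} and
#'   \code{true_effects} gene x study matrices, \code{module_labels},
#'   \code{q}).
#' @export
generate_multistudy_counts <- function(config) {
  .assert(inherits(config, "lncmeta_simconfig"),
          "config must come from simulation_config()",
          class = "lncmeta_config_error")
  set.seed(config$seed)
  G <- config$n_genes; k <- config$n_studies; phi <- config$nb_dispersion
  genes <- sprintf("gene%05d", seq_len(G))

  # baseline relative abundances (sum 1)
  q <- stats::rgamma(G, shape = 1.5, rate = 1)
  q <- q / sum(q)
  names(q) <- genes

  n_de <- round(config$frac_de * G)
  de_flags <- logical(G)
  de_flags[sample.int(G, n_de)] <- TRUE
  sign_g <- ifelse(stats::runif(G) < config$frac_up, 1, -1)
  delta_g <- ifelse(de_flags, sign_g * config$delta, 0)

  module_labels <- rep(0L, G)
  if (config$n_modules > 0) {
    # block assignment over the first half of genes, balanced sizes
    per <- floor(G / (2 * config$n_modules))
    for (m in seq_len(config$n_modules))
      module_labels[seq((m - 1) * per + 1, m * per)] <- m
  }
  w <- config$module_cor
  loading <- sqrt(w / (1 - w))  # factor loading in units of sigma_g

  true_smd <- true_log2 <- matrix(0, G, k, dimnames = list(genes, NULL))
  studies <- vector("list", k)
  for (j in seq_len(k)) {
    n1 <- config$n_cases[j]; n0 <- config$n_controls[j]
    n <- n1 + n0
    x <- c(rep(1L, n1), rep(0L, n0))
    lib <- exp(stats::runif(n, log(config$lib_size_range[1]),
                            log(config$lib_size_range[2])))
    mu0 <- outer(q, lib)                      # control-level means
    sigma_g <- sqrt(rowMeans(1 / mu0) + trigamma(1 / phi)) / log(2)
    b <- if (config$tau2 > 0) stats::rnorm(G, 0, sqrt(config$tau2)) else
      numeric(G)
    smd_gj <- ifelse(de_flags, delta_g + b, 0)
    lam <- smd_gj * sigma_g                   # log2 shift for cases
    shift <- 2^(outer(lam, x))                # genes x samples
    mu <- mu0 * shift
    if (config$n_modules > 0) {
      trait_z <- (x - mean(x)) / stats::sd(x)
      for (m in seq_len(config$n_modules)) {
        f <- stats::rnorm(n)
        if (m == 1) {
          r <- config$module_trait_cor
          f <- r * trait_z + sqrt(1 - r^2) * f
        }
        idx <- module_labels == m
        # per-sample log2 bump shared by module genes
        mu[idx, ] <- mu[idx, ] *
          2^(outer(loading * sigma_g[idx], f))
      }
    }
    counts <- matrix(stats::rnbinom(G * n, size = 1 / phi, mu = mu), G, n,
                     dimnames = list(genes,
                                     sprintf("s%02d_%03d", j, seq_len(n))))
    design <- data.frame(
      sample_id = colnames(counts),
      group = ifelse(x == 1, "case", "control"),
      study_id = sprintf("study%02d", j),
      tissue_class = config$tissue_class[j], stringsAsFactors = FALSE)
    studies[[j]] <- list(counts = counts, design = design)
    true_smd[, j] <- smd_gj
    true_log2[, j] <- lam
  }
  list(studies = studies,
       truth = list(de_flags = stats::setNames(de_flags, genes),
                    delta = stats::setNames(delta_g, genes),
                    true_smd = true_smd, true_effects = true_log2,
                    module_labels = stats::setNames(module_labels, genes),
                    q = q))
}

#' Generate a gene-by-tissue expression atlas with planted specific genes
#'
#' Specific genes have one dominant tissue at \code{dominance} times the
#' largest other tissue; the remaining genes are near-uniform.
#'
#' @param n_genes Number of genes.
#' @param tissues Character vector of >= 2 tissue labels.
#' @param frac_specific Fraction of genes made tissue-specific.
#' @param dominance Fold dominance of the specific tissue (default 10).
#' @param seed Integer seed.
#' @return List with \code{atlas} (genes x tissues matrix) and \code{truth}
#'   (\code{specific_tissue}: per-gene label or NA).
#' @export
generate_tissue_atlas <- function(n_genes, tissues, frac_specific = 0.3,
                                  dominance = 10, seed = 1L) {
  .assert(length(tissues) >= 2, "need >= 2 tissues",
          class = "lncmeta_config_error")
  set.seed(as.integer(seed))
  G <- n_genes; T <- length(tissues)
  genes <- sprintf("gene%05d", seq_len(G))
  base <- matrix(stats::rlnorm(G * T, meanlog = 0, sdlog = 0.2), G, T,
                 dimnames = list(genes, tissues))
  n_spec <- round(frac_specific * G)
  spec_tissue <- rep(NA_character_, G)
  if (n_spec > 0) {
    which_t <- sample.int(T, n_spec, replace = TRUE)
    for (i in seq_len(n_spec))
      base[i, which_t[i]] <- dominance * max(base[i, -which_t[i]])
    spec_tissue[seq_len(n_spec)] <- tissues[which_t]
  }
  list(atlas = base,
       truth = list(specific_tissue = stats::setNames(spec_tissue, genes)))
}

#' Generate module-structured expression with a trait-linked module
#'
#' Gene g in module m is \code{within_cor * E_m +
#' sqrt(1 - within_cor^2) * noise} with latent eigengene \code{E_m};
#' module 1's eigengene is correlated \code{trait_cor} with a balanced
#' binary trait.
#'
#' @param n_samples,n_genes,n_modules Dimensions (modules >= 1; genes are
#'   split evenly across modules).
#' @param within_cor Gene-eigengene correlation in (0, 1); pairwise
#'   within-module correlation is its square.
#' @param trait_cor Eigengene-trait correlation in [0, 1).
#' @param seed Integer seed.
#' @return List with \code{expression} (genes x samples), \code{trait}
#'   (0/1 per sample) and \code{truth} (\code{module_labels}).
#' @export
generate_coexpression_data <- function(n_samples, n_genes, n_modules,
                                       within_cor = 0.8, trait_cor = 0.5,
                                       seed = 1L) {
  .assert(n_modules >= 1, "need n_modules >= 1",
          class = "lncmeta_config_error")
  .assert(within_cor > 0 && within_cor < 1, "within_cor must be in (0, 1)",
          class = "lncmeta_config_error")
  .assert(n_genes >= n_modules && n_samples >= 4, "dimensions inconsistent",
          class = "lncmeta_config_error")
  set.seed(as.integer(seed))
  trait <- rep(c(1L, 0L), length.out = n_samples)
  z <- (trait - mean(trait)) / stats::sd(trait)
  labels <- rep(seq_len(n_modules), length.out = n_genes)
  labels <- sort(labels)
  E <- matrix(stats::rnorm(n_modules * n_samples), n_modules, n_samples)
  if (trait_cor > 0)
    E[1, ] <- trait_cor * z + sqrt(1 - trait_cor^2) * E[1, ]
  expr <- within_cor * E[labels, , drop = FALSE] +
    sqrt(1 - within_cor^2) *
    matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
  dimnames(expr) <- list(sprintf("gene%05d", seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n_samples)))
  list(expression = expr, trait = trait,
       truth = list(module_labels = stats::setNames(labels,
                                                    rownames(expr))))
}

#' Generate a gene-set collection with sets enriched in planted modules
#'
#' One planted set per module draws \code{enrichment_strength} of its
#' members from that module and the rest uniformly from the background;
#' decoy sets draw uniformly.
#'
#' @param module_labels Named integer vector (0 = background), as in the
#'   truth of \code{\link{generate_coexpression_data}}.
#' @param n_sets Total number of sets (planted sets come first, one per
#'   nonzero module while sets remain).
#' @param enrichment_strength Fraction of a planted set's members drawn
#'   from its module.
#' @param set_size Members per set (default 20).
#' @param seed Integer seed.
#' @return List with \code{sets} (named list of gene-id vectors),
#'   \code{universe} and \code{truth} (\code{enriched_sets},
#'   \code{set_module}).
#' @export
generate_gene_sets <- function(module_labels, n_sets,
                               enrichment_strength = 0.8, set_size = 20,
                               seed = 1L) {
  .assert(length(module_labels) > 0, "empty module label vector",
          class = "lncmeta_config_error")
  set.seed(as.integer(seed))
  genes <- names(module_labels)
  .assert(!is.null(genes), "module_labels must be named by gene id")
  mods <- setdiff(sort(unique(module_labels)), 0L)
  sets <- list(); planted <- character(0); set_module <- integer(0)
  i <- 0L
  for (m in mods) {
    if (i >= n_sets) break
    i <- i + 1L
    id <- sprintf("SET%03d_planted_m%d", i, m)
    members <- module_genes <- genes[module_labels == m]
    n_in <- min(round(enrichment_strength * set_size), length(module_genes))
    inside <- sample(module_genes, n_in)
    outside <- sample(setdiff(genes, inside), set_size - n_in)
    sets[[id]] <- sort(unique(c(inside, outside)))
    planted <- c(planted, id); set_module <- c(set_module, m)
  }
  while (i < n_sets) {
    i <- i + 1L
    id <- sprintf("SET%03d_decoy", i)
    sets[[id]] <- sort(sample(genes, min(set_size, length(genes))))
  }
  list(sets = sets, universe = genes,
       truth = list(enriched_sets = planted, set_module = set_module))
}
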
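# End-to-end orchestration: simulate (optional) -> normalize -> meta
# (whole + per-subgroup) -> DE-set overlap -> tissue specificity ->
# co-expression network on the DE genes -> over-representation of the top
# modules. Every stage writes a TSV artifact and the run ends with a JSON
# manifest of file hashes so a rerun under the same config and seed can be
# verified byte-identical.

#' Pipeline configuration
#'
#' Either \code{simulate = TRUE} (the synthetic fixture; generator options
#' in \code{sim}) or paths to per-study count TSVs plus a design TSV. The
#' statistical thresholds default to the reference analysis: heterogeneity
#' rule I2 > 50 with p_Q < 0.01, DE FDR < 0.05, enrichment adjusted p <
#' 0.05, scale-free fit target 0.8.
#'
#' @param simulate Generate the inputs with the package simulators.
#' @param sim Optional \code{\link{simulation_config}} (default: 5 studies,
#'   2000 genes, 3 latent modules).
#' @param study_paths,design_path,tx2gene_path,atlas_path,gmt_path Input
#'   files when \code{simulate = FALSE} (counts TSVs have a gene_id column;
#'   design TSV columns sample_id, group, study_id, tissue_class).
#' @param i2_threshold,pq_threshold,fdr_threshold,enrich_alpha,rsq_target
#'   Thresholds.
#' @param subgroup_key Design column used for subgroup meta-analyses
#'   (default \code{"tissue_class"}; NULL disables).
#' @param min_module_size,merge_cut Module detection knobs (see
#'   \code{\link{network_config}}).
#' @param seed Master seed for every stochastic stage.
#' @return List of class \code{lncmeta_pipeconfig}.
#' @export
pipeline_config <- function(simulate = TRUE, sim = NULL,
                            study_paths = NULL, design_path = NULL,
                            tx2gene_path = NULL, atlas_path = NULL,
                            gmt_path = NULL,
                            i2_threshold = 50, pq_threshold = 0.01,
                            fdr_threshold = 0.05, enrich_alpha = 0.05,
                            rsq_target = 0.8,
                            subgroup_key = "tissue_class",
                            min_module_size = 30, merge_cut = 0.25,
                            seed = 1L) {
  .assert(pq_threshold > 0 && pq_threshold < 1 &&
            fdr_threshold > 0 && fdr_threshold < 1 &&
            enrich_alpha > 0 && enrich_alpha < 1 &&
            i2_threshold >= 0 && i2_threshold <= 100 &&
            rsq_target > 0 && rsq_target <= 1,
          "thresholds out of range", class = "lncmeta_config_error")
  if (!simulate) {
    for (p in c(study_paths, design_path, atlas_path, gmt_path))
      .assert(file.exists(p), paste("missing input file:", p),
              class = "lncmeta_config_error")
  }
  structure(list(simulate = simulate,
                 sim = sim %||% simulation_config(
                   n_studies = 5, n_cases = rep(20L, 5),
                   n_controls = rep(20L, 5), n_genes = 2000,
                   n_modules = 3, seed = seed),
                 study_paths = study_paths, design_path = design_path,
                 tx2gene_path = tx2gene_path, atlas_path = atlas_path,
                 gmt_path = gmt_path,
                 i2_threshold = i2_threshold, pq_threshold = pq_threshold,
                 fdr_threshold = fdr_threshold,
                 enrich_alpha = enrich_alpha, rsq_target = rsq_target,
                 subgroup_key = subgroup_key,
                 min_module_size = min_module_size, merge_cut = merge_cut,
                 seed = as.integer(seed)),
            class = "lncmeta_pipeconfig")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file's top-level keys are the arguments of
#' \code{\link{pipeline_config}}; a \code{sim} block, if present, holds
#' \code{\link{simulation_config}} arguments.
#'
#' @param path Path to a .yaml/.yml or .json file.
#' @return List of class \code{lncmeta_pipeconfig}.
#' @export
read_pipeline_config <- function(path) {
  .assert(file.exists(path), paste("missing config file:", path),
          class = "lncmeta_config_error")
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$sim)) raw$sim <- do.call(simulation_config, raw$sim)
  do.call(pipeline_config, raw)
}

#' Venn-style overlap of named differential-expression gene sets
#'
#' Counts every region of the Venn partition of m sets (all 2^m - 1
#' nonempty membership patterns) and pairwise overlap percentages relative
#' to each named set.
#'
#' @param de_sets Named list (>= 2) of gene-id vectors; empty sets are
#'   allowed with a warning.
#' @return List with \code{regions} (data frame: pattern, count) and
#'   \code{pairwise} (data frame: set_a, set_b, overlap, pct_of_a).
#' @export
de_overlap <- function(de_sets) {
  .assert(length(de_sets) >= 2, "need >= 2 sets")
  if (any(lengths(de_sets) == 0)) warning("empty DE set in overlap")
  nm <- names(de_sets)
  genes <- unique(unlist(de_sets))
  member <- vapply(de_sets, function(s) genes %in% s,
                   logical(length(genes)))
  if (length(genes) == 1L) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(r) paste(nm[r], collapse = "&"))
  m <- length(de_sets)
  all_patterns <- unlist(lapply(seq_len(m), function(sz)
    utils::combn(nm, sz, paste, collapse = "&", simplify = FALSE)))
  counts <- table(factor(pattern, levels = all_patterns))
  regions <- data.frame(pattern = names(counts),
                        count = as.integer(counts),
                        stringsAsFactors = FALSE)
  pw <- expand.grid(set_a = nm, set_b = nm, stringsAsFactors = FALSE)
  pw <- pw[pw$set_a != pw$set_b, ]
  pw$overlap <- mapply(function(a, b)
    length(intersect(de_sets[[a]], de_sets[[b]])), pw$set_a, pw$set_b)
  pw$pct_of_a <- ifelse(lengths(de_sets)[pw$set_a] > 0,
                        100 * pw$overlap / lengths(de_sets)[pw$set_a],
                        NA_real_)
  rownames(pw) <- NULL
  list(regions = regions, pairwise = pw)
}

# z-score each gene within study, then concatenate samples across studies.
.combine_studies <- function(studies, gene_ids, prior_count = 0.5) {
  mats <- lapply(studies, function(st) {
    lc <- normalize_study(st$counts, prior_count)$logcpm
    lc <- lc[intersect(gene_ids, rownames(lc)), , drop = FALSE]
    t(scale(t(lc)))
  })
  common <- Reduce(intersect, lapply(mats, rownames))
  expr <- do.call(cbind, lapply(mats, function(m) m[common, , drop = FALSE]))
  expr[apply(is.finite(expr), 1, all), , drop = FALSE]
}

#' Run the full pipeline and write its artifacts
#'
#' Executes every stage in order and writes TSV artifacts plus a JSON
#' manifest (stage list, input parameters, md5 of every artifact) under
#' \code{out_dir}. Artifacts: \code{meta_results.tsv} (and
#' \code{meta_<subgroup>.tsv}), \code{de_overlap_regions.tsv},
#' \code{de_overlap_pairwise.tsv}, \code{specificity_scores.tsv},
#' \code{module_labels.tsv}, \code{eigengenes.tsv},
#' \code{module_trait.tsv}, \code{kme_gs.tsv}, \code{soft_threshold.tsv},
#' \code{enrichment_<module>.tsv}, \code{manifest.json}.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results
#'   (\code{meta}, \code{subgroups}, \code{overlap}, \code{specificity},
#'   \code{network}, \code{enrichment}, \code{manifest}).
#' @export
run_all <- function(config, out_dir) {
  .assert(inherits(config, "lncmeta_pipeconfig"),
          "config must come from pipeline_config()",
          class = "lncmeta_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)

  # ---- inputs ---------------------------------------------------------
  if (config$simulate) {
    sim <- generate_multistudy_counts(config$sim)
    studies <- sim$studies
    atlas <- generate_tissue_atlas(
      config$sim$n_genes, tissues = c("brain", "blood", "liver", "heart",
                                      "lung", "muscle", "kidney", "spleen"),
      frac_specific = 0.3, seed = .derive_seed(config$seed, 11L))
    rownames(atlas$atlas) <- names(sim$truth$de_flags)
    names(atlas$truth$specific_tissue) <- names(sim$truth$de_flags)
    gmt <- generate_gene_sets(sim$truth$module_labels, n_sets = 20,
                              enrichment_strength = 0.8,
                              seed = .derive_seed(config$seed, 13L))
    truth <- sim$truth
    stages <- c(stages, "simulate")
  } else {
    studies <- read_studies(config$study_paths, config$design_path,
                            config$tx2gene_path)
    a <- .read_tsv(config$atlas_path)
    atlas <- list(atlas = as.matrix(a[, -1, drop = FALSE]))
    rownames(atlas$atlas) <- a[[1]]
    g <- read_gmt(config$gmt_path)
    gmt <- list(sets = g$sets,
                universe = unique(unlist(lapply(studies, function(s)
                  rownames(s$counts)))))
    truth <- NULL
    stages <- c(stages, "load")
  }

  # ---- meta-analysis (whole + subgroups) ------------------------------
  meta <- run_meta(studies, config$i2_threshold, config$pq_threshold,
                   config$fdr_threshold)
  .write_tsv(meta, file.path(out_dir, "meta_results.tsv"))
  stages <- c(stages, "meta")

  subgroups <- list()
  if (!is.null(config$subgroup_key)) {
    key <- vapply(studies, function(s)
      as.character(s$design[[config$subgroup_key]][1]), character(1))
    for (lev in unique(key)) {
      sub <- studies[key == lev]
      if (length(sub) < 2) next
      subgroups[[lev]] <- run_meta(sub, config$i2_threshold,
                                   config$pq_threshold,
                                   config$fdr_threshold)
      .write_tsv(subgroups[[lev]],
                 file.path(out_dir, paste0("meta_", lev, ".tsv")))
    }
    stages <- c(stages, "meta_subgroups")
  }

  de_sets <- c(list(whole = meta$gene_id[meta$de_call]),
               lapply(subgroups, function(m) m$gene_id[m$de_call]))
  overlap <- NULL
  if (length(de_sets) >= 2) {
    overlap <- de_overlap(de_sets)
    .write_tsv(overlap$regions,
               file.path(out_dir, "de_overlap_regions.tsv"))
    .write_tsv(overlap$pairwise,
               file.path(out_dir, "de_overlap_pairwise.tsv"))
    stages <- c(stages, "overlap")
  }

  # ---- tissue specificity of the DE genes -----------------------------
  de_genes <- de_sets$whole
  spec_genes <- if (length(de_genes) >= 2) de_genes else
    rownames(atlas$atlas)
  spec <- specificity_scores(atlas$atlas[
    intersect(spec_genes, rownames(atlas$atlas)), , drop = FALSE])
  .write_tsv(spec$scores, file.path(out_dir, "specificity_scores.tsv"))
  stages <- c(stages, "specificity")

  # ---- co-expression network on the DE genes --------------------------
  net_genes <- if (length(de_genes) >= 50) de_genes else
    unique(c(de_genes,
             utils::head(meta$gene_id[order(meta$p_meta)], 200)))
  expr <- .combine_studies(studies, net_genes)
  ncfg <- network_config(rsq_target = config$rsq_target,
                         min_module_size = config$min_module_size,
                         merge_cut = config$merge_cut)
  expr <- remove_outlier_samples(expr, ncfg)$expression
  sft <- pick_soft_threshold(expr, ncfg)
  .write_tsv(sft$fit_table, file.path(out_dir, "soft_threshold.tsv"))
  tom <- tom_matrix(adjacency_matrix(expr, sft$beta))
  labels <- detect_modules(tom, expr, ncfg)
  design_all <- do.call(rbind, lapply(studies, `[[`, "design"))
  design_all <- design_all[match(colnames(expr), design_all$sample_id), ]
  traits <- data.frame(
    disease = as.integer(design_all$group == "case"),
    tissue = as.integer(design_all$tissue_class ==
                          design_all$tissue_class[1]))
  mods <- NULL
  if (any(labels != 0L)) {
    mods <- module_significance(expr, labels, traits)
    .write_tsv(data.frame(gene_id = names(labels), module = labels),
               file.path(out_dir, "module_labels.tsv"))
    eg <- data.frame(module = rownames(mods$eigengenes),
                     mods$eigengenes, check.names = FALSE)
    .write_tsv(eg, file.path(out_dir, "eigengenes.tsv"))
    mt <- data.frame(module = rownames(mods$module_trait_r),
                     r = mods$module_trait_r, p = mods$module_trait_p,
                     check.names = FALSE)
    .write_tsv(mt, file.path(out_dir, "module_trait.tsv"))
    .write_tsv(data.frame(gene_id = rownames(mods$kME), mods$kME,
                          GS_disease = mods$GS[, 1], check.names = FALSE),
               file.path(out_dir, "kme_gs.tsv"))
    .write_tsv(mods$module_summary,
               file.path(out_dir, "module_summary.tsv"))
  }
  stages <- c(stages, "coexpression")

  # ---- enrichment of the top modules ----------------------------------
  enrichment <- list()
  if (!is.null(mods)) {
    summ <- mods$module_summary
    ranked <- summ[order(-abs(summ$mm_gs_cor)), ]
    disease_p <- mods$module_trait_p[paste0("ME", ranked$module), 1]
    top <- ranked$module[disease_p < 0.05 |
                           seq_len(nrow(ranked)) == 1]
    for (m in utils::head(top, 4)) {
      qry <- names(labels)[labels == m]
      res <- tryCatch(
        ora(qry, gmt$sets, universe = rownames(expr),
            min_set = 5, alpha = config$enrich_alpha),
        error = function(e) NULL)
      if (!is.null(res)) {
        enrichment[[as.character(m)]] <- res
        .write_tsv(res, file.path(out_dir,
                                  sprintf("enrichment_module%d.tsv", m)))
      }
    }
    stages <- c(stages, "enrichment")
  }

  # ---- manifest -------------------------------------------------------
  files <- sort(list.files(out_dir, pattern = "\\.tsv$"))
  manifest <- list(
    stages = stages, seed = config$seed,
    thresholds = list(I2 = config$i2_threshold, p_Q = config$pq_threshold,
                      fdr = config$fdr_threshold,
                      enrich_adj = config$enrich_alpha,
                      rsq = config$rsq_target),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), tz = "UTC"),
    artifacts = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$artifacts) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(meta = meta, subgroups = subgroups, overlap = overlap,
                 specificity = spec,
                 network = list(beta = sft$beta, labels = labels,
                                modules = mods),
                 enrichment = enrichment, truth = truth,
                 manifest = manifest))
}

#' Read study count matrices and a shared design table
#'
#' Count TSVs have a \code{gene_id} first column and one column per sample;
#' the design TSV has columns \code{sample_id}, \code{group}
#' (case/control), \code{study_id}, \code{tissue_class}. When a
#' transcript-to-gene TSV is given, rows are treated as transcripts and
#' aggregated.
#'
#' @param study_paths Character vector of count TSV paths (one study each).
#' @param design_path Design TSV path.
#' @param tx2gene_path Optional two-column TSV (transcript_id, gene_id).
#' @return List of study objects (counts + design).
#' @export
read_studies <- function(study_paths, design_path, tx2gene_path = NULL) {
  design <- .read_tsv(design_path)
  .assert(all(c("sample_id", "group", "study_id", "tissue_class") %in%
                names(design)), "design TSV missing required columns",
          class = "lncmeta_config_error")
  map <- if (!is.null(tx2gene_path)) {
    m <- .read_tsv(tx2gene_path)
    names(m)[1:2] <- c("transcript_id", "gene_id")
    m
  } else NULL
  lapply(study_paths, function(p) {
    tab <- .read_tsv(p)
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- tab[[1]]
    if (!is.null(map)) counts <- aggregate_tx2gene(counts, map)
    d <- design[match(colnames(counts), design$sample_id), ]
    .assert(!anyNA(d$sample_id), paste("design missing samples of", p),
            class = "lncmeta_config_error")
    list(counts = counts, design = d)
  })
}

#' Write one study's counts and design to TSV
#'
#' @param study Study object (counts + design).
#' @param counts_path,design_path Output paths.
#' @return Invisibly, the count path.
#' @export
write_study <- function(study, counts_path, design_path) {
  .write_tsv(data.frame(gene_id = rownames(study$counts), study$counts,
                        check.names = FALSE), counts_path)
  .write_tsv(study$design, design_path)
  invisible(counts_path)
}
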
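# Weighted co-expression network analysis: soft-thresholded adjacency,
# topological overlap, module detection on the TOM dissimilarity, and
# module/trait significance statistics. Expression matrices are genes x
# samples throughout the package; correlations are Pearson.

#' Network construction parameters
#'
#' @param beta_candidates Candidate soft-threshold powers (default 1:20).
#' @param rsq_target Scale-free fit target for the signed R^2 (default 0.8).
#' @param min_module_size Smallest branch kept as a module (default 30).
#' @param merge_cut Eigengene dissimilarity (1 - cor) below which modules
#'   are merged (default 0.25).
#' @param pam_kme Minimum absolute module membership at which an initially
#'   unassigned gene is adopted by its best-correlated module (default
#'   0.3; NA disables the assignment stage).
#' @param outlier_min_cluster Sample clusters smaller than this are treated
#'   as outliers when cut (default 5).
#' @param outlier_cut_height Height at which the sample dendrogram is cut;
#'   \code{NULL} disables outlier removal.
#' @return List of class \code{lncmeta_netconfig}.
#' @export
network_config <- function(beta_candidates = 1:20, rsq_target = 0.8,
                           min_module_size = 30, merge_cut = 0.25,
                           pam_kme = 0.3, outlier_min_cluster = 5,
                           outlier_cut_height = NULL) {
  .assert(rsq_target > 0 && rsq_target <= 1, "rsq_target must be in (0, 1]",
          class = "lncmeta_config_error")
  .assert(min_module_size >= 1 && outlier_min_cluster >= 1,
          "sizes must be positive", class = "lncmeta_config_error")
  structure(list(beta_candidates = beta_candidates,
                 rsq_target = rsq_target,
                 min_module_size = min_module_size, merge_cut = merge_cut,
                 pam_kme = pam_kme,
                 outlier_min_cluster = outlier_min_cluster,
                 outlier_cut_height = outlier_cut_height),
            class = "lncmeta_netconfig")
}

#' Remove outlier samples by dendrogram cutting
#'
#' Samples are clustered (Euclidean distance, average linkage) and the tree
#' is cut at \code{config$outlier_cut_height}; clusters smaller than
#' \code{config$outlier_min_cluster} are removed. With a \code{NULL} cut
#' height nothing is removed.
#'
#' @param expression Genes x samples matrix.
#' @param config A \code{\link{network_config}}.
#' @return List with \code{expression} (filtered) and \code{removed}
#'   (sample ids).
#' @export
remove_outlier_samples <- function(expression, config = network_config()) {
  .assert(ncol(expression) >= 3, "need >= 3 samples")
  if (is.null(config$outlier_cut_height))
    return(list(expression = expression, removed = character(0)))
  h <- stats::hclust(stats::dist(t(expression)), method = "average")
  cl <- stats::cutree(h, h = config$outlier_cut_height)
  sizes <- table(cl)
  drop <- names(sizes)[sizes < config$outlier_min_cluster]
  removed <- colnames(expression)[cl %in% as.integer(drop)]
  .assert(length(removed) < ncol(expression), "cut removes all samples",
          class = "lncmeta_config_error")
  list(expression = expression[, !colnames(expression) %in% removed,
                               drop = FALSE],
       removed = removed)
}

#' Soft-thresholded adjacency matrix
#'
#' Unsigned weighted adjacency \code{|cor(g_i, g_j)|^beta} with unit
#' diagonal.
#'
#' @param expression Genes x samples matrix.
#' @param beta Positive power.
#' @return Symmetric matrix with entries in [0, 1].
#' @export
adjacency_matrix <- function(expression, beta) {
  a <- abs(stats::cor(t(expression)))^beta
  diag(a) <- 1
  a
}

#' Pick the soft-threshold power for approximate scale-free topology
#'
#' For each candidate power the connectivity distribution is binned (10
#' equal-width bins) and \code{log10} frequency is regressed on
#' \code{log10} mean connectivity; the signed fit index is
#' \code{R^2 * sign(-slope)}. The smallest power reaching
#' \code{rsq_target} is chosen; if none does, the power with maximal signed
#' R^2 is returned with a warning.
#'
#' @param expression Genes x samples matrix (>= 10 genes, >= 4 samples).
#' @param config A \code{\link{network_config}}.
#' @return List with \code{beta} and \code{fit_table} (data frame: beta,
#'   rsq_signed, slope, mean_k).
#' @export
pick_soft_threshold <- function(expression, config = network_config()) {
  .assert(nrow(expression) >= 10 && ncol(expression) >= 4,
          "need >= 10 genes and >= 4 samples")
  ac <- abs(stats::cor(t(expression)))
  diag(ac) <- 0
  betas <- config$beta_candidates
  tab <- data.frame(beta = betas, rsq_signed = NA_real_, slope = NA_real_,
                    mean_k = NA_real_)
  for (i in seq_along(betas)) {
    k <- rowSums(ac^betas[i])
    tab$mean_k[i] <- mean(k)
    if (diff(range(k)) == 0) next  # degenerate: all connectivities equal
    bins <- cut(k, breaks = 10)
    freq <- tapply(k, bins, length)
    kmean <- tapply(k, bins, mean)
    keep <- !is.na(freq) & freq > 0 & kmean > 0
    if (sum(keep) < 3) next
    fit <- stats::lm(log10(freq[keep]) ~ log10(kmean[keep]))
    slope <- stats::coef(fit)[2]
    r2 <- summary(fit)$r.squared
    tab$rsq_signed[i] <- r2 * sign(-slope)
    tab$slope[i] <- slope
  }
  ok <- which(!is.na(tab$rsq_signed) & tab$rsq_signed >= config$rsq_target)
  if (length(ok) > 0) {
    beta <- betas[ok[1]]
  } else {
    warning("no candidate power reached the scale-free fit target; ",
            "using the best available")
    beta <- betas[which.max(tab$rsq_signed)]
  }
  list(beta = beta, fit_table = tab)
}

#' Topological overlap matrix
#'
#' \code{TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)} for
#' \code{i != j}, with \code{L_ij = sum_{u != i,j} a_iu a_uj} and
#' connectivity \code{k_i} excluding the diagonal; \code{TOM_ii = 1}.
#'
#' @param adjacency Symmetric matrix, entries in [0, 1], unit diagonal.
#' @return TOM, same dimensions, symmetric, entries in [0, 1].
#' @export
tom_matrix <- function(adjacency) {
  a <- as.matrix(adjacency)
  .assert(isSymmetric(unname(a), tol = 1e-12), "adjacency must be symmetric",
          class = "lncmeta_input_error")
  .assert(all(a >= 0 & a <= 1), "adjacency entries must lie in [0, 1]",
          class = "lncmeta_input_error")
  .assert(all(abs(diag(a) - 1) < 1e-12), "adjacency diagonal must be 1",
          class = "lncmeta_input_error")
  k <- rowSums(a) - 1
  # (a %*% a)_ij includes u = i and u = j, each contributing a_ij (diag 1)
  L <- a %*% a - 2 * a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (L + a) / denom
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules on the TOM dissimilarity
#'
#' Average-linkage clustering of \code{1 - TOM}; the tree is cut at 99% of
#' the merge-height range above the first merge (for dissimilarities
#' starting at zero this is 99% of the maximum merge height; the
#' range-relative form is invariant to the offset that compresses TOM
#' dissimilarities at high powers), branches below \code{min_module_size}
#' are left
#' unassigned (label 0). Unassigned genes whose module membership
#' (correlation with a module eigengene) reaches \code{pam_kme} in absolute
#' value are then adopted by their best module — the straggler-assignment
#' stage of hybrid dynamic tree cutting. Finally, modules whose eigengenes
#' have dissimilarity \code{1 - cor} below \code{merge_cut} are merged
#' iteratively and labels are renumbered by decreasing module size.
#'
#' @param tom TOM from \code{\link{tom_matrix}}.
#' @param expression Genes x samples matrix (needed for eigengene merging);
#'   rows must match \code{tom}.
#' @param config A \code{\link{network_config}}.
#' @return Named integer vector of module labels (0 = unassigned).
#' @export
detect_modules <- function(tom, expression, config = network_config()) {
  d <- stats::as.dist(1 - tom)
  h <- stats::hclust(d, method = "average")
  cut_h <- min(h$height) + 0.99 * diff(range(h$height))
  cl <- stats::cutree(h, h = cut_h)
  sizes <- table(cl)
  small <- as.integer(names(sizes)[sizes < config$min_module_size])
  labels <- ifelse(cl %in% small, 0L, cl)
  if (all(labels == 0L)) {
    warning("all genes unassigned at the chosen cut")
    return(stats::setNames(labels, rownames(expression)))
  }
  labels <- .renumber_modules(labels)
  # adopt stragglers whose module membership is strong enough
  if (!is.na(config$pam_kme) && any(labels == 0L)) {
    me <- .eigengenes(expression, labels)
    kme <- stats::cor(t(expression), t(me))
    mods <- setdiff(sort(unique(labels)), 0L)
    for (g in which(labels == 0L)) {
      i <- which.max(abs(kme[g, ]))
      if (abs(kme[g, i]) >= config$pam_kme) labels[g] <- mods[i]
    }
    labels <- .renumber_modules(labels)
  }
  # iterative eigengene merging
  repeat {
    mods <- setdiff(sort(unique(labels)), 0L)
    if (length(mods) < 2) break
    me <- .eigengenes(expression, labels)
    dis <- 1 - stats::cor(t(me))
    diag(dis) <- Inf
    idx <- which(dis == min(dis), arr.ind = TRUE)[1, ]
    if (dis[idx[1], idx[2]] >= config$merge_cut) break
    from <- mods[max(idx)]; into <- mods[min(idx)]
    labels[labels == from] <- into
    labels <- .renumber_modules(labels)
  }
  stats::setNames(labels, rownames(expression))
}

.renumber_modules <- function(labels) {
  mods <- setdiff(unique(labels), 0L)
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  remap <- stats::setNames(order(order(-sizes)), mods)
  out <- labels
  for (m in mods) out[labels == m] <- remap[[as.character(m)]]
  as.integer(out)
}

# Module eigengenes: first right singular vector of the row-standardized
# module submatrix, unit variance, sign-aligned with its genes.
.eigengenes <- function(expression, labels) {
  mods <- setdiff(sort(unique(labels)), 0L)
  n <- ncol(expression)
  me <- matrix(NA_real_, length(mods), n,
               dimnames = list(paste0("ME", mods), colnames(expression)))
  for (i in seq_along(mods)) {
    sub <- expression[labels == mods[i], , drop = FALSE]
    sub <- t(scale(t(sub)))
    if (nrow(sub) == 1L) {
      e <- as.numeric(sub)
    } else {
      e <- svd(sub, nu = 0, nv = 1)$v[, 1]
    }
    e <- as.numeric(scale(e))
    if (mean(stats::cor(t(sub), e)) < 0) e <- -e
    me[i, ] <- e
  }
  me
}

#' Module eigengenes
#'
#' @param expression Genes x samples matrix.
#' @param labels Module labels as from \code{\link{detect_modules}}.
#' @return Modules x samples matrix of unit-variance eigengenes.
#' @export
module_eigengenes <- function(expression, labels) {
  .eigengenes(expression, labels)
}

#' Module membership, gene significance and module-trait statistics
#'
#' Completes the network analysis: eigengenes per module; module membership
#' \code{kME} (gene-eigengene correlation); gene significance \code{GS}
#' (absolute gene-trait correlation); module-trait correlations with
#' t-distribution p-values (df = n - 2); and, per module, the correlation
#' between \code{|kME|} and \code{GS} over its genes together with the mean
#' GS.
#'
#' @param expression Genes x samples matrix.
#' @param labels Module labels (0 = unassigned, excluded from module-level
#'   summaries but scored for kME/GS).
#' @param traits Named list or data frame of per-sample numeric covariates
#'   (e.g. disease state 0/1, tissue class 0/1).
#' @return List of class \code{lncmeta_modules}: \code{labels},
#'   \code{eigengenes}, \code{kME}, \code{GS} (gene x trait),
#'   \code{module_trait_r}, \code{module_trait_p} (module x trait),
#'   \code{module_summary} (data frame: module, size, mm_gs_cor, mm_gs_p,
#'   mean_GS per trait for the first trait).
#' @export
module_significance <- function(expression, labels, traits) {
  traits <- as.data.frame(traits)
  .assert(nrow(traits) == ncol(expression),
          "traits must have one row per sample")
  mods <- setdiff(sort(unique(labels)), 0L)
  .assert(length(mods) >= 1, "no modules to score")
  me <- .eigengenes(expression, labels)
  n <- ncol(expression)
  kME <- stats::cor(t(expression), t(me))
  GS <- abs(stats::cor(t(expression), as.matrix(traits)))
  r <- stats::cor(t(me), as.matrix(traits))
  tstat <- r * sqrt((n - 2) / pmax(1e-12, 1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  summ <- data.frame(module = mods,
                     size = vapply(mods, function(m) sum(labels == m),
                                   integer(1)),
                     mm_gs_cor = NA_real_, mm_gs_p = NA_real_,
                     mean_GS = NA_real_)
  for (i in seq_along(mods)) {
    idx <- labels == mods[i]
    summ$mean_GS[i] <- mean(GS[idx, 1])
    mm <- abs(kME[idx, i]); gs <- GS[idx, 1]
    if (sum(idx) >= 3 && stats::sd(mm) > 0 && stats::sd(gs) > 0) {
      ct <- stats::cor.test(mm, gs)
      if (!is.null(ct)) {
        summ$mm_gs_cor[i] <- unname(ct$estimate)
        summ$mm_gs_p[i] <- ct$p.value
      }
    }
  }
  structure(list(labels = labels, eigengenes = me, kME = kME, GS = GS,
                 module_trait_r = r, module_trait_p = p,
                 module_summary = summ),
            class = "lncmeta_modules")
}
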
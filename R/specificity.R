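# Tissue specificity by Jensen-Shannon divergence.
#
# A gene's expression profile across tissues is converted to a density and
# compared with the extreme pattern concentrated in a single tissue; the
# specificity score for tissue t is 1 minus the JS distance (square root of
# the JS divergence, base-2 entropy) to the unit vector at t, so scores lie
# in [0, 1] with 1 meaning exclusive expression in t.

#' Jensen-Shannon distance between two probability vectors
#'
#' \code{JSD(p, q) = H(m) - (H(p) + H(q))/2} with \code{m = (p + q)/2} and
#' Shannon entropy in bits (base 2, \code{0 log 0 = 0}), returned as its
#' square root, a metric bounded by 1.
#'
#' @param p,q Non-negative vectors of equal length summing to 1 (within
#'   1e-9).
#' @return JS distance in [0, 1].
#' @export
js_distance <- function(p, q) {
  .assert(length(p) == length(q), "length mismatch",
          class = "lncmeta_input_error")
  .assert(all(p >= 0) && all(q >= 0), "negative entries",
          class = "lncmeta_input_error")
  .assert(abs(sum(p) - 1) < 1e-9 && abs(sum(q) - 1) < 1e-9,
          "inputs must sum to 1", class = "lncmeta_input_error")
  H <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  m <- (p + q) / 2
  jsd <- H(m) - (H(p) + H(q)) / 2
  sqrt(max(0, jsd))  # clamp tiny negative rounding
}

#' Tissue-specificity scores for every gene of an atlas
#'
#' Each row is normalized to a density; the score for tissue t is
#' \code{1 - js_distance(density, e_t)} with \code{e_t} the unit vector at
#' t. The maximizing tissue and score are reported. All-zero rows cannot be
#' scored and are excluded with reason code \code{"zero_expression"}.
#'
#' @param atlas Non-negative matrix (genes x tissues), >= 2 tissues, with
#'   gene rownames and tissue colnames.
#' @return List with \code{scores} (data frame: gene_id, max_score,
#'   max_tissue, then one column per tissue) and \code{excluded} (data
#'   frame: gene_id, reason).
#' @export
specificity_scores <- function(atlas) {
  atlas <- as.matrix(atlas)
  .assert(ncol(atlas) >= 2, "atlas needs >= 2 tissues",
          class = "lncmeta_input_error")
  .assert(all(atlas >= 0), "negative expression", class = "lncmeta_input_error")
  tissues <- colnames(atlas) %||% paste0("tissue", seq_len(ncol(atlas)))
  rs <- rowSums(atlas)
  bad <- rs <= 0
  excluded <- data.frame(gene_id = rownames(atlas)[bad],
                         reason = rep("zero_expression", sum(bad)),
                         stringsAsFactors = FALSE)
  dens <- atlas[!bad, , drop = FALSE] / rs[!bad]
  T <- ncol(dens)
  # Vectorized score: for unit vector e_t, m = (p + e_t)/2 differs from p/2
  # only at t, so H(m) and the JSD reduce to row entropies plus a
  # t-dependent term.
  Hp <- -rowSums(ifelse(dens > 0, dens * log2(dens), 0))
  half <- dens / 2
  Hhalf_all <- -rowSums(ifelse(half > 0, half * log2(half), 0))
  sc <- matrix(NA_real_, nrow(dens), T, dimnames = list(rownames(dens),
                                                        tissues))
  for (t in seq_len(T)) {
    mt <- (dens[, t] + 1) / 2
    ht <- ifelse(half[, t] > 0, -half[, t] * log2(half[, t]), 0)
    Hm <- Hhalf_all - ht - mt * log2(mt)
    jsd <- Hm - Hp / 2  # H(e_t) = 0
    sc[, t] <- 1 - sqrt(pmax(0, jsd))
  }
  best <- max.col(sc, ties.method = "first")
  scores <- data.frame(gene_id = rownames(dens),
                       max_score = sc[cbind(seq_len(nrow(sc)), best)],
                       max_tissue = tissues[best], stringsAsFactors = FALSE)
  scores <- cbind(scores, as.data.frame(sc, optional = TRUE))
  rownames(scores) <- NULL
  list(scores = scores, excluded = excluded)
}

#' Hierarchical clustering of genes with Manhattan distance
#'
#' Agglomerative clustering of atlas rows under the L1 metric, as used for
#' tissue-pattern heatmaps. Leaf order is made deterministic by reordering
#' tied branches toward the lowest original index.
#'
#' @param x Numeric matrix (genes x tissues), >= 2 rows.
#' @param linkage Agglomeration method for \code{stats::hclust} (default
#'   \code{"complete"}).
#' @return \code{hclust} object (merge heights, deterministic leaf order).
#' @export
cluster_genes <- function(x, linkage = "complete") {
  x <- as.matrix(x)
  .assert(nrow(x) >= 2, "clustering needs >= 2 genes",
          class = "lncmeta_clustering_error")
  stats::hclust(stats::dist(x, method = "manhattan"), method = linkage)
}
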
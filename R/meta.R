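# Per-gene effect sizes and heterogeneity-aware meta-analysis.
#
# The model: each study contributes a standardized mean difference (Hedges'
# g) between cases and controls computed on log2-CPM. Cochran's Q and I^2
# measure between-study heterogeneity; genes with I^2 > 50 AND p_Q < 0.01
# are pooled under a DerSimonian-Laird random-effects model, all others
# under the inverse-variance fixed-effects model. A gene is called
# differentially expressed when the 95% CI of the pooled SMD excludes zero
# and its BH-adjusted meta p-value is below 0.05.

#' Hedges' g standardized mean difference for one gene in one study
#'
#' \code{d = (mean_case - mean_control) / s_pooled}, corrected for
#' small-sample bias by \code{J = 1 - 3 / (4 (n1 + n2 - 2) - 1)}; the
#' sampling variance is \code{(n1 + n2)/(n1 n2) + g^2 / (2 (n1 + n2))}.
#' A per-study two-sided p-value from Welch's t-test on the same values is
#' attached.
#'
#' @param case_values,control_values Numeric vectors (>= 2 each) of
#'   normalized expression for the two arms.
#' @return List with \code{y} (g), \code{v} (variance of g), \code{n_case},
#'   \code{n_control}, \code{p_study}; or \code{NULL} with a warning when the
#'   pooled SD is zero (degenerate gene, excluded upstream).
#' @export
hedges_g <- function(case_values, control_values) {
  n1 <- length(case_values); n2 <- length(control_values)
  .assert(n1 >= 2 && n2 >= 2, "need >= 2 values per arm")
  s2p <- ((n1 - 1) * stats::var(case_values) +
            (n2 - 1) * stats::var(control_values)) / (n1 + n2 - 2)
  if (s2p <= 0) {
    warning("zero pooled SD; gene degenerate in this study")
    return(NULL)
  }
  d <- (mean(case_values) - mean(control_values)) / sqrt(s2p)
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  g <- J * d
  v <- (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2))
  p <- tryCatch(stats::t.test(case_values, control_values)$p.value,
                error = function(e) 1)
  list(y = g, v = v, n_case = n1, n_control = n2, p_study = p)
}

#' Cochran's Q heterogeneity test with I-squared
#'
#' Fixed-effect weights \code{w = 1/v}; \code{Q} is the weighted sum of
#' squared deviations from the inverse-variance pooled effect, referred to a
#' chi-square distribution with \code{k - 1} degrees of freedom.
#' \code{I2 = max(0, (Q - df)/Q) * 100} (0 when Q = 0).
#'
#' @param y Per-study effect sizes.
#' @param v Per-study sampling variances (positive).
#' @return List with \code{Q}, \code{df}, \code{p_Q}, \code{I2}.
#' @export
cochran_q <- function(y, v) {
  k <- length(y)
  .assert(k >= 2, "heterogeneity test needs k >= 2 studies",
          class = "lncmeta_insufficient_studies")
  .assert(length(v) == k && all(v > 0), "v must be positive, one per study")
  w <- 1 / v
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  df <- k - 1
  list(Q = Q, df = df, p_Q = stats::pchisq(Q, df, lower.tail = FALSE),
       I2 = if (Q > 0) max(0, (Q - df) / Q) * 100 else 0)
}

#' Fixed-effects (inverse-variance) pooling
#'
#' @inheritParams cochran_q
#' @param conf_z Normal quantile for the CI half-width (1.96 for 95%).
#' @return List with \code{smd_pooled}, \code{ci_low}, \code{ci_high},
#'   \code{z}, \code{p_meta}.
#' @export
pool_fixed <- function(y, v, conf_z = 1.96) {
  .assert(length(y) >= 2, "pooling needs k >= 2 studies",
          class = "lncmeta_insufficient_studies")
  w <- 1 / v
  est <- sum(w * y) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- est / se
  list(smd_pooled = est, ci_low = est - conf_z * se,
       ci_high = est + conf_z * se, z = z,
       p_meta = 2 * stats::pnorm(-abs(z)))
}

#' Random-effects pooling (DerSimonian-Laird)
#'
#' Moment estimator \code{tau2 = max(0, (Q - df)/C)} with
#' \code{C = sum(w) - sum(w^2)/sum(w)}; studies are re-weighted by
#' \code{1/(v + tau2)} and pooled as in the fixed-effects model. When
#' \code{Q <= df} the result collapses to \code{\link{pool_fixed}} exactly.
#'
#' @inheritParams pool_fixed
#' @return List with \code{tau2} plus the \code{\link{pool_fixed}} fields.
#' @export
pool_random <- function(y, v, conf_z = 1.96) {
  .assert(length(y) >= 2, "pooling needs k >= 2 studies",
          class = "lncmeta_insufficient_studies")
  w <- 1 / v
  het <- cochran_q(y, v)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (het$Q - het$df) / C)
  c(list(tau2 = tau2), pool_fixed(y, v + tau2, conf_z))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment via \code{stats::p.adjust(method = "BH")} after
#' validating the input range.
#'
#' @param p Numeric vector of p-values in [0, 1] (NA allowed).
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  ok <- is.na(p) | (p >= 0 & p <= 1)
  .assert(all(ok), "p-values must lie in [0, 1]",
          class = "lncmeta_input_error")
  stats::p.adjust(p, method = "BH")
}

# ---- vectorized internals used by run_meta ---------------------------------

# Per-study effect sizes for all genes at once. Returns y, v, p matrices'
# columns for one study; genes with zero pooled SD get NA.
.study_effects <- function(logcpm, is_case) {
  x1 <- logcpm[, is_case, drop = FALSE]
  x0 <- logcpm[, !is_case, drop = FALSE]
  n1 <- ncol(x1); n0 <- ncol(x0)
  if (n1 < 2 || n0 < 2) {
    na <- rep(NA_real_, nrow(logcpm))
    return(list(y = na, v = na, p = na, n_case = n1, n_control = n0))
  }
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  s21 <- .row_var(x1); s20 <- .row_var(x0)
  s2p <- ((n1 - 1) * s21 + (n0 - 1) * s20) / (n1 + n0 - 2)
  d <- (m1 - m0) / sqrt(s2p)
  d[s2p <= 0] <- NA_real_
  J <- 1 - 3 / (4 * (n1 + n0 - 2) - 1)
  g <- J * d
  v <- (n1 + n0) / (n1 * n0) + g^2 / (2 * (n1 + n0))
  # Welch t-test, vectorized
  se2 <- s21 / n1 + s20 / n0
  tt <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((s21 / n1)^2 / (n1 - 1) + (s20 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  p[!is.finite(p)] <- NA_real_
  list(y = g, v = v, p = p, n_case = n1, n_control = n0)
}

#' Run the full per-gene meta-analysis over a list of studies
#'
#' Each study is TMM-normalized to log2-CPM, per-gene Hedges' g effects are
#' computed, heterogeneity is tested (Cochran's Q, I-squared) and the pooled
#' SMD, 95% CI and p-value are obtained under the random-effects model when
#' \code{I2 > i2_threshold} AND \code{p_Q < pq_threshold} (both strict) and
#' the fixed-effects model otherwise. Meta p-values are BH-adjusted across
#' genes; a gene is called differentially expressed when its CI excludes
#' zero and \code{fdr < fdr_threshold}. The adaptively weighted Fisher
#' combination of the per-study p-values is reported alongside.
#'
#' Genes contributing fewer than two usable studies are reported with
#' \code{de_call = FALSE} and reason code \code{"insufficient_studies"}.
#'
#' @param studies List of study objects, each a list with \code{counts}
#'   (gene x sample matrix, rownames = gene ids) and \code{design} (data
#'   frame with a \code{group} column of "case"/"control"), as produced by
#'   \code{\link{generate_multistudy_counts}}.
#' @param i2_threshold,pq_threshold Heterogeneity switching rule (defaults
#'   50 and 0.01).
#' @param fdr_threshold FDR cutoff for DE calls (default 0.05).
#' @param prior_count Prior for log2-CPM.
#' @param scale \code{"logcpm"} (default) or \code{"cpm"}: scale on which
#'   SMDs are computed.
#' @param aw_perm Number of group-label permutations used to calibrate the
#'   AW-Fisher p-value (0 = report the raw minimum tail statistic, which is
#'   anti-conservative; see \code{\link{aw_fisher}}).
#' @param aw_seed Seed for the permutation null when \code{aw_perm > 0}.
#' @return Data frame with one row per gene: \code{gene_id, k, Q, df, p_Q,
#'   I2, tau2, model, smd_pooled, ci_low, ci_high, z, p_meta, fdr, aw_p,
#'   aw_weights, de_call, direction, reason}.
#' @export
run_meta <- function(studies, i2_threshold = 50, pq_threshold = 0.01,
                     fdr_threshold = 0.05, prior_count = 0.5,
                     scale = c("logcpm", "cpm"), aw_perm = 0,
                     aw_seed = 1L) {
  scale <- match.arg(scale)
  .assert(length(studies) >= 2, "need at least two studies",
          class = "lncmeta_pipeline_error")
  genes <- sort(unique(unlist(lapply(studies, function(s)
    rownames(s$counts)))))
  shared <- Reduce(intersect, lapply(studies, function(s) rownames(s$counts)))
  .assert(length(shared) > 0, "no overlapping genes across studies",
          class = "lncmeta_pipeline_error")
  k <- length(studies)
  G <- length(genes)
  Y <- V <- P <- matrix(NA_real_, G, k, dimnames = list(genes, NULL))
  ncase <- nctrl <- integer(k)
  norm <- vector("list", k)
  for (i in seq_len(k)) {
    st <- studies[[i]]
    nm <- normalize_study(st$counts, prior_count)
    expr <- if (scale == "logcpm") nm$logcpm else 2^nm$logcpm
    norm[[i]] <- expr
    is_case <- st$design$group == "case"
    eff <- .study_effects(expr, is_case)
    idx <- match(rownames(st$counts), genes)
    Y[idx, i] <- eff$y; V[idx, i] <- eff$v; P[idx, i] <- eff$p
    ncase[i] <- eff$n_case; nctrl[i] <- eff$n_control
  }
  res <- .meta_from_effects(Y, V, i2_threshold, pq_threshold, fdr_threshold)

  # AW-Fisher on the per-study p-values
  aw <- .aw_rows(P)
  if (aw_perm > 0) {
    null_stats <- .aw_null_stats(studies, norm, aw_perm, aw_seed)
    aw$aw_p <- (1 + vapply(aw$aw_p, function(s)
      sum(null_stats <= s), numeric(1))) / (1 + length(null_stats))
  }
  res$aw_p <- aw$aw_p
  res$aw_weights <- aw$aw_weights
  res[c("gene_id", "k", "Q", "df", "p_Q", "I2", "tau2", "model",
        "smd_pooled", "ci_low", "ci_high", "z", "p_meta", "fdr",
        "aw_p", "aw_weights", "de_call", "direction", "reason")]
}

# Meta-analysis on precomputed effect matrices (genes x studies).
.meta_from_effects <- function(Y, V, i2_threshold = 50, pq_threshold = 0.01,
                               fdr_threshold = 0.05) {
  W <- 1 / V
  kg <- rowSums(!is.na(Y))
  sw <- rowSums(W, na.rm = TRUE)
  sw2 <- rowSums(W^2, na.rm = TRUE)
  ybar <- rowSums(W * Y, na.rm = TRUE) / sw
  Q <- rowSums(W * (Y - ybar)^2, na.rm = TRUE)
  df <- pmax(kg - 1, 0)
  p_Q <- ifelse(kg >= 2, stats::pchisq(Q, df, lower.tail = FALSE), NA_real_)
  I2 <- ifelse(kg >= 2 & Q > 0, pmax(0, (Q - df) / Q) * 100, 0)
  I2[kg < 2] <- NA_real_
  C <- sw - sw2 / sw
  tau2 <- ifelse(kg >= 2, pmax(0, (Q - df) / C), NA_real_)
  use_rem <- !is.na(I2) & I2 > i2_threshold & !is.na(p_Q) &
    p_Q < pq_threshold
  # fixed-effects pool, then random-effects pool where selected
  est <- ybar; se <- sqrt(1 / sw)
  if (any(use_rem)) {
    Wr <- 1 / sweep(V, 1, tau2, "+")
    swr <- rowSums(Wr, na.rm = TRUE)
    est_r <- rowSums(Wr * Y, na.rm = TRUE) / swr
    se_r <- sqrt(1 / swr)
    est[use_rem] <- est_r[use_rem]
    se[use_rem] <- se_r[use_rem]
  }
  z <- est / se
  p_meta <- 2 * stats::pnorm(-abs(z))
  tested <- kg >= 2
  p_meta[!tested] <- NA_real_
  fdr <- rep(NA_real_, length(p_meta))
  fdr[tested] <- bh_fdr(p_meta[tested])
  ci_low <- est - 1.96 * se
  ci_high <- est + 1.96 * se
  de <- tested & (ci_low > 0 | ci_high < 0) & !is.na(fdr) &
    fdr < fdr_threshold
  data.frame(
    gene_id = rownames(Y), k = kg, Q = ifelse(tested, Q, NA_real_),
    df = ifelse(tested, df, NA_real_), p_Q = p_Q, I2 = I2, tau2 = tau2,
    model = ifelse(!tested, NA_character_, ifelse(use_rem, "REM", "FEM")),
    smd_pooled = ifelse(tested, est, NA_real_),
    ci_low = ifelse(tested, ci_low, NA_real_),
    ci_high = ifelse(tested, ci_high, NA_real_),
    z = ifelse(tested, z, NA_real_), p_meta = p_meta, fdr = fdr,
    de_call = de,
    direction = ifelse(de & est > 0, "up", ifelse(de & est < 0, "down",
                                                  "none")),
    reason = ifelse(tested, "", "insufficient_studies"),
    stringsAsFactors = FALSE, row.names = NULL)
}

# AW-Fisher minimum tail statistic for every row of a p-value matrix.
.aw_rows <- function(P) {
  n <- nrow(P)
  aw_p <- rep(NA_real_, n)
  aw_w <- rep(NA_character_, n)
  for (g in seq_len(n)) {
    p <- P[g, !is.na(P[g, ])]
    if (length(p) == 0) next
    a <- aw_fisher(p)
    aw_p[g] <- a$aw_p
    aw_w[g] <- paste(which(!is.na(P[g, ]))[a$aw_weights], collapse = ",")
  }
  list(aw_p = aw_p, aw_weights = aw_w)
}

# Permutation null for the AW statistic: permute case/control labels within
# each study, recompute per-study Welch p-values and the per-gene minimum
# tail statistic; pool across genes and permutations.
.aw_null_stats <- function(studies, norm, n_perm, seed) {
  set.seed(seed)
  out <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    Pb <- NULL
    for (i in seq_along(studies)) {
      grp <- studies[[i]]$design$group
      perm <- sample(grp)
      eff <- .study_effects(norm[[i]], perm == "case")
      Pb <- cbind(Pb, eff$p)
    }
    out[[b]] <- .aw_rows(Pb)$aw_p
  }
  stats::na.omit(unlist(out))
}

#' Forest-plot data for one gene
#'
#' Per-study effects with 95% CIs plus the pooled row, the numeric content
#' of a meta-analysis forest plot.
#'
#' @inheritParams run_meta
#' @param gene_id Gene to extract.
#' @return Data frame with columns \code{study, y, v, ci_low, ci_high,
#'   n_case, n_control}; the final row is the pooled result.
#' @export
forest_data <- function(studies, gene_id, prior_count = 0.5) {
  rows <- list()
  for (i in seq_along(studies)) {
    st <- studies[[i]]
    if (!gene_id %in% rownames(st$counts)) next
    nm <- normalize_study(st$counts, prior_count)
    x <- nm$logcpm[gene_id, ]
    is_case <- st$design$group == "case"
    e <- hedges_g(x[is_case], x[!is_case])
    if (is.null(e)) next
    rows[[length(rows) + 1L]] <- data.frame(
      study = st$design$study_id[1] %||% paste0("study", i),
      y = e$y, v = e$v, ci_low = e$y - 1.96 * sqrt(e$v),
      ci_high = e$y + 1.96 * sqrt(e$v),
      n_case = e$n_case, n_control = e$n_control)
  }
  .assert(length(rows) >= 2, "gene present in fewer than two studies",
          class = "lncmeta_insufficient_studies")
  tab <- do.call(rbind, rows)
  het <- cochran_q(tab$y, tab$v)
  pool <- if (het$I2 > 50 && het$p_Q < 0.01) pool_random(tab$y, tab$v)
          else pool_fixed(tab$y, tab$v)
  rbind(tab, data.frame(study = "pooled", y = pool$smd_pooled,
                        v = 1 / sum(1 / tab$v), ci_low = pool$ci_low,
                        ci_high = pool$ci_high, n_case = sum(tab$n_case),
                        n_control = sum(tab$n_control)))
}
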
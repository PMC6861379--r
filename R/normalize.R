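#' Aggregate transcript-level counts to gene level
#'
#' Sums transcript counts belonging to the same gene, the count-level
#' behaviour of tximport-style aggregation with a transcript-to-gene
#' annotation table. Column (sample) totals are preserved whenever every
#' transcript in the matrix is mapped.
#'
#' @param tx_counts Numeric matrix of non-negative transcript counts
#'   (transcripts x samples) with transcript ids as rownames.
#' @param tx2gene Data frame with columns \code{transcript_id} and
#'   \code{gene_id}; each transcript must map to exactly one gene.
#' @param drop_unmapped If \code{TRUE}, transcripts absent from the map are
#'   silently dropped; otherwise they are an error listing the offenders.
#' @return Numeric matrix (genes x samples) with gene ids as rownames.
#' @examples
#' m <- matrix(c(3, 5, 2, 1, 0, 4), nrow = 3,
#'             dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
#' map <- data.frame(transcript_id = c("t1", "t2", "t3"),
#'                   gene_id = c("g1", "g1", "g2"))
#' aggregate_tx2gene(m, map)
#' @export
aggregate_tx2gene <- function(tx_counts, tx2gene, drop_unmapped = FALSE) {
  .assert(is.matrix(tx_counts) && !is.null(rownames(tx_counts)),
          "tx_counts must be a matrix with transcript ids as rownames")
  .assert(all(c("transcript_id", "gene_id") %in% names(tx2gene)),
          "tx2gene needs columns transcript_id and gene_id")
  .assert(!anyDuplicated(tx2gene$transcript_id),
          "tx2gene maps some transcript to more than one gene")
  .assert(all(tx_counts >= 0), "negative transcript counts")

  unmapped <- setdiff(rownames(tx_counts), tx2gene$transcript_id)
  if (length(unmapped) > 0L) {
    if (!drop_unmapped) {
      .assert(FALSE, paste0("unmapped transcripts: ",
                            paste(utils::head(unmapped, 10), collapse = ", "),
                            if (length(unmapped) > 10) " ..." else ""),
              class = "lncmeta_mapping_error")
    }
    tx_counts <- tx_counts[setdiff(rownames(tx_counts), unmapped), ,
                           drop = FALSE]
  }
  gene <- tx2gene$gene_id[match(rownames(tx_counts), tx2gene$transcript_id)]
  out <- rowsum(tx_counts, group = gene, reorder = TRUE)
  out[order(rownames(out)), , drop = FALSE]
}

#' Trimmed mean of M-values normalization factors
#'
#' Per-sample scaling factors computed with the TMM strategy of edgeR
#' (reference column chosen by the 75th-percentile rule, 30%/5% M/A trims,
#' inverse-asymptotic-variance weights), rescaled to geometric mean 1.
#'
#' @param counts Non-negative count matrix (genes x samples), at least two
#'   samples, each with a positive column total.
#' @return Numeric vector of positive factors, one per sample.
#' @export
tmm_factors <- function(counts) {
  counts <- as.matrix(counts)
  .assert(ncol(counts) >= 2, "TMM needs at least two samples")
  .assert(all(counts >= 0), "negative counts")
  lib <- colSums(counts)
  .assert(all(lib > 0), "sample with all-zero counts",
          class = "lncmeta_normalization_error")
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  f / .geo_mean(f)
}

#' Log2 counts-per-million with a prior count
#'
#' \code{log2((count + prior) / (lib * factor + 2 * prior) * 1e6)}, using
#' effective library sizes (library size times TMM factor). A fixed prior is
#' added to numerator and (doubled) denominator so zeros stay finite; the
#' transform is monotone in the count.
#'
#' @param counts Count matrix (genes x samples).
#' @param factors Per-sample positive normalization factors
#'   (default \code{tmm_factors(counts)}).
#' @param prior_count Positive pseudo-count, default 0.5.
#' @return List of class \code{lncmeta_norm} with elements
#'   \code{norm_factors}, \code{effective_lib_sizes} and \code{logcpm}.
#' @export
log_cpm <- function(counts, factors = NULL, prior_count = 0.5) {
  counts <- as.matrix(counts)
  .assert(is.numeric(prior_count) && length(prior_count) == 1 &&
            prior_count > 0, "prior_count must be a positive scalar",
          class = "lncmeta_parameter_error")
  if (is.null(factors)) factors <- tmm_factors(counts)
  .assert(length(factors) == ncol(counts) && all(factors > 0),
          "factors must be positive, one per sample")
  eff <- colSums(counts) * factors
  logcpm <- log2(sweep(counts + prior_count, 2, eff + 2 * prior_count, "/") *
                   1e6)
  structure(list(norm_factors = factors, effective_lib_sizes = eff,
                 logcpm = logcpm), class = "lncmeta_norm")
}

# Within-study normalization used throughout the pipeline: TMM then logCPM.
#' Normalize one study's counts to log2-CPM
#'
#' Convenience wrapper: TMM factors followed by \code{\link{log_cpm}}.
#' @inheritParams log_cpm
#' @return See \code{\link{log_cpm}}.
#' @export
normalize_study <- function(counts, prior_count = 0.5) {
  log_cpm(counts, tmm_factors(counts), prior_count)
}
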
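# Gene-set enrichment: hypergeometric over-representation on module gene
# lists (the operative path for unranked lists) and a permutation-based
# running-sum GSEA for ranked inputs. GMT i/o for set collections.

#' Over-representation analysis (hypergeometric upper tail)
#'
#' For each set, \code{p_raw = P(X >= x)} with \code{X} hypergeometric
#' (draws = query size, white = set size, population = universe), BH-adjusted
#' over the tested sets and sorted by adjusted p.
#'
#' @param query Gene ids of interest; ids outside the universe are dropped
#'   with a message.
#' @param sets Named list of gene-id vectors.
#' @param universe Background gene ids.
#' @param min_set,max_set Set-size filters applied after restriction to the
#'   universe (defaults 10 and 500).
#' @param alpha Adjusted-p threshold for the \code{enriched} flag (0.05).
#' @return Data frame: \code{set_id, overlap, set_size, query_size,
#'   universe_size, p_raw, p_adj, enriched}.
#' @export
ora <- function(query, sets, universe, min_set = 10, max_set = 500,
                alpha = 0.05) {
  outside <- setdiff(query, universe)
  if (length(outside) > 0)
    message(length(outside), " query genes outside the universe dropped")
  query <- intersect(unique(query), universe)
  .assert(length(query) > 0, "empty query after restriction to universe",
          class = "lncmeta_input_error")
  sets <- lapply(sets, intersect, universe)
  keep <- vapply(sets, function(s)
    length(s) >= min_set && length(s) <= max_set, logical(1))
  sets <- sets[keep]
  .assert(length(sets) > 0, "no sets left after size filtering",
          class = "lncmeta_input_error")
  N <- length(universe); n <- length(query)
  K <- vapply(sets, length, integer(1))
  x <- vapply(sets, function(s) length(intersect(s, query)), integer(1))
  p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(set_id = names(sets), overlap = x, set_size = K,
                    query_size = n, universe_size = N, p_raw = p,
                    p_adj = bh_fdr(p), stringsAsFactors = FALSE,
                    row.names = NULL)
  out$enriched <- out$p_adj < alpha
  out[order(out$p_adj, out$p_raw, out$set_id), ]
}

#' Weighted Kolmogorov-Smirnov running-sum enrichment score
#'
#' Genes are ranked by decreasing score; hits advance the running sum in
#' proportion to \code{|score|} (normalized within the set), misses retreat
#' by \code{1/(N - N_hit)}. ES is the maximum deviation from zero (signed).
#' The permutation p-value resamples set membership \code{n_perm} times and
#' is two-sided over the permutations matching the observed ES sign.
#'
#' @param scores Named numeric vector (gene id -> ranking score).
#' @param set Gene ids; must overlap the ranked list.
#' @param n_perm Number of membership permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @return List with \code{ES} and \code{p_perm}.
#' @export
gsea_running_sum <- function(scores, set, n_perm = 1000, seed = 1L) {
  .assert(all(is.finite(scores)), "scores must be finite",
          class = "lncmeta_input_error")
  hits <- names(scores) %in% set
  .assert(any(hits), "set does not overlap the ranked list",
          class = "lncmeta_input_error")
  es_of <- function(hits, s) {
    inc <- abs(s) * hits
    tot <- sum(inc)
    if (tot == 0) inc <- hits / sum(hits) else inc <- inc / tot
    dec <- (!hits) / max(1, sum(!hits))
    rs <- cumsum(inc - dec)
    rs[which.max(abs(rs))]
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; h <- hits[ord]
  ES <- es_of(h, s)
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(n_perm), function(b) es_of(sample(h), s),
                 numeric(1))
  same <- perm[sign(perm) == sign(ES)]
  p <- if (length(same) == 0) 1 / (n_perm + 1) else
    (1 + sum(abs(same) >= abs(ES))) / (1 + length(same))
  list(ES = ES, p_perm = min(1, 2 * p))
}

#' Read a GMT gene-set file
#'
#' Lines are \code{name <TAB> description <TAB> member...}; duplicate
#' members within a set are dropped with a message.
#'
#' @param path GMT file path.
#' @return List with \code{sets} (named list of members) and
#'   \code{descriptions}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    .assert(length(f) >= 3, sprintf("malformed GMT line %d: need >= 3 fields",
                                    i),
            class = "lncmeta_parse_error")
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      message("duplicate members in set ", f[1], " deduplicated")
      members <- unique(members)
    }
    sets[[f[1]]] <- members
    desc[f[1]] <- f[2]
  }
  list(sets = sets, descriptions = desc)
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of member vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (default "na").
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(id) {
    d <- if (!is.null(descriptions) && !is.na(descriptions[id]))
      descriptions[id] else "na"
    paste(c(id, d, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
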
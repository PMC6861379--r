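# Independent oracles used across tests. These deliberately re-derive each
# quantity by a different route (brute force, enumeration, closed form)
# than the package implementation.

# Inverse-variance pooling via weighted least squares on an intercept-only
# model.
wls_pool <- function(y, v) {
  fit <- stats::lm(y ~ 1, weights = 1 / v)
  est <- unname(stats::coef(fit)[1])
  se <- sqrt(1 / sum(1 / v))
  list(est = est, se = se)
}

# DerSimonian-Laird tau2 from first principles.
dl_tau2 <- function(y, v) {
  w <- 1 / v
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  max(0, (Q - (length(y) - 1)) / C)
}

# BH step-up by explicit sort / cummin loop (independent of p.adjust).
bh_manual <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- cummin(n / (n:1) * p[o])
  pmin(1, adj)[ro]
}

# Exhaustive AW-Fisher search over all 2^k - 1 nonempty weight vectors.
aw_exhaustive <- function(p) {
  k <- length(p)
  best <- Inf
  for (code in 1:(2^k - 1)) {
    w <- as.logical(bitwAnd(code, 2^(0:(k - 1))))
    U <- -2 * sum(log(p[w]))
    s <- stats::pchisq(U, df = 2 * sum(w), lower.tail = FALSE)
    if (s < best) best <- s
  }
  best
}

# Triple-loop TOM.
tom_brute <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - 1
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    L <- 0
    for (u in seq_len(n)) if (u != i && u != j) L <- L + a[i, u] * a[u, j]
    out[i, j] <- (L + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# Hypergeometric upper tail by direct enumeration of choose() terms.
hyper_tail <- function(x, K, N, n) {
  xs <- x:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Shannon entropy (bits) and direct JS distance.
shannon <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
js_direct <- function(p, q) {
  m <- (p + q) / 2
  sqrt(shannon(m) - (shannon(p) + shannon(q)) / 2)
}

# Small deterministic multi-study fixture used by several files.
small_sim <- function(n_studies = 4, n_genes = 300, frac_de = 0.2,
                      delta = 0.8, tau2 = 0, seed = 101, ...) {
  generate_multistudy_counts(simulation_config(
    n_studies = n_studies, n_cases = rep(15L, n_studies),
    n_controls = rep(15L, n_studies), n_genes = n_genes,
    frac_de = frac_de, delta = delta, tau2 = tau2, seed = seed, ...))
}
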
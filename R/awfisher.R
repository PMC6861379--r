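#' Adaptively weighted Fisher combination of per-study p-values
#'
#' For a binary study-inclusion weight vector \code{w}, the Fisher statistic
#' is \code{U(w) = -2 sum(w * log(p))} and its significance
#' \code{s(w) = P(chisq_{2|w|} >= U(w))}. The adaptive combination reports
#' the weight vector minimizing \code{s(w)}. Because \code{s} is minimized
#' by including the smallest p-values first, the search can be restricted to
#' the \code{k} nested vectors selecting the \code{m} smallest p-values
#' (\code{m = 1..k}); this restricted search provably contains the global
#' minimizer over all \code{2^k - 1} nonempty vectors.
#'
#' The returned \code{aw_p} is the raw minimum tail statistic, which is
#' anti-conservative as a p-value because of the adaptive minimization; for
#' calibrated inference use the permutation null exposed through
#' \code{\link{run_meta}(aw_perm = ...)}.
#'
#' @param p Numeric vector of per-study p-values in (0, 1]; zeros are
#'   clipped to the smallest positive double with a warning.
#' @return List with \code{aw_p} (minimum s(w)), \code{aw_weights} (logical
#'   vector marking the selected studies, in input order) and \code{U}
#'   (the Fisher statistic at the optimum).
#' @examples
#' aw_fisher(c(0.001, 0.9))  # selects study 1 only; aw_p == 0.001
#' @export
aw_fisher <- function(p) {
  .assert(length(p) >= 1, "need at least one p-value")
  .assert(all(p <= 1) && all(p >= 0), "p-values must lie in (0, 1]",
          class = "lncmeta_input_error")
  if (any(p == 0)) {
    warning("p-value of 0 clipped to .Machine$double.xmin")
    p[p == 0] <- .Machine$double.xmin
  }
  ord <- order(p)
  cum <- -2 * cumsum(log(p[ord]))
  s <- stats::pchisq(cum, df = 2 * seq_along(p), lower.tail = FALSE)
  m <- which.min(s)
  sel <- logical(length(p))
  sel[ord[seq_len(m)]] <- TRUE
  list(aw_p = s[m], aw_weights = sel, U = cum[m])
}
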
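# Sequential whole-domain structural comparison scored by TM-score, used
# to filter template libraries down to structurally unrelated domains.

#' TM-score between two domains
#'
#' Sequential (order-preserving) structural alignment of two C-alpha traces
#' by iterated gapless-threading superposition and dynamic programming,
#' scored as `TM = (1/L_norm) sum 1/(1 + d_i^2/d0(L_norm)^2)` with the
#' sequential d0. The score is computed normalizing by each domain's length
#' in turn; the returned value is the maximum of the two (a conservative
#' choice when the score is used as a dissimilarity filter), with both
#' values attached as the `"by_domain"` attribute.
#'
#' @param domA,domB `domain_instance` objects (or plain N x 3 C-alpha
#'   matrices) with at least 15 residues each.
#' @param params a [ddi_params()] object (uses `d0_floor`).
#' @param normalize `"max"` (default), `"a"`, or `"b"`: which normalization
#'   to return.
#' @return TM-score in `(0, 1]`.
#' @export
tm_score_domains <- function(domA, domB, params = ddi_params(),
                             normalize = c("max", "a", "b")) {
  normalize <- match.arg(normalize)
  A <- if (inherits(domA, "domain_instance")) domA$ca else as.matrix(domA)
  B <- if (inherits(domB, "domain_instance")) domB$ca else as.matrix(domB)
  if (nrow(A) < 15L || nrow(B) < 15L)
    stop("TM-score needs at least 15 residues per domain (d0 regime)")
  tm_for <- function(Lnorm) {
    d0 <- d0_scale(Lnorm, "sequential", params$d0_floor)
    .tm_align_cpp(A, B, d0, Lnorm, 20L)$tm
  }
  ta <- tm_for(nrow(A))
  tb <- tm_for(nrow(B))
  out <- switch(normalize, max = max(ta, tb), a = ta, b = tb)
  attr(out, "by_domain") <- c(a = ta, b = tb)
  out
}
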
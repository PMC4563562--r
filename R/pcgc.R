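# PCGC (phenotype-correlation genotype-correlation / Haseman-Elston-type)
# regression: an estimator of liability-scale heritability that avoids the
# observed-to-liability conversion bias of REML under ascertainment, used
# here as a cross-check on the GREML track.

#' Fit PCGC regression of pairwise phenotype products on GRM entries
#'
#' Standardizes the binary phenotype as `y* = (y - P) / sqrt(P(1-P))`,
#' regresses all off-diagonal pairwise products `y*_j y*_k` on the GRM
#' entries through the origin, and transforms the slope to the liability
#' scale by the ascertainment factor `K^2 (1-K)^2 / (z^2 P (1-P))`.
#' Standard errors come from a delete-one-sample jackknife (all pairs
#' involving the deleted sample are removed).
#'
#' @param y binary phenotype vector (0/1).
#' @param g a [grm()] aligned with `y`.
#' @param K lifetime risk (or a [liability_context()]; its `P` is replaced
#'   by the sample case fraction).
#' @return A `pcgc_fit`: `slope`, `h2_liab`, `se` (jackknife, liability
#'   scale), `n_pairs`, `P`, `K`.
#' @export
fit_pcgc <- function(y, g, K) {
  stopifnot(inherits(g, "grm"))
  if (inherits(K, "liability_context")) K <- K$K
  n <- length(y)
  if (nrow(g$values) != n)
    .err("GRM and phenotype dimensions differ", "liabh2_invalid_input")
  P <- mean(y)
  if (P == 0 || P == 1)
    .err("phenotype is constant", "liabh2_invalid_input")
  ys <- (y - P) / sqrt(P * (1 - P))
  A0 <- g$values
  diag(A0) <- 0
  # per-sample contributions (each pair counted once after halving)
  num_vec <- ys * drop(A0 %*% ys)
  den_vec <- rowSums(A0^2)
  num <- sum(num_vec) / 2
  den <- sum(den_vec) / 2
  if (den == 0) {
    slope <- 0
    se_slope <- NA_real_
  } else {
    slope <- num / den
    loo <- (num - num_vec) / (den - den_vec)
    loo[!is.finite(loo)] <- slope
    se_slope <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  }
  ctx <- liability_context(K, P)
  fac <- liability_factor(ctx)
  structure(list(slope = slope, h2_liab = slope * fac,
                 se = se_slope * fac, n_pairs = n * (n - 1) / 2,
                 P = P, K = K),
            class = "pcgc_fit")
}

#' @export
print.pcgc_fit <- function(x, ...) {
  cat(sprintf(
    "pcgc_fit: %d pairs | slope %.4f | h2 (liability) %.4f (SE %.4f) | P = %.3f, K = %.3f\n",
    x$n_pairs, x$slope, x$h2_liab, x$se, x$P, x$K))
  invisible(x)
}
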
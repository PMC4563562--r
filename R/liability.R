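# Liability-threshold scale transformations, ascertainment correction, and
# conversion of heritability to familial recurrence risk.

#' Liability-scale context
#'
#' Holds the lifetime risk `K`, the sample case fraction `P`, and the
#' derived liability threshold `t = qnorm(1 - K)` and normal density at the
#' threshold `z = dnorm(t)` (always recomputed from `K`).
#'
#' @param K lifetime risk (population probability of disease), in `(0, 1)`.
#' @param P sample case proportion; defaults to `K` (unascertained).
#' @return A list of class `liability_context` with fields `K`, `P`, `t`,
#'   `z`.
#' @export
liability_context <- function(K, P = K) {
  if (K <= 0 || K >= 1) .err("K must be in (0, 1)", "liabh2_invalid_context")
  if (P < 0 || P > 1) .err("P must be in [0, 1]", "liabh2_invalid_context")
  t <- qnorm(1 - K)
  structure(list(K = K, P = P, t = t, z = dnorm(t)),
            class = "liability_context")
}

#' Transform observed-scale heritability to the liability scale
#'
#' Applies the ascertainment-corrected transformation
#' `h2_liab = h2_obs * K^2 (1-K)^2 / (z^2 P (1-P))`. With `P = K` this
#' reduces to the unascertained factor `K(1-K)/z^2`. Standard errors
#' transform by the same multiplicative factor.
#'
#' @param h2_obs observed-scale heritability (0/1 phenotype), in `[0, 1]`.
#' @param ctx a [liability_context()] (with `P` set for ascertained
#'   samples).
#' @param se optional observed-scale standard error.
#' @return `h2_liab`, with attribute `se` when `se` was supplied.
#' @export
obs_to_liability <- function(h2_obs, ctx, se = NULL) {
  stopifnot(inherits(ctx, "liability_context"))
  if (any(h2_obs < 0 | h2_obs > 1))
    .err("h2_obs must be in [0, 1]", "liabh2_invalid_input")
  if (ctx$P <= 0 || ctx$P >= 1)
    .err("P must be strictly inside (0, 1) for the transformation",
         "liabh2_invalid_context")
  fac <- liability_factor(ctx)
  out <- h2_obs * fac
  if (!is.null(se)) attr(out, "se") <- se * fac
  out
}

#' Ascertainment transformation factor
#' @param ctx a [liability_context()].
#' @return The multiplicative factor `K^2 (1-K)^2 / (z^2 P (1-P))`.
#' @export
liability_factor <- function(ctx) {
  stopifnot(inherits(ctx, "liability_context"))
  ctx$K^2 * (1 - ctx$K)^2 / (ctx$z^2 * ctx$P * (1 - ctx$P))
}

#' Recurrence risk ratio for a relative under the liability-threshold model
#'
#' The liabilities of a proband and a relative with additive relationship
#' `a` are standard bivariate normal with correlation `a * h2_liab`. The
#' recurrence risk ratio is `P(l2 > t | l1 > t) / K`, computed by adaptive
#' outer quadrature over the proband liability with the inner integral as a
#' normal CDF.
#'
#' @param h2_liab liability-scale heritability, in `[0, 1]`.
#' @param ctx a [liability_context()] (or a bare `K`).
#' @param relatedness_a additive relationship (0.5 for full siblings or
#'   parent-offspring), in `(0, 1]`.
#' @return The risk ratio `lambda`: `1` under independence, approaching
#'   `1/K` as the liability correlation approaches 1.
#' @export
sibling_rr <- function(h2_liab, ctx, relatedness_a = 0.5) {
  if (!inherits(ctx, "liability_context")) ctx <- liability_context(ctx)
  if (h2_liab < 0 || h2_liab > 1)
    .err("h2_liab must be in [0, 1]", "liabh2_invalid_input")
  if (relatedness_a <= 0 || relatedness_a > 1)
    .err("relatedness_a must be in (0, 1]", "liabh2_invalid_input")
  r <- relatedness_a * h2_liab
  K <- ctx$K
  t <- ctx$t
  if (r == 0) return(1)
  if (r >= 1) return(1 / K)
  f <- function(x)
    dnorm(x) * pnorm((t - r * x) / sqrt(1 - r^2), lower.tail = FALSE)
  res <- tryCatch(
    integrate(f, t, Inf, rel.tol = 1e-10, abs.tol = 0, subdivisions = 500L),
    error = function(e)
      .err(paste("tail integration failed:", conditionMessage(e)),
           "liabh2_numerical"))
  if (res$message != "OK")
    .err(paste("tail integration did not converge:", res$message),
         "liabh2_numerical")
  res$value / K^2
}

#' Share of excess familial risk attributable to genetics
#'
#' Default definition `(lambda_genetic - 1) / (lambda_observed - 1)`: the
#' genetically explained excess recurrence risk as a fraction of the
#' observed excess.
#'
#' @param lambda_genetic recurrence risk ratio implied by heritability
#'   (must be > 1).
#' @param lambda_observed epidemiologically observed recurrence risk ratio
#'   (must be > 1).
#' @return The fraction, labelled by attribute `definition`.
#' @export
excess_familial_share <- function(lambda_genetic, lambda_observed) {
  if (lambda_observed <= 1)
    .err("lambda_observed must exceed 1", "liabh2_invalid_input")
  if (lambda_genetic < 1)
    .err("lambda_genetic must be >= 1", "liabh2_invalid_input")
  out <- (lambda_genetic - 1) / (lambda_observed - 1)
  attr(out, "definition") <- "(lambda_genetic - 1) / (lambda_observed - 1)"
  out
}
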
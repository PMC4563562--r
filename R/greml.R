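# Restricted-maximum-likelihood variance-component estimation with one or
# many GRMs: average-information (AI) updates with expectation-maximization
# fallback steps, a variance floor instead of unconstrained estimates, and
# Wald standard errors from the inverse AI matrix. A single-GRM fast path
# rotates the model to the GRM eigenbasis so each iteration is O(n p^2).

# restricted log-likelihood (up to constant):
# -0.5 [ log|V| + log|X'V^-1 X| + y'Py ]

.design_matrix <- function(X, n) {
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  # drop collinear columns (e.g. a SNP appended twice)
  q <- qr(X)
  if (q$rank < ncol(X)) X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
  X
}

#' Fit variance components by AI-REML
#'
#' Maximizes the restricted likelihood of
#' `y ~ N(X beta, sum_c sigma2_c A_c + sigma2_e I)` using average-information
#' updates with EM fallback steps (the first `em_iters` iterations, and any
#' AI step that fails or decreases the restricted likelihood, use EM).
#' Components are floored at `floor_frac * var(y)`. Standard errors come
#' from the inverse of the final AI matrix; a near-singular AI matrix (e.g.
#' a GRM indistinguishable from the identity) is flagged via
#' `identifiable = FALSE` with `NA` standard errors.
#'
#' @param y numeric phenotype vector (0/1 for case-control on the observed
#'   scale, or quantitative).
#' @param grms a [grm()] or list of GRMs sharing `y`'s sample order.
#' @param X fixed-effect design matrix; default intercept-only. Collinear
#'   columns are dropped.
#' @param max_iter,tol iteration cap and convergence tolerance on the change
#'   in restricted log-likelihood.
#' @param em_iters number of initial EM iterations before switching to AI.
#' @param floor_frac variance floor as a fraction of `var(y)`.
#' @param method `"ai"` (default) or `"em"` (pure EM throughout).
#' @return A `vc_fit`: `sigma2` (named per-component variances), `sigma2_e`,
#'   `se` (including residual), `loglik`, `h2_obs` (per component),
#'   `h2_obs_total`, `n_iter`, `converged`, `identifiable`, `n`, `vp`.
#' @export
fit_reml <- function(y, grms, X = NULL, max_iter = 100L, tol = 1e-6,
                     em_iters = 2L, floor_frac = 1e-8,
                     method = c("ai", "em")) {
  method <- match.arg(method)
  if (inherits(grms, "grm")) grms <- list(grms)
  if (!length(grms)) .err("need at least one GRM", "liabh2_invalid_input")
  if (!is.null(names(grms)) && all(nzchar(names(grms))))
    for (i in seq_along(grms)) grms[[i]]$snp_subset <- names(grms)[i]
  n <- length(y)
  for (g in grms)
    if (!inherits(g, "grm") || nrow(g$values) != n)
      .err("all GRMs must be grm objects aligned with y",
           "liabh2_invalid_input")
  X <- .design_matrix(X, n)
  k <- length(grms)
  if (n <= ncol(X) + k + 1)
    .err("too few samples for the number of parameters",
         "liabh2_invalid_input")
  if (k == 1)
    return(.reml_eigen(y, grms[[1]], X, max_iter, tol, em_iters, floor_frac,
                       method))
  .reml_dense(y, grms, X, max_iter, tol, em_iters, floor_frac, method)
}

# shared bookkeeping at the end of either path
.vc_result <- function(sigma2, names_c, AI, loglik, n_iter, converged, n,
                       vp) {
  k <- length(sigma2) - 1L
  se <- rep(NA_real_, k + 1L)
  identifiable <- TRUE
  rc <- tryCatch(rcond(AI), error = function(e) 0)
  if (is.finite(rc) && rc > 1e-10) {
    se <- sqrt(pmax(diag(solve(AI)), 0))
  } else identifiable <- FALSE
  tot <- sum(sigma2)
  h2 <- sigma2[seq_len(k)] / tot
  structure(list(
    sigma2 = setNames(sigma2[seq_len(k)], names_c),
    sigma2_e = sigma2[k + 1L],
    se = setNames(se, c(names_c, "residual")),
    loglik = loglik, h2_obs = setNames(h2, names_c),
    h2_obs_total = sum(h2),
    # delta-method SE of total h2 = (1-h2) SEg/tot approx for single comp;
    # stored per component as se_h2 using var of ratio with AI covariance
    n_iter = n_iter, converged = converged, identifiable = identifiable,
    n = n, vp = vp), class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("vc_fit: %d samples | logL %.4f | %s after %d iter%s\n",
              x$n, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter,
              if (x$identifiable) "" else " | AI matrix near-singular"))
  comp <- data.frame(sigma2 = c(x$sigma2, residual = x$sigma2_e),
                     se = x$se,
                     h2_obs = c(x$h2_obs, NA))
  print(round(comp, 5))
  invisible(x)
}

# --- dense multi-GRM path --------------------------------------------------

.reml_dense <- function(y, grms, X, max_iter, tol, em_iters, floor_frac,
                        method) {
  n <- length(y)
  k <- length(grms)
  vp <- var(y)
  floorv <- floor_frac * vp
  As <- lapply(grms, function(g) g$values)
  names_c <- vapply(grms, function(g) g$snp_subset, "")
  if (anyDuplicated(names_c)) names_c <- paste0("V", seq_len(k))
  s2 <- rep(vp / (k + 1), k + 1)  # equal split start

  eval_state <- function(s2) {
    V <- diag(rep(s2[k + 1], n))
    for (c in seq_len(k)) V <- V + s2[c] * As[[c]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {
      V <- V + diag(1e-6 * vp, n)  # ridge-and-retry
      ch <- chol(V)
    }
    Vi <- chol2inv(ch)
    XtViX <- crossprod(X, Vi %*% X)
    XtViX_i <- solve(XtViX)
    ViX <- Vi %*% X
    P <- Vi - ViX %*% XtViX_i %*% t(ViX)
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) +
                    determinant(XtViX, logarithm = TRUE)$modulus +
                    sum(y * Py))
    list(P = P, Py = Py, ll = as.numeric(ll))
  }

  st <- eval_state(s2)
  ll <- st$ll
  converged <- FALSE
  AI <- matrix(NA_real_, k + 1, k + 1)
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    Py <- st$Py
    P <- st$P
    # score and AI over all components (residual uses A = I)
    w <- vector("list", k + 1)
    trPA <- numeric(k + 1)
    quad <- numeric(k + 1)
    for (c in seq_len(k)) {
      w[[c]] <- As[[c]] %*% Py
      trPA[c] <- sum(P * As[[c]])
      quad[c] <- sum(Py * w[[c]])
    }
    w[[k + 1]] <- Py
    trPA[k + 1] <- sum(diag(P))
    quad[k + 1] <- sum(Py * Py)
    score <- 0.5 * (quad - trPA)
    AI <- matrix(0, k + 1, k + 1)
    Pw <- lapply(w, function(v) P %*% v)
    for (a in seq_len(k + 1))
      for (b in a:(k + 1)) {
        AI[a, b] <- 0.5 * sum(w[[a]] * Pw[[b]])
        AI[b, a] <- AI[a, b]
      }
    use_em <- method == "em" || iter <= em_iters
    s2_new <- NULL
    if (!use_em) {
      step <- tryCatch(solve(AI, score), error = function(e) NULL)
      if (!is.null(step)) s2_new <- pmax(s2 + step, floorv)
    }
    if (is.null(s2_new))
      s2_new <- pmax(s2 + s2^2 * (quad - trPA) / n, floorv)
    st_new <- eval_state(s2_new)
    if (!use_em && st_new$ll < ll - 1e-10) {
      # AI step worsened the restricted likelihood: EM fallback
      s2_new <- pmax(s2 + s2^2 * (quad - trPA) / n, floorv)
      st_new <- eval_state(s2_new)
    }
    dll <- st_new$ll - ll
    s2 <- s2_new
    st <- st_new
    ll <- st$ll
    if (abs(dll) < tol && iter > em_iters) {
      converged <- TRUE
      break
    }
  }
  .vc_result(s2, names_c, AI, ll, iter, converged, n, vp)
}

# --- single-GRM eigen path -------------------------------------------------

.reml_eigen <- function(y, g, X, max_iter, tol, em_iters, floor_frac,
                        method) {
  n <- length(y)
  vp <- var(y)
  floorv <- floor_frac * vp
  eg <- eigen(g$values, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  yt <- drop(crossprod(eg$vectors, y))
  Xt <- crossprod(eg$vectors, X)
  p <- ncol(Xt)
  s2 <- rep(vp / 2, 2)

  eval_state <- function(s2) {
    v <- s2[1] * d + s2[2]
    if (any(v <= 0)) v <- v + 1e-6 * vp
    vi <- 1 / v
    XtViX <- crossprod(Xt * vi, Xt)
    XtViX_i <- solve(XtViX)
    viy <- vi * yt
    bhat <- XtViX_i %*% crossprod(Xt, viy)
    Py <- viy - (vi * Xt) %*% bhat  # P y in rotated basis
    Py <- drop(Py)
    ll <- -0.5 * (sum(log(v)) +
                    determinant(XtViX, logarithm = TRUE)$modulus +
                    sum(yt * Py))
    list(vi = vi, XtViX_i = XtViX_i, Py = Py, ll = as.numeric(ll))
  }

  # P m for a vector m in rotated basis
  apply_P <- function(st, m) {
    vim <- st$vi * m
    drop(vim - (st$vi * Xt) %*% (st$XtViX_i %*% crossprod(Xt, vim)))
  }
  # tr(P D_a) where D_a = diag(a)
  tr_PD <- function(st, a) {
    t1 <- sum(st$vi * a)
    B <- Xt * (st$vi * a * st$vi)  # rows scaled
    t2 <- sum(st$XtViX_i * crossprod(Xt, B))
    t1 - t2
  }

  st <- eval_state(s2)
  ll <- st$ll
  converged <- FALSE
  AI <- matrix(NA_real_, 2, 2)
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    Py <- st$Py
    w1 <- d * Py
    w2 <- Py
    trPA <- c(tr_PD(st, d), tr_PD(st, rep(1, n)))
    quad <- c(sum(Py * w1), sum(Py * w2))
    score <- 0.5 * (quad - trPA)
    Pw1 <- apply_P(st, w1)
    Pw2 <- apply_P(st, w2)
    AI <- 0.5 * matrix(c(sum(w1 * Pw1), sum(w1 * Pw2),
                         sum(w2 * Pw1), sum(w2 * Pw2)), 2, 2)
    use_em <- method == "em" || iter <= em_iters
    s2_new <- NULL
    if (!use_em) {
      step <- tryCatch(solve(AI, score), error = function(e) NULL)
      if (!is.null(step)) s2_new <- pmax(s2 + step, floorv)
    }
    if (is.null(s2_new))
      s2_new <- pmax(s2 + s2^2 * (quad - trPA) / n, floorv)
    st_new <- eval_state(s2_new)
    if (!use_em && st_new$ll < ll - 1e-10) {
      s2_new <- pmax(s2 + s2^2 * (quad - trPA) / n, floorv)
      st_new <- eval_state(s2_new)
    }
    dll <- st_new$ll - ll
    s2 <- s2_new
    st <- st_new
    ll <- st$ll
    if (abs(dll) < tol && iter > em_iters) {
      converged <- TRUE
      break
    }
  }
  .vc_result(s2, g$snp_subset, AI, ll, iter, converged, n, vp)
}

#' Restricted log-likelihood at fixed variance components
#'
#' Direct evaluation of
#' `-0.5 [log|V| + log|X' V^-1 X| + y' P y]` for given components; used for
#' profiling and by validation against independent dense-matrix evaluation.
#'
#' @param y phenotype vector.
#' @param grms a [grm()] or list of GRMs.
#' @param sigma2 per-GRM variance components.
#' @param sigma2_e residual variance.
#' @param X design matrix (default intercept).
#' @return The restricted log-likelihood (no additive constant).
#' @export
reml_loglik <- function(y, grms, sigma2, sigma2_e, X = NULL) {
  if (inherits(grms, "grm")) grms <- list(grms)
  n <- length(y)
  X <- .design_matrix(X, n)
  V <- diag(rep(sigma2_e, n))
  for (c in seq_along(grms)) V <- V + sigma2[c] * grms[[c]]$values
  ch <- chol(V)
  Vi <- chol2inv(ch)
  XtViX <- crossprod(X, Vi %*% X)
  ViX <- Vi %*% X
  P <- Vi - ViX %*% solve(XtViX) %*% t(ViX)
  as.numeric(-0.5 * (2 * sum(log(diag(ch))) +
                       determinant(XtViX, logarithm = TRUE)$modulus +
                       sum(y * (P %*% y))))
}

#' Joint per-chromosome variance-component fit
#'
#' Fits one variance component per chromosome GRM simultaneously (plus
#' residual), and also reports the single whole-set GRM estimate for
#' comparison: the per-chromosome total and the whole-set estimate need not
#' agree and both are returned.
#'
#' @param y phenotype vector.
#' @param per_chr_grms named list of per-chromosome GRMs (>= 2).
#' @param X design matrix.
#' @param whole_set optional precomputed whole-set [grm()]; computed as the
#'   SNP-count-weighted average of the chromosome GRMs when `NULL`.
#' @param ... passed to [fit_reml()].
#' @return A list: `joint` (multi-component `vc_fit`), `whole` (single-GRM
#'   `vc_fit`), `per_chromosome` (data.frame of `h2_obs` and `se` per
#'   chromosome), `total_joint`, `total_whole`.
#' @export
fit_joint_chromosomes <- function(y, per_chr_grms, X = NULL,
                                  whole_set = NULL, ...) {
  if (length(per_chr_grms) < 2)
    .err("need >= 2 chromosome GRMs", "liabh2_invalid_input")
  joint <- fit_reml(y, per_chr_grms, X = X, ...)
  if (is.null(whole_set)) {
    wts <- vapply(per_chr_grms, function(g) mean(g$n_snps_pairwise), 0)
    if (any(is.na(wts))) wts <- rep(1, length(per_chr_grms))
    V <- Reduce(`+`, Map(function(g, w) g$values * w, per_chr_grms,
                         as.list(wts))) / sum(wts)
    Nn <- Reduce(`+`, lapply(per_chr_grms, function(g) g$n_snps_pairwise))
    whole_set <- grm(V, per_chr_grms[[1]]$sample_ids, Nn, "all")
  }
  whole <- fit_reml(y, whole_set, X = X, ...)
  per_chr <- data.frame(
    chromosome = names(joint$h2_obs),
    h2_obs = unname(joint$h2_obs),
    se = unname(joint$se[seq_along(joint$h2_obs)]))
  list(joint = joint, whole = whole, per_chromosome = per_chr,
       total_joint = joint$h2_obs_total, total_whole = whole$h2_obs_total)
}

#' Per-SNP variance attribution by covariate-difference
#'
#' Fits the joint per-chromosome model twice — without and with the SNP
#' dosage appended as a fixed covariate — and attributes to the SNP the
#' change in its chromosome's heritability:
#' `h2_chr(without) - h2_chr(with)`.
#'
#' @param y phenotype vector.
#' @param per_chr_grms named list of chromosome GRMs.
#' @param snp_genotypes dosage vector aligned to samples (missing values are
#'   mean-imputed); or a matrix for batch mode (one column per SNP).
#' @param snp_chr chromosome label(s) the SNP(s) map to (must name entries
#'   of `per_chr_grms`).
#' @param X base design matrix.
#' @param base_fit optional precomputed no-SNP joint fit (reused in batch
#'   mode).
#' @param ... passed to [fit_reml()].
#' @return For one SNP, the attributed variance fraction (named numeric); a
#'   named vector in batch mode.
#' @export
per_snp_variance <- function(y, per_chr_grms, snp_genotypes, snp_chr,
                             X = NULL, base_fit = NULL, ...) {
  snp_genotypes <- as.matrix(snp_genotypes)
  if (is.null(colnames(snp_genotypes)))
    colnames(snp_genotypes) <- paste0("snp", seq_len(ncol(snp_genotypes)))
  snp_chr <- as.character(snp_chr)
  if (length(snp_chr) == 1) snp_chr <- rep(snp_chr, ncol(snp_genotypes))
  if (!all(snp_chr %in% names(per_chr_grms)))
    .err("snp_chr must name entries of per_chr_grms", "liabh2_invalid_input")
  n <- length(y)
  X <- .design_matrix(X, n)
  if (is.null(base_fit)) base_fit <- fit_reml(y, per_chr_grms, X = X, ...)
  out <- numeric(ncol(snp_genotypes))
  names(out) <- colnames(snp_genotypes)
  for (s in seq_len(ncol(snp_genotypes))) {
    dose <- snp_genotypes[, s]
    if (anyNA(dose)) dose[is.na(dose)] <- mean(dose, na.rm = TRUE)
    if (var(dose) == 0)
      .err(paste("monomorphic SNP:", colnames(snp_genotypes)[s]),
           "liabh2_zero_variance_covariate")
    with_fit <- fit_reml(y, per_chr_grms, X = cbind(X, dose), ...)
    out[s] <- base_fit$h2_obs[[snp_chr[s]]] - with_fit$h2_obs[[snp_chr[s]]]
  }
  out
}

#' Stratified (per-subtype) variance-component fit
#'
#' Re-fits using only cases of the named subtype together with all controls;
#' cases of other subtypes (e.g. mixed or indeterminate histology) are
#' excluded.
#'
#' @param y binary status vector.
#' @param subtype label per sample (`NA` for controls).
#' @param which subtype to keep.
#' @param grms a [grm()] or list of GRMs (subset internally).
#' @param X design matrix (subset internally).
#' @param ... passed to [fit_reml()].
#' @return A `vc_fit` plus attribute `stratum_n` (cases kept).
#' @export
stratified_fit <- function(y, subtype, which, grms, X = NULL, ...) {
  if (inherits(grms, "grm")) grms <- list(grms)
  keep_case <- y == 1 & !is.na(subtype) & subtype == which
  if (!any(keep_case))
    .err(paste("no cases with subtype", which), "liabh2_invalid_input")
  keep <- y == 0 | keep_case   # logical: the `which` argument shadows base::which
  fit <- fit_reml(y[keep], lapply(grms, function(g) g[keep]),
                  X = if (is.null(X)) NULL else X[keep, , drop = FALSE], ...)
  attr(fit, "stratum_n") <- sum(keep_case)
  fit
}
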
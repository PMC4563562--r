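# Pedigree container, numerator relationship matrix (Henderson recursion),
# its sparse inverse, and the Bayesian liability-threshold "animal" model
# fitted by Gibbs sampling with latent-liability data augmentation.

#' Pedigree container
#'
#' Validates a LINKAGE-style pedigree table: integer-codable ids, parent
#' references (`0` or `NA` = unknown), and checks acyclicity by topological
#' sort. Rows may be in any order; operations sort parents-before-offspring
#' internally.
#'
#' @param df data.frame with columns `id`, `father`, `mother` and optionally
#'   `sex`, `status`.
#' @return A data.frame of class `pedigree` with an attribute `topo_order`
#'   (row permutation placing parents before offspring).
#' @export
pedigree <- function(df) {
  need <- c("id", "father", "mother")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .err(paste("pedigree is missing columns:", paste(miss, collapse = ", ")),
         "liabh2_pedigree_integrity")
  df$father[is.na(df$father)] <- 0L
  df$mother[is.na(df$mother)] <- 0L
  if (anyDuplicated(df$id))
    .err("duplicate individual ids in pedigree", "liabh2_pedigree_integrity")
  bad <- (df$father != 0 & !(df$father %in% df$id)) |
    (df$mother != 0 & !(df$mother %in% df$id))
  if (any(bad))
    .err("parent id not present in pedigree", "liabh2_pedigree_integrity")
  if (any(df$father == df$id | df$mother == df$id))
    .err("individual listed as its own parent", "liabh2_pedigree_integrity")
  ord <- .topo_order(df)
  structure(df, class = c("pedigree", "data.frame"), topo_order = ord)
}

# Kahn topological sort: returns a row permutation with parents before
# offspring, or errors on a parentage cycle.
.topo_order <- function(df) {
  n <- nrow(df)
  idx <- match(df$id, df$id)
  f <- match(df$father, df$id)  # NA when founder
  m <- match(df$mother, df$id)
  indeg <- (!is.na(f)) + (!is.na(m))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(f[i])) children[[f[i]]] <- c(children[[f[i]]], i)
    if (!is.na(m[i])) children[[m[i]]] <- c(children[[m[i]]], i)
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != n)
    .err("pedigree contains a parentage cycle (individual is its own ancestor)",
         "liabh2_pedigree_integrity")
  out
}

#' Read a LINKAGE-style pedigree TSV
#'
#' Expects columns `id`, `father`, `mother` and optionally `sex`, `status`
#' (header required; `0` = unknown parent).
#'
#' @param path file path.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path) {
  pedigree(read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE))
}

#' Write a pedigree as TSV
#' @param ped a [pedigree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  write.table(as.data.frame(ped), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Numerator relationship matrix by Henderson's recursion
#'
#' In topological order, `A[i,i] = 1 + 0.5 * A[f(i), m(i)]` and
#' `A[j,i] = 0.5 * (A[j, f(i)] + A[j, m(i)])` for earlier `j`; unknown
#' parents contribute zero. The result is returned in the input row order.
#'
#' @param ped a [pedigree()].
#' @return A list of class `nrm`: `values` (dense symmetric matrix with
#'   dimnames = ids, in input order), `F` (inbreeding coefficients,
#'   `diag - 1`), `ids`.
#' @export
build_nrm <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ord <- attr(ped, "topo_order")
  n <- nrow(ped)
  id <- ped$id[ord]
  f <- match(ped$father[ord], id)  # positions within topo order
  m <- match(ped$mother[ord], id)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    fi <- f[i]; mi <- m[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(fi)) row <- row + 0.5 * A[j, fi]
      if (!is.na(mi)) row <- row + 0.5 * A[j, mi]
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (!is.na(fi) && !is.na(mi)) 0.5 * A[fi, mi] else 0
  }
  dimnames(A) <- list(id, id)
  # back to input order
  back <- match(ped$id, id)
  A <- A[back, back, drop = FALSE]
  structure(list(values = A, F = diag(A) - 1, ids = ped$id), class = "nrm")
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Built directly from pedigree structure and inbreeding coefficients via
#' Henderson's rules: for each individual the Mendelian-sampling variance is
#' `d = 0.5 - 0.25 (F_f + F_m)` (both parents known), `0.75 - 0.25 F_p` (one
#' known) or `1` (founder), and `1/d` contributes to the (individual,
#' parents) block.
#'
#' @param ped a [pedigree()].
#' @param nrm optional precomputed [build_nrm()] result (for the inbreeding
#'   coefficients).
#' @return A list: `Ainv` (a `dgCMatrix` in the pedigree's input row order),
#'   `ids`.
#' @export
nrm_inverse <- function(ped, nrm = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(nrm)) nrm <- build_nrm(ped)
  Fi <- nrm$F
  n <- nrow(ped)
  f <- match(ped$father, ped$id)
  m <- match(ped$mother, ped$id)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  Ff <- ifelse(is.na(f), 0, Fi[f])
  Fm <- ifelse(is.na(m), 0, Fi[m])
  d <- ifelse(!is.na(f) & !is.na(m), 0.5 - 0.25 * (Ff + Fm),
              ifelse(!is.na(f), 0.75 - 0.25 * Ff,
                     ifelse(!is.na(m), 0.75 - 0.25 * Fm, 1)))
  w <- 1 / d
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  i_all <- seq_len(n)
  add(i_all, i_all, w)
  hasf <- !is.na(f); hasm <- !is.na(m)
  add(i_all[hasf], f[hasf], -0.5 * w[hasf])
  add(f[hasf], i_all[hasf], -0.5 * w[hasf])
  add(i_all[hasm], m[hasm], -0.5 * w[hasm])
  add(m[hasm], i_all[hasm], -0.5 * w[hasm])
  both <- hasf & hasm
  add(f[both], m[both], 0.25 * w[both])
  add(m[both], f[both], 0.25 * w[both])
  add(f[hasf], f[hasf], 0.25 * w[hasf])
  add(m[hasm], m[hasm], 0.25 * w[hasm])
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Ainv <- methods::as(Ainv, "CsparseMatrix")
  dimnames(Ainv) <- list(ped$id, ped$id)
  list(Ainv = Ainv, ids = ped$id)
}

#' MCMC chain configuration for the threshold animal model
#'
#' Defaults mirror a registry-scale analysis: 1,100,000 rounds, 100,000
#' burn-in, thinning 1,000 (1,000 retained samples). Tests and desk-scale
#' runs override to shorter chains.
#'
#' @param n_rounds total Gibbs rounds.
#' @param burn_in rounds discarded before thinning starts.
#' @param thin keep every `thin`-th round after burn-in.
#' @param prior_df,prior_scale scaled-inverse-chi-square hyperparameters for
#'   the additive variance.
#' @param seed integer seed.
#' @return A list of class `chain_config`.
#' @export
chain_config <- function(n_rounds = 1100000L, burn_in = 100000L,
                         thin = 1000L, prior_df = 1, prior_scale = 1,
                         seed = 1L) {
  if (burn_in >= n_rounds) .err("burn_in must be < n_rounds",
                                "liabh2_invalid_config")
  if (thin < 1) .err("thin must be >= 1", "liabh2_invalid_config")
  if (prior_df <= 0 || prior_scale <= 0)
    .err("prior_df and prior_scale must be positive (zero-variance prior not allowed)",
         "liabh2_invalid_config")
  structure(list(n_rounds = as.integer(n_rounds),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 prior_df = prior_df, prior_scale = prior_scale,
                 seed = as.integer(seed)),
            class = "chain_config")
}

#' Fit the Bayesian liability-threshold animal model by Gibbs sampling
#'
#' Probit animal model with data augmentation: latent liabilities are drawn
#' from truncated-normal full conditionals (side set by case status,
#' threshold fixed at 0 with a free intercept), fixed effects from their
#' Gaussian full conditional, breeding values by single-site Gibbs over the
#' sparse inverse numerator relationship matrix, and the additive variance
#' from its scaled-inverse-chi-square full conditional. The residual
#' variance is fixed at 1 for identifiability, so the per-round heritability
#' is `h2 = sigma2_a / (sigma2_a + 1)`.
#'
#' @param ped a [pedigree()].
#' @param y binary status vector aligned to the pedigree rows (or `NULL` to
#'   use `ped$status`).
#' @param X fixed-effect design matrix (default intercept-only); an
#'   intercept column is prepended if absent.
#' @param cfg a [chain_config()].
#' @param sample_prior if `TRUE`, the phenotype likelihood is disabled and
#'   the chain samples `(u, sigma2_a)` from the prior — used to validate the
#'   full-conditional wiring.
#' @return A `posterior_chain`: `samples` (data.frame `round`, `sigma2_a`,
#'   `h2`), `summary` (posterior means and 95% quantile credible intervals),
#'   `diagnostics` (effective sample size and Geweke z for `h2`), `config`.
#' @export
fit_threshold_animal_model <- function(ped, y = NULL, X = NULL,
                                       cfg = chain_config(),
                                       sample_prior = FALSE) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "chain_config"))
  n <- nrow(ped)
  if (is.null(y)) y <- ped$status
  if (length(y) != n) .err("y must align with pedigree rows",
                           "liabh2_invalid_input")
  if (!all(y %in% c(0, 1))) .err("y must be binary 0/1",
                                 "liabh2_invalid_input")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  if (!any(apply(X, 2, function(c) all(c == c[1]) && c[1] != 0)))
    X <- cbind(intercept = 1, X)
  ainv <- nrm_inverse(ped)
  Ainv <- ainv$Ainv
  XtXinv <- solve(crossprod(X))
  Uchol <- t(chol(XtXinv))   # beta = mean + Uchol %*% z
  set.seed(cfg$seed)
  res <- gibbs_threshold_animal(
    as.integer(y), X, XtXinv, Uchol,
    Ainv@p, Ainv@i, Ainv@x,
    cfg$n_rounds, cfg$burn_in, cfg$thin,
    cfg$prior_df, cfg$prior_scale, !sample_prior)
  sigma2_a <- res$sigma2_a
  h2 <- sigma2_a / (sigma2_a + 1)
  samples <- data.frame(round = res$round, sigma2_a = sigma2_a, h2 = h2)
  structure(list(
    samples = samples,
    summary = list(
      h2_mean = mean(h2), h2_ci = unname(quantile(h2, c(0.025, 0.975))),
      sigma2_a_mean = mean(sigma2_a),
      sigma2_a_ci = unname(quantile(sigma2_a, c(0.025, 0.975)))),
    diagnostics = list(ess = .ess(h2), geweke_z = .geweke_z(h2)),
    config = cfg, n_individuals = n, n_cases = sum(y)),
    class = "posterior_chain")
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat(sprintf(
    "posterior_chain: %d samples | h2 posterior mean %.3f (95%% CrI %.3f-%.3f) | ESS %.0f | Geweke z %.2f\n",
    nrow(x$samples), x$summary$h2_mean, x$summary$h2_ci[1], x$summary$h2_ci[2],
    x$diagnostics$ess, x$diagnostics$geweke_z))
  invisible(x)
}

# spectral density at frequency zero via AR fit (Heidelberger-style)
.spectrum0 <- function(x) {
  x <- as.numeric(x)
  if (length(unique(x)) < 3) return(var(x))
  fit <- tryCatch(ar(x, aic = TRUE, order.max = min(20, length(x) %/% 5)),
                  error = function(e) NULL)
  if (is.null(fit) || length(fit$ar) == 0) return(var(x))
  fit$var.pred / (1 - sum(fit$ar))^2
}

.ess <- function(x) {
  s0 <- .spectrum0(x)
  if (s0 <= 0) return(length(x))
  min(length(x), length(x) * var(x) / s0)
}

.geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(max(2, floor(frac1 * n)))]
  b <- x[seq.int(n - max(2, floor(frac2 * n)) + 1, n)]
  (mean(a) - mean(b)) /
    sqrt(.spectrum0(a) / length(a) + .spectrum0(b) / length(b))
}

#' Build a fixed-effect design matrix from a covariate table
#'
#' Numeric columns are standardized (mean 0, SD 1); categorical columns are
#' one-hot encoded with the reference level dropped. An intercept column is
#' always included first.
#'
#' @param table data.frame of covariates (or path to a TSV with header).
#' @param spec character vector of column names to include; empty gives an
#'   intercept-only design.
#' @return A numeric matrix with `intercept` as the first column.
#' @export
fixed_effect_covariates <- function(table, spec = character(0)) {
  if (is.character(table) && length(table) == 1)
    table <- read.table(table, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
  miss <- setdiff(spec, names(table))
  if (length(miss))
    .err(paste("covariate column(s) not found:", paste(miss, collapse = ", ")),
         "liabh2_schema")
  n <- nrow(table)
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  for (nm in spec) {
    v <- table[[nm]]
    if (is.numeric(v)) {
      s <- sd(v)
      col <- if (s > 0) (v - mean(v)) / s else v * 0
      X <- cbind(X, setNames(data.frame(col), nm))
      colnames(X)[ncol(X)] <- nm
    } else {
      fv <- factor(v)
      mm <- model.matrix(~ fv)[, -1, drop = FALSE]
      colnames(mm) <- paste0(nm, "_", levels(fv)[-1])
      X <- cbind(X, mm)
    }
  }
  as.matrix(X)
}

#' Fit the threshold animal model separately per cohort
#'
#' Splits the pedigree by an era / cohort label (individuals whose parents
#' fall outside their cohort are treated as having unknown parents) and fits
#' an independent chain per cohort, reporting whether the 95% credible
#' intervals overlap.
#'
#' @param ped a [pedigree()].
#' @param y binary status aligned to pedigree rows.
#' @param era_labels label per individual (two or more levels).
#' @param cfg a [chain_config()]; each cohort chain uses `cfg$seed` offset by
#'   its cohort index.
#' @param X optional fixed-effect design (subset per cohort).
#' @return A list of `posterior_chain` objects (one per level, named), with
#'   attribute `ci_overlap` (logical, first two cohorts).
#' @export
cohort_split_fit <- function(ped, y, era_labels, cfg, X = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  lv <- unique(era_labels)
  if (any(tabulate(factor(era_labels, levels = lv)) == 0) || length(lv) < 2)
    .err("need at least two non-empty cohorts", "liabh2_invalid_input")
  fits <- list()
  for (k in seq_along(lv)) {
    keep <- which(era_labels == lv[k])
    if (!length(keep)) .err(paste("empty cohort:", lv[k]),
                            "liabh2_invalid_input")
    sub <- as.data.frame(ped)[keep, , drop = FALSE]
    sub$father[!(sub$father %in% sub$id)] <- 0L
    sub$mother[!(sub$mother %in% sub$id)] <- 0L
    cfg_k <- cfg
    cfg_k$seed <- cfg$seed + k
    fits[[as.character(lv[k])]] <- fit_threshold_animal_model(
      pedigree(sub), y[keep],
      if (is.null(X)) NULL else X[keep, , drop = FALSE], cfg_k)
  }
  ci1 <- fits[[1]]$summary$h2_ci
  ci2 <- fits[[2]]$summary$h2_ci
  attr(fits, "ci_overlap") <- ci1[1] <= ci2[2] && ci2[1] <= ci1[2]
  fits
}
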
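# SNP- and sample-level quality control for case-control genotype data, and
# genomic-control inflation statistics (lambda and lambda_1000).

#' Quality-control thresholds
#'
#' Defaults reproduce a strict GWAS filter: remove SNPs with MAF < 1%, call
#' rate < 95% in cases or in controls, MAF 1-5% with call rate < 99%, or
#' Hardy-Weinberg disequilibrium P < 0.05 (tested in controls); remove
#' samples with call rate < 99% or autosomal heterozygosity beyond 3 SD of
#' the sample mean.
#'
#' @param maf_min minimum minor allele frequency.
#' @param callrate_min minimum per-group (cases / controls) SNP call rate.
#' @param callrate_min_lowmaf stricter call-rate floor applied when MAF is
#'   in `[maf_min, lowmaf_upper]`.
#' @param lowmaf_upper upper MAF bound of the stricter call-rate band.
#' @param hwe_p_min Hardy-Weinberg equilibrium P-value floor.
#' @param sample_callrate_min minimum per-sample call rate.
#' @param het_sd_limit allowed deviation of per-sample heterozygosity from
#'   the mean, in SD units (`Inf` disables the rule).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.01, callrate_min = 0.95,
                          callrate_min_lowmaf = 0.99, lowmaf_upper = 0.05,
                          hwe_p_min = 0.05, sample_callrate_min = 0.99,
                          het_sd_limit = 3) {
  probs <- c(maf_min, callrate_min, callrate_min_lowmaf, lowmaf_upper,
             hwe_p_min, sample_callrate_min)
  if (any(probs < 0 | probs > 1))
    .err("all probability thresholds must be in [0, 1]",
         "liabh2_invalid_config")
  structure(list(maf_min = maf_min, callrate_min = callrate_min,
                 callrate_min_lowmaf = callrate_min_lowmaf,
                 lowmaf_upper = lowmaf_upper, hwe_p_min = hwe_p_min,
                 sample_callrate_min = sample_callrate_min,
                 het_sd_limit = het_sd_limit),
            class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' 1-df goodness-of-fit chi-square of observed genotype counts against
#' Hardy-Weinberg expectations at the sample allele frequency (no continuity
#' correction). An exact-test mode (sum of probabilities of tables at most
#' as likely, conditional on allele counts) is available for PLINK parity.
#'
#' @param n_aa,n_ab,n_bb genotype counts (vectors allowed).
#' @param exact use the exact conditional test instead of chi-square.
#' @return Vector of P-values (1 where the SNP is monomorphic).
#' @export
hwe_test <- function(n_aa, n_ab, n_bb, exact = FALSE) {
  if (exact) {
    return(mapply(.hwe_exact_one, n_aa, n_ab, n_bb))
  }
  n <- n_aa + n_ab + n_bb
  p <- (2 * n_aa + n_ab) / (2 * n)
  e_aa <- n * p^2
  e_ab <- n * 2 * p * (1 - p)
  e_bb <- n * (1 - p)^2
  chi <- ifelse(p == 0 | p == 1, 0,
                (n_aa - e_aa)^2 / pmax(e_aa, .Machine$double.eps) +
                  (n_ab - e_ab)^2 / pmax(e_ab, .Machine$double.eps) +
                  (n_bb - e_bb)^2 / pmax(e_bb, .Machine$double.eps))
  pchisq(chi, df = 1, lower.tail = FALSE)
}

# exact HWE test for one SNP: conditional distribution of heterozygote count
# given allele counts; P = sum of probabilities <= observed
.hwe_exact_one <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  if (na == 0 || na == 2 * n) return(1)
  nab_all <- seq.int(na %% 2, min(na, 2 * n - na), by = 2)
  logp <- lfactorial(n) - lfactorial((na - nab_all) / 2) -
    lfactorial(nab_all) - lfactorial(n - (na + nab_all) / 2) +
    nab_all * log(2) - (lfactorial(2 * n) - lfactorial(na) -
                          lfactorial(2 * n - na))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(nab_all == n_ab)
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

# per-SNP genotype counts within a sample subset
.geno_counts <- function(dosage, rows) {
  x <- dosage[rows, , drop = FALSE]
  n2 <- colSums(x == 2, na.rm = TRUE)
  n1 <- colSums(x == 1, na.rm = TRUE)
  n0 <- colSums(x == 0, na.rm = TRUE)
  list(n0 = n0, n1 = n1, n2 = n2)
}

#' SNP-level quality-control filter
#'
#' A SNP is removed if (i) pooled MAF < `maf_min`, (ii) call rate <
#' `callrate_min` in cases or in controls, (iii) MAF in
#' `[maf_min, lowmaf_upper]` with call rate < `callrate_min_lowmaf`, or
#' (iv) Hardy-Weinberg P < `hwe_p_min` (computed in controls). Each SNP's
#' decision depends only on its own data, so the filter is idempotent and
#' order-independent.
#'
#' @param G a [genotype_matrix()].
#' @param status 0/1 vector aligned to samples.
#' @param thr a [qc_thresholds()].
#' @param hwe_exact use the exact HWE test.
#' @return A list: `genotypes` (filtered [genotype_matrix()]) and `log`
#'   (data.frame `snp_id`, `rule_fired` (`"pass"`, `"maf"`, `"callrate"`,
#'   `"callrate_lowmaf"`, `"hwe"`), `value`).
#' @export
filter_snps <- function(G, status, thr = qc_thresholds(), hwe_exact = FALSE) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (ncol(G$dosage) == 0 || nrow(G$dosage) == 0)
    .err("empty genotype matrix", "liabh2_invalid_input")
  if (length(status) != nrow(G$dosage))
    .err("status must align with samples", "liabh2_invalid_input")
  dos <- G$dosage
  cases <- status == 1
  controls <- status == 0
  maf <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(maf, 1 - maf)
  maf[is.nan(maf)] <- 0
  cr_case <- if (any(cases)) colMeans(!is.na(dos[cases, , drop = FALSE]))
    else rep(1, ncol(dos))
  cr_ctrl <- if (any(controls))
    colMeans(!is.na(dos[controls, , drop = FALSE])) else rep(1, ncol(dos))
  cr_min <- pmin(cr_case, cr_ctrl)
  hwe_rows <- if (any(controls)) controls else rep(TRUE, nrow(dos))
  cts <- .geno_counts(dos, hwe_rows)
  hwe_p <- hwe_test(cts$n2, cts$n1, cts$n0, exact = hwe_exact)
  rule <- rep("pass", ncol(dos))
  value <- rep(NA_real_, ncol(dos))
  r4 <- hwe_p < thr$hwe_p_min
  rule[r4] <- "hwe"; value[r4] <- hwe_p[r4]
  r3 <- maf >= thr$maf_min & maf <= thr$lowmaf_upper &
    cr_min < thr$callrate_min_lowmaf
  rule[r3] <- "callrate_lowmaf"; value[r3] <- cr_min[r3]
  r2 <- cr_min < thr$callrate_min
  rule[r2] <- "callrate"; value[r2] <- cr_min[r2]
  r1 <- maf < thr$maf_min
  rule[r1] <- "maf"; value[r1] <- maf[r1]
  keep <- rule == "pass"
  list(genotypes = G[, keep],
       log = data.frame(snp_id = G$snps$id, rule_fired = rule, value = value,
                        stringsAsFactors = FALSE))
}

#' Sample-level quality-control filter
#'
#' Removes samples with call rate below `sample_callrate_min` and samples
#' whose autosomal heterozygosity (fraction of heterozygous calls among
#' non-missing calls) lies more than `het_sd_limit` SDs from the sample
#' mean.
#'
#' @param G a [genotype_matrix()].
#' @param thr a [qc_thresholds()].
#' @return A list: `genotypes` (filtered) and `log` (data.frame `sample_id`,
#'   `rule_fired` (`"pass"`, `"callrate"`, `"heterozygosity"`), `value`).
#' @export
filter_samples <- function(G, thr = qc_thresholds()) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (nrow(G$dosage) < 2) .err("need >= 2 samples", "liabh2_invalid_input")
  dos <- G$dosage
  cr <- rowMeans(!is.na(dos))
  het <- rowMeans(dos == 1, na.rm = TRUE)
  rule <- rep("pass", nrow(dos))
  value <- rep(NA_real_, nrow(dos))
  if (is.finite(thr$het_sd_limit)) {
    mu <- mean(het); s <- sd(het)
    if (is.finite(s) && s > 0) {
      rh <- abs(het - mu) > thr$het_sd_limit * s
      rule[rh] <- "heterozygosity"; value[rh] <- het[rh]
    }
  }
  rc <- cr < thr$sample_callrate_min
  rule[rc] <- "callrate"; value[rc] <- cr[rc]
  keep <- rule == "pass"
  if (!any(keep)) .err("all samples removed", "liabh2_empty_result")
  list(genotypes = G[keep, ],
       log = data.frame(sample_id = G$sample_ids, rule_fired = rule,
                        value = value, stringsAsFactors = FALSE))
}

#' Cochran-Armitage trend test per SNP
#'
#' 1-df trend chi-square of case status on genotype dosage (scores 0, 1, 2),
#' vectorized over SNPs with per-SNP handling of missing calls.
#'
#' @param G a [genotype_matrix()].
#' @param status 0/1 vector aligned to samples.
#' @return Numeric vector of chi-square statistics (0 for monomorphic SNPs).
#' @export
assoc_trend_test <- function(G, status) {
  stopifnot(inherits(G, "genotype_matrix"))
  dos <- G$dosage
  if (length(status) != nrow(dos))
    .err("status must align with samples", "liabh2_invalid_input")
  M <- !is.na(dos)
  x <- dos; x[!M] <- 0
  N <- colSums(M)
  R <- colSums(M * status)           # cases with a call, per SNP
  S1 <- colSums(x * status)          # sum of scores in cases
  S2 <- colSums(x)                   # sum of scores overall
  S3 <- colSums(x^2)
  num <- N * (N * S1 - R * S2)^2
  den <- R * (N - R) * (N * S3 - S2^2)
  chi <- ifelse(den > 0, num / den, 0)
  unname(chi)
}

#' Genomic-control inflation factor and its 1,000-case rescaling
#'
#' `lambda` is the median of the 1-df association chi-squares divided by the
#' theoretical null median (0.4549364); `lambda_1000` rescales it to a
#' 1,000-case / 1,000-control study:
#' `1 + (lambda - 1) (1/n_cases + 1/n_controls) / (2/1000)`.
#'
#' @param chisq vector of 1-df association chi-square statistics (or a
#'   single precomputed `lambda` with `is_lambda = TRUE`).
#' @param n_cases,n_controls sample counts.
#' @param is_lambda if `TRUE`, `chisq` is already a lambda value.
#' @return A list with `lambda` and `lambda_1000`.
#' @export
inflation_lambda <- function(chisq, n_cases, n_controls, is_lambda = FALSE) {
  if (n_cases <= 0 || n_controls <= 0)
    .err("sample counts must be positive", "liabh2_invalid_input")
  if (!length(chisq)) .err("need at least one statistic",
                           "liabh2_invalid_input")
  if (any(chisq < 0)) .err("chi-square values must be >= 0",
                           "liabh2_invalid_input")
  lambda <- if (is_lambda) chisq else
    median(chisq) / qchisq(0.5, df = 1)
  lambda_1000 <- 1 + (lambda - 1) * (1 / n_cases + 1 / n_controls) /
    (2 / 1000)
  list(lambda = lambda, lambda_1000 = lambda_1000)
}
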
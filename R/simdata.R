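# Seeded generators for case-control GWAS genotypes and multi-generation
# pedigrees under the additive liability-threshold model. These stand in for
# registry / GWAS data in every recovery test: the disease is a threshold
# exceedance of a unit-variance latent liability, with lifetime risk K
# setting the threshold at qnorm(1 - K).

#' Configuration for the genotype / case-control simulator
#'
#' @param n_snps number of independent SNPs.
#' @param n_cases,n_controls target sample counts.
#' @param n_causal number of causal SNPs (`<= n_snps`).
#' @param h2_liab liability-scale heritability in `[0, 1]`.
#' @param prevalence_K lifetime risk in `(0, 1)`; sets the liability
#'   threshold `qnorm(1 - K)`.
#' @param maf_low,maf_high bounds for the uniform allele-frequency draw,
#'   in `(0, 0.5]`.
#' @param missing_rate per-call missingness probability (completely at
#'   random).
#' @param n_chromosomes chromosome labels are assigned round-robin over
#'   `1:n_chromosomes`.
#' @param subtype_split probability a case is labelled subtype "A" rather
#'   than "B" (seeded Bernoulli); supports stratified re-analysis.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output from every generator.
#' @return A validated list of class `geno_sim_config`.
#' @export
geno_sim_config <- function(n_snps, n_cases, n_controls,
                            n_causal = max(1L, round(n_snps / 10)),
                            h2_liab = 0.374, prevalence_K = 0.005,
                            maf_low = 0.05, maf_high = 0.5,
                            missing_rate = 0, n_chromosomes = 22L,
                            subtype_split = 0.5, seed = 1L) {
  if (n_snps < 1 || (n_cases + n_controls) < 1)
    .err("n_snps and total sample count must be positive",
         "liabh2_invalid_config")
  if (n_causal > n_snps)
    .err("n_causal must not exceed n_snps", "liabh2_invalid_config")
  if (h2_liab < 0 || h2_liab > 1)
    .err("h2_liab must be in [0, 1]", "liabh2_invalid_config")
  if (prevalence_K <= 0 || prevalence_K >= 1)
    .err("prevalence_K must be in (0, 1)", "liabh2_invalid_config")
  if (maf_low > maf_high || maf_low <= 0 || maf_high > 0.5)
    .err("require 0 < maf_low <= maf_high <= 0.5", "liabh2_invalid_config")
  if (missing_rate < 0 || missing_rate >= 1)
    .err("missing_rate must be in [0, 1)", "liabh2_invalid_config")
  structure(list(n_snps = as.integer(n_snps), n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_causal = as.integer(n_causal), h2_liab = h2_liab,
                 prevalence_K = prevalence_K, maf_low = maf_low,
                 maf_high = maf_high, missing_rate = missing_rate,
                 n_chromosomes = as.integer(n_chromosomes),
                 subtype_split = subtype_split, seed = as.integer(seed)),
            class = "geno_sim_config")
}

# Frozen "truth" of the simulated architecture: allele frequencies, causal
# set, per-SNP effects on standardized dosages. Drawn from config$seed so
# that simulate_genotypes / assign_liability_phenotypes / ascertainment all
# see the same model. Effects are drawn N(0, h2/n_causal) and then rescaled
# so the population genetic variance equals h2_liab exactly.
.sim_geno_model <- function(config) {
  set.seed(config$seed)
  freq <- runif(config$n_snps, config$maf_low, config$maf_high)
  causal <- sort(sample.int(config$n_snps, config$n_causal))
  beta <- numeric(config$n_snps)
  if (config$h2_liab > 0) {
    b <- rnorm(config$n_causal, 0, sqrt(config$h2_liab / config$n_causal))
    if (sum(b^2) > 0) b <- b * sqrt(config$h2_liab / sum(b^2))
    beta[causal] <- b
  }
  snps <- data.frame(
    id = sprintf("snp%06d", seq_len(config$n_snps)),
    chr = rep_len(seq_len(config$n_chromosomes), config$n_snps),
    pos = seq_len(config$n_snps) * 1000L,
    a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  list(freq = freq, causal = causal, beta = beta, snps = snps)
}

# draw n genotype rows under Hardy-Weinberg at the model's frequencies
.draw_hw <- function(n, freq) {
  m <- length(freq)
  matrix(rbinom(n * m, 2L, rep(freq, each = n)), nrow = n, ncol = m)
}

# genetic value from standardized dosages at the *population* frequencies;
# missing dosages are mean-imputed (2p) so they contribute zero
.genetic_value <- function(dosage, model) {
  idx <- model$causal
  b <- model$beta[idx]
  p <- model$freq[idx]
  x <- dosage[, idx, drop = FALSE]
  xc <- sweep(x, 2, 2 * p)
  xc[is.na(xc)] <- 0
  drop(xc %*% (b / sqrt(2 * p * (1 - p))))
}

.apply_missing <- function(dosage, rate) {
  if (rate > 0)
    dosage[runif(length(dosage)) < rate] <- NA_integer_
  dosage
}

#' Simulate population genotypes under Hardy-Weinberg equilibrium
#'
#' SNP allele frequencies are drawn uniformly in `[maf_low, maf_high]`
#' (seeded), genotypes in Hardy-Weinberg proportions at those frequencies,
#' and missing calls inserted completely at random at `missing_rate`.
#' Chromosome labels are assigned round-robin.
#'
#' @param config a [geno_sim_config()].
#' @param n_samples number of individuals to draw; defaults to
#'   `n_cases + n_controls`.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(config,
                               n_samples = config$n_cases + config$n_controls) {
  stopifnot(inherits(config, "geno_sim_config"))
  if (n_samples < 1) .err("n_samples must be positive", "liabh2_invalid_config")
  model <- .sim_geno_model(config)
  set.seed(config$seed + 1L)
  dosage <- .apply_missing(.draw_hw(n_samples, model$freq),
                           config$missing_rate)
  genotype_matrix(dosage, model$snps, sprintf("ind%06d", seq_len(n_samples)))
}

#' Assign liability-threshold phenotypes to simulated genotypes
#'
#' The latent liability is `g + e`, where `g` is the additive genetic value
#' of the (seeded) causal SNPs on the standardized scale — population
#' variance exactly `h2_liab` — and `e ~ N(0, 1 - h2_liab)`. Disease status
#' is `liability > qnorm(1 - K)`. Cases receive a seeded Bernoulli subtype
#' label ("A"/"B").
#'
#' @param G a [genotype_matrix()] produced under the same `config`.
#' @param config the [geno_sim_config()] used to generate `G`.
#' @return A data.frame with columns `sample_id`, `genetic_value`,
#'   `liability`, `status` (0/1) and `subtype` (`NA` for controls).
#' @export
assign_liability_phenotypes <- function(G, config) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(config, "geno_sim_config"))
  model <- .sim_geno_model(config)
  n <- nrow(G$dosage)
  g <- .genetic_value(G$dosage, model)
  set.seed(config$seed + 2L)
  e <- if (config$h2_liab < 1) rnorm(n, 0, sqrt(1 - config$h2_liab)) else
    numeric(n)
  liab <- g + e
  status <- as.integer(liab > qnorm(1 - config$prevalence_K))
  subtype <- rep(NA_character_, n)
  ncase <- sum(status)
  if (ncase > 0)
    subtype[status == 1L] <- ifelse(
      runif(ncase) < config$subtype_split, "A", "B")
  data.frame(sample_id = G$sample_ids, genetic_value = g, liability = liab,
             status = status, subtype = subtype, stringsAsFactors = FALSE)
}

#' Ascertain a case-control sample by rejection from the population model
#'
#' Draws genotype + liability batches from the population model until the
#' case and control quotas are met, keeping the genotype-liability coupling
#' exact. Records the realized case fraction `P` and the population lifetime
#' risk `K` for downstream liability-scale transformation.
#'
#' @param config a [geno_sim_config()].
#' @param batch_size batch size for rejection sampling; default scales with
#'   the expected number of draws needed.
#' @param max_batches resource budget; simulations with very small `K`
#'   exceed it and error with advice to use a larger `K`.
#' @return A list with elements `genotypes` (a [genotype_matrix()], cases and
#'   controls in sampling order), `phenotypes` (as
#'   [assign_liability_phenotypes()]), `P` and `K`.
#' @export
ascertain_case_control <- function(config, batch_size = NULL,
                                   max_batches = 1000L) {
  stopifnot(inherits(config, "geno_sim_config"))
  model <- .sim_geno_model(config)
  K <- config$prevalence_K
  n_target <- config$n_cases + config$n_controls
  if (is.null(batch_size))
    batch_size <- max(200L, as.integer(ceiling(
      1.5 * max(config$n_cases / max(K, 1e-12), config$n_controls / (1 - K)) /
        10)))
  exp_batches <- (config$n_cases / max(K * batch_size, 1e-12))
  if (exp_batches > max_batches)
    .err(paste0("expected ", round(exp_batches), " batches to ascertain ",
                config$n_cases, " cases at K = ", K,
                "; increase K (tests should use K >= 0.05) or max_batches"),
         "liabh2_resource_budget")
  thr <- qnorm(1 - K)
  set.seed(config$seed + 3L)
  keep_dos <- vector("list", 0L)
  keep_phe <- vector("list", 0L)
  got_cases <- 0L; got_controls <- 0L; b <- 0L
  while ((got_cases < config$n_cases || got_controls < config$n_controls) &&
         b < max_batches) {
    b <- b + 1L
    dos <- .draw_hw(batch_size, model$freq)
    g <- .genetic_value(dos, model)
    e <- if (config$h2_liab < 1)
      rnorm(batch_size, 0, sqrt(1 - config$h2_liab)) else numeric(batch_size)
    liab <- g + e
    status <- as.integer(liab > thr)
    want_case <- min(config$n_cases - got_cases, sum(status == 1L))
    want_ctrl <- min(config$n_controls - got_controls, sum(status == 0L))
    take <- c(which(status == 1L)[seq_len(want_case)],
              which(status == 0L)[seq_len(want_ctrl)])
    if (length(take)) {
      keep_dos[[length(keep_dos) + 1L]] <- dos[take, , drop = FALSE]
      keep_phe[[length(keep_phe) + 1L]] <- data.frame(
        genetic_value = g[take], liability = liab[take],
        status = status[take])
      got_cases <- got_cases + want_case
      got_controls <- got_controls + want_ctrl
    }
  }
  if (got_cases < config$n_cases || got_controls < config$n_controls)
    .err("ascertainment budget exhausted before quotas were met; increase K or max_batches",
         "liabh2_resource_budget")
  dosage <- do.call(rbind, keep_dos)
  phe <- do.call(rbind, keep_phe)
  dosage <- .apply_missing(dosage, config$missing_rate)
  ids <- sprintf("ind%06d", seq_len(nrow(dosage)))
  subtype <- rep(NA_character_, nrow(phe))
  ncase <- sum(phe$status)
  if (ncase > 0)
    subtype[phe$status == 1L] <- ifelse(
      runif(ncase) < config$subtype_split, "A", "B")
  phenotypes <- data.frame(sample_id = ids,
                           genetic_value = phe$genetic_value,
                           liability = phe$liability, status = phe$status,
                           subtype = subtype, stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(dosage, model$snps, ids),
       phenotypes = phenotypes,
       P = config$n_cases / n_target, K = K)
}

#' Configuration for the pedigree simulator
#'
#' @param n_families number of independent families.
#' @param n_generations generations per family (2-5).
#' @param sibship_mean mean number of children per couple (Poisson,
#'   truncated at 1).
#' @param h2_liab liability-scale heritability in `[0, 1]`.
#' @param prevalence_K lifetime risk in `(0, 1)`.
#' @param covariate_effects named numeric vector of liability effect sizes
#'   for standard-normal covariates (e.g. `c(birth_year = 0.1)`).
#' @param seed integer seed.
#' @return A validated list of class `ped_sim_config`.
#' @export
ped_sim_config <- function(n_families, n_generations = 2L, sibship_mean = 2.5,
                           h2_liab = 0.489, prevalence_K = 0.005,
                           covariate_effects = numeric(0), seed = 1L) {
  if (n_families < 1) .err("n_families must be positive",
                           "liabh2_invalid_config")
  if (n_generations < 2 || n_generations > 5)
    .err("n_generations must be between 2 and 5", "liabh2_invalid_config")
  if (sibship_mean <= 0) .err("sibship_mean must be positive",
                              "liabh2_invalid_config")
  if (h2_liab < 0 || h2_liab > 1)
    .err("h2_liab must be in [0, 1]", "liabh2_invalid_config")
  if (prevalence_K <= 0 || prevalence_K >= 1)
    .err("prevalence_K must be in (0, 1)", "liabh2_invalid_config")
  if (length(covariate_effects) && is.null(names(covariate_effects)))
    .err("covariate_effects must be a named numeric vector",
         "liabh2_invalid_config")
  structure(list(n_families = as.integer(n_families),
                 n_generations = as.integer(n_generations),
                 sibship_mean = sibship_mean, h2_liab = h2_liab,
                 prevalence_K = prevalence_K,
                 covariate_effects = covariate_effects,
                 seed = as.integer(seed)),
            class = "ped_sim_config")
}

#' Simulate multi-generation pedigrees with additive liability transmission
#'
#' Each family starts from a founder couple; every generation one child of
#' the previous couple marries an unrelated immigrant founder and the couple
#' has a Poisson (truncated at 1) number of children. Founders receive
#' additive genetic values `a ~ N(0, h2)`; offspring receive
#' `(a_f + a_m)/2` plus a Mendelian-segregation deviate `N(0, h2/2)`
#' (founder-immigrant design, so all individuals are non-inbred). The
#' liability is `a + X beta + e`, `e ~ N(0, 1 - h2)`, and status is a
#' threshold exceedance at `qnorm(1 - K)`.
#'
#' @param config a [ped_sim_config()].
#' @return A list with `pedigree` (a [pedigree()]), `phenotypes` (data.frame
#'   with `id`, `genetic_value`, `liability`, `status`, `generation`,
#'   `family`) and `covariates` (data.frame of simulated covariates, or
#'   `NULL` when none were requested).
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "ped_sim_config"))
  set.seed(config$seed)
  h2 <- config$h2_liab
  nf <- config$n_families
  id <- integer(0); father <- integer(0); mother <- integer(0)
  sex <- integer(0); gen <- integer(0); fam <- integer(0)
  a <- numeric(0)
  nxt <- 1L
  new_founders <- function(k) {
    ids <- nxt + seq_len(k) - 1L
    nxt <<- nxt + k
    ids
  }
  # generation 1: founder couples, vectorized across families
  f_ids <- seq.int(1L, by = 2L, length.out = nf)
  m_ids <- f_ids + 1L
  nxt <- 2L * nf + 1L
  id <- c(f_ids, m_ids); father <- rep(0L, 2 * nf); mother <- rep(0L, 2 * nf)
  sex <- c(rep(1L, nf), rep(2L, nf)); gen <- rep(1L, 2 * nf)
  fam <- c(seq_len(nf), seq_len(nf))
  a <- rnorm(2 * nf, 0, sqrt(h2))
  cur_f <- f_ids; cur_m <- m_ids
  a_vec <- a
  for (g in 2L:config$n_generations) {
    nkids <- pmax(1L, rpois(nf, config$sibship_mean))
    tot <- sum(nkids)
    kid_ids <- nxt + seq_len(tot) - 1L
    nxt <- nxt + tot
    kf <- rep(cur_f, nkids); km <- rep(cur_m, nkids)
    kfam <- rep(seq_len(nf), nkids)
    ka <- 0.5 * (a_vec[kf] + a_vec[km]) + rnorm(tot, 0, sqrt(h2 / 2))
    ksex <- sample(c(1L, 2L), tot, replace = TRUE)
    id <- c(id, kid_ids); father <- c(father, kf); mother <- c(mother, km)
    sex <- c(sex, ksex); gen <- c(gen, rep(g, tot)); fam <- c(fam, kfam)
    a_tmp <- numeric(max(kid_ids))
    a_tmp[seq_along(a_vec)] <- a_vec
    a_tmp[kid_ids] <- ka
    a_vec <- a_tmp
    if (g < config$n_generations) {
      # first child of each sibship continues the line with an immigrant
      first_kid <- kid_ids[c(1L, head(cumsum(nkids), -1L) + 1L)]
      sp_ids <- nxt + seq_len(nf) - 1L
      nxt <- nxt + nf
      sp_sex <- ifelse(sex[match(first_kid, id)] == 1L, 2L, 1L)
      id <- c(id, sp_ids); father <- c(father, rep(0L, nf))
      mother <- c(mother, rep(0L, nf)); sex <- c(sex, sp_sex)
      gen <- c(gen, rep(g, nf)); fam <- c(fam, seq_len(nf))
      sp_a <- rnorm(nf, 0, sqrt(h2))
      a_tmp <- numeric(max(sp_ids))
      a_tmp[seq_along(a_vec)] <- a_vec
      a_tmp[sp_ids] <- sp_a
      a_vec <- a_tmp
      is_male <- sex[match(first_kid, id)] == 1L
      cur_f <- ifelse(is_male, first_kid, sp_ids)
      cur_m <- ifelse(is_male, sp_ids, first_kid)
    }
  }
  n <- length(id)
  a_all <- a_vec[id]
  covariates <- NULL
  fixed <- numeric(n)
  if (length(config$covariate_effects)) {
    covariates <- data.frame(id = id)
    for (nm in names(config$covariate_effects)) {
      x <- rnorm(n)
      covariates[[nm]] <- x
      fixed <- fixed + config$covariate_effects[[nm]] * x
    }
  }
  e <- if (h2 < 1) rnorm(n, 0, sqrt(1 - h2)) else numeric(n)
  liab <- a_all + fixed + e
  status <- as.integer(liab > qnorm(1 - config$prevalence_K))
  ped <- pedigree(data.frame(id = id, father = father, mother = mother,
                             sex = sex, status = status))
  phenotypes <- data.frame(id = id, genetic_value = a_all, liability = liab,
                           status = status, generation = gen, family = fam)
  list(pedigree = ped, phenotypes = phenotypes, covariates = covariates)
}
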
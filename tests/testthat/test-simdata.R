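test_that("generators are deterministic under a fixed config and seed", {
  cfg <- geno_sim_config(n_snps = 50, n_cases = 20, n_controls = 30,
                         h2_liab = 0.4, prevalence_K = 0.2,
                         missing_rate = 0.05, seed = 42)
  expect_identical(simulate_genotypes(cfg)$dosage,
                   simulate_genotypes(cfg)$dosage)
  G <- simulate_genotypes(cfg)
  expect_identical(assign_liability_phenotypes(G, cfg),
                   assign_liability_phenotypes(G, cfg))
  a1 <- ascertain_case_control(cfg)
  a2 <- ascertain_case_control(cfg)
  expect_identical(a1$genotypes$dosage, a2$genotypes$dosage)
  pcfg <- ped_sim_config(n_families = 30, n_generations = 3,
                         h2_liab = 0.5, prevalence_K = 0.1, seed = 9)
  expect_identical(simulate_pedigree(pcfg)$phenotypes,
                   simulate_pedigree(pcfg)$phenotypes)
})

test_that("missing_rate = 0 gives complete data; rate > 0 inserts NA", {
  cfg <- geno_sim_config(n_snps = 100, n_cases = 0, n_controls = 50,
                         missing_rate = 0, seed = 1)
  expect_false(anyNA(simulate_genotypes(cfg)$dosage))
  cfg2 <- geno_sim_config(n_snps = 200, n_cases = 0, n_controls = 100,
                          missing_rate = 0.1, seed = 1)
  frac <- mean(is.na(simulate_genotypes(cfg2)$dosage))
  expect_gt(frac, 0.08)
  expect_lt(frac, 0.12)
})

test_that("invalid simulator configs are rejected", {
  expect_error(geno_sim_config(n_snps = 0, n_cases = 1, n_controls = 1),
               class = "liabh2_invalid_config")
  expect_error(geno_sim_config(n_snps = 10, n_cases = 0, n_controls = 0),
               class = "liabh2_invalid_config")
  expect_error(geno_sim_config(n_snps = 10, n_cases = 1, n_controls = 1,
                               n_causal = 11),
               class = "liabh2_invalid_config")
  expect_error(geno_sim_config(n_snps = 10, n_cases = 1, n_controls = 1,
                               h2_liab = 1.2),
               class = "liabh2_invalid_config")
  expect_error(ped_sim_config(n_families = 10, n_generations = 7),
               class = "liabh2_invalid_config")
})

test_that("sample MAF concentrates around its drawn value (binomial check)", {
  cfg <- geno_sim_config(n_snps = 200, n_cases = 0, n_controls = 20000,
                         maf_low = 0.2, maf_high = 0.5, seed = 5)
  G <- simulate_genotypes(cfg, 20000)
  model <- liabh2:::.sim_geno_model(cfg)
  p_hat <- colMeans(G$dosage) / 2
  sd3 <- 3 * sqrt(model$freq * (1 - model$freq) / (2 * 20000))
  expect_gte(mean(abs(p_hat - model$freq) <= sd3), 0.95)
})

test_that("liability decomposes into genetic value + residual as configured", {
  # pure noise: case fraction converges to K
  cfg0 <- geno_sim_config(n_snps = 50, n_cases = 0, n_controls = 100000,
                          n_causal = 10, h2_liab = 0, prevalence_K = 0.1,
                          seed = 2)
  G0 <- simulate_genotypes(cfg0, 100000)
  ph0 <- assign_liability_phenotypes(G0, cfg0)
  se <- sqrt(0.1 * 0.9 / 100000)
  expect_lt(abs(mean(ph0$status) - 0.1), 3 * se)

  # fully genetic: status determined by genetic value alone
  cfg1 <- geno_sim_config(n_snps = 100, n_cases = 0, n_controls = 2000,
                          n_causal = 50, h2_liab = 1, prevalence_K = 0.2,
                          seed = 3)
  G1 <- simulate_genotypes(cfg1, 2000)
  ph1 <- assign_liability_phenotypes(G1, cfg1)
  expect_identical(ph1$liability, ph1$genetic_value)
  expect_identical(ph1$status,
                   as.integer(ph1$genetic_value > qnorm(1 - 0.2)))

  # intermediate: R^2 of liability on genetic value ~= h2
  cfg <- geno_sim_config(n_snps = 300, n_cases = 0, n_controls = 50000,
                         n_causal = 150, h2_liab = 0.4, prevalence_K = 0.1,
                         seed = 4)
  G <- simulate_genotypes(cfg, 50000)
  ph <- assign_liability_phenotypes(G, cfg)
  fit <- lm(ph$liability ~ ph$genetic_value)
  expect_lt(abs(coef(fit)[2] - 1), 0.02)
  expect_lt(abs(summary(fit)$r.squared - 0.4), 0.02)
})

test_that("ascertainment meets quotas, records P/K, enriches case genetics", {
  # controls-only dataset
  cfg0 <- geno_sim_config(n_snps = 40, n_cases = 0, n_controls = 50,
                          h2_liab = 0.3, prevalence_K = 0.2, seed = 6)
  a0 <- ascertain_case_control(cfg0)
  expect_equal(sum(a0$phenotypes$status), 0)
  expect_equal(a0$P, 0)

  # K = 0.5, h2 = 0: population case rate ~ 0.5
  cfg5 <- geno_sim_config(n_snps = 40, n_cases = 0, n_controls = 20000,
                          n_causal = 10, h2_liab = 0, prevalence_K = 0.5,
                          seed = 7)
  ph5 <- assign_liability_phenotypes(simulate_genotypes(cfg5, 20000), cfg5)
  expect_lt(abs(mean(ph5$status) - 0.5), 3 * sqrt(0.25 / 20000))

  # truncation raises the conditional mean genetic value of cases
  deltas <- vapply(1:10, function(s) {
    cfg <- geno_sim_config(n_snps = 60, n_cases = 500, n_controls = 500,
                           n_causal = 30, h2_liab = 0.5, prevalence_K = 0.1,
                           seed = 100 + s)
    a <- ascertain_case_control(cfg)
    mean(a$phenotypes$genetic_value[a$phenotypes$status == 1]) -
      mean(a$phenotypes$genetic_value[a$phenotypes$status == 0])
  }, 0)
  expect_true(all(deltas > 0))
  cfg <- geno_sim_config(n_snps = 60, n_cases = 500, n_controls = 500,
                         h2_liab = 0.5, prevalence_K = 0.1, seed = 1)
  a <- ascertain_case_control(cfg)
  expect_equal(sum(a$phenotypes$status == 1), 500)
  expect_equal(sum(a$phenotypes$status == 0), 500)
  expect_equal(a$P, 0.5)
  expect_equal(a$K, 0.1)
})

test_that("ascertainment at tiny K errors with a resource-budget message", {
  cfg <- geno_sim_config(n_snps = 10, n_cases = 500, n_controls = 10,
                         h2_liab = 0.2, prevalence_K = 1e-6, seed = 1)
  expect_error(ascertain_case_control(cfg, batch_size = 100,
                                      max_batches = 5),
               class = "liabh2_resource_budget")
})

test_that("pedigree simulation matches additive-model expectations", {
  # h2 = 0: sib liabilities uncorrelated
  p0 <- simulate_pedigree(ped_sim_config(n_families = 25000,
                                         n_generations = 2,
                                         sibship_mean = 2, h2_liab = 0,
                                         prevalence_K = 0.1, seed = 11))
  sib_cor <- function(sim) {
    # first two children per family
    ph <- sim$phenotypes
    kids <- ph[ph$generation == 2, ]
    sp <- split(kids$liability, kids$family)
    pairs <- vapply(sp, function(v)
      if (length(v) >= 2) v[1:2] else c(NA_real_, NA_real_),
      numeric(2))
    ok <- !is.na(pairs[1, ])
    cor(pairs[1, ok], pairs[2, ok])
  }
  expect_lt(abs(sib_cor(p0)), 0.02)

  # h2 = 0.5: sib liability correlation ~ h2/2 = 0.25
  p5 <- simulate_pedigree(ped_sim_config(n_families = 25000,
                                         n_generations = 2,
                                         sibship_mean = 2, h2_liab = 0.5,
                                         prevalence_K = 0.1, seed = 12))
  expect_lt(abs(sib_cor(p5) - 0.25), 0.012)

  # founder genetic variance ~ h2
  founders <- p5$phenotypes[p5$phenotypes$generation == 1, ]
  expect_lt(abs(var(founders$genetic_value) - 0.5), 0.01)

  # small family passes the topological-order invariant
  tiny <- simulate_pedigree(ped_sim_config(n_families = 1,
                                           n_generations = 2,
                                           sibship_mean = 2, seed = 13))
  ped <- tiny$pedigree
  ord <- attr(ped, "topo_order")
  pos <- match(seq_len(nrow(ped)), ord)
  f <- match(ped$father, ped$id)
  ok <- is.na(f) | pos[f] < pos[seq_len(nrow(ped))]
  expect_true(all(ok))
})

test_that("covariate effects enter the liability and are returned", {
  cfg <- ped_sim_config(n_families = 2000, n_generations = 2,
                        sibship_mean = 2, h2_liab = 0.3, prevalence_K = 0.2,
                        covariate_effects = c(birth_year = 0.5), seed = 14)
  sim <- simulate_pedigree(cfg)
  expect_true("birth_year" %in% names(sim$covariates))
  r <- cor(sim$covariates$birth_year, sim$phenotypes$liability)
  # expected correlation 0.5 / sqrt(1 + 0.25)
  expect_lt(abs(r - 0.5 / sqrt(1.25)), 0.03)
})
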
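test_that("pedigree validation catches structural defects", {
  expect_error(pedigree(data.frame(id = 1:2, father = c(2, 1),
                                   mother = c(0, 0))),
               class = "liabh2_pedigree_integrity")
  expect_error(pedigree(data.frame(id = c(1, 1), father = 0, mother = 0)),
               class = "liabh2_pedigree_integrity")
  expect_error(pedigree(data.frame(id = 1, father = 1, mother = 0)),
               class = "liabh2_pedigree_integrity")
  expect_error(pedigree(data.frame(id = 1, father = 5, mother = 0)),
               class = "liabh2_pedigree_integrity")
  # valid pedigree round-trips through TSV
  ped <- pedigree(data.frame(id = 1:3, father = c(0, 0, 1),
                             mother = c(0, 0, 2), sex = c(1, 2, 1),
                             status = c(0, 0, 1)))
  tmp <- tempfile(fileext = ".tsv")
  write_pedigree(ped, tmp)
  ped2 <- read_pedigree(tmp)
  expect_equal(as.data.frame(ped2), as.data.frame(ped))
})

test_that("numerator relationship matrix matches hand-derived values", {
  # founder couple + child
  ped <- pedigree(data.frame(id = 1:3, father = c(0, 0, 1),
                             mother = c(0, 0, 2)))
  A <- build_nrm(ped)$values
  expect_equal(unname(diag(A)), rep(1, 3))
  expect_equal(A["1", "3"], 0.5)
  expect_equal(A["1", "2"], 0)

  # offspring of a half-sib mating: diagonal 1 + F = 1.125
  ped2 <- pedigree(data.frame(id = 1:6, father = c(0, 0, 0, 1, 1, 4),
                              mother = c(0, 0, 0, 2, 3, 5)))
  nrm <- build_nrm(ped2)
  expect_equal(nrm$values[6, 6], 1.125)
  expect_equal(unname(nrm$F[6]), 0.125)

  # full-sib pair relationship 0.5
  ped3 <- pedigree(data.frame(id = 1:4, father = c(0, 0, 1, 1),
                              mother = c(0, 0, 2, 2)))
  expect_equal(build_nrm(ped3)$values[3, 4], 0.5)
})

test_that("NRM is invariant to input row order and inverts correctly", {
  sim <- simulate_pedigree(ped_sim_config(n_families = 15,
                                          n_generations = 3,
                                          sibship_mean = 2, seed = 51))
  ped <- sim$pedigree
  A <- build_nrm(ped)$values
  set.seed(52)
  perm <- sample(nrow(ped))
  ped_p <- pedigree(as.data.frame(ped)[perm, ])
  A_p <- build_nrm(ped_p)$values
  ids <- as.character(ped$id)
  expect_equal(A_p[ids, ids], A[ids, ids])

  ainv <- nrm_inverse(ped)$Ainv
  expect_lt(max(abs(as.matrix(ainv) %*% A - diag(nrow(ped)))), 1e-10)
})

test_that("NRM agrees with gene-dropping kinship on a random pedigree", {
  sim <- simulate_pedigree(ped_sim_config(n_families = 10,
                                          n_generations = 3,
                                          sibship_mean = 2, seed = 53))
  ped <- sim$pedigree
  n <- nrow(ped)
  A <- build_nrm(ped)$values
  ndrops <- 5000
  set.seed(54)
  ord <- attr(ped, "topo_order")
  f <- match(ped$father, ped$id)
  m <- match(ped$mother, ped$id)
  pat <- mat <- matrix(0L, n, ndrops)
  next_allele <- 1L
  for (i in ord) {
    if (is.na(f[i])) {
      pat[i, ] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- runif(ndrops) < 0.5
      pat[i, ] <- ifelse(pick, pat[f[i], ], mat[f[i], ])
    }
    if (is.na(m[i])) {
      mat[i, ] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- runif(ndrops) < 0.5
      mat[i, ] <- ifelse(pick, pat[m[i], ], mat[m[i], ])
    }
  }
  for (pair in list(c(1, 2), c(5, 9), c(10, 20), c(30, 31))) {
    i <- pair[1]; j <- pair[2]
    kin <- mean((pat[i, ] == pat[j, ]) + (pat[i, ] == mat[j, ]) +
                  (mat[i, ] == pat[j, ]) + (mat[i, ] == mat[j, ])) / 4
    se <- sd((pat[i, ] == pat[j, ]) + (pat[i, ] == mat[j, ]) +
               (mat[i, ] == pat[j, ]) + (mat[i, ] == mat[j, ])) /
      (4 * sqrt(ndrops))
    expect_lt(abs(kin - A[i, j] / 2), 3 * se + 1e-9)
  }
})

test_that("chain bookkeeping: length, bounds, determinism", {
  sim <- simulate_pedigree(ped_sim_config(n_families = 40,
                                          n_generations = 2,
                                          sibship_mean = 2, h2_liab = 0.4,
                                          prevalence_K = 0.2, seed = 55))
  cfg <- chain_config(3000, 500, 5, seed = 56)
  ch1 <- fit_threshold_animal_model(sim$pedigree, sim$phenotypes$status,
                                    cfg = cfg)
  expect_equal(nrow(ch1$samples), (3000 - 500) / 5)
  expect_true(all(ch1$samples$h2 >= 0 & ch1$samples$h2 <= 1))
  expect_true(all(ch1$samples$round > 500))
  ch2 <- fit_threshold_animal_model(sim$pedigree, sim$phenotypes$status,
                                    cfg = cfg)
  expect_identical(ch1$samples, ch2$samples)
  # invalid chain configs rejected
  expect_error(chain_config(100, 200, 5), class = "liabh2_invalid_config")
  expect_error(chain_config(100, 10, 5, prior_scale = 0),
               class = "liabh2_invalid_config")
})

test_that("with the likelihood disabled the chain reproduces the prior", {
  ped <- simulate_pedigree(ped_sim_config(n_families = 3,
                                          n_generations = 2,
                                          sibship_mean = 2,
                                          seed = 57))$pedigree
  cfg <- chain_config(120500, 500, 120, prior_df = 1, prior_scale = 1,
                      seed = 58)
  ch <- fit_threshold_animal_model(ped, rep(0L, nrow(ped)), cfg = cfg,
                                   sample_prior = TRUE)
  # scaled-inverse-chi-square(1, 1): P(sigma2 <= x) = P(chi2_1 >= 1/x)
  ks <- ks.test(ch$samples$sigma2_a,
                function(x) pchisq(1 / x, df = 1, lower.tail = FALSE))
  expect_gt(ks$p.value, 0.01)
})

test_that("Gibbs sampler recovers zero and moderate heritability", {
  # null: with enough affected individuals the data overwhelm the
  # heavy-tailed prior and posterior mass concentrates near zero
  sim0 <- simulate_pedigree(ped_sim_config(n_families = 800,
                                           n_generations = 2,
                                           sibship_mean = 3, h2_liab = 0,
                                           prevalence_K = 0.3, seed = 59))
  ch0 <- fit_threshold_animal_model(sim0$pedigree, sim0$phenotypes$status,
                                    cfg = chain_config(30000, 5000, 25,
                                                       seed = 60))
  expect_lt(ch0$summary$h2_mean, 0.1)

  # moderate h2 at modest scale: a single ~500-case dataset carries large
  # sampling variability, so recovery is judged on a 3-dataset average
  means <- vapply(c(61, 161, 261), function(s) {
    sim5 <- simulate_pedigree(ped_sim_config(n_families = 500,
                                             n_generations = 2,
                                             sibship_mean = 3,
                                             h2_liab = 0.5,
                                             prevalence_K = 0.2, seed = s))
    fit_threshold_animal_model(sim5$pedigree, sim5$phenotypes$status,
                               cfg = chain_config(60000, 10000, 50,
                                                  seed = s + 1)
    )$summary$h2_mean
  }, 0)
  expect_lt(abs(mean(means) - 0.5), 0.12)
})

test_that("fixed-effect design builder standardizes and encodes", {
  tab <- data.frame(age = c(30, 40, 50, 60), region = c("a", "b", "b", "c"),
                    status = c(0, 1, 0, 1))
  X0 <- fixed_effect_covariates(tab, character(0))
  expect_equal(ncol(X0), 1)
  X <- fixed_effect_covariates(tab, c("age", "region"))
  expect_equal(colnames(X), c("intercept", "age", "region_b", "region_c"))
  expect_equal(mean(X[, "age"]), 0, tolerance = 1e-12)
  expect_equal(sd(X[, "age"]), 1, tolerance = 1e-12)
  expect_error(fixed_effect_covariates(tab, "missing_col"),
               class = "liabh2_schema")
})

test_that("cohort split fits eras independently and reproducibly", {
  sim <- simulate_pedigree(ped_sim_config(n_families = 200,
                                          n_generations = 2,
                                          sibship_mean = 3, h2_liab = 0.4,
                                          prevalence_K = 0.2, seed = 63))
  era <- ifelse(sim$phenotypes$family <= 100, "historical", "recent")
  cfg <- chain_config(8000, 2000, 10, seed = 64)
  fits <- cohort_split_fit(sim$pedigree, sim$phenotypes$status, era, cfg)
  expect_named(fits, c("historical", "recent"))
  expect_true(attr(fits, "ci_overlap"))
  fits2 <- cohort_split_fit(sim$pedigree, sim$phenotypes$status, era, cfg)
  expect_identical(fits[[1]]$samples, fits2[[1]]$samples)
  expect_error(cohort_split_fit(sim$pedigree, sim$phenotypes$status,
                                rep("one", nrow(sim$pedigree)), cfg),
               class = "liabh2_invalid_input")
})
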
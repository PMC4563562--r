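# Shared fixture builders: small synthetic datasets built in code.

# quick unascertained case-control dataset with its GRM
make_cc_dataset <- function(n = 400, m = 300, h2 = 0.4, K = 0.2, seed = 1,
                            n_causal = max(1, min(100, m %/% 2)),
                            n_chromosomes = 2,
                            missing_rate = 0) {
  cfg <- geno_sim_config(n_snps = m, n_cases = 0, n_controls = n,
                         n_causal = n_causal, h2_liab = h2,
                         prevalence_K = K, missing_rate = missing_rate,
                         n_chromosomes = n_chromosomes, seed = seed)
  G <- simulate_genotypes(cfg, n)
  phe <- assign_liability_phenotypes(G, cfg)
  list(config = cfg, G = G, phe = phe)
}

# random symmetric GRM-like matrix for IO round trips
make_random_grm <- function(n = 10, seed = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(n * 50), n, 50)
  grm(tcrossprod(Z) / 50, sprintf("s%02d", seq_len(n)),
      matrix(50, n, n), "random")
}

# simulate genotypes of relative pairs by explicit allele transmission:
# returns list(dosage of pair members stacked, kin expectation)
sim_parent_offspring <- function(n_pairs, m, p, seed = 1) {
  set.seed(seed)
  # parent alleles
  pa1 <- matrix(rbinom(n_pairs * m, 1, rep(p, each = n_pairs)), n_pairs, m)
  pa2 <- matrix(rbinom(n_pairs * m, 1, rep(p, each = n_pairs)), n_pairs, m)
  # other parent
  qa1 <- matrix(rbinom(n_pairs * m, 1, rep(p, each = n_pairs)), n_pairs, m)
  # child: one allele from parent (random), one from other parent
  pick <- matrix(runif(n_pairs * m) < 0.5, n_pairs, m)
  child <- ifelse(pick, pa1, pa2) + qa1
  parent <- pa1 + pa2
  list(parent = parent, child = child)
}
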
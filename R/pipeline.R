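# End-to-end orchestration of the twin-track analysis on synthetic data:
# simulate -> QC -> GRM -> GREML (whole-set, per-chromosome, per-SNP) ->
# PCGC -> liability conversions -> pedigree Gibbs fit -> report, with every
# intermediate persisted and a manifest of seeds and file hashes.

#' Default pipeline configuration
#'
#' Analysis constants default to the registry/GWAS-scale study design
#' (lifetime risk 0.005, QC thresholds, chain 1,100,000 / 100,000 / 1,000);
#' problem sizes are meant to be overridden to desk scale via `overrides`.
#'
#' @param overrides named nested list merged over the defaults.
#' @return Nested configuration list.
#' @export
pipeline_config <- function(overrides = list()) {
  base <- list(
    seed = 1L,
    geno = list(n_snps = 283274L, n_cases = 922L, n_controls = 4842L,
                n_causal = 1000L, h2_liab = 0.374, prevalence_K = 0.005,
                maf_low = 0.05, maf_high = 0.5, missing_rate = 0.002,
                n_chromosomes = 22L),
    qc = list(maf_min = 0.01, callrate_min = 0.95,
              callrate_min_lowmaf = 0.99, hwe_p_min = 0.05,
              sample_callrate_min = 0.99, het_sd_limit = 3),
    ped = list(n_families = 7749L, n_generations = 5L, sibship_mean = 2.5,
               h2_liab = 0.489, prevalence_K = 0.005),
    chain = list(n_rounds = 1100000L, burn_in = 100000L, thin = 1000L,
                 prior_df = 1, prior_scale = 1),
    snp_attrib = list(n_snps = 5L),
    ascertained = FALSE)
  .merge_config(base, overrides)
}

.merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

.require_keys <- function(config, keys, where) {
  miss <- setdiff(keys, names(config))
  if (length(miss))
    .err(paste0("missing config key(s) in ", where, ": ",
                paste(miss, collapse = ", ")), "liabh2_schema")
}

#' Run the full synthetic twin-track analysis
#'
#' @param config nested configuration list (see [pipeline_config()]); may be
#'   a path to a YAML file.
#' @param out_dir output directory (created if needed).
#' @param seed overrides `config$seed` when given.
#' @return A run manifest (list): config snapshot, seeds, package version,
#'   per-stage output files with MD5 hashes, and headline estimates. Also
#'   written to `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- .merge_config(pipeline_config(), yaml::read_yaml(config))
  .require_keys(config, c("seed", "geno", "qc", "ped", "chain"), "top level")
  .require_keys(config$geno, c("n_snps", "n_cases", "n_controls", "h2_liab",
                               "prevalence_K"), "geno")
  .require_keys(config$ped, c("n_families", "h2_liab", "prevalence_K"),
                "ped")
  .require_keys(config$chain, c("n_rounds", "burn_in", "thin"), "chain")
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("liabh2")),
                   seed = config$seed, config = config, stages = list())
  files <- character(0)
  stage_done <- function(name, fs) {
    manifest$stages[[name]] <<- list(
      files = basename(fs),
      md5 = unname(tools::md5sum(fs)))
    files <<- c(files, fs)
  }
  # a stage failure still leaves the manifest of completed stages on disk
  on.exit(jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                               auto_unbox = TRUE, digits = NA))

  # --- simulate ------------------------------------------------------------
  gcfg <- do.call(geno_sim_config,
                  c(config$geno, list(seed = config$seed)))
  asc <- isTRUE(config$ascertained)
  if (asc) {
    sim <- ascertain_case_control(gcfg)
    G <- sim$genotypes; phe <- sim$phenotypes
  } else {
    G <- simulate_genotypes(gcfg)
    phe <- assign_liability_phenotypes(G, gcfg)
  }
  f_pheno <- file.path(out_dir, "phenotypes.tsv")
  write_phenotypes(phe, f_pheno)
  f_bed <- file.path(out_dir, "genotypes")
  write_plink_bed(G, f_bed, phe$status)
  stage_done("simulate_geno", c(f_pheno, paste0(f_bed, c(".bed", ".bim",
                                                         ".fam"))))

  # --- qc ------------------------------------------------------------------
  thr <- do.call(qc_thresholds, config$qc)
  snp_qc <- filter_snps(G, phe$status, thr)
  samp_qc <- filter_samples(snp_qc$genotypes, thr)
  Gq <- samp_qc$genotypes
  pheq <- phe[match(Gq$sample_ids, phe$sample_id), ]
  chi <- assoc_trend_test(Gq, pheq$status)
  lam <- inflation_lambda(chi, sum(pheq$status == 1), sum(pheq$status == 0))
  f_snplog <- file.path(out_dir, "qc_snp_log.tsv")
  write.table(snp_qc$log, f_snplog, sep = "\t", quote = FALSE,
              row.names = FALSE)
  f_samplog <- file.path(out_dir, "qc_sample_log.tsv")
  write.table(samp_qc$log, f_samplog, sep = "\t", quote = FALSE,
              row.names = FALSE)
  stage_done("qc", c(f_snplog, f_samplog))
  manifest$lambda <- lam

  # --- grm -----------------------------------------------------------------
  gall <- compute_grm(Gq)
  gchr <- per_chromosome_grms(Gq)
  f_grm <- file.path(out_dir, "grm_all")
  write_grm(gall, f_grm)
  stage_done("grm", paste0(f_grm, c(".grm.bin", ".grm.N.bin", ".grm.id")))

  # --- greml + liability ---------------------------------------------------
  y <- pheq$status
  K <- config$geno$prevalence_K
  Pfrac <- mean(y)
  ctx <- liability_context(K, Pfrac)
  fit_all <- fit_reml(y, gall)
  h2_liab <- obs_to_liability(min(1, max(0, fit_all$h2_obs_total)), ctx,
                              se = fit_all$se[1] / fit_all$vp)
  res <- list(h2_obs = fit_all$h2_obs_total,
              h2_liab = as.numeric(h2_liab),
              converged = fit_all$converged)
  joint <- NULL
  if (length(gchr) >= 2) {
    joint <- fit_joint_chromosomes(y, gchr, whole_set = gall)
    f_part <- file.path(out_dir, "per_chromosome")
    pt <- partition_table(joint$per_chromosome$chromosome,
                          pmax(joint$per_chromosome$h2_obs, 0),
                          joint$per_chromosome$se,
                          total = joint$total_whole,
                          total_source = "whole_set_fit")
    write_partition_table(pt, f_part)
    stage_done("greml_per_chromosome", paste0(f_part, c(".tsv", ".md")))
    res$h2_obs_per_chr_total <- joint$total_joint
  }
  if (!is.null(config$snp_attrib) && length(gchr) >= 2) {
    ns <- min(config$snp_attrib$n_snps, ncol(Gq$dosage))
    set.seed(config$seed + 10L)
    pick <- sort(sample.int(ncol(Gq$dosage), ns))
    attrib <- per_snp_variance(y, gchr,
                               Gq$dosage[, pick, drop = FALSE],
                               as.character(Gq$snps$chr[pick]),
                               base_fit = joint$joint)
    f_attrib <- file.path(out_dir, "per_snp_attribution.tsv")
    write.table(data.frame(snp = Gq$snps$id[pick], fraction = attrib),
                f_attrib, sep = "\t", quote = FALSE, row.names = FALSE)
    stage_done("per_snp", f_attrib)
  }

  # --- pcgc ----------------------------------------------------------------
  pc <- fit_pcgc(y, gall, K)
  res$h2_pcgc <- pc$h2_liab
  res$lambda_s <- sibling_rr(min(1, max(0, res$h2_liab)), liability_context(K))
  f_res <- file.path(out_dir, "genomic_track.json")
  jsonlite::write_json(res, f_res, auto_unbox = TRUE, digits = NA)
  stage_done("genomic_track", f_res)

  # --- pedigree track ------------------------------------------------------
  pcfg <- do.call(ped_sim_config, c(config$ped,
                                    list(seed = config$seed + 100L)))
  psim <- simulate_pedigree(pcfg)
  f_ped <- file.path(out_dir, "pedigree.tsv")
  write_pedigree(psim$pedigree, f_ped)
  ccfg <- do.call(chain_config, c(config$chain,
                                  list(seed = config$seed + 200L)))
  chain <- fit_threshold_animal_model(psim$pedigree, psim$phenotypes$status,
                                      cfg = ccfg)
  f_chain <- file.path(out_dir, "chain_samples.tsv")
  write.table(chain$samples, f_chain, sep = "\t", quote = FALSE,
              row.names = FALSE)
  f_chainsum <- file.path(out_dir, "pedigree_track.json")
  jsonlite::write_json(list(h2_mean = chain$summary$h2_mean,
                            h2_ci = chain$summary$h2_ci,
                            ess = chain$diagnostics$ess,
                            geweke_z = chain$diagnostics$geweke_z),
                       f_chainsum, auto_unbox = TRUE, digits = NA)
  f_fig <- file.path(out_dir, "chain_trace.png")
  plot_chain(chain, f_fig)
  stage_done("pedigree_track", c(f_ped, f_chain, f_chainsum))
  manifest$estimates <- list(
    genomic_h2_liab = res$h2_liab, pcgc_h2_liab = res$h2_pcgc,
    pedigree_h2 = chain$summary$h2_mean, sibling_rr = res$lambda_s,
    lambda = lam$lambda, lambda_1000 = lam$lambda_1000)

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
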
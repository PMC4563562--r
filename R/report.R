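# Assembly of result artifacts: variance-partition tables, the
# chromosome-length correlation, known-loci summaries, and simple trace /
# posterior-density figures for the pedigree chain.

#' GRCh37 autosome lengths in base pairs
#'
#' Named numeric vector for chromosomes 1-22 (GRCh37/hg19 assembly
#' lengths).
#' @export
grch37_chr_lengths <- c(
  `1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
  `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
  `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
  `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
  `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
  `21` = 48129895, `22` = 51304566)

#' Published per-chromosome variance fractions for testicular germ cell
#' tumour
#'
#' Reference table of the fraction of phenotypic variance explained by each
#' autosome (with standard errors) from the joint per-chromosome GREML
#' analysis of the TGCT case-control GWAS, used as input to the
#' chromosome-length correlation. The `total` attribute carries the printed
#' whole-autosome estimate (0.3736), which is the single whole-set fit, not
#' the sum of the per-chromosome entries.
#' @export
tgct_chromosome_partition <- local({
  df <- data.frame(
    chromosome = as.character(1:22),
    fraction = c(0.0422, 0.0232, 0.0506, 0.0313, 0.0017, 0.0248, 0.0178,
                 0.0095, 0.0200, 0.0124, 0.0192, 0.0339, 0.0058, 0.0117,
                 0.0150, 0.0083, 0.0188, 0.0143, 0.0050, 0.0342, 0.0033,
                 0.0000),
    se = c(0.0150, 0.0143, 0.0140, 0.0129, 0.0122, 0.0128, 0.0116, 0.0112,
           0.0115, 0.0118, 0.0111, 0.0119, 0.0095, 0.0093, 0.0091, 0.0097,
           0.0093, 0.0096, 0.0080, 0.0104, 0.0062, 0.0069),
    stringsAsFactors = FALSE)
  attr(df, "total") <- 0.3736
  attr(df, "total_se") <- 0.0500
  df
})

#' Published per-SNP variance fractions for the 19 TGCT risk loci
#'
#' Reference table of the 19 GWAS-identified risk SNPs with odds ratios and
#' the fraction of phenotypic variance attributed to each by the
#' covariate-difference procedure. The `total` attribute carries the printed
#' collective estimate (0.0921).
#' @export
tgct_risk_loci <- local({
  df <- data.frame(
    snp = c("rs2072499", "rs3790672", "rs10510452", "rs1510272",
            "rs17021463", "rs2720460", "rs4635969", "rs4624820",
            "rs3805663", "rs210138", "rs12699477", "rs7010162", "rs755383",
            "rs995030", "rs2900333", "rs8046148", "rs4888265", "rs9905704",
            "rs2839243"),
    odds_ratio = c(1.19, 1.20, 1.24, 1.16, 1.15, 1.24, 1.54, 1.37, 1.25,
                   1.50, 1.16, 1.22, 1.37, 2.55, 1.27, 1.32, 1.20, 1.21,
                   1.26),
    locus = c("1q22", "1q24.1", "3p24.3", "3q25", "4q22.2", "4q24", "5p15",
              "5q31", "5q31.1", "6p21", "7p22.3", "8q13.3", "9p24", "12q21",
              "12p13", "16q12.1", "16q22.3", "17q22", "21q22.3"),
    fraction = c(0.0030, 0.0013, 0.0029, 0.0048, 0.0035, 0.0046, 0.0001,
                 0.0017, 0.0001, 0.0108, 0.0049, 0.0012, 0.0144, 0.0177,
                 0.0028, 0.0044, 0.0013, 0.0095, 0.0033),
    se = c(0.0211, 0.0211, 0.0197, 0.0197, 0.0182, 0.0181, 0.0171, 0.0172,
           0.0172, 0.0178, 0.0162, 0.0157, 0.0159, 0.0163, 0.0167, 0.0136,
           0.0136, 0.0104, 0.0090),
    stringsAsFactors = FALSE)
  attr(df, "total") <- 0.0921
  attr(df, "total_se") <- 0.0735
  df
})

#' Build a variance-partition table from fits
#'
#' @param labels unit labels (chromosomes or SNP ids).
#' @param fractions variance fractions (>= 0).
#' @param se standard errors.
#' @param total total fraction; `total_source` records whether it is the sum
#'   of rows or a separate whole-set fit.
#' @param total_source `"sum"` or `"whole_set_fit"`.
#' @return data.frame of class `partition_table`.
#' @export
partition_table <- function(labels, fractions, se = NA_real_,
                            total = sum(fractions),
                            total_source = "sum") {
  if (any(fractions < 0)) .err("fractions must be >= 0",
                               "liabh2_invalid_input")
  df <- data.frame(label = as.character(labels), fraction = fractions,
                   se = se, stringsAsFactors = FALSE)
  attr(df, "total") <- total
  attr(df, "total_source") <- total_source
  class(df) <- c("partition_table", "data.frame")
  df
}

#' Correlation between per-chromosome heritability and chromosome length
#'
#' Pearson correlation of the variance fractions against physical
#' chromosome lengths, with a two-sided P-value from the t transform with
#' `n - 2` degrees of freedom.
#'
#' @param fractions per-chromosome variance fractions (or a
#'   [partition_table()] / the `tgct_chromosome_partition` constant).
#' @param lengths per-chromosome lengths, aligned; defaults to
#'   [grch37_chr_lengths] matched by label when `fractions` is a table.
#' @return A list with `r`, `p`, `n`.
#' @export
chromosome_length_correlation <- function(fractions,
                                          lengths = grch37_chr_lengths) {
  if (is.data.frame(fractions)) {
    lab <- if ("chromosome" %in% names(fractions)) fractions$chromosome
      else fractions$label
    lengths <- lengths[as.character(lab)]
    fractions <- fractions$fraction
  }
  if (length(fractions) != length(lengths) || anyNA(lengths))
    .err("need one length per table row", "liabh2_invalid_input")
  if (length(fractions) < 3)
    .err("need at least 3 rows", "liabh2_invalid_input")
  if (sd(fractions) == 0 || sd(lengths) == 0)
    .err("correlation undefined: zero variance", "liabh2_invalid_input")
  ct <- cor.test(fractions, lengths, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(fractions))
}

#' Summarize known risk loci against total heritability
#'
#' @param per_snp a [partition_table()] (or data.frame with a `fraction`
#'   column) of per-SNP variance fractions.
#' @param total_h2 total (observed- or liability-scale, as appropriate)
#'   heritability; must be positive.
#' @return A list: `sum_fraction` (collective variance of the loci) and
#'   `share_of_h2` (`sum_fraction / total_h2`).
#' @export
known_loci_summary <- function(per_snp, total_h2) {
  if (is.data.frame(per_snp)) per_snp <- per_snp$fraction
  if (!length(per_snp)) .err("empty table", "liabh2_invalid_input")
  if (total_h2 <= 0) .err("total_h2 must be positive",
                          "liabh2_invalid_input")
  s <- sum(per_snp)
  list(sum_fraction = s, share_of_h2 = s / total_h2)
}

#' Trace and posterior-density figure for a pedigree chain
#'
#' Writes a two-panel PNG: the thinned heritability trace and its posterior
#' density, mirroring the standard presentation of an animal-model fit.
#'
#' @param chain a `posterior_chain`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
plot_chain <- function(chain, path) {
  stopifnot(inherits(chain, "posterior_chain"))
  grDevices::png(path, width = 1000, height = 420)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(chain$samples$round, chain$samples$h2, type = "l",
                 xlab = "round", ylab = expression(h^2), main = "Trace")
  graphics::plot(stats::density(chain$samples$h2), main = "Posterior",
                 xlab = expression(h^2))
  graphics::abline(v = chain$summary$h2_mean, lty = 2)
  invisible(path)
}

#' Write a partition table as TSV and Markdown
#' @param table a [partition_table()].
#' @param prefix output path prefix (writes `<prefix>.tsv` and
#'   `<prefix>.md`).
#' @return `prefix`, invisibly.
#' @export
write_partition_table <- function(table, prefix) {
  write.table(as.data.frame(table), paste0(prefix, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  lines <- c("| unit | fraction | SE |", "|---|---|---|",
             sprintf("| %s | %.4f | %s |", table$label, table$fraction,
                     ifelse(is.na(table$se), "", sprintf("%.4f", table$se))),
             sprintf("| total (%s) | %.4f | |", attr(table, "total_source"),
                     attr(table, "total")))
  writeLines(lines, paste0(prefix, ".md"))
  invisible(prefix)
}
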
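# Sex-linkage screen: per-family Fisher's exact tests on genotype-by-sex
# tables, combined across families by Fisher's meta-analysis.

#' Combine p-values by Fisher's method
#'
#' @param p Vector of p-values.
#' @return A list with the statistic `X = -2 * sum(log(p))`, degrees of
#'   freedom `2 * length(p)`, and the combined p-value from the chi-squared
#'   distribution.
#' @export
fisher_meta <- function(p) {
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  X <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(statistic = X, df = df, p = stats::pchisq(X, df, lower.tail = FALSE))
}

#' Test SNPs for sex linkage
#'
#' For every SNP, builds the genotype-by-sex contingency table within each
#' G2 family, computes Fisher's exact test, and combines the per-family
#' p-values with Fisher's meta-analysis. A family with only one sex
#' genotyped (or fewer than two genotype classes) contributes p = 1.
#'
#' @param snps Long SNP tibble (`snp_id`, `id`, `call`).
#' @param pedigree Pedigree tibble with `id`, `sex`, `generation`,
#'   `family`; families are taken from the G2 generation.
#' @param mc_cell_bound Tables with more than this many counts use a
#'   Monte-Carlo Fisher test (with fixed internal replicates) instead of
#'   exhaustive enumeration.
#' @return A tibble: `snp_id`, `meta_p`, `statistic`, `df`, and a
#'   list-column `family_p` of per-family p-values.
#' @export
test_sex_linkage <- function(snps, pedigree, mc_cell_bound = 400) {
  g2 <- pedigree[pedigree$generation == "G2", ]
  fams <- sort(unique(g2$family))
  G <- snp_matrix(snps)
  ids <- rownames(G)
  fam_ids <- lapply(fams, function(f) intersect(g2$id[g2$family == f], ids))
  sex <- stats::setNames(pedigree$sex, pedigree$id)

  res <- purrr::map(colnames(G), function(s) {
    ps <- vapply(fam_ids, function(fi) {
      g <- G[fi, s]
      sx <- sex[fi]
      ok <- !is.na(g)
      g <- g[ok]; sx <- sx[ok]
      if (length(unique(sx)) < 2 || length(unique(g)) < 2) return(1)
      tab <- table(factor(g, levels = 1:3), sx)
      tab <- tab[rowSums(tab) > 0, , drop = FALSE]
      if (sum(tab) > mc_cell_bound) {
        stats::fisher.test(tab, simulate.p.value = TRUE, B = 2000)$p.value
      } else {
        stats::fisher.test(tab)$p.value
      }
    }, numeric(1))
    fm <- fisher_meta(ps)
    tibble::tibble(snp_id = s, meta_p = fm$p, statistic = fm$statistic,
                   df = fm$df, family_p = list(stats::setNames(ps, fams)))
  })
  dplyr::bind_rows(res)
}
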
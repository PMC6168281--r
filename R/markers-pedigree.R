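# Pedigree-error screening: G2 individuals whose genotypes are
# incompatible with their recorded F1 mother but compatible with another,
# and individuals incompatible with every candidate mother.

#' Screen G2 individuals for pedigree errors
#'
#' For every G2 individual and every candidate F1 mother, counts genotype
#' calls that are Mendelian-impossible given the imputed (mother, father)
#' genotype pair of that family, restricted to SNPs that are informative
#' for the family (some genotype class has zero expected frequency).
#' Individuals whose recorded mother exceeds `mother_threshold`
#' incompatibility while some other mother does not are flagged with that
#' reassignment hypothesis; individuals above `all_threshold` under every
#' mother are flagged as globally incompatible.
#'
#' @param snps Long SNP tibble after QC.
#' @param segregation A `segregation` object from [infer_segregation()].
#' @param pedigree Pedigree tibble.
#' @param mother_threshold Incompatibility rate above which the recorded
#'   mother is rejected (default 0.05).
#' @param all_threshold Rate above which an individual is incompatible
#'   with all mothers (default 0.10: uniform-random calls produce roughly
#'   10-15% impossible genotypes at informative sites, while one-step
#'   genotyping error at realistic rates stays below about 2%).
#' @param min_informative Minimum informative calls required to score a
#'   candidate mother.
#' @return A tibble, one row per G2: `id`, `family`, `rate_recorded`,
#'   `best_family`, `rate_best`, `flag` in
#'   `c("ok", "reassign", "all_incompatible")`.
#' @export
screen_pedigree <- function(snps, segregation, pedigree,
                            mother_threshold = 0.05, all_threshold = 0.10,
                            min_informative = 20) {
  G <- snp_matrix(snps)
  g2 <- pedigree[pedigree$generation == "G2", ]
  g2 <- g2[g2$id %in% rownames(G), ]
  fams <- sort(unique(g2$family))
  famtab <- segregation$families

  # zero-probability genotype classes per SNP per candidate family
  snp_ids <- colnames(G)
  impossible <- list()
  for (f in fams) {
    ft <- famtab[famtab$family == f, ]
    ft <- ft[match(snp_ids, ft$snp_id), ]
    gm <- geno_to_code(ft$f1_mother)
    gf <- geno_to_code(ft$f1_father)
    imp <- matrix(FALSE, length(snp_ids), 3)
    okrow <- !is.na(gm) & !is.na(gf)
    tv <- t(mapply(.transmission, gm[okrow], gf[okrow]))
    imp[okrow, ] <- tv == 0
    impossible[[f]] <- imp
  }

  Gg2 <- G[g2$id, , drop = FALSE]
  rates <- matrix(NA_real_, nrow(g2), length(fams),
                  dimnames = list(g2$id, fams))
  for (f in fams) {
    imp <- impossible[[f]]
    informative <- rowSums(imp) > 0
    sub <- Gg2[, informative, drop = FALSE]
    impsub <- imp[informative, , drop = FALSE]
    # incompatible call: observed class has zero expected frequency
    bad <- matrix(FALSE, nrow(sub), ncol(sub))
    for (cls in 1:3) {
      bad[, impsub[, cls]] <- bad[, impsub[, cls]] |
        (sub[, impsub[, cls], drop = FALSE] == cls)
    }
    bad[is.na(sub)] <- FALSE
    n_inf <- rowSums(!is.na(sub))
    r <- rowSums(bad) / pmax(n_inf, 1)
    r[n_inf < min_informative] <- NA
    rates[, f] <- r
  }

  rate_recorded <- rates[cbind(seq_len(nrow(g2)), match(g2$family, fams))]
  best_idx <- apply(rates, 1, function(r) {
    if (all(is.na(r))) NA_integer_ else which.min(r)
  })
  best_family <- fams[best_idx]
  rate_best <- rates[cbind(seq_len(nrow(g2)), best_idx)]

  flag <- rep("ok", nrow(g2))
  all_bad <- apply(rates, 1, function(r) all(is.na(r)) ||
                     all(r > all_threshold, na.rm = TRUE))
  reassign <- !all_bad & !is.na(rate_recorded) &
    rate_recorded > mother_threshold &
    !is.na(rate_best) & rate_best <= mother_threshold &
    best_family != g2$family
  flag[reassign] <- "reassign"
  flag[all_bad] <- "all_incompatible"

  tibble::tibble(
    id = g2$id, family = g2$family,
    rate_recorded = rate_recorded,
    best_family = best_family, rate_best = rate_best,
    flag = flag
  )
}
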
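# Backcross of G2 males to planktotrophic dams: shifts the maternal
# background while the chaetae loci keep segregating from the sire.

#' Simulate a G2-male backcross to planktotrophic females
#'
#' Each selected G2 male is mated to a distinct simulated planktotroph dam
#' (all P alleles). Offspring inherit one allele from the sire (with
#' recombination between linked loci) and a P allele from the dam, so
#' genotypes at each chaetae locus are PP or PL. Chaetae phenotypes follow
#' the zygotic models of the cross configuration plus a brood-level random
#' intercept.
#'
#' @param cross A `true_cross` from [simulate_cross()].
#' @param n_males Number of G2 sires (must not exceed available G2 males).
#' @param offspring_per_family Offspring measured per brood.
#' @param brood_sd_frac Brood random-intercept SD as a fraction of each
#'   trait's residual SD.
#' @param traits Traits to generate (zygotic chaetae traits).
#' @param seed RNG seed.
#' @return A list of class `backcross_sim` with `offspring` (tibble: brood,
#'   sire_id, per-locus L dosage, trait values), `sires` (tibble of sire
#'   genotypes at the trait loci, as L-allele dosage 0/1/2) and `loci`.
#' @export
simulate_backcross <- function(cross, n_males = 30, offspring_per_family = 45,
                               brood_sd_frac = 0.5,
                               traits = c("chaetae_count", "chaetae_length"),
                               seed = 1L) {
  stopifnot(inherits(cross, "true_cross"))
  set.seed(seed)
  ped <- cross$pedigree
  males <- ped$id[ped$generation == "G2" & ped$sex == "M"]
  if (n_males > length(males)) {
    stop("n_males exceeds the ", length(males), " available G2 males")
  }
  sires <- sample(males, n_males)

  qtl <- cross$qtl_truth$qtl_spec
  qtl <- qtl[qtl$trait %in% traits, ]
  loci <- unique(qtl[, c("chrom", "pos")])
  loci$locus <- sprintf("LG%d_%.1fcM", loci$chrom, loci$pos)

  # sire haplotype origins at each locus (from the truth arrays)
  sire_hap <- array(0L, c(n_males, nrow(loci), 2))
  for (j in seq_len(nrow(loci))) {
    ch <- as.character(loci$chrom[j])
    gi <- match(loci$pos[j], cross$grids[[ch]])
    for (s in 1:2) {
      sire_hap[, j, s] <- cross$hap[[ch]][sires, gi, s]
    }
  }

  n_off <- n_males * offspring_per_family
  brood <- rep(seq_len(n_males), each = offspring_per_family)
  # transmit sire strand per offspring with recombination between loci
  # that share a chromosome (Haldane), independent across chromosomes
  dosage <- matrix(0L, n_off, nrow(loci),
                   dimnames = list(NULL, loci$locus))
  for (ch in unique(loci$chrom)) {
    jj <- which(loci$chrom == ch)
    jj <- jj[order(loci$pos[jj])]
    strand <- stats::rbinom(n_off, 1, 0.5)
    for (k in seq_along(jj)) {
      if (k > 1) {
        r <- haldane_r(loci$pos[jj[k]] - loci$pos[jj[k - 1]])
        strand <- bitwXor(strand, stats::rbinom(n_off, 1, r))
      }
      hap_pick <- ifelse(strand == 0, sire_hap[brood, jj[k], 1],
                         sire_hap[brood, jj[k], 2])
      dosage[, jj[k]] <- as.integer(hap_pick >= 3L) # L allele from sire?
    }
  }

  sire_of_brood <- sires[brood]
  off <- tibble::tibble(
    brood = sprintf("brood%02d", brood),
    sire_id = sire_of_brood
  )
  for (j in seq_len(nrow(loci))) off[[loci$locus[j]]] <- dosage[, j]

  tm <- cross$config$trait_models
  for (trait in traits) {
    m <- tm[[trait]]
    eff <- qtl[qtl$trait == trait, ]
    lp <- rep(m$intercept, n_off)
    for (e in seq_len(nrow(eff))) {
      lj <- match(sprintf("LG%d_%.1fcM", eff$chrom[e], eff$pos[e]), loci$locus)
      a <- dosage[, lj] - 1L        # dam contributes P: dosage in {0,1}
      d <- as.integer(dosage[, lj] == 1L)
      lp <- lp + a * eff$add[e] + d * eff$dom[e]
    }
    bint <- stats::rnorm(n_males, 0, brood_sd_frac * m$residual_sd)
    y <- lp + bint[brood] + stats::rnorm(n_off, 0, m$residual_sd)
    if (m$type == "count") y <- pmax(0, round(y))
    off[[paste0(trait, "_expected")]] <- lp
    off[[trait]] <- y
  }

  sire_tbl <- tibble::tibble(sire_id = sires)
  for (j in seq_len(nrow(loci))) {
    sire_tbl[[loci$locus[j]]] <-
      as.integer(sire_hap[, j, 1] >= 3L) + as.integer(sire_hap[, j, 2] >= 3L)
  }

  structure(list(offspring = off, sires = sire_tbl, loci = loci),
            class = "backcross_sim")
}
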
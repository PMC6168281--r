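# Founder-of-origin assignment: orient each chromosome's two inferred P0
# genotypes to the planktotroph and lecithotroph source populations using
# pooled population allele frequencies, then polarize the map so that
# "L" alleles always derive from the lecithotroph founder.

#' Estimate population allele frequencies from pooled read counts
#'
#' Replicate libraries of the same population are summed, one read is
#' added to every allele count to keep estimates off the boundary, and
#' the resulting proportions are used as population frequency estimates:
#' `p_ref = (n_ref + 1) / (n_ref + n_alt + 2)`.
#'
#' @param counts Tibble with `snp_id`, `population`, `replicate`,
#'   `ref_count`, `alt_count` (as written by [simulate_poolseq()] or read
#'   from an allele-count TSV).
#' @return A tibble: `snp_id`, `population`, `n_ref`, `n_alt`, `p_ref`.
#' @export
pool_allele_freqs <- function(counts) {
  counts |>
    dplyr::group_by(.data$snp_id, .data$population) |>
    dplyr::summarise(
      n_ref = sum(.data$ref_count), n_alt = sum(.data$alt_count),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      p_ref = (.data$n_ref + 1) / (.data$n_ref + .data$n_alt + 2)
    )
}

#' Assign founder origin to each chromosome's inferred P0 genotypes
#'
#' For every linkage group, compares the two labellings of the inferred
#' homozygous-alternate founder genotypes against the population allele
#' frequencies under Hardy-Weinberg equilibrium. Hypothesis H1 assigns
#' founder genotype 1 (the marker "P" side) to `pop1` and genotype 2 to
#' `pop2`; H2 is the mirror. The statistic is
#' `log10 L(H1) - log10 L(H2)`, summed over the chromosome's informative
#' SNPs, each contributing `2*log10 p_hat` per homozygous genotype.
#'
#' @param founder_snps Tibble with `group` (linkage group), `snp_id`,
#'   `allele1`, `allele2` (1 = reference/A, 2 = alternative/B): the
#'   alleles carried by founder genotype 1 and 2 at SNPs inferred
#'   homozygous for alternate alleles.
#' @param freqs Output of [pool_allele_freqs()].
#' @param pop1,pop2 Population labels in `freqs` to test as the origin of
#'   founder genotype 1 and 2 under H1.
#' @return A tibble of class `founder_assignment`: `group`, `log10_lr`
#'   (positive favors H1), `orientation` (`"H1"`/`"H2"`/`"undetermined"`),
#'   `n_snps`, and a list-column `per_snp` of per-SNP contributions.
#' @export
assign_founders <- function(founder_snps, freqs, pop1 = "pop_P",
                            pop2 = "pop_L") {
  f1 <- freqs[freqs$population == pop1, ]
  f2 <- freqs[freqs$population == pop2, ]
  fs <- founder_snps |>
    dplyr::mutate(
      p1_ref = f1$p_ref[match(.data$snp_id, f1$snp_id)],
      p2_ref = f2$p_ref[match(.data$snp_id, f2$snp_id)]
    ) |>
    dplyr::filter(!is.na(.data$p1_ref), !is.na(.data$p2_ref))
  pop_p <- function(p_ref, allele) ifelse(allele == 1L, p_ref, 1 - p_ref)
  fs <- fs |>
    dplyr::mutate(
      # H1: genotype1 drawn from pop1, genotype2 from pop2 (HWE: p^2)
      log10_lr_snp =
        2 * log10(pop_p(.data$p1_ref, .data$allele1)) +
        2 * log10(pop_p(.data$p2_ref, .data$allele2)) -
        2 * log10(pop_p(.data$p1_ref, .data$allele2)) -
        2 * log10(pop_p(.data$p2_ref, .data$allele1))
    )
  out <- fs |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      log10_lr = sum(.data$log10_lr_snp),
      n_snps = dplyr::n(),
      per_snp = list(stats::setNames(
        dplyr::pick("snp_id", "log10_lr_snp"),
        c("snp_id", "log10_lr")
      )),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      orientation = dplyr::case_when(
        .data$n_snps == 0 | .data$log10_lr == 0 ~ "undetermined",
        .data$log10_lr > 0 ~ "H1",
        TRUE ~ "H2"
      )
    ) |>
    dplyr::select("group", "orientation", "log10_lr", "n_snps", "per_snp")
  class(out) <- c("founder_assignment", class(out))
  out
}

#' Polarize a genetic map to founder origin
#'
#' Relabels marker genotypes chromosome by chromosome so that the "L"
#' allele (code 3 homozygote) consistently derives from the lecithotroph
#' founder: groups assigned orientation H2 have their genotype codes
#' flipped (PP <-> LL, not-PP <-> not-LL). Undetermined groups are left
#' as coded but flagged.
#'
#' @param map A `genetic_map` from [build_linkage_map()].
#' @param assignment A `founder_assignment` from [assign_founders()].
#' @return The map with polarized `geno`, a `polarity` tibble recording
#'   the flip applied per group, and flagged undetermined groups.
#' @export
polarize_map <- function(map, assignment) {
  stopifnot(inherits(map, "genetic_map"))
  pol <- tibble::tibble(
    group = assignment$group,
    orientation = assignment$orientation,
    flip = assignment$orientation == "H2"
  )
  geno <- map$geno
  for (g in pol$group[pol$flip]) {
    mk <- map$map$marker[map$map$group == g]
    geno[, mk] <- FLIP_CODES[geno[, mk]]
  }
  map$geno <- geno
  map$polarity <- pol
  map
}
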
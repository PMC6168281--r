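# Pool-seq read counts from two weakly diverged source populations, used
# to test founder-of-origin assignment.

#' Simulate pooled-population allele read counts
#'
#' For each intercross SNP (founders homozygous for alternate alleles), the
#' allele carried by the planktotroph founder is given frequency
#' `0.5 + divergence/2` in its own source population and `0.5 -
#' divergence/2` in the other. Each population pool resamples `pool_size`
#' diploid females from those frequencies; sequencing replicates then draw
#' reads binomially from the pool's allele proportion at Poisson depth.
#'
#' @param cross A `true_cross`, or a tibble with columns `snp_id`, `chrom`,
#'   `pos`, `p_allele`, `l_allele` (alleles 1 = A, 2 = B).
#' @param divergence Expected allele-frequency difference between the two
#'   populations (|dp|).
#' @param pool_size Number of diploid females per pool.
#' @param depth Mean sequencing depth per SNP per replicate (> 0).
#' @param n_replicates Number of library replicates per population.
#' @param seed RNG seed.
#' @return A tibble of class `pool_counts`: `snp_id`, `population`
#'   (`pop_P`, `pop_L`), `replicate`, `ref_count`, `alt_count` (reference
#'   allele = allele A), plus the true population frequencies as
#'   attributes.
#' @export
simulate_poolseq <- function(cross, divergence = 0.2, pool_size = 25,
                             depth = 20, n_replicates = 2, seed = 1L) {
  if (depth <= 0) stop("depth must be positive")
  set.seed(seed)
  snps <- if (inherits(cross, "true_cross")) {
    sm <- cross$snp_map[cross$snp_map$config == "AAxBB" &
                          cross$snp_map$chrom != "X", ]
    # hap1/hap2 = one founder, hap3/hap4 = other; P founder is haps 1,2
    tibble::tibble(snp_id = sm$snp_id, chrom = sm$chrom, pos = sm$pos,
                   p_allele = sm$hap1, l_allele = sm$hap3)
  } else tibble::as_tibble(cross)
  n <- nrow(snps)
  # frequency of the P-founder allele in each population
  fP <- pmin(pmax(0.5 + divergence / 2, 0), 1)
  fL <- pmin(pmax(0.5 - divergence / 2, 0), 1)
  freq <- cbind(pop_P = rep(fP, n), pop_L = rep(fL, n))
  # fixed differences when divergence = 1
  out <- vector("list", 2L * n_replicates)
  k <- 0
  pool_freq <- matrix(0, n, 2, dimnames = list(snps$snp_id,
                                               c("pop_P", "pop_L")))
  for (pop in c("pop_P", "pop_L")) {
    # one pool of 2*pool_size chromosomes per population, shared by its
    # library replicates
    ppool <- stats::rbinom(n, 2 * pool_size, freq[, pop]) / (2 * pool_size)
    pool_freq[, pop] <- ppool
    for (rep_i in seq_len(n_replicates)) {
      dp <- stats::rpois(n, depth)
      # reads carrying the P-founder allele
      p_reads <- stats::rbinom(n, dp, ppool)
      # express as reference (allele A) vs alternative (allele B) counts
      ref <- ifelse(snps$p_allele == 1L, p_reads, dp - p_reads)
      k <- k + 1
      out[[k]] <- tibble::tibble(
        snp_id = snps$snp_id, population = pop, replicate = rep_i,
        ref_count = as.integer(ref), alt_count = as.integer(dp - ref)
      )
    }
  }
  res <- dplyr::arrange(dplyr::bind_rows(out), .data$snp_id,
                        .data$population, .data$replicate)
  attr(res, "snps") <- snps
  attr(res, "pool_freq") <- pool_freq
  class(res) <- c("pool_counts", class(res))
  res
}
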
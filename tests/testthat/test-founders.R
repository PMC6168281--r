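# Founder-of-origin assignment from pooled allele frequencies.

test_that("pool frequency estimates follow the pseudocount formula", {
  counts <- tibble::tibble(
    snp_id = c("s1", "s1", "s2", "s3"),
    population = "pop_P",
    replicate = c(1L, 2L, 1L, 1L),
    ref_count = c(0L, 0L, 19L, 10L),
    alt_count = c(0L, 0L, 0L, 10L)
  )
  f <- pool_allele_freqs(counts)
  expect_equal(f$p_ref[f$snp_id == "s1"], 0.5) # (0+1)/(0+2)
  expect_equal(f$p_ref[f$snp_id == "s2"], 20 / 21)
  expect_equal(f$p_ref[f$snp_id == "s3"], 11 / 22)
  # replicates are summed before the pseudocount
  counts2 <- dplyr::mutate(counts, ref_count = c(5L, 4L, 19L, 10L),
                           alt_count = c(1L, 0L, 0L, 10L))
  f2 <- pool_allele_freqs(counts2)
  expect_equal(f2$p_ref[f2$snp_id == "s1"], 10 / 12)
})

make_freqs <- function(p1_ref, p2_ref, snp_id = "s1") {
  tibble::tibble(
    snp_id = rep(snp_id, 2),
    population = c("pop_P", "pop_L"),
    n_ref = NA_integer_, n_alt = NA_integer_,
    p_ref = c(p1_ref, p2_ref)
  )
}

test_that("the single-SNP likelihood ratio matches its closed form", {
  # population 1 has the A allele at 0.9; population 2 has B at 0.9;
  # founder genotype 1 = AA, genotype 2 = BB
  fs <- tibble::tibble(group = 1L, snp_id = "s1",
                       allele1 = 1L, allele2 = 2L)
  asg <- assign_founders(fs, make_freqs(0.9, 0.1))
  expect_equal(asg$log10_lr, 4 * log10(9), tolerance = 1e-9)
  expect_equal(asg$orientation, "H1")
  # antisymmetry: swapping the founder genotypes flips the sign exactly
  fs_swap <- dplyr::mutate(fs, allele1 = 2L, allele2 = 1L)
  asg_swap <- assign_founders(fs_swap, make_freqs(0.9, 0.1))
  expect_equal(asg_swap$log10_lr, -asg$log10_lr, tolerance = 1e-12)
  # identical frequencies in both populations: exactly zero
  asg0 <- assign_founders(fs, make_freqs(0.7, 0.7))
  expect_equal(asg0$log10_lr, 0)
  expect_equal(asg0$orientation, "undetermined")
})

test_that("per-SNP factors stay in (0,1), keeping the statistic finite", {
  fs <- tibble::tibble(group = 1L, snp_id = "s1",
                       allele1 = 1L, allele2 = 2L)
  # extreme counts still give finite LR thanks to the pseudocount
  counts <- tibble::tibble(
    snp_id = "s1", population = c("pop_P", "pop_L"),
    replicate = 1L, ref_count = c(1000L, 0L), alt_count = c(0L, 1000L)
  )
  asg <- assign_founders(fs, pool_allele_freqs(counts))
  expect_true(is.finite(asg$log10_lr))
})

test_that("LR magnitude grows with the number of informative SNPs", {
  set.seed(13)
  lr_of <- function(n_snps) {
    mean(vapply(1:30, function(i) {
      fs <- tibble::tibble(group = 1L,
                           snp_id = sprintf("s%02d", 1:n_snps),
                           allele1 = 1L, allele2 = 2L)
      pc <- simulate_poolseq(
        tibble::tibble(snp_id = fs$snp_id, chrom = "1", pos = 1,
                       p_allele = 1L, l_allele = 2L),
        divergence = 0.2, depth = 20, seed = 1000 * n_snps + i
      )
      abs(assign_founders(fs, pool_allele_freqs(pc))$log10_lr)
    }, numeric(1)))
  }
  lrs <- vapply(c(4, 12, 27), lr_of, numeric(1))
  expect_true(all(diff(lrs) > 0))
})

test_that("polarization is idempotent, local, and fixes effect signs", {
  cr <- shared_cross()
  tr <- true_intercross_genotypes(cr)
  # construct a map whose groups are the true chromosomes
  gm <- structure(list(
    map = tibble::tibble(marker = tr$map$marker,
                         group = as.integer(tr$map$chrom),
                         pos = tr$map$pos),
    geno = tr$geno, flipped = NULL, error_rate = 0
  ), class = "genetic_map")
  asg <- tibble::tibble(
    group = 1:10,
    orientation = rep(c("H1", "H2"), 5),
    log10_lr = rep(c(5, -5), 5), n_snps = 10
  )
  p1 <- polarize_map(gm, asg)
  p2 <- polarize_map(p1, dplyr::mutate(asg, orientation = "H1"))
  expect_identical(p1$geno, p2$geno) # reapplying H1 changes nothing
  # only H2 groups flipped
  for (g in 1:10) {
    mk <- gm$map$marker[gm$map$group == g]
    if (asg$orientation[g] == "H2") {
      expect_true(all(p1$geno[, mk] == 4L - gm$geno[, mk], na.rm = TRUE))
    } else {
      expect_identical(p1$geno[, mk], gm$geno[, mk])
    }
  }
  # flipping one group's assignment flips only that group
  asg2 <- asg
  asg2$orientation[3] <- "H2"
  p3 <- polarize_map(gm, asg2)
  mk3 <- gm$map$marker[gm$map$group == 3]
  expect_true(all(p3$geno[, mk3] == 4L - p1$geno[, mk3], na.rm = TRUE))
  other <- gm$map$marker[gm$map$group != 3]
  expect_identical(p3$geno[, other], p1$geno[, other])
})
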
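# Backcross and pool-seq simulators.

test_that("backcross offspring genotypes segregate from the sire", {
  cr <- shared_cross()
  bc <- simulate_backcross(cr, n_males = 30, offspring_per_family = 45,
                           seed = 3)
  expect_equal(nrow(bc$offspring), 30 * 45)
  expect_equal(nrow(bc$sires), 30)
  loci <- bc$loci$locus
  off <- dplyr::left_join(bc$offspring, bc$sires, by = "sire_id",
                          suffix = c("", "_sire"))
  for (l in loci) {
    dos <- off[[l]]
    sire <- off[[paste0(l, "_sire")]]
    # dam contributes P: offspring dosage is 0 or 1 only
    expect_true(all(dos %in% 0:1))
    # homozygous sires transmit deterministically
    expect_true(all(dos[sire == 0] == 0))
    expect_true(all(dos[sire == 2] == 1))
    # heterozygous sires transmit about half L
    het <- dos[sire == 1]
    if (length(het) > 100) expect_lt(abs(mean(het) - 0.5), 0.1)
  }
})

test_that("heterozygous-sire broods are mixtures separated by the
           additive effect", {
  cr <- shared_cross()
  bc <- simulate_backcross(cr, n_males = 30, offspring_per_family = 60,
                           seed = 4)
  l3 <- "LG3_2.5cM" # the chaetae-number locus on LG3
  l8 <- "LG8_1.7cM"
  off <- dplyr::left_join(bc$offspring, bc$sires, by = "sire_id",
                          suffix = c("", "_sire"))
  het <- off[off[[paste0(l3, "_sire")]] == 1 & off[[paste0(l8, "_sire")]] != 1, ]
  # the expected value is exactly linear in the two backcross dosages,
  # with slope additive + dominance (PL vs PP coding) at each locus
  co <- coef(lm(off$chaetae_count_expected ~ off[[l3]] + off[[l8]]))
  expect_equal(unname(co[2]), -2.53 - 0.58, tolerance = 1e-9)
  expect_equal(unname(co[3]), -2.30 + 0.31, tolerance = 1e-9)
  gap <- -2.53 - 0.58
  # realized counts show the same separation up to noise
  gap_obs <- mean(het$chaetae_count[het[[l3]] == 1]) -
    mean(het$chaetae_count[het[[l3]] == 0])
  expect_lt(abs(gap_obs - gap), 1.5)
  # and within-brood variance in het-sire broods exceeds that of
  # fully homozygous-sire broods (segregating mixture)
  hom <- off[off[[paste0(l3, "_sire")]] != 1 &
               off[[paste0(l8, "_sire")]] != 1, ]
  v_het <- mean(tapply(het$chaetae_count, het$brood, var), na.rm = TRUE)
  v_hom <- mean(tapply(hom$chaetae_count, hom$brood, var), na.rm = TRUE)
  expect_gt(v_het, v_hom)
})

test_that("backcross rejects more sires than available", {
  cr <- shared_cross()
  n_males <- sum(cr$pedigree$generation == "G2" & cr$pedigree$sex == "M")
  expect_error(simulate_backcross(cr, n_males = n_males + 1), "exceeds")
})

test_that("pool-seq counts have the promised structure", {
  cr <- shared_cross()
  pc <- simulate_poolseq(cr, divergence = 0.2, depth = 20, seed = 5)
  expect_true(all(pc$ref_count >= 0 & pc$alt_count >= 0))
  # replicates share SNP keys
  keys <- split(pc$snp_id, paste(pc$population, pc$replicate))
  expect_true(all(vapply(keys, function(k) identical(sort(k),
                                                     sort(keys[[1]])),
                         logical(1))))
  # mean depth near the Poisson mean
  expect_lt(abs(mean(pc$ref_count + pc$alt_count) - 20), 1)
  expect_error(simulate_poolseq(cr, depth = 0), "depth")
})

test_that("a fixed difference yields population-diagnostic counts", {
  cr <- shared_cross()
  pc <- simulate_poolseq(cr, divergence = 1, depth = 20, seed = 6)
  snps <- attr(pc, "snps")
  agg <- pool_allele_freqs(pc)
  # the P population pool is fixed for the P founder allele
  pP <- agg[agg$population == "pop_P", ]
  pL <- agg[agg$population == "pop_L", ]
  pa <- snps$p_allele[match(pP$snp_id, snps$snp_id)]
  fP <- ifelse(pa == 1, pP$p_ref, 1 - pP$p_ref)
  fL <- ifelse(snps$p_allele[match(pL$snp_id, snps$snp_id)] == 1,
               pL$p_ref, 1 - pL$p_ref)
  expect_gt(min(fP), 0.9) # all reads carry the P allele (plus pseudocount)
  expect_lt(max(fL), 0.1)
})

test_that("zero divergence leaves founder assignment uninformative on
           average", {
  set.seed(11)
  snps <- tibble::tibble(
    snp_id = sprintf("s%03d", 1:200),
    chrom = rep(as.character(1:10), each = 20), pos = runif(200, 0, 50),
    p_allele = sample(1:2, 200, TRUE)
  )
  snps$l_allele <- 3L - snps$p_allele
  pc <- simulate_poolseq(snps, divergence = 0, depth = 20, seed = 12)
  freqs <- pool_allele_freqs(pc)
  fs <- tibble::tibble(group = as.integer(snps$chrom),
                       snp_id = snps$snp_id,
                       allele1 = snps$p_allele, allele2 = snps$l_allele)
  asg <- assign_founders(fs, freqs)
  # symmetric model: mean per-chromosome statistic is near zero
  expect_lt(abs(mean(asg$log10_lr)), 2)
  expect_lt(mean(abs(asg$log10_lr)), 6)
})
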
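# Family-structured scans, permutation thresholds, and multi-QTL fits.

test_that("a constant phenotype gives zero LOD everywhere", {
  sp <- shared_probs()
  ph <- sp$cross$phenotypes
  ph$flat <- 1.0
  sc <- scan_structured(ph, sp$probs, "flat")
  expect_true(all(abs(sc$scan$lod) < 1e-8))
})

test_that("Haley-Knott at a fully observed marker equals the exact
           genotype regression", {
  sp <- shared_probs()
  cr <- sp$cross
  ph <- cr$phenotypes
  probs0 <- genotype_probs(sp$geno, sp$map, step_cM = 1e6, error_prob = 0)
  sc <- scan_structured(ph, probs0, "chaetae_count")
  # direct per-family regression oracle at a handful of markers
  for (mk in sp$map$marker[c(3, 40, 90)]) {
    g <- as.character(sp$map$group[sp$map$marker == mk])
    pos <- sp$map$pos[sp$map$marker == mk]
    k <- which(sc$scan$group == g & abs(sc$scan$pos - pos) < 1e-9)
    lod_direct <- 0
    for (f in unique(ph$family)) {
      ids <- ph$id[ph$family == f & !is.na(ph$chaetae_count)]
      y <- ph$chaetae_count[match(ids, ph$id)]
      gg <- sp$geno[ids, mk]
      a <- gg - 2; d <- as.integer(gg == 2)
      rss1 <- sum(residuals(lm(y ~ a + d))^2)
      rss0 <- sum((y - mean(y))^2)
      lod_direct <- lod_direct + length(y) / 2 * log10(rss0 / rss1)
    }
    expect_equal(sc$scan$lod[k], lod_direct, tolerance = 1e-8)
  }
})

test_that("scans recover the generating chaetae architecture", {
  sp <- shared_probs()
  sc <- scan_structured(sp$cross$phenotypes, sp$probs, "chaetae_count",
                        n_perm = 100, seed = 9)
  pk <- scan_peaks(sc)
  expect_setequal(pk$group[order(-pk$lod)][1:2], c("3", "8"))
  expect_true(all(pk$lod[pk$group %in% c("3", "8")] > sc$threshold))
  # maternal trait maps through the mother's genotype
  scm <- scan_structured(sp$cross$phenotypes, sp$probs, "g3_area",
                         n_perm = 100, seed = 9)
  pkm <- scan_peaks(scm)
  expect_true("7" %in% pkm$group)
  all_pk <- scan_peaks(scm, threshold = 0)
  expect_true(all(c("6", "7") %in%
                    all_pk$group[order(-all_pk$lod)][1:3]))
  # G2's own larval size maps nowhere (maternal trait, F1 mothers all het)
  scl <- scan_structured(sp$cross$phenotypes, sp$probs, "larval_area",
                         n_perm = 100, seed = 9)
  expect_lt(max(scl$scan$lod), scl$threshold)
})

test_that("binary logistic scan finds the anal-cirri locus", {
  sp <- shared_probs()
  sc <- scan_structured(sp$cross$phenotypes, sp$probs, "anal_cirri",
                        model = "binary")
  expect_equal(sc$scan$group[which.max(sc$scan$lod)], "5")
})

test_that("structured permutations are within-family, seeded, and leave
           family-invariant phenotypes fixed", {
  sp <- shared_probs()
  ph <- sp$cross$phenotypes
  s1 <- scan_structured(ph, sp$probs, "chaetae_count", n_perm = 120,
                        seed = 4)
  s2 <- scan_structured(ph, sp$probs, "chaetae_count", n_perm = 120,
                        seed = 4)
  expect_identical(s1$threshold, s2$threshold)
  expect_identical(s1$perm_max, s2$perm_max)
  s3 <- scan_structured(ph, sp$probs, "chaetae_count", n_perm = 120,
                        seed = 5)
  expect_false(identical(s1$perm_max, s3$perm_max))
  # a phenotype constant within each family is invariant under any
  # within-family shuffle: every permutation reproduces the observed scan
  ph$famval <- as.numeric(factor(ph$family))
  s4 <- suppressWarnings(
    scan_structured(ph, sp$probs, "famval", n_perm = 20, seed = 6)
  )
  expect_true(all(abs(s4$perm_max - max(s4$scan$lod)) < 1e-9))
  # warning below 100 permutations
  expect_warning(
    scan_structured(ph, sp$probs, "chaetae_count", n_perm = 20, seed = 1),
    "unstable"
  )
})

test_that("fit_qtl_model recovers generating coefficients and drop-one
           shares", {
  sp <- shared_probs()
  ph <- sp$cross$phenotypes
  qtl_cn <- tibble::tibble(group = c(3, 8), pos = c(2.5, 1.7),
                           name = c("LG3", "LG8"))
  fit <- fit_qtl_model(ph, sp$probs, "chaetae_count", qtl_cn)
  cf <- fit$coefficients
  est <- function(t) cf$estimate[cf$term == t]
  se <- function(t) cf$std_error[cf$term == t]
  expect_lt(abs(est("a_LG3") - (-2.53)), 3 * se("a_LG3"))
  expect_lt(abs(est("a_LG8") - (-2.30)), 3 * se("a_LG8"))
  expect_lt(abs(est("(Intercept)") - 4.29), 3 * se("(Intercept)"))
  # drop-one shares approximate the generating variance fractions
  d1 <- fit$drop_one
  expect_gt(d1$pct_explained[d1$term == "LG3"], 10)
  expect_lt(d1$pct_explained[d1$term == "LG3"], 35)
  # a null locus contributes essentially nothing
  qtl_null <- dplyr::bind_rows(
    qtl_cn, tibble::tibble(group = 2, pos = 25, name = "null")
  )
  fit0 <- fit_qtl_model(ph, sp$probs, "chaetae_count", qtl_null)
  expect_lt(fit0$drop_one$pct_explained[fit0$drop_one$term == "null"], 2)
  # epistatic maternal model: the LG6 x LG7 interaction improves fit
  qtl_g3 <- tibble::tibble(group = c(6, 7), pos = c(17.9, 2.1),
                           name = c("LG6", "LG7"))
  fit_int <- fit_qtl_model(ph, sp$probs, "g3_area", qtl_g3,
                           interactions = list(c("LG6", "LG7")))
  axd <- fit_int$coefficients
  expect_lt(abs(axd$estimate[axd$term == "ad_LG6_x_LG7"] - (-3297.03)),
            3 * axd$std_error[axd$term == "ad_LG6_x_LG7"])
})

test_that("family effects are detected when simulated and the test needs
           two families", {
  sp <- shared_probs()
  ph <- sp$cross$phenotypes
  # chaetae length carries simulated family effects (H shifted ~ -20)
  out <- family_effect_test(ph, trait = "chaetae_length")
  expect_lt(out$p_value, 0.01)
  # single family: undefined
  expect_error(
    family_effect_test(ph[ph$family == "A", ], trait = "chaetae_length"),
    "two families"
  )
  # calibration under the null: larval area has family effects, so use a
  # synthetic family-free trait
  set.seed(2)
  pvals <- replicate(200, {
    ph$noise <- rnorm(nrow(ph))
    family_effect_test(ph, trait = "noise")$p_value
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("residual correlation separates shared-QTL from shared-noise
           trait pairs", {
  sp <- shared_probs()
  cr <- sp$cross
  ph <- cr$phenotypes
  qg <- cr$qtl_truth$qtl_geno
  g3 <- qg[qg$trait == "chaetae_count" & qg$chrom == 3, ]
  a <- g3$a[match(ph$id, g3$id)]
  d <- g3$d[match(ph$id, g3$id)]
  set.seed(14)
  ph$t1 <- 2 - 1.5 * a + 0.4 * d + rnorm(nrow(ph))
  ph$t2 <- 1 + 1.2 * a - 0.2 * d + rnorm(nrow(ph))
  shared_noise <- rnorm(nrow(ph))
  ph$t3 <- ph$t1 + 2 * shared_noise
  ph$t4 <- 1 + 1.2 * a + 2 * shared_noise + 0.5 * rnorm(nrow(ph))
  qtl3 <- tibble::tibble(group = 3, pos = 2.5)
  # traits sharing only the QTL: residual correlation collapses
  rc <- residual_correlation(ph, sp$probs, "t1", "t2", qtl3)
  expect_gt(rc$r2_raw, 0.15)
  expect_lt(rc$r2_residual, 0.05)
  # traits sharing the QTL and correlated residuals: it persists
  rc2 <- residual_correlation(ph, sp$probs, "t3", "t4", qtl3)
  expect_gt(rc2$r2_residual, 0.3)
  # identical traits: r2 = 1
  rc3 <- residual_correlation(ph, sp$probs, "t1", "t1", qtl3)
  expect_equal(rc3$r2_raw, 1)
  expect_error(residual_correlation(ph[1:5, ], sp$probs, "t1", "t2",
                                    qtl3), "10")
})
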
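# The synthetic-cross generator: determinism, Mendelian consistency,
# observation model, phenotype architecture.

test_that("identical configuration and seed give identical crosses", {
  c1 <- simulate_cross(sim_config(seed = 7, n_contigs = 60))
  c2 <- simulate_cross(sim_config(seed = 7, n_contigs = 60))
  expect_identical(c1$obs_geno, c2$obs_geno)
  expect_identical(c1$phenotypes, c2$phenotypes)
  c3 <- simulate_cross(sim_config(seed = 8, n_contigs = 60))
  expect_false(identical(c1$obs_geno, c3$obs_geno))
})

test_that("with zero error and missingness, observed calls equal truth and
           segregate in a Mendelian way", {
  cr <- simulate_cross(sim_config(seed = 3, n_contigs = 80,
                                  error_rate = 0, missing_rate = 0))
  expect_identical(cr$obs_geno, cr$true_geno)
  # every G2 autosomal genotype must be a possible union of parental
  # gametes, checked exhaustively against the true F1 parent genotypes
  ped <- cr$pedigree
  g2 <- ped[ped$generation == "G2", ]
  aut <- cr$snp_map$snp_id[cr$snp_map$chrom != "X"]
  ok <- TRUE
  for (f in unique(g2$family)) {
    mo <- unique(g2$mother[g2$family == f])
    gm <- cr$true_geno[mo, aut]
    gf <- cr$true_geno["F1sire_Z", aut]
    kids <- cr$true_geno[g2$id[g2$family == f], aut, drop = FALSE]
    for (s in seq_along(aut)) {
      probs <- bf_offspring_probs(gm[s], gf[s])
      if (any(probs[kids[, s]] == 0)) ok <- FALSE
    }
  }
  expect_true(ok)
})

test_that("the one-step error model perturbs calls at the configured rate", {
  cr0 <- simulate_cross(sim_config(seed = 5, n_contigs = 200,
                                   error_rate = 0, missing_rate = 0))
  cr1 <- simulate_cross(sim_config(seed = 5, n_contigs = 200,
                                   error_rate = 0.05, missing_rate = 0))
  expect_identical(cr0$true_geno, cr1$true_geno)
  dif <- mean(cr1$obs_geno != cr1$true_geno)
  # realized flip rate approximates the per-call error probability
  # implied by the renormalized one-step matrix
  em <- larvaqtl:::error_matrix(0.05)
  expected <- mean(1 - diag(em)[cr1$true_geno])
  expect_lt(abs(dif - expected), 0.005)
  crm <- simulate_cross(sim_config(seed = 5, n_contigs = 200,
                                   error_rate = 0, missing_rate = 0.2))
  expect_lt(abs(mean(is.na(crm$obs_geno)) - 0.2), 0.01)
})

test_that("chaetae-number architecture matches its closed form", {
  cfg <- sim_config(seed = 9, n_contigs = 10,
                    n_G2_per_family = c(A = 2500, C = 2500,
                                        F = 2500, H = 2500))
  cr <- simulate_cross(cfg)
  ph <- cr$phenotypes
  qg <- cr$qtl_truth$qtl_geno
  qg <- qg[qg$trait == "chaetae_count" & qg$id %in% ph$id, ]
  wide <- tidyr::pivot_wider(qg[, c("id", "chrom", "n_L")],
                             names_from = "chrom", values_from = "n_L")
  ph <- dplyr::left_join(ph, wide, by = "id")
  hi <- ph$chaetae_count_expected[ph$`3` == 0 & ph$`8` == 0] # PP/PP
  lo <- ph$chaetae_count_expected[ph$`3` == 2 & ph$`8` == 2] # LL/LL
  # expected genetic values differ by exactly 2*(2.53 + 2.30)
  expect_equal(mean(hi) - mean(lo), 2 * (2.53 + 2.30), tolerance = 1e-9)
  # realized counts: compare to the rounded/zero-floored normal oracle
  floor_mean <- function(mu, sd = 3) {
    k <- 1:60
    sum(k * (stats::pnorm(k + 0.5, mu, sd) - stats::pnorm(k - 0.5, mu, sd)))
  }
  exp_hi <- floor_mean(4.29 + 2.53 + 2.30)
  exp_lo <- floor_mean(4.29 - 2.53 - 2.30)
  obs_diff <- mean(ph$chaetae_count[ph$`3` == 0 & ph$`8` == 0]) -
    mean(ph$chaetae_count[ph$`3` == 2 & ph$`8` == 2])
  n_class <- min(length(hi), length(lo))
  expect_lt(abs(obs_diff - (exp_hi - exp_lo)), 3 * 3 * sqrt(2 / n_class))
  # zero-truncation emerges at roughly the observed real-data fraction
  expect_gt(mean(ph$chaetae_count == 0), 0.05)
  expect_lt(mean(ph$chaetae_count == 0), 0.30)
  # anal cirri absent in about a quarter of G2s
  expect_gt(mean(ph$anal_cirri == 0), 0.15)
  expect_lt(mean(ph$anal_cirri == 0), 0.40)
})

test_that("the maternal trait is a function of the mother's genotype only", {
  cr <- shared_cross()
  ph <- cr$phenotypes
  qg <- cr$qtl_truth$qtl_geno
  qg <- qg[qg$trait == "g3_area", ]
  key <- qg |>
    dplyr::group_by(id) |>
    dplyr::summarise(k = paste(n_L[order(chrom)], collapse = "/"),
                     .groups = "drop")
  ph <- dplyr::left_join(ph, key, by = "id")
  fem <- ph[ph$sex == "F", ]
  # identical maternal two-locus genotypes -> identical expected brood
  # means, regardless of the mother's own phenotypes
  per_class <- tapply(fem$g3_area_expected, fem$k,
                      function(v) diff(range(v)))
  expect_true(all(per_class < 1e-9))
  # and males carry no maternal-trait value
  expect_true(all(is.na(ph$g3_area[ph$sex == "M"])))
})

test_that("regression on true genotypes recovers the generating effects", {
  cr <- shared_cross()
  ph <- cr$phenotypes
  qg <- cr$qtl_truth$qtl_geno
  dat <- ph[, c("id", "chaetae_count")]
  for (ch in c(3, 8)) {
    sub <- qg[qg$trait == "chaetae_count" & qg$chrom == ch, ]
    dat[[paste0("a", ch)]] <- sub$a[match(dat$id, sub$id)]
    dat[[paste0("d", ch)]] <- sub$d[match(dat$id, sub$id)]
  }
  fit <- summary(lm(chaetae_count ~ a3 + d3 + a8 + d8, data = dat))$coef
  expect_lt(abs(fit["a3", 1] - (-2.53)), 3 * fit["a3", 2])
  expect_lt(abs(fit["a8", 1] - (-2.30)), 3 * fit["a8", 2])
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(error_rate = 0.2), "error_rate")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  qs <- default_qtl_spec()
  qs$pos[1] <- 99
  expect_error(sim_config(qtl_spec = qs), "within the chromosome")
  tm <- default_trait_models()
  tm$g3_area$residual_sd <- -1
  expect_error(sim_config(trait_models = tm), "residual")
  tm2 <- default_trait_models()
  tm2$g3_area$maternal <- NULL
  expect_error(sim_config(trait_models = tm2), "maternal")
})
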
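# Multi-SNP contig recoding into founder-origin intercross markers, and
# pedigree-error screening.

# Build a two-family cross at one contig from explicit founder haplotypes.
# haps: list of integer vectors (alleles 1/2 per SNP). parents: per family
# list(mother = c(i, j), father = c(i, j)) indexing (P0-1 hap, P0-2 hap).
make_contig_cross <- function(haps, parents, n_g2 = 40, n_panel = 30,
                              f1_pool = NULL, seed = 1) {
  set.seed(seed)
  S <- length(haps[[1]])
  geno_of <- function(h1, h2) haps[[h1]] + haps[[h2]] - 1L
  rows <- list(); ped <- list()
  # F1 panel drawn from the possible (P0-1 hap x P0-2 hap) combinations
  if (is.null(f1_pool)) {
    f1_pool <- unique(do.call(rbind, lapply(parents, function(p) {
      rbind(p$mother, p$father)
    })))
  }
  panel_ids <- paste0("F1_", seq_len(n_panel))
  pick <- f1_pool[sample(nrow(f1_pool), n_panel, replace = TRUE), ,
                  drop = FALSE]
  rows$panel <- tibble::tibble(
    snp_id = rep(paste0("c1_s", 1:S), each = n_panel),
    contig_id = "c1",
    id = rep(panel_ids, S),
    call = c("AA", "AB", "BB")[as.vector(apply(pick, 1, function(p) {
      geno_of(p[1], p[2])
    }))]
  )
  ped$panel <- tibble::tibble(
    id = panel_ids, sex = rep(c("M", "F"), length.out = n_panel),
    generation = "F1", mother = "P0_dam", father = "P0_sire",
    family = "F1"
  )
  truth <- list()
  for (f in names(parents)) {
    p <- parents[[f]]
    ids <- paste0(f, "_", seq_len(n_g2))
    mat <- sample(p$mother, n_g2, replace = TRUE) # transmitted hap index
    pat <- sample(p$father, n_g2, replace = TRUE)
    g <- vapply(seq_len(n_g2), function(i) geno_of(mat[i], pat[i]),
                integer(S))
    g <- if (S == 1) matrix(g, 1) else g
    rows[[f]] <- tibble::tibble(
      snp_id = rep(paste0("c1_s", 1:S), n_g2),
      contig_id = "c1",
      id = rep(ids, each = S),
      call = c("AA", "AB", "BB")[as.vector(g)]
    )
    ped[[f]] <- tibble::tibble(
      id = ids, sex = rep(c("M", "F"), length.out = n_g2),
      generation = "G2", mother = paste0("mo_", f), father = "Z",
      family = f
    )
    # founder-origin truth: hap indices of (P0-1, P0-2) transmitted sides
    o_mat <- ifelse(mat == p$mother[1], 1L, 2L)
    o_pat <- ifelse(pat == p$father[1], 1L, 2L)
    truth[[f]] <- stats::setNames(o_mat + o_pat - 1L, ids)
  }
  list(snps = dplyr::bind_rows(rows), pedigree = dplyr::bind_rows(ped),
       truth = truth, parents = parents)
}

test_that("a concordant two-SNP intercross contig recodes codominantly", {
  # founder haplotypes: P0-1 = X/X with X=(A,A); P0-2 = Y/Y with Y=(B,B)
  haps <- list(c(1L, 1L), c(2L, 2L))
  parents <- list(
    A = list(mother = c(1L, 2L), father = c(1L, 2L)),
    B = list(mother = c(1L, 2L), father = c(1L, 2L))
  )
  cc <- make_contig_cross(haps, parents, seed = 2)
  seg <- infer_segregation(cc$snps, cc$pedigree, include_x = FALSE)
  expect_true(all(seg$patterns$config == "AAxBB"))
  mk <- recode_contig(cc$snps, seg, cc$pedigree)
  expect_equal(nrow(mk), 1)
  expect_true(all(unlist(mk$resolvable[[1]])))
  g <- mk$geno[[1]]
  # marker genotype equals the shared SNP genotype (both SNPs agree),
  # up to the arbitrary global founder orientation
  G <- larvaqtl:::snp_matrix(cc$snps)
  s1 <- G[names(g), "c1_s1"]
  match1 <- mean(g == s1, na.rm = TRUE)
  match2 <- mean(g == 4L - s1, na.rm = TRUE)
  expect_equal(max(match1, match2), 1)
})

test_that("the AB x AC founder-haplotype case gives codominant and
           dominant families as appropriate", {
  # three distinct haplotypes over two SNPs; both SNPs segregate AAxAB
  hapA <- c(1L, 1L); hapB <- c(2L, 1L); hapC <- c(1L, 2L)
  haps <- list(hapA, hapB, hapC)
  parents <- list(
    # mother A/C, father B/C: fully resolvable
    R = list(mother = c(1L, 3L), father = c(2L, 3L)),
    # mother A/A, father B/C: maternal origin ambiguous -> dominant
    D = list(mother = c(1L, 1L), father = c(2L, 3L))
  )
  f1_pool <- rbind(c(1L, 1L), c(1L, 3L), c(2L, 1L), c(2L, 3L))
  cc <- make_contig_cross(haps, parents, n_g2 = 60, f1_pool = f1_pool,
                          seed = 5)
  seg <- infer_segregation(cc$snps, cc$pedigree, include_x = FALSE)
  mk <- recode_contig(cc$snps, seg, cc$pedigree)
  expect_equal(nrow(mk), 1)
  res <- mk$resolvable[[1]]
  expect_true(res[["R"]])
  expect_false(res[["D"]])
  g <- mk$geno[[1]]
  gR <- g[names(cc$truth$R)]
  # codominant family: codes match founder-origin truth up to global flip
  okR <- !is.na(gR)
  acc <- max(mean(gR[okR] == cc$truth$R[okR]),
             mean(gR[okR] == 4L - cc$truth$R[okR]))
  expect_equal(acc, 1)
  # ambiguous family receives only dominant or missing codes for
  # genotypes whose maternal origin cannot be resolved
  gD <- g[names(cc$truth$D)]
  expect_true(all(is.na(gD) | gD %in% c(2L, 4L, 5L)))
  expect_true(any(gD %in% c(4L, 5L)))
})

test_that("a call violating every founder haplotype pair becomes missing", {
  haps <- list(c(1L, 1L), c(2L, 2L))
  parents <- list(
    A = list(mother = c(1L, 2L), father = c(1L, 2L)),
    B = list(mother = c(1L, 2L), father = c(1L, 2L))
  )
  cc <- make_contig_cross(haps, parents, seed = 3)
  # plant an impossible two-SNP genotype: AA at snp1 with BB at snp2
  victim <- cc$pedigree$id[cc$pedigree$generation == "G2"][1]
  cc$snps$call[cc$snps$id == victim & cc$snps$snp_id == "c1_s1"] <- "AA"
  cc$snps$call[cc$snps$id == victim & cc$snps$snp_id == "c1_s2"] <- "BB"
  seg <- infer_segregation(cc$snps, cc$pedigree, include_x = FALSE)
  mk <- recode_contig(cc$snps, seg, cc$pedigree)
  expect_true(is.na(mk$geno[[1]][victim]))
})

test_that("recoding is deterministic and single AAxBB SNPs pass through", {
  cr <- shared_cross()
  seg <- infer_segregation(cr$observed_snps, cr$pedigree)
  xsnps <- cr$snp_map$snp_id[cr$snp_map$chrom == "X"]
  m1 <- recode_contigs(cr$observed_snps, seg, cr$pedigree,
                       sex_linked_snps = xsnps)
  m2 <- recode_contigs(cr$observed_snps, seg, cr$pedigree,
                       sex_linked_snps = xsnps)
  expect_identical(m1$geno, m2$geno)
  # recoded genotypes never leave the code alphabet
  expect_true(all(is.na(m1$geno) | m1$geno %in% 1:5))
  # single-SNP markers exist and equal their SNP's genotypes
  single <- m1$info$marker[
    m1$info$marker %in% cr$snp_map$contig_id[
      !duplicated(cr$snp_map$contig_id) &
        !cr$snp_map$contig_id %in%
          cr$snp_map$contig_id[duplicated(cr$snp_map$contig_id)]
    ]
  ]
  expect_gt(length(single), 0)
  s <- single[1]
  snp <- cr$snp_map$snp_id[cr$snp_map$contig_id == s]
  G <- larvaqtl:::snp_matrix(
    dplyr::filter(cr$observed_snps, snp_id == snp)
  )
  ids <- rownames(m1$geno)
  expect_equal(unname(m1$geno[, s]), unname(G[ids, 1]))
})

test_that("pedigree screening recovers planted errors", {
  cr <- shared_cross()
  ped <- cr$pedigree
  seg <- infer_segregation(cr$observed_snps, cr$pedigree)

  # no planted errors: no reassignment flags
  scr0 <- screen_pedigree(cr$observed_snps, seg, ped)
  expect_true(all(scr0$flag == "ok"))

  # swap one G2 from family A into family C
  victim <- ped$id[ped$generation == "G2" & ped$family == "A"][1]
  ped_swap <- ped
  ped_swap$family[ped_swap$id == victim] <- "C"
  ped_swap$mother[ped_swap$id == victim] <- "F1mother_C"
  seg_swap <- infer_segregation(cr$observed_snps, ped_swap)
  scr <- screen_pedigree(cr$observed_snps, seg_swap, ped_swap)
  row <- scr[scr$id == victim, ]
  expect_equal(row$flag, "reassign")
  expect_equal(row$best_family, "A")

  # an individual with heavy random genotype noise is incompatible with
  # every candidate mother
  noisy <- ped$id[ped$generation == "G2" & ped$family == "H"][1]
  snps_noise <- cr$observed_snps
  sel <- which(snps_noise$id == noisy)
  sel <- sel[runif(length(sel)) < 0.3]
  set.seed(8)
  snps_noise$call[sel] <- sample(c("AA", "AB", "BB"), length(sel),
                                 replace = TRUE)
  seg_n <- infer_segregation(snps_noise, ped)
  scr_n <- screen_pedigree(snps_noise, seg_n, ped)
  expect_equal(scr_n$flag[scr_n$id == noisy], "all_incompatible")
})
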
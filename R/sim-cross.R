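# Synthetic outbred cross: P0 (planktotroph dam x lecithotroph sire) -> F1
# -> four half-sib G2 families sharing a single F1 sire. Founder haplotypes
# are tracked explicitly: haplotype ids 1,2 belong to the P0 dam (origin P),
# 3,4 to the P0 sire (origin L; on the X, 3 = sire X, 4 = Y).

AUTOSOMAL_CONFIGS <- c("AAxBB", "ABxAB", "AAxAB", "ABxBB", "AAxAA", "BBxBB")
X_CONFIGS <- c("AAxBY", "BBxAY", "fixedXY", "monoX")

# Draw founder-haplotype alleles (1 = A, 2 = B) for one autosomal SNP.
.autosomal_alleles <- function(config) {
  swap <- stats::runif(1) < 0.5 # which P0 carries which genotype
  g <- switch(config,
    AAxBB = list(c(1L, 1L), c(2L, 2L)),
    ABxAB = list(sample(1:2), sample(1:2)),
    AAxAB = list(c(1L, 1L), sample(1:2)),
    ABxBB = list(sample(1:2), c(2L, 2L)),
    AAxAA = list(c(1L, 1L), c(1L, 1L)),
    BBxBB = list(c(2L, 2L), c(2L, 2L))
  )
  if (swap) g <- g[2:1]
  c(g[[1]], g[[2]])
}

# Alleles for one X-linked SNP: haps 1,2 = dam X's, hap 3 = sire X,
# slot 4 = Y allele (0 = locus absent from Y).
.x_alleles <- function(config) {
  switch(config,
    AAxBY  = c(1L, 1L, 2L, 0L),
    BBxAY  = c(2L, 2L, 1L, 0L),
    fixedXY = if (stats::runif(1) < 0.5) c(1L, 1L, 1L, 2L) else c(2L, 2L, 2L, 1L),
    monoX  = c(1L, 1L, 1L, 0L)
  )
}

# One gamete per offspring from a parent's pair of haplotype-id vectors,
# sampled at the chromosome's position grid under Haldane's model: the
# active strand follows a two-state Markov chain with switch probability
# equal to the recombination fraction between adjacent positions.
.meiosis <- function(h1, h2, rvec, n) {
  p <- length(h1)
  s <- matrix(0L, n, p)
  s[, 1] <- stats::rbinom(n, 1, 0.5)
  if (p > 1) {
    for (k in 2:p) {
      s[, k] <- bitwXor(s[, k - 1], stats::rbinom(n, 1, rvec[k - 1]))
    }
  }
  out <- matrix(h1[col(s)], n, p)
  out[s == 1L] <- matrix(h2[col(s)], n, p)[s == 1L]
  out
}

.make_ids <- function(prefix, n) sprintf("%s_%02d", prefix, seq_len(n))

#' Simulate a structured outbred mapping cross with known truth
#'
#' Generates the full cross the downstream stages assume: founder
#' haplotypes, F1 panel, four (by default) half-sib G2 families sharing one
#' F1 sire, SNP calls with one-step genotyping error and missing data,
#' larval phenotypes generated from the configured QTL architecture
#' (including LG6 x LG7 epistasis and a maternal-effect trait expressed
#' through the G2 mother's genotype), and complete founder-origin truth at
#' every contig and QTL position.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `true_cross`: a list with elements
#'   `pedigree`, `snp_map`, `observed_snps` (long tibble of calls),
#'   `phenotypes`, `qtl_truth`, plus internal truth matrices
#'   (`true_geno`, `obs_geno`, `origin`, `contig_pos`).
#' @examples
#' cross <- simulate_cross(sim_config(n_contigs = 40, seed = 7))
#' cross$phenotypes
#' @export
simulate_cross <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  qtl <- config$qtl_spec

  ## --- marker panel -------------------------------------------------------
  n_contigs <- config$n_contigs
  contig_chrom <- ifelse(
    stats::runif(n_contigs) < config$frac_x, "X",
    as.character(sample.int(config$n_autosomes, n_contigs, replace = TRUE))
  )
  contig_len <- ifelse(contig_chrom == "X", config$x_length_cM,
                       config$chrom_length_cM)
  contig_pos <- stats::runif(n_contigs) * contig_len
  spc <- config$snps_per_contig
  n_snps_per <- if (is.list(spc)) {
    sample(spc$sizes, n_contigs, replace = TRUE, prob = spc$prob)
  } else rep(as.integer(spc), n_contigs)

  contig_id <- sprintf("ctg%04d", seq_len(n_contigs))
  snp_contig <- rep(seq_len(n_contigs), n_snps_per)
  n_snp <- length(snp_contig)
  snp_id <- paste0(contig_id[snp_contig], "_s",
                   unlist(lapply(n_snps_per, seq_len)))
  snp_chrom <- contig_chrom[snp_contig]
  snp_pos <- contig_pos[snp_contig]

  is_x <- snp_chrom == "X"
  snp_config <- character(n_snp)
  snp_config[!is_x] <- sample(AUTOSOMAL_CONFIGS, sum(!is_x), replace = TRUE,
                              prob = config$config_weights)
  snp_config[is_x] <- sample(X_CONFIGS, sum(is_x), replace = TRUE,
                             prob = c(0.3, 0.3, 0.2, 0.2))
  alleles <- matrix(0L, n_snp, 4) # founder hap -> allele (1/2); col4 = Y on X
  for (s in seq_len(n_snp)) {
    alleles[s, ] <- if (is_x[s]) .x_alleles(snp_config[s])
                    else .autosomal_alleles(snp_config[s])
  }

  snp_map <- tibble::tibble(
    snp_id = snp_id, contig_id = contig_id[snp_contig],
    chrom = snp_chrom, pos = snp_pos, config = snp_config,
    hap1 = alleles[, 1], hap2 = alleles[, 2],
    hap3 = alleles[, 3], hap4 = alleles[, 4]
  )

  ## --- position grids (unique contig + QTL positions per chromosome) -----
  chroms <- c(as.character(seq_len(config$n_autosomes)), "X")
  grids <- lapply(chroms, function(ch) {
    p <- contig_pos[contig_chrom == ch]
    if (ch != "X") p <- c(p, qtl$pos[qtl$chrom == as.integer(ch)])
    sort(unique(p))
  })
  names(grids) <- chroms
  rgrids <- lapply(grids, function(g) {
    if (length(g) > 1) haldane_r(diff(g)) else numeric(0)
  })

  ## --- pedigree -----------------------------------------------------------
  fams <- names(config$n_G2_per_family)
  nf1 <- config$n_F1_panel
  n_f1_male <- ceiling(nf1 / 2)
  f1_panel_ids <- .make_ids("F1", nf1)
  f1_panel_sex <- c(rep("M", n_f1_male), rep("F", nf1 - n_f1_male))
  f1_mother_ids <- paste0("F1mother_", fams)
  f1_sire_id <- "F1sire_Z"
  g2_ids <- unlist(lapply(fams, function(f) {
    .make_ids(f, config$n_G2_per_family[[f]])
  }))
  g2_family <- rep(fams, config$n_G2_per_family)
  g2_sex <- unname(unlist(lapply(config$n_G2_per_family, function(n) {
    nm <- round(0.25 * n)
    sample(c(rep("M", nm), rep("F", n - nm)))
  })))

  pedigree <- dplyr::bind_rows(
    tibble::tibble(id = c("P0_dam", "P0_sire"), sex = c("F", "M"),
                   generation = "P0", mother = NA_character_,
                   father = NA_character_, family = NA_character_),
    tibble::tibble(id = c(f1_panel_ids, f1_mother_ids, f1_sire_id),
                   sex = c(f1_panel_sex, rep("F", length(fams)), "M"),
                   generation = "F1", mother = "P0_dam", father = "P0_sire",
                   family = "F1"),
    tibble::tibble(id = g2_ids, sex = g2_sex, generation = "G2",
                   mother = paste0("F1mother_", g2_family),
                   father = f1_sire_id, family = g2_family)
  )

  ## --- haplotype simulation ----------------------------------------------
  all_f1 <- c(f1_panel_ids, f1_mother_ids, f1_sire_id)
  f1_sex <- c(f1_panel_sex, rep("F", length(fams)), "M")
  names(f1_sex) <- all_f1
  n_f1 <- length(all_f1)
  n_g2 <- length(g2_ids)
  geno_ids <- c(all_f1, g2_ids)
  n_ind <- length(geno_ids)

  # hap[[chrom]] is an n_ind x n_pos x 2 array of founder-haplotype ids;
  # on the X, males carry their X in slot 1 and Y (id 4) in slot 2.
  hap <- list()
  for (ch in chroms) {
    g <- grids[[ch]]
    p <- length(g)
    rv <- rgrids[[ch]]
    arr <- array(0L, c(n_ind, max(p, 1), 2))
    if (p == 0) { hap[[ch]] <- arr; next }
    if (ch != "X") {
      arr[1:n_f1, , 1] <- .meiosis(rep(1L, p), rep(2L, p), rv, n_f1)
      arr[1:n_f1, , 2] <- .meiosis(rep(3L, p), rep(4L, p), rv, n_f1)
    } else {
      # F1 maternal X is a dam recombinant; females add the sire X (3),
      # males add Y (4).
      arr[1:n_f1, , 1] <- .meiosis(rep(1L, p), rep(2L, p), rv, n_f1)
      arr[1:n_f1, , 2] <- rep(ifelse(f1_sex == "M", 4L, 3L), p)
    }
    sire_row <- match(f1_sire_id, geno_ids)
    offset <- n_f1
    for (f in fams) {
      mo_row <- match(paste0("F1mother_", f), geno_ids)
      nfam <- config$n_G2_per_family[[f]]
      rows <- offset + seq_len(nfam)
      sexes <- g2_sex[rows - n_f1]
      if (ch != "X") {
        arr[rows, , 1] <- .meiosis(arr[mo_row, , 1], arr[mo_row, , 2], rv, nfam)
        arr[rows, , 2] <- .meiosis(arr[sire_row, , 1], arr[sire_row, , 2],
                                   rv, nfam)
      } else {
        arr[rows, , 1] <- .meiosis(arr[mo_row, , 1], arr[mo_row, , 2], rv, nfam)
        # father transmits his X intact to daughters, Y to sons
        patx <- matrix(rep(arr[sire_row, , 1], each = nfam), nfam)
        patx[sexes == "M", ] <- 4L
        arr[rows, , 2] <- patx
      }
      offset <- offset + nfam
    }
    dimnames(arr) <- list(geno_ids, NULL, NULL)
    hap[[ch]] <- arr
  }

  ## --- SNP genotypes ------------------------------------------------------
  sex_all <- c(f1_sex, stats::setNames(g2_sex, g2_ids))
  true_geno <- matrix(NA_integer_, n_ind, n_snp,
                      dimnames = list(geno_ids, snp_id))
  for (ch in chroms) {
    idx <- which(snp_chrom == ch)
    if (!length(idx)) next
    gidx <- match(snp_pos[idx], grids[[ch]])
    h1 <- hap[[ch]][, gidx, 1, drop = FALSE][, , 1]
    h2 <- hap[[ch]][, gidx, 2, drop = FALSE][, , 1]
    if (is.null(dim(h1))) { h1 <- matrix(h1, n_ind); h2 <- matrix(h2, n_ind) }
    a1 <- matrix(alleles[cbind(rep(idx, each = n_ind), as.vector(h1))],
                 n_ind, length(idx))
    if (ch != "X") {
      a2 <- matrix(alleles[cbind(rep(idx, each = n_ind), as.vector(h2))],
                   n_ind, length(idx))
      true_geno[, idx] <- a1 + a2 - 1L
    } else {
      male <- sex_all[geno_ids] == "M"
      a2 <- matrix(alleles[cbind(rep(idx, each = n_ind), as.vector(h2))],
                   n_ind, length(idx))
      g <- a1 + a2 - 1L
      # males: slot 2 is Y (allele column 4; 0 means absent -> hemizygous)
      ya <- alleles[idx, 4]
      ya_m <- matrix(rep(ya, each = n_ind), n_ind)
      gm <- ifelse(ya_m == 0L, 2L * a1 - 1L, a1 + ya_m - 1L)
      g[male, ] <- gm[male, ]
      true_geno[, idx] <- g
    }
  }

  ## --- observation model: one-step error, then missingness ---------------
  obs_geno <- true_geno
  if (config$error_rate > 0) {
    em <- error_matrix(config$error_rate)
    for (tg in 1:3) {
      cells <- which(true_geno == tg)
      obs_geno[cells] <- sample.int(3L, length(cells), replace = TRUE,
                                    prob = em[tg, ])
    }
  }
  if (config$missing_rate > 0) {
    drop <- stats::runif(length(obs_geno)) < config$missing_rate
    obs_geno[drop] <- NA_integer_
  }

  ## --- founder-origin truth at contig and QTL positions -------------------
  origin <- list() # per chromosome: n_ind x n_pos count of L haplotypes
  for (ch in chroms) {
    if (!length(grids[[ch]])) { origin[[ch]] <- NULL; next }
    origin[[ch]] <- (hap[[ch]][, , 1] >= 3L) + (hap[[ch]][, , 2] >= 3L)
    if (is.null(dim(origin[[ch]]))) {
      origin[[ch]] <- matrix(origin[[ch]], n_ind)
    }
    dimnames(origin[[ch]]) <- list(geno_ids, NULL)
  }

  qtl_geno <- tibble::tibble(
    id = rep(geno_ids, nrow(qtl)),
    trait = rep(qtl$trait, each = n_ind),
    chrom = rep(qtl$chrom, each = n_ind),
    pos = rep(qtl$pos, each = n_ind),
    n_L = unlist(lapply(seq_len(nrow(qtl)), function(q) {
      ch <- as.character(qtl$chrom[q])
      origin[[ch]][, match(qtl$pos[q], grids[[ch]])]
    }))
  )
  qtl_geno$a <- qtl_geno$n_L - 1L
  qtl_geno$d <- as.integer(qtl_geno$n_L == 1L)

  ## --- phenotypes ---------------------------------------------------------
  phenotypes <- .simulate_phenotypes(
    geno_ids = g2_ids, family = g2_family, sex = g2_sex,
    qtl = qtl, qtl_geno = qtl_geno, trait_models = config$trait_models
  )

  observed_snps <- tibble::tibble(
    snp_id = rep(snp_id, each = n_ind),
    contig_id = rep(snp_map$contig_id, each = n_ind),
    id = rep(geno_ids, n_snp),
    call = code_to_geno(as.vector(obs_geno))
  )

  structure(
    list(
      config = config,
      pedigree = pedigree,
      snp_map = snp_map,
      observed_snps = observed_snps,
      phenotypes = phenotypes,
      qtl_truth = list(qtl_spec = qtl, qtl_geno = qtl_geno),
      true_geno = true_geno,
      obs_geno = obs_geno,
      origin = origin,
      hap = hap,
      grids = grids,
      contig_pos = tibble::tibble(
        contig_id = contig_id, chrom = contig_chrom, pos = contig_pos
      ),
      families = fams
    ),
    class = "true_cross"
  )
}

# Trait values from the configured architecture. Zygotic traits use the
# individual's own genotype; the maternal trait uses the genotype of the G2
# female herself as mother of her G3 brood. *_expected columns hold the
# noise-free genetic values used by tests.
.simulate_phenotypes <- function(geno_ids, family, sex, qtl, qtl_geno,
                                 trait_models) {
  n <- length(geno_ids)
  out <- tibble::tibble(id = geno_ids, family = family, sex = sex)
  ad <- function(trait) {
    g <- qtl_geno[qtl_geno$trait == trait & qtl_geno$id %in% geno_ids, ]
    loci <- unique(g[, c("chrom", "pos")])
    A <- D <- matrix(0, n, nrow(loci))
    for (j in seq_len(nrow(loci))) {
      gj <- g[g$chrom == loci$chrom[j] & g$pos == loci$pos[j], ]
      A[, j] <- gj$a[match(geno_ids, gj$id)]
      D[, j] <- gj$d[match(geno_ids, gj$id)]
    }
    list(A = A, D = D, loci = loci)
  }
  linpred <- function(trait, m) {
    eff <- qtl[qtl$trait == trait, ]
    lp <- rep(m$intercept, n)
    if (nrow(eff)) {
      x <- ad(trait)
      for (j in seq_len(nrow(eff))) {
        lp <- lp + x$A[, j] * eff$add[j] + x$D[, j] * eff$dom[j]
      }
      for (ep in m$epistasis %||% list()) {
        i1 <- match(ep$chroms[1], x$loci$chrom)
        i2 <- match(ep$chroms[2], x$loci$chrom)
        lp <- lp + ep$axa * x$A[, i1] * x$A[, i2] +
          ep$dxa * x$D[, i1] * x$A[, i2] +
          ep$axd * x$A[, i1] * x$D[, i2] +
          ep$dxd * x$D[, i1] * x$D[, i2]
      }
    }
    fe <- m$family_effects %||% NULL
    if (!is.null(fe)) {
      fv <- fe[family]
      fv[is.na(fv)] <- 0
      lp <- lp + fv
    }
    lp
  }

  tm <- trait_models
  for (trait in names(tm)) {
    m <- tm[[trait]]
    lp <- linpred(trait, m)
    if (m$type == "binary") {
      out[[paste0(trait, "_prob")]] <- stats::plogis(lp)
      out[[trait]] <- stats::rbinom(n, 1, stats::plogis(lp))
    } else {
      y <- lp + stats::rnorm(n, 0, m$residual_sd)
      if (m$type == "count") y <- pmax(0, round(y))
      out[[paste0(trait, "_expected")]] <- lp
      out[[trait]] <- y
    }
    if (isTRUE(m$maternal)) {
      # maternal trait observed only on G2 females (mothers of G3 broods)
      out[[trait]][sex != "F"] <- NA_real_
    }
  }
  if (all(c("chaetae_count", "chaetae_length") %in% names(out))) {
    out$chaetae_length[out$chaetae_count == 0] <- NA_real_
  }
  out
}

#' @export
print.true_cross <- function(x, ...) {
  cat("<true_cross>\n")
  cat("  individuals:", nrow(x$pedigree), " (",
      sum(x$pedigree$generation == "G2"), "G2 in",
      length(x$families), "families)\n")
  cat("  SNPs:", nrow(x$snp_map), "on",
      length(unique(x$snp_map$contig_id)), "contigs\n")
  invisible(x)
}

#' Extract true founder-origin intercross genotypes at contig positions
#'
#' Returns the simulated truth as perfectly recoded intercross markers
#' (one marker per autosomal contig), coded PP/PL/LL by the number of
#' lecithotroph-founder haplotypes each individual carries. Used to test
#' map construction and QTL machinery against known truth.
#'
#' @param cross A `true_cross`.
#' @param ids Individuals to include (default: all G2s).
#' @return A list with `geno` (individuals x markers integer matrix,
#'   codes 1/2/3) and `map` (tibble: marker, chrom, pos).
#' @export
true_intercross_genotypes <- function(cross, ids = NULL) {
  stopifnot(inherits(cross, "true_cross"))
  if (is.null(ids)) {
    ids <- cross$pedigree$id[cross$pedigree$generation == "G2"]
  }
  cp <- cross$contig_pos[cross$contig_pos$chrom != "X", ]
  cp <- cp[order(as.integer(cp$chrom), cp$pos), ]
  geno <- matrix(NA_integer_, length(ids), nrow(cp),
                 dimnames = list(ids, cp$contig_id))
  for (j in seq_len(nrow(cp))) {
    ch <- cp$chrom[j]
    gi <- match(cp$pos[j], cross$grids[[ch]])
    geno[, j] <- cross$origin[[ch]][ids, gi] + 1L
  }
  list(geno = geno, map = tibble::tibble(
    marker = cp$contig_id, chrom = cp$chrom, pos = cp$pos
  ))
}
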
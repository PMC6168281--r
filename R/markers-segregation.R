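# Composite-likelihood inference of segregation patterns without parental
# genotypes. For each SNP and each candidate P0 configuration, the F1
# parents of every G2 family are profiled out: we enumerate F1 genotype
# pairs consistent with the configuration, weight them by their Mendelian
# prior, convolve the implied G2 genotype expectations with a one-step
# error model (error rate maximized per family on a grid), and multiply the
# per-family maxima together with the F1-panel likelihood.

# Offspring genotype distribution from a parental genotype pair (codes 1-3).
.transmission <- function(gm, gf) {
  pa <- c(1, 0.5, 0) # P(transmit allele A) per genotype
  am <- pa[gm]; af <- pa[gf]
  c(am * af, am * (1 - af) + (1 - am) * af, (1 - am) * (1 - af))
}

# F1 genotype distribution under each P0 configuration.
.f1_dist <- function(config) {
  switch(config,
    AAxBB = c(0, 1, 0),
    ABxAB = c(0.25, 0.5, 0.25),
    AAxAB = c(0.5, 0.5, 0),
    ABxBB = c(0, 0.5, 0.5),
    AAxAA = c(1, 0, 0),
    BBxBB = c(0, 0, 1)
  )
}

# Enumerate F1 parent pairs with positive prior under a configuration.
.config_pairs <- function(config) {
  v0 <- .f1_dist(config)
  gs <- which(v0 > 0)
  out <- expand.grid(gm = gs, gf = gs)
  out$prior <- v0[out$gm] * v0[out$gf]
  out
}

.v_key <- function(v) paste(signif(v, 10), collapse = "/")

# Precompute log observation probabilities over the error grid for a set of
# genotype-class distributions: list of (n_eps x 3) matrices.
.log_obs_tables <- function(vs, eps) {
  E <- lapply(eps, error_matrix)
  lapply(vs, function(v) {
    t(vapply(E, function(e) log(pmax(as.vector(v %*% e), 1e-300)),
             numeric(3)))
  })
}

# Maximize sum(counts * log P(obs; eps)) over the error grid for each row
# of a count matrix. Returns max log-likelihood and the maximizing eps
# (ties broken toward smaller eps: the grid is increasing and max.col
# "first" takes the earliest maximum).
.profile_eps <- function(C, logp, eps) {
  LL <- C %*% t(logp) # n x n_eps
  j <- max.col(LL, ties.method = "first")
  list(ll = LL[cbind(seq_len(nrow(LL)), j)], eps = eps[j])
}

AUTOSOMAL_SEG_CONFIGS <- c("AAxBB", "ABxAB", "AAxAB", "ABxBB",
                           "AAxAA", "BBxBB")
X_SEG_CONFIGS <- c("AAxBY", "BBxAY", "fixedXY_A", "fixedXY_B")

# Expected genotype-class distributions for X-linked configurations,
# by group (panel/G2) and sex. Hemizygous males are called homozygous.
.x_expect <- function(config) {
  switch(config,
    AAxBY = list(panel_f = c(0, 1, 0), panel_m = c(1, 0, 0),
                 g2_f = c(0.5, 0.5, 0), g2_m = c(0.5, 0, 0.5)),
    BBxAY = list(panel_f = c(0, 1, 0), panel_m = c(0, 0, 1),
                 g2_f = c(0, 0.5, 0.5), g2_m = c(0.5, 0, 0.5)),
    fixedXY_A = list(panel_f = c(1, 0, 0), panel_m = c(0, 1, 0),
                     g2_f = c(1, 0, 0), g2_m = c(0, 1, 0)),
    fixedXY_B = list(panel_f = c(0, 0, 1), panel_m = c(0, 1, 0),
                     g2_f = c(0, 0, 1), g2_m = c(0, 1, 0))
  )
}

#' Infer segregation patterns by composite likelihood
#'
#' Identifies, for every SNP, the P0 genotype configuration (four
#' segregating autosomal configurations, two monomorphic "erroneously
#' called" ones, and optionally X-linked configurations) that maximizes the
#' composite likelihood over the F1 panel and all G2 families, imputing the
#' F1 parents of each family and a per-family one-step genotyping error
#' rate capped at `eps_max`.
#'
#' @param snps Long SNP tibble (`snp_id`, `id`, `call`).
#' @param pedigree Pedigree tibble (`id`, `sex`, `generation`, `family`).
#' @param eps_max Upper bound of the per-family error rate (default 0.1).
#' @param eps_step Grid resolution for the error-rate profile.
#' @param include_x Also evaluate X-linked configurations (requires sexes).
#' @return A list of class `segregation` with
#'   \describe{
#'     \item{patterns}{tibble: `snp_id`, `config`, `loglik`, `eps_panel`,
#'       `undetermined`.}
#'     \item{families}{tibble: `snp_id`, `family`, `f1_mother`,
#'       `f1_father` (genotype labels), `eps`, `loglik`.}
#'   }
#' @export
infer_segregation <- function(snps, pedigree, eps_max = 0.1,
                              eps_step = 0.001, include_x = TRUE) {
  G <- snp_matrix(snps)
  ids <- rownames(G)
  ped <- pedigree[match(ids, pedigree$id), ]
  panel_ids <- ids[ped$generation == "F1"]
  g2 <- ped[ped$generation == "G2", ]
  fams <- sort(unique(g2$family))
  sex <- stats::setNames(ped$sex, ped$id)

  count3 <- function(rows) {
    sub <- G[rows, , drop = FALSE]
    cbind(colSums(sub == 1L, na.rm = TRUE),
          colSums(sub == 2L, na.rm = TRUE),
          colSums(sub == 3L, na.rm = TRUE))
  }
  C_panel <- count3(panel_ids)
  C_fam <- lapply(fams, function(f) count3(g2$id[g2$family == f]))
  names(C_fam) <- fams
  if (include_x) {
    C_panel_f <- count3(panel_ids[sex[panel_ids] == "F"])
    C_panel_m <- count3(panel_ids[sex[panel_ids] == "M"])
    C_fam_f <- lapply(fams, function(f) {
      count3(g2$id[g2$family == f & g2$sex == "F"])
    })
    C_fam_m <- lapply(fams, function(f) {
      count3(g2$id[g2$family == f & g2$sex == "M"])
    })
  }

  eps <- seq(0, eps_max, by = eps_step)
  # collect all distinct genotype-class distributions used anywhere
  pair_tabs <- lapply(AUTOSOMAL_SEG_CONFIGS, .config_pairs)
  names(pair_tabs) <- AUTOSOMAL_SEG_CONFIGS
  vs <- list()
  add_v <- function(vs, v) { vs[[.v_key(v)]] <- v; vs }
  for (cfg in AUTOSOMAL_SEG_CONFIGS) {
    vs <- add_v(vs, .f1_dist(cfg))
    pt <- pair_tabs[[cfg]]
    for (k in seq_len(nrow(pt))) {
      vs <- add_v(vs, .transmission(pt$gm[k], pt$gf[k]))
    }
  }
  if (include_x) {
    for (cfg in X_SEG_CONFIGS) for (v in .x_expect(cfg)) vs <- add_v(vs, v)
  }
  logp <- .log_obs_tables(vs, eps)

  n_snp <- ncol(G)
  # profiled (ll, eps) per group x distribution
  prof <- function(C) lapply(logp, function(lp) .profile_eps(C, lp, eps))
  P_panel <- prof(C_panel)
  P_fam <- lapply(C_fam, prof)
  if (include_x) {
    # X-linked groups need a shared eps across the two sexes of one group:
    # profile on the summed log-likelihood surface of the sex pair
    x_prof <- function(Cf, Cm, vf, vm) {
      LL <- Cf %*% t(logp_of(vf)) + Cm %*% t(logp_of(vm))
      j <- max.col(LL, ties.method = "first")
      list(ll = LL[cbind(seq_len(nrow(LL)), j)], eps = eps[j])
    }
    logp_of <- function(v) logp[[.v_key(v)]]
  }

  geno_lab <- c("AA", "AB", "BB")
  best_ll <- rep(-Inf, n_snp)
  best_cfg <- rep(NA_character_, n_snp)
  best_eps_sum <- rep(Inf, n_snp)
  best_panel_eps <- rep(NA_real_, n_snp)
  fam_detail <- list()

  consider <- function(cfg, total, eps_sum, panel_eps, detail) {
    better <- total > best_ll + 1e-9 |
      (abs(total - best_ll) <= 1e-9 & eps_sum < best_eps_sum)
    best_cfg[better] <<- cfg
    best_ll[better] <<- total[better]
    best_eps_sum[better] <<- eps_sum[better]
    best_panel_eps[better] <<- panel_eps[better]
    for (f in fams) {
      d <- fam_detail[[f]]
      if (is.null(d)) {
        d <- tibble::tibble(
          f1_mother = rep(NA_character_, n_snp),
          f1_father = rep(NA_character_, n_snp),
          eps = rep(NA_real_, n_snp), loglik = rep(NA_real_, n_snp)
        )
      }
      d$f1_mother[better] <- detail[[f]]$mother[better]
      d$f1_father[better] <- detail[[f]]$father[better]
      d$eps[better] <- detail[[f]]$eps[better]
      d$loglik[better] <- detail[[f]]$ll[better]
      fam_detail[[f]] <<- d
    }
  }

  for (cfg in AUTOSOMAL_SEG_CONFIGS) {
    v0 <- .f1_dist(cfg)
    panel <- P_panel[[.v_key(v0)]]
    pt <- pair_tabs[[cfg]]
    total <- panel$ll
    eps_sum <- panel$eps
    detail <- list()
    for (f in fams) {
      scores <- matrix(-Inf, n_snp, nrow(pt))
      eps_mat <- matrix(0, n_snp, nrow(pt))
      for (k in seq_len(nrow(pt))) {
        v <- .transmission(pt$gm[k], pt$gf[k])
        pr <- P_fam[[f]][[.v_key(v)]]
        scores[, k] <- log(pt$prior[k]) + pr$ll
        eps_mat[, k] <- pr$eps
      }
      kbest <- max.col(scores, ties.method = "first")
      ll_f <- scores[cbind(seq_len(n_snp), kbest)]
      eps_f <- eps_mat[cbind(seq_len(n_snp), kbest)]
      total <- total + ll_f
      eps_sum <- eps_sum + eps_f
      detail[[f]] <- list(
        mother = geno_lab[pt$gm[kbest]], father = geno_lab[pt$gf[kbest]],
        eps = eps_f, ll = ll_f
      )
    }
    consider(cfg, total, eps_sum, panel$eps, detail)
  }

  if (include_x) {
    for (cfg in X_SEG_CONFIGS) {
      xe <- .x_expect(cfg)
      panel <- x_prof(C_panel_f, C_panel_m, xe$panel_f, xe$panel_m)
      total <- panel$ll
      eps_sum <- panel$eps
      detail <- list()
      for (fi in seq_along(fams)) {
        fam <- x_prof(C_fam_f[[fi]], C_fam_m[[fi]], xe$g2_f, xe$g2_m)
        total <- total + fam$ll
        eps_sum <- eps_sum + fam$eps
        detail[[fams[fi]]] <- list(
          mother = rep(NA_character_, n_snp),
          father = rep(NA_character_, n_snp),
          eps = fam$eps, ll = fam$ll
        )
      }
      consider(cfg, total, eps_sum, panel$eps, detail)
    }
  }

  n_called <- C_panel + Reduce(`+`, C_fam)
  undetermined <- rowSums(n_called) == 0
  best_cfg[undetermined] <- NA_character_

  patterns <- tibble::tibble(
    snp_id = colnames(G), config = best_cfg, loglik = best_ll,
    eps_panel = best_panel_eps, undetermined = undetermined
  )
  families <- dplyr::bind_rows(lapply(fams, function(f) {
    tibble::tibble(snp_id = colnames(G), family = f,
                   f1_mother = fam_detail[[f]]$f1_mother,
                   f1_father = fam_detail[[f]]$f1_father,
                   eps = fam_detail[[f]]$eps,
                   loglik = fam_detail[[f]]$loglik)
  }))
  structure(list(patterns = patterns, families = families),
            class = "segregation")
}

#' @export
print.segregation <- function(x, ...) {
  cat("<segregation> inferred patterns for", nrow(x$patterns), "SNPs\n")
  print(table(x$patterns$config, useNA = "ifany"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.segregation <- function(x, ...) x$patterns
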
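# Independent oracles used across test files. These reimplement the
# quantities under test by direct enumeration, sharing no code with the
# package internals.

# Brute-force segregation inference: loops over every autosomal
# configuration, every F1 parent pair, and an error grid, computing the
# composite likelihood directly from first principles.
bf_error_matrix <- function(eps) {
  m <- rbind(c(1, eps, eps^2), c(eps, 1, eps), c(eps^2, eps, 1))
  sweep(m, 1, rowSums(m), "/")
}

bf_offspring_probs <- function(gm, gf) {
  pa <- c(1, 0.5, 0)[c(gm, gf)]
  c(pa[1] * pa[2],
    pa[1] * (1 - pa[2]) + (1 - pa[1]) * pa[2],
    (1 - pa[1]) * (1 - pa[2]))
}

bf_f1_dist <- function(config) {
  list(AAxBB = c(0, 1, 0), ABxAB = c(0.25, 0.5, 0.25),
       AAxAB = c(0.5, 0.5, 0), ABxBB = c(0, 0.5, 0.5),
       AAxAA = c(1, 0, 0), BBxBB = c(0, 0, 1))[[config]]
}

# panel_counts: length-3 counts of F1 genotypes; fam_counts: list of
# length-3 count vectors per family. Returns the winning config and its
# composite log-likelihood.
bf_infer_segregation <- function(panel_counts, fam_counts,
                                 eps_grid = seq(0, 0.1, by = 0.001)) {
  configs <- c("AAxBB", "ABxAB", "AAxAB", "ABxBB", "AAxAA", "BBxBB")
  best <- list(loglik = -Inf, config = NA, eps_sum = Inf)
  for (cfg in configs) {
    v0 <- bf_f1_dist(cfg)
    # panel term: F1s are P0 offspring; profile the panel error rate
    panel_best <- -Inf; panel_eps <- 0
    for (e in eps_grid) {
      p_obs <- as.vector(v0 %*% bf_error_matrix(e))
      ll <- sum(panel_counts * log(pmax(p_obs, 1e-300)))
      if (ll > panel_best) { panel_best <- ll; panel_eps <- e }
    }
    total <- panel_best
    eps_sum <- panel_eps
    for (cc in fam_counts) {
      fam_best <- -Inf; fam_eps <- 0
      gs <- which(v0 > 0)
      for (gm in gs) for (gf in gs) {
        prior <- v0[gm] * v0[gf]
        v <- bf_offspring_probs(gm, gf)
        for (e in eps_grid) {
          p_obs <- as.vector(v %*% bf_error_matrix(e))
          ll <- log(prior) + sum(cc * log(pmax(p_obs, 1e-300)))
          if (ll > fam_best) { fam_best <- ll; fam_eps <- e }
        }
      }
      total <- total + fam_best
      eps_sum <- eps_sum + fam_eps
    }
    if (total > best$loglik + 1e-9 ||
        (abs(total - best$loglik) <= 1e-9 && eps_sum < best$eps_sum)) {
      best <- list(loglik = total, config = cfg, eps_sum = eps_sum)
    }
  }
  best
}

# Build a long SNP tibble + pedigree from explicit genotype count vectors
# (panel and per-family), for feeding the package's infer_segregation().
make_counts_snp <- function(panel_counts, fam_counts, snp_id = "s1") {
  labs <- c("AA", "AB", "BB")
  panel_ids <- paste0("F1_", seq_len(sum(panel_counts)))
  rows <- list(tibble::tibble(
    snp_id = snp_id, contig_id = "c1", id = panel_ids,
    call = rep(labs, panel_counts)
  ))
  ped <- list(tibble::tibble(
    id = panel_ids, sex = rep(c("M", "F"), length.out = length(panel_ids)),
    generation = "F1", mother = "P0_dam", father = "P0_sire",
    family = "F1"
  ))
  for (f in seq_along(fam_counts)) {
    cc <- fam_counts[[f]]
    ids <- paste0("fam", f, "_", seq_len(sum(cc)))
    rows[[f + 1]] <- tibble::tibble(
      snp_id = snp_id, contig_id = "c1", id = ids,
      call = rep(labs, cc)
    )
    ped[[f + 1]] <- tibble::tibble(
      id = ids, sex = rep(c("M", "F"), length.out = length(ids)),
      generation = "G2", mother = paste0("M", f), father = "Z",
      family = LETTERS[f]
    )
  }
  list(snps = dplyr::bind_rows(rows), pedigree = dplyr::bind_rows(ped))
}

# Exhaustive path-sum marginal genotype probabilities for a short
# chromosome: enumerates all 3^m true genotype sequences.
bf_genotype_marginals <- function(obs, rvec, eps) {
  m <- length(obs)
  obs_sets <- list(1L, 2L, 3L, c(2L, 3L), c(1L, 2L))
  em <- bf_error_matrix(eps)
  emis <- function(g, o) {
    if (is.na(o)) return(1)
    sum(em[g, obs_sets[[o]]])
  }
  trans <- function(r) {
    s <- 1 - r
    rbind(c(s^2, 2 * r * s, r^2),
          c(r * s, s^2 + r^2, r * s),
          c(r^2, 2 * r * s, s^2))
  }
  Ts <- lapply(rvec, trans)
  prior <- c(0.25, 0.5, 0.25)
  paths <- as.matrix(expand.grid(rep(list(1:3), m)))
  w <- apply(paths, 1, function(g) {
    p <- prior[g[1]] * emis(g[1], obs[1])
    if (m > 1) {
      for (k in 2:m) p <- p * Ts[[k - 1]][g[k - 1], g[k]] * emis(g[k], obs[k])
    }
    p
  })
  marg <- sapply(seq_len(m), function(k) {
    vapply(1:3, function(s) sum(w[paths[, k] == s]), numeric(1))
  })
  sweep(marg, 2, colSums(marg), "/") # 3 x m, columns sum to 1
}

# small simulated cross shared by several test files (lazy singleton)
shared_cross <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cross(sim_config(seed = 101, n_contigs = 250))
    }
    cache
  }
})

# genotype probabilities at true marker positions for the shared cross
shared_probs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cr <- shared_cross()
      tr <- true_intercross_genotypes(cr)
      map <- tibble::tibble(marker = tr$map$marker,
                            group = as.integer(tr$map$chrom),
                            pos = tr$map$pos)
      cache <<- list(
        cross = cr, geno = tr$geno, map = map,
        probs = genotype_probs(tr$geno, map, step_cM = 2,
                               error_prob = 1e-4)
      )
    }
    cache
  }
})
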
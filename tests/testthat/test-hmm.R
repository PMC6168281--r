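# HMM genotype probabilities, error-LOD scores, and error-rate
# estimation.

test_that("genotype probability marginals match exhaustive path
           enumeration on short chromosomes", {
  map <- tibble::tibble(marker = paste0("m", 1:5), group = 1,
                        pos = c(0, 3, 7, 12, 20))
  rvec <- haldane_r(diff(map$pos))
  cases <- list(
    c(1L, 2L, NA, 3L, 1L),
    c(2L, 2L, 2L, 2L, 2L),
    c(1L, 4L, NA, 5L, 3L), # dominant codes
    c(NA, NA, NA, NA, NA),
    c(3L, 3L, 1L, 3L, 3L)  # apparent double recombinant
  )
  geno <- do.call(rbind, cases)
  colnames(geno) <- map$marker
  rownames(geno) <- paste0("i", seq_along(cases))
  for (eps in c(0.01, 0.05)) {
    gp <- genotype_probs(geno, map, step_cM = 1000, error_prob = eps)
    # marker positions are on the evaluation grid
    at <- match(map$pos, gp[["1"]]$pos)
    for (i in seq_along(cases)) {
      oracle <- bf_genotype_marginals(cases[[i]], rvec, eps)
      for (k in seq_len(5)) {
        expect_equal(as.numeric(gp[["1"]]$prob[i, , at[k]]),
                     oracle[, k], tolerance = 1e-8)
      }
    }
  }
})

test_that("probability triples are normalized and degenerate cases hit
           their closed forms", {
  map <- tibble::tibble(marker = c("m1", "m2"), group = 1, pos = c(0, 20))
  geno <- rbind(i1 = c(1L, 1L), i2 = c(NA, NA))
  colnames(geno) <- map$marker
  gp <- genotype_probs(geno, map, step_cM = 10, error_prob = 0)
  P <- gp[["1"]]$prob
  expect_true(all(abs(apply(P, c(1, 3), sum) - 1) < 1e-9))
  # with zero error the observed marker class has probability one
  at0 <- which(gp[["1"]]$pos == 0)
  expect_equal(P[1, 1, at0], 1, tolerance = 1e-12)
  # all-missing individual sits at the prior everywhere
  expect_true(all(abs(P[2, 1, ] - 0.25) < 1e-9))
  expect_true(all(abs(P[2, 2, ] - 0.5) < 1e-9))
  # midpoint between two PP markers 20 cM apart: closed form from the
  # two-flank transition products
  r <- haldane_r(10)
  w <- c((1 - r)^2, r * (1 - r), r^2) *
    c((1 - r)^2, r * (1 - r), r^2) * c(1, 2, 1)
  at10 <- which(gp[["1"]]$pos == 10)
  expect_equal(P[1, , at10], w / sum(w), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("error LOD flags double-recombinant singletons between tight
           flanks and not concordant calls", {
  map <- tibble::tibble(marker = paste0("m", 1:3), group = 1,
                        pos = c(0, 0.01, 0.02))
  geno <- rbind(bad = c(1L, 3L, 1L), good = c(1L, 1L, 1L))
  colnames(geno) <- map$marker
  el <- error_lod(geno, map, error_prob = 0.01)
  bad_mid <- el$error_lod[el$id == "bad" & el$marker == "m2"]
  good_mid <- el$error_lod[el$id == "good" & el$marker == "m2"]
  # closed-form two-flank oracle for the flagged call
  r <- haldane_r(0.01)
  Tm <- larvaqtl:::f2_transition(r)
  pri <- c(0.25, 0.5, 0.25)[1] * Tm[1, ] * Tm[, 1]
  pri <- pri / sum(pri)
  Em <- larvaqtl:::emission_matrix(0.01)
  oracle <- log10((pri[1] * Em[1, 3] + pri[2] * Em[2, 3]) /
                    (pri[3] * Em[3, 3]))
  expect_equal(bad_mid, oracle, tolerance = 1e-9)
  expect_gt(bad_mid, 6)
  expect_lt(good_mid, 0)
  # cleaning converts exactly the flagged call
  cl <- clean_genotypes(geno, el, threshold = 6)
  expect_equal(cl$n_converted, 1)
  expect_true(is.na(cl$geno["bad", "m2"]))
})

test_that("flagged calls are overwhelmingly planted errors on a clustered
           map", {
  set.seed(31)
  n <- 200
  # clusters of three co-located markers, clusters 5 cM apart
  pos <- as.vector(outer(c(0, 0.001, 0.002), seq(0, 45, by = 5), "+"))
  map <- tibble::tibble(marker = paste0("m", seq_along(pos)), group = 1,
                        pos = sort(pos))
  thetas <- haldane_r(diff(map$pos))
  g <- matrix(0L, n, length(pos))
  a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
  g[, 1] <- 1L + a + b
  for (k in 2:length(pos)) {
    a <- bitwXor(a, rbinom(n, 1, thetas[k - 1]))
    b <- bitwXor(b, rbinom(n, 1, thetas[k - 1]))
    g[, k] <- 1L + a + b
  }
  colnames(g) <- map$marker
  rownames(g) <- paste0("i", 1:n)
  planted <- matrix(runif(length(g)) < 0.005, n)
  gobs <- g
  gobs[planted] <- ifelse(g[planted] == 2L,
                          sample(c(1L, 3L), sum(planted), replace = TRUE),
                          2L)
  el <- error_lod(gobs, map, error_prob = 0.005)
  flagged <- el[el$error_lod > 6, ]
  expect_gt(nrow(flagged), 5)
  is_planted <- planted[cbind(match(flagged$id, rownames(g)),
                              match(flagged$marker, colnames(g)))]
  expect_gte(mean(is_planted), 0.8)
})

test_that("error-rate estimation tracks truth and is monotone", {
  sim_geno <- function(eps, seed) {
    set.seed(seed)
    n <- 240
    pos <- seq(0, 48, by = 2)
    thetas <- haldane_r(diff(pos))
    g <- matrix(0L, n, length(pos))
    a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
    g[, 1] <- 1L + a + b
    for (k in 2:length(pos)) {
      a <- bitwXor(a, rbinom(n, 1, thetas[k - 1]))
      b <- bitwXor(b, rbinom(n, 1, thetas[k - 1]))
      g[, k] <- 1L + a + b
    }
    if (eps > 0) {
      em <- larvaqtl:::error_matrix(eps)
      for (tg in 1:3) {
        cells <- which(g == tg)
        g[cells] <- sample.int(3L, length(cells), TRUE, prob = em[tg, ])
      }
    }
    colnames(g) <- paste0("m", seq_along(pos))
    list(geno = g, map = tibble::tibble(marker = colnames(g), group = 1,
                                        pos = pos))
  }
  s0 <- sim_geno(0, 41)
  expect_lt(estimate_error_rate(s0$geno, s0$map), 0.002)
  ests <- vapply(c(0.005, 0.013, 0.03), function(e) {
    s <- sim_geno(e, 42)
    estimate_error_rate(s$geno, s$map)
  }, numeric(1))
  expect_true(all(diff(ests) > 0))
  expect_lt(abs(ests[2] - 0.013), 0.005)
})

test_that("ordering likelihood is invariant to whole-group reversal", {
  g <- sim_chain <- NULL # not used; construct directly
  set.seed(9)
  n <- 100
  pos <- c(0, 5, 12, 20)
  thetas <- haldane_r(diff(pos))
  G <- matrix(0L, n, 4)
  a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
  G[, 1] <- 1L + a + b
  for (k in 2:4) {
    a <- bitwXor(a, rbinom(n, 1, thetas[k - 1]))
    b <- bitwXor(b, rbinom(n, 1, thetas[k - 1]))
    G[, k] <- 1L + a + b
  }
  ll_fwd <- as.numeric(hmm_loglik(G, thetas, 0.01))
  ll_rev <- as.numeric(hmm_loglik(G[, 4:1], rev(thetas), 0.01))
  expect_equal(ll_fwd, ll_rev, tolerance = 1e-9)
})

test_that("crossover counts match the Poisson expectation from map
           length", {
  cr <- shared_cross()
  tr <- true_intercross_genotypes(cr)
  map <- tibble::tibble(marker = tr$map$marker,
                        group = as.integer(tr$map$chrom),
                        pos = tr$map$pos)
  xo <- count_crossovers(tr$geno, map)
  # two meioses per individual; expected crossovers bounded by twice the
  # total marker-spanned length in Morgans (inner markers miss some)
  span <- sum(tapply(map$pos, map$group, function(p) diff(range(p)))) / 100
  expect_lt(abs(mean(xo$n_crossovers) - 2 * span), 0.15 * 2 * span + 1)
})
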
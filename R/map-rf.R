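# Two-point recombination fractions for intercross markers, allowing
# dominant codes and missing data. Because founder orientation is
# arbitrary per marker until the pool-seq stage, every pair is evaluated
# in both linkage phases and the better one retained.

# observed-class index sets (codes 1..5) over true genotypes 1..3
.OBS_SETS <- list(1L, 2L, 3L, c(2L, 3L), c(1L, 2L))
# code permutation that flips founder orientation of a marker
FLIP_CODES <- c(3L, 2L, 1L, 5L, 4L)

# log P(obs_a, obs_b; theta) over the 5x5 observed classes
.joint_logp <- function(theta) {
  J <- F2_PRIOR * f2_transition(theta)
  P <- matrix(0, 5, 5)
  for (a in 1:5) for (b in 1:5) {
    P[a, b] <- sum(J[.OBS_SETS[[a]], .OBS_SETS[[b]], drop = FALSE])
  }
  log(pmax(P, 1e-300))
}

.pair_counts <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  tab <- matrix(0, 5, 5)
  if (any(ok)) {
    t0 <- table(factor(g1[ok], levels = 1:5), factor(g2[ok], levels = 1:5))
    tab <- matrix(as.numeric(t0), 5, 5)
  }
  tab
}

#' Estimate the recombination fraction between two markers
#'
#' Maximum likelihood under the two-locus intercross transmission model,
#' summing over the true genotypes compatible with dominant codes and
#' skipping missing data. Both linkage phases of the second marker are
#' evaluated and the better-supported one reported.
#'
#' @param g1,g2 Genotype vectors (integer codes 1-5 or labels), same
#'   individuals.
#' @param min_shared Minimum jointly informative individuals; below this
#'   the estimate is undefined (`NA`).
#' @return A list: `theta`, `lod`, `phase` (`1` = as coded, `-1` =
#'   second marker flipped), `n_shared`.
#' @export
estimate_rf <- function(g1, g2, min_shared = 10) {
  g1 <- geno_to_code(g1); g2 <- geno_to_code(g2)
  n_shared <- sum(!is.na(g1) & !is.na(g2))
  if (n_shared < min_shared) {
    return(list(theta = NA_real_, lod = NA_real_, phase = NA_integer_,
                n_shared = n_shared))
  }
  N <- .pair_counts(g1, g2)
  ll <- function(theta, N) sum(N * .joint_logp(theta))
  fits <- lapply(list(N, N[, FLIP_CODES]), function(Nc) {
    o <- stats::optimize(ll, c(1e-6, 0.4999), N = Nc, maximum = TRUE)
    list(theta = o$maximum, ll = o$objective)
  })
  best <- if (fits[[1]]$ll >= fits[[2]]$ll) 1L else 2L
  ll0 <- ll(0.5, N)
  list(
    theta = min(fits[[best]]$theta, 0.5),
    lod = (fits[[best]]$ll - ll0) / log(10),
    phase = c(1L, -1L)[best],
    n_shared = n_shared
  )
}

#' Pairwise recombination fractions and LOD scores for a marker panel
#'
#' Grid-profiled two-point likelihoods for all marker pairs, in both
#' phases, computed with indicator cross-products so the cost is a few
#' dozen matrix multiplications.
#'
#' @param geno Individuals x markers integer matrix (codes 1-5, NA).
#' @param theta_grid Candidate recombination fractions.
#' @param min_shared Pairs with fewer jointly typed individuals are `NA`.
#' @return A list of m x m matrices: `theta`, `lod`, `phase`, `n_shared`.
#' @export
rf_matrix <- function(geno,
                      theta_grid = c(1e-4, 0.001, 0.0025,
                                     seq(0.005, 0.495, by = 0.005)),
                      min_shared = 10) {
  m <- ncol(geno)
  Ind <- lapply(1:5, function(cl) {
    M <- geno == cl
    M[is.na(M)] <- FALSE
    storage.mode(M) <- "double"
    M
  })
  N <- vector("list", 25)
  for (a in 1:5) for (b in 1:5) {
    N[[(a - 1) * 5 + b]] <- crossprod(Ind[[a]], Ind[[b]])
  }
  shared <- Reduce(`+`, N)

  acc_ll <- function(logp, perm) {
    LL <- matrix(0, m, m)
    for (a in 1:5) for (b in 1:5) {
      LL <- LL + logp[a, perm[b]] * N[[(a - 1) * 5 + b]]
    }
    LL
  }
  id_perm <- 1:5
  best_ll <- matrix(-Inf, m, m)
  best_theta <- matrix(NA_real_, m, m)
  best_phase <- matrix(NA_integer_, m, m)
  for (theta in theta_grid) {
    logp <- .joint_logp(theta)
    for (ph in 1:2) {
      perm <- if (ph == 1) id_perm else FLIP_CODES
      LL <- acc_ll(logp, perm)
      upd <- LL > best_ll
      best_ll[upd] <- LL[upd]
      best_theta[upd] <- theta
      best_phase[upd] <- c(1L, -1L)[ph]
    }
  }
  ll0 <- acc_ll(.joint_logp(0.5), id_perm)
  lod <- (best_ll - ll0) / log(10)
  und <- shared < min_shared
  best_theta[und] <- NA; lod[und] <- NA; best_phase[und] <- NA
  diag(lod) <- NA; diag(best_theta) <- NA
  dimnames(best_theta) <- dimnames(lod) <- dimnames(best_phase) <-
    dimnames(shared) <- list(colnames(geno), colnames(geno))
  list(theta = best_theta, lod = lod, phase = best_phase,
       n_shared = shared)
}
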
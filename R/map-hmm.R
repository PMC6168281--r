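# Hidden Markov machinery over the intercross transmission model:
# multipoint likelihoods, conditional genotype probabilities, error-LOD
# scores for individual calls, and maximum-likelihood estimation of the
# genotyping error rate.

# n x 3 emission probabilities for a vector of observed codes (NA -> 1).
.emis <- function(obs, Em) {
  e <- matrix(1, length(obs), 3)
  ok <- which(!is.na(obs))
  if (length(ok)) e[ok, ] <- t(Em)[obs[ok], , drop = FALSE]
  e
}

#' Multipoint log-likelihood of ordered intercross genotypes
#'
#' Forward-algorithm likelihood of a chromosome's genotype matrix under
#' the intercross transmission HMM with a one-step emission error rate.
#'
#' @param geno Individuals x markers matrix (codes 1-5, NA), columns in
#'   map order.
#' @param rvec Recombination fractions between adjacent markers.
#' @param error_prob One-step genotyping error rate.
#' @return Total log-likelihood (sum over individuals); per-individual
#'   values in attribute `"by_individual"`.
#' @export
hmm_loglik <- function(geno, rvec, error_prob = 0.01) {
  geno <- as.matrix(geno)
  n <- nrow(geno); m <- ncol(geno)
  Em <- emission_matrix(max(error_prob, 1e-12))
  alpha <- matrix(F2_PRIOR, n, 3, byrow = TRUE) * .emis(geno[, 1], Em)
  sc <- pmax(rowSums(alpha), 1e-300)
  ll <- log(sc)
  alpha <- alpha / sc
  if (m > 1) {
    for (k in 2:m) {
      alpha <- (alpha %*% f2_transition(rvec[k - 1])) * .emis(geno[, k], Em)
      sc <- pmax(rowSums(alpha), 1e-300)
      ll <- ll + log(sc)
      alpha <- alpha / sc
    }
  }
  out <- sum(ll)
  attr(out, "by_individual") <- ll
  out
}

#' Conditional genotype probabilities on a grid
#'
#' Forward-backward posterior probabilities of the PP/PL/LL founder
#' genotypes at every marker and at grid positions every `step_cM`,
#' conditioned on all flanking markers and the error rate: the substrate
#' for Haley-Knott interval mapping.
#'
#' @param geno Individuals x markers matrix (codes 1-5, NA).
#' @param map Tibble with `marker`, `group`, `pos` (cM).
#' @param step_cM Grid step in cM (marker positions are always included).
#' @param error_prob One-step genotyping error rate.
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @return Object of class `genoprob`: per linkage group a list with
#'   `pos`, `prob` (n x 3 x P array), `a` (expected additive dosage,
#'   `P(LL) - P(PP)`), `d` (heterozygote probability).
#' @export
genotype_probs <- function(geno, map, step_cM = 1, error_prob = 0.01,
                           map_function = "haldane") {
  mf <- map_fun(map_function)
  groups <- sort(unique(map$group))
  out <- lapply(groups, function(g) {
    mg <- map[map$group == g, ]
    mg <- mg[order(mg$pos), ]
    G <- geno[, mg$marker, drop = FALSE]
    grid <- sort(unique(c(mg$pos, seq(0, max(mg$pos), by = step_cM))))
    .fb_chrom(G, mg$pos, grid, error_prob, mf)
  })
  names(out) <- as.character(groups)
  structure(out, class = "genoprob")
}

# Forward-backward on one chromosome. Steps are markers plus evaluation
# positions interleaved by position (markers first at ties, r = 0 between
# co-located steps); posteriors are read at the evaluation steps.
.fb_chrom <- function(G, pos_m, grid, error_prob, mf) {
  n <- nrow(G); m <- ncol(G); P <- length(grid)
  step_pos <- c(pos_m, grid)
  step_obs <- c(seq_len(m), rep(NA_integer_, P)) # marker column or NA
  o <- order(step_pos, is.na(step_obs) * 1L)     # markers before eval steps
  step_pos <- step_pos[o]; step_obs <- step_obs[o]
  S <- length(step_pos)
  rstep <- mf$r(diff(step_pos))
  Em <- emission_matrix(max(error_prob, 1e-12))
  emis_at <- function(k) {
    if (is.na(step_obs[k])) matrix(1, n, 3) else .emis(G[, step_obs[k]], Em)
  }
  Ts <- lapply(rstep, f2_transition)

  alphas <- vector("list", S)
  alpha <- matrix(F2_PRIOR, n, 3, byrow = TRUE) * emis_at(1)
  alpha <- alpha / pmax(rowSums(alpha), 1e-300)
  alphas[[1]] <- alpha
  for (k in seq_len(S - 1)) {
    alpha <- (alpha %*% Ts[[k]]) * emis_at(k + 1)
    alpha <- alpha / pmax(rowSums(alpha), 1e-300)
    alphas[[k + 1]] <- alpha
  }
  beta <- matrix(1, n, 3)
  post <- array(0, c(n, 3, S))
  post[, , S] <- alphas[[S]]
  for (k in seq(S - 1, 1, length.out = max(S - 1, 0))) {
    beta <- (beta * emis_at(k + 1)) %*% t(Ts[[k]])
    beta <- beta / pmax(rowSums(beta), 1e-300)
    p <- alphas[[k]] * beta
    post[, , k] <- p / pmax(rowSums(p), 1e-300)
  }
  eval_idx <- which(is.na(step_obs))
  prob <- post[, , eval_idx, drop = FALSE]
  dimnames(prob) <- list(rownames(G), c("PP", "PL", "LL"), NULL)
  list(
    pos = step_pos[eval_idx],
    prob = prob,
    a = prob[, 3, ] - prob[, 1, ],
    d = prob[, 2, ]
  )
}

#' Error-LOD scores for individual genotype calls
#'
#' For every non-missing call, the log10 posterior odds that the call is
#' erroneous versus correct given the two nearest informative flanking
#' markers of the same individual (one flank at chromosome ends),
#' following the flanking-marker logic of Lincoln and Lander.
#'
#' @inheritParams genotype_probs
#' @param error_prob Error rate used in the emission model.
#' @return A tibble: `id`, `marker`, `group`, `error_lod`.
#' @export
error_lod <- function(geno, map, error_prob = 0.01,
                      map_function = "haldane") {
  mf <- map_fun(map_function)
  Em <- emission_matrix(max(error_prob, 1e-12))
  out <- list()
  for (g in sort(unique(map$group))) {
    mg <- map[map$group == g, ]
    mg <- mg[order(mg$pos), ]
    G <- geno[, mg$marker, drop = FALSE]
    m <- ncol(G)
    res <- matrix(NA_real_, nrow(G), m,
                  dimnames = list(rownames(G), mg$marker))
    for (i in seq_len(nrow(G))) {
      idx <- which(!is.na(G[i, ]))
      if (length(idx) < 2) next
      for (jj in seq_along(idx)) {
        k <- idx[jj]
        obs <- G[i, k]
        lft <- if (jj > 1) idx[jj - 1] else NA
        rgt <- if (jj < length(idx)) idx[jj + 1] else NA
        pri <- F2_PRIOR
        if (!is.na(lft)) {
          Sl <- .OBS_SETS[[G[i, lft]]]
          Tl <- f2_transition(mf$r(mg$pos[k] - mg$pos[lft]))
          pri <- colSums((F2_PRIOR[Sl]) * Tl[Sl, , drop = FALSE])
        }
        if (!is.na(rgt)) {
          Sr <- .OBS_SETS[[G[i, rgt]]]
          Tr <- f2_transition(mf$r(mg$pos[rgt] - mg$pos[k]))
          pri <- pri * rowSums(Tr[, Sr, drop = FALSE])
        }
        pri <- pri / sum(pri)
        w <- pri * Em[, obs]
        inset <- seq_len(3) %in% .OBS_SETS[[obs]]
        res[i, k] <- log10(pmax(sum(w[!inset]), 1e-300) /
                             pmax(sum(w[inset]), 1e-300))
      }
    }
    out[[as.character(g)]] <- tibble::tibble(
      id = rep(rownames(G), m),
      marker = rep(mg$marker, each = nrow(G)),
      group = g,
      error_lod = as.vector(res)
    )
  }
  dplyr::filter(dplyr::bind_rows(out), !is.na(.data$error_lod))
}

#' Convert probable genotyping errors to missing data
#'
#' @param geno Individuals x markers matrix.
#' @param elod Tibble from [error_lod()].
#' @param threshold Error-LOD threshold (default 6).
#' @return List: `geno` (cleaned matrix), `n_converted`, `converted`
#'   (tibble of the affected calls).
#' @export
clean_genotypes <- function(geno, elod, threshold = 6) {
  bad <- dplyr::filter(elod, .data$error_lod > threshold)
  g <- geno
  if (nrow(bad)) {
    g[cbind(match(bad$id, rownames(g)), match(bad$marker, colnames(g)))] <-
      NA_integer_
  }
  list(geno = g, n_converted = nrow(bad), converted = bad)
}

#' Maximum-likelihood genotyping error rate
#'
#' Maximizes the summed multipoint HMM likelihood of all linkage groups
#' over the one-step error rate on `[0, 0.1]` (golden-section search via
#' [stats::optimize()]).
#'
#' @inheritParams genotype_probs
#' @return The estimated error rate.
#' @export
estimate_error_rate <- function(geno, map, map_function = "haldane") {
  mf <- map_fun(map_function)
  groups <- sort(unique(map$group))
  pieces <- lapply(groups, function(g) {
    mg <- map[map$group == g, ]
    mg <- mg[order(mg$pos), ]
    list(G = geno[, mg$marker, drop = FALSE], r = mf$r(diff(mg$pos)))
  })
  nll <- function(e) {
    -sum(vapply(pieces, function(p) as.numeric(hmm_loglik(p$G, p$r, e)),
                numeric(1)))
  }
  stats::optimize(nll, c(1e-6, 0.1))$minimum
}

#' Minimal crossover counts per individual
#'
#' Counts the minimum number of recombination events implied by adjacent
#' codominant calls on each linkage group, used to spot individuals with
#' excess apparent crossovers (a signature of high genotyping error).
#'
#' @inheritParams genotype_probs
#' @return A tibble: `id`, `n_crossovers`.
#' @export
count_crossovers <- function(geno, map) {
  total <- stats::setNames(rep(0, nrow(geno)), rownames(geno))
  for (g in sort(unique(map$group))) {
    mg <- map[map$group == g, ]
    mg <- mg[order(mg$pos), ]
    G <- geno[, mg$marker, drop = FALSE]
    G[G > 3] <- NA
    for (i in seq_len(nrow(G))) {
      v <- G[i, !is.na(G[i, ])]
      if (length(v) > 1) total[i] <- total[i] + sum(abs(diff(v)))
    }
  }
  tibble::tibble(id = names(total), n_crossovers = unname(total))
}
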
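# Fully multivariate QTL scan: Y = XB + e at each position, with the
# Pillai-Bartlett trace testing the marker's additive and dominance
# columns against the intercept+family null, and genome-wide thresholds
# from within-family permutation of phenotype row-vectors.

# Pillai-Bartlett trace and F approximation for adding q columns to a
# fitted null: E and H are residual and hypothesis cross-product matrices.
.pillai_test <- function(E0, E1, q, df_res, p) {
  H <- E0 - E1
  V <- sum(diag(H %*% solve(H + E1)))
  s <- min(p, q)
  m <- (abs(p - q) - 1) / 2
  nn <- (df_res - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  Fstat <- (df2 / df1) * V / (s - V)
  list(pillai = V, F = Fstat, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Multivariate QTL scan with the Pillai-Bartlett statistic
#'
#' At every grid position fits `Y = XB + e`, with X holding the intercept,
#' G2 family, and the marker's additive and dominance dosages, on the
#' complete-case individuals for the chosen traits. The position's
#' Pillai-Bartlett trace (against the intercept+family null) is converted
#' to a p-value by the standard F approximation; a genome-wide threshold
#' comes from permuting phenotype row-vectors among individuals within G2
#' families.
#'
#' @param phenotypes Tibble with `id`, `family` and the trait columns.
#' @param probs A `genoprob` object.
#' @param traits Character vector of trait columns (complete cases used).
#' @param n_perm Structured permutations for the threshold (0 = none).
#' @param alpha Genome-wide level.
#' @param seed Permutation seed.
#' @return Object of class `mv_scan`: `scan` (tibble: group, pos, pillai,
#'   F, p), `threshold` (on the Pillai trace), `perm_max`, `n`, `traits`.
#' @export
scan_multivariate <- function(phenotypes, probs, traits, n_perm = 0,
                              alpha = 0.05, seed = 1L) {
  ph <- phenotypes[stats::complete.cases(phenotypes[traits]) &
                     phenotypes$id %in% rownames(probs[[1]]$prob), ]
  Y <- as.matrix(ph[traits])
  n <- nrow(Y); p <- length(traits)
  n_par <- length(unique(ph$family)) + 2
  if (n <= n_par + p) {
    stop("fewer complete cases than model parameters")
  }
  fam <- factor(ph$family)
  X0 <- stats::model.matrix(~fam)
  rows <- match(ph$id, rownames(probs[[1]]$prob))
  ptab <- .prob_positions(probs)

  set.seed(seed)
  perms <- if (n_perm > 0) {
    lapply(seq_len(n_perm), function(i) {
      idx <- seq_len(n)
      for (f in levels(fam)) {
        w <- which(fam == f)
        idx[w] <- w[sample.int(length(w))]
      }
      idx
    })
  } else list()

  q0 <- qr(X0)
  scan_once <- function(Yc) {
    E0r <- qr.resid(q0, Yc)
    E0 <- crossprod(E0r)
    res <- matrix(NA_real_, nrow(ptab), 3)
    for (g in names(probs)) {
      sel <- which(ptab$group == g)
      A <- probs[[g]]$a[rows, , drop = FALSE]
      D <- probs[[g]]$d[rows, , drop = FALSE]
      for (k in seq_along(sel)) {
        X1 <- cbind(X0, A[, k], D[, k])
        q1 <- qr(X1)
        E1 <- crossprod(qr.resid(q1, Yc))
        pt <- .pillai_test(E0, E1, q = q1$rank - q0$rank,
                           df_res = n - q1$rank, p = p)
        res[sel[k], ] <- c(pt$pillai, pt$F, pt$p)
      }
    }
    res
  }

  obs <- scan_once(Y)
  perm_max <- vapply(perms, function(idx) {
    max(scan_once(Y[idx, , drop = FALSE])[, 1], na.rm = TRUE)
  }, numeric(1))
  threshold <- if (n_perm > 0) {
    as.numeric(stats::quantile(perm_max, 1 - alpha))
  } else NA_real_

  structure(
    list(
      scan = tibble::tibble(group = ptab$group, pos = ptab$pos,
                            pillai = obs[, 1], F = obs[, 2], p = obs[, 3]),
      threshold = threshold, perm_max = perm_max,
      n = n, traits = traits, n_perm = n_perm, alpha = alpha
    ),
    class = "mv_scan"
  )
}

#' @export
print.mv_scan <- function(x, ...) {
  cat("<mv_scan>", paste(x$traits, collapse = " + "), "on", x$n,
      "complete cases\n")
  pk <- x$scan[which.max(x$scan$pillai), ]
  cat("  peak: group", pk$group, "at", round(pk$pos, 1),
      "cM, Pillai", round(pk$pillai, 3), ", p =", signif(pk$p, 2), "\n")
  if (!is.na(x$threshold)) {
    cat("  genome-wide Pillai threshold:", round(x$threshold, 3), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.mv_scan <- function(x, ...) x$scan

#' Reduced multivariate QTL model with standardized effects
#'
#' Fits the multivariate model with additive and dominance columns for
#' each declared QTL plus family, backward-prunes effect columns whose
#' multivariate (Pillai) p-value is at or above `prune_p`, and reports the
#' retained coefficients on traits standardized to unit variance, i.e.
#' effect vectors in units of G2 phenotypic standard deviations.
#'
#' @inheritParams scan_multivariate
#' @param qtl Tibble of QTL: `group`, `pos`, optional `name`.
#' @param prune_p Retention threshold for effect columns (default 0.01).
#' @return A list of class `mv_fit`: `effects` (terms x traits tibble of
#'   standardized coefficients), `retained`, `dropped`, `fit`.
#' @export
reduce_multivariate_model <- function(phenotypes, probs, traits, qtl,
                                      prune_p = 0.01) {
  ph <- phenotypes[stats::complete.cases(phenotypes[traits]) &
                     phenotypes$id %in% rownames(probs[[1]]$prob), ]
  Ys <- scale(as.matrix(ph[traits]))
  fam <- factor(ph$family)
  qtl <- dplyr::mutate(qtl, name = .qtl_names(qtl))
  X <- .qtl_design(probs, qtl, ph$id)
  terms <- names(X)
  repeat {
    Xf <- cbind(stats::model.matrix(~fam), as.matrix(X[terms]))
    qf <- qr(Xf)
    Ef <- crossprod(qr.resid(qf, Ys))
    worst <- NULL; worst_p <- -1
    for (tm in terms) {
      Xr <- cbind(stats::model.matrix(~fam),
                  as.matrix(X[setdiff(terms, tm)]))
      Er <- crossprod(qr.resid(qr(Xr), Ys))
      pt <- .pillai_test(Er, Ef, q = 1, df_res = nrow(Ys) - qf$rank,
                         p = ncol(Ys))
      if (pt$p > worst_p) { worst_p <- pt$p; worst <- tm }
    }
    if (worst_p >= prune_p && length(terms) > 1) {
      terms <- setdiff(terms, worst)
    } else break
  }
  Xf <- cbind(stats::model.matrix(~fam), as.matrix(X[terms]))
  B <- qr.coef(qr(Xf), Ys)
  eff <- tibble::as_tibble(B, rownames = "term")
  structure(
    list(effects = eff, retained = terms,
         dropped = setdiff(names(X), terms),
         n = nrow(Ys), traits = traits),
    class = "mv_fit"
  )
}
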
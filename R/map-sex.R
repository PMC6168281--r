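# Sex-linked (X) linkage group: X-informative SNPs are those segregating
# as AAxBY or BBxAY; SNPs segregating as fixed X/Y differences diagnose
# sex but carry no mapping information.

# Maternal-origin allele (1/2) of each G2 at an X-informative SNP; the F1
# mother is heterozygous A/B, daughters additionally carry the paternal X
# (the sire's maternally inherited allele).
.x_maternal_allele <- function(calls, sexes, config) {
  out <- rep(NA_integer_, length(calls))
  if (config == "AAxBY") {
    # daughters: AA -> maternal A, AB -> maternal B; sons: AA/BB hemizygous
    out[sexes == "F" & calls == 1L] <- 1L
    out[sexes == "F" & calls == 2L] <- 2L
    out[sexes == "M" & calls == 1L] <- 1L
    out[sexes == "M" & calls == 3L] <- 2L
  } else if (config == "BBxAY") {
    out[sexes == "F" & calls == 3L] <- 2L
    out[sexes == "F" & calls == 2L] <- 1L
    out[sexes == "M" & calls == 1L] <- 1L
    out[sexes == "M" & calls == 3L] <- 2L
  }
  out
}

#' Assemble and order the X-linked linkage group
#'
#' Retains SNPs with informative X-linked segregation (`AAxBY`, `BBxAY`),
#' converts each G2 to its maternal-origin X allele, estimates pairwise
#' recombination fractions under the single-meiosis (two-state) model,
#' and orders the markers by the same seriation/ripple search as the
#' autosomes. SNPs segregating as fixed X/Y differences are excluded from
#' the map but returned as sex diagnostics.
#'
#' @param snps Long SNP tibble.
#' @param segregation A `segregation` object from [infer_segregation()].
#' @param pedigree Pedigree tibble.
#' @param min_informative Minimum informative G2 calls per SNP.
#' @param ripple_window,n_restarts,seed As [order_markers()].
#' @return A list of class `x_map`: `map` (tibble snp_id/pos),
#'   `maternal_allele` (matrix of G2 maternal alleles), `diagnostic`
#'   (fixed X/Y SNP ids), `loglik`.
#' @export
assemble_sex_linked <- function(snps, segregation, pedigree,
                                min_informative = 20,
                                ripple_window = 7, n_restarts = 20,
                                seed = 1L) {
  pat <- segregation$patterns
  info_ids <- pat$snp_id[pat$config %in% c("AAxBY", "BBxAY") &
                           !is.na(pat$config)]
  diag_ids <- pat$snp_id[pat$config %in% c("fixedXY_A", "fixedXY_B") &
                           !is.na(pat$config)]
  if (!length(info_ids)) {
    return(structure(list(map = tibble::tibble(snp_id = character(0),
                                               pos = numeric(0)),
                          maternal_allele = NULL, diagnostic = diag_ids,
                          loglik = NA_real_), class = "x_map"))
  }
  G <- snp_matrix(dplyr::filter(snps, .data$snp_id %in% info_ids))
  g2 <- pedigree[pedigree$generation == "G2", ]
  G <- G[intersect(rownames(G), g2$id), info_ids, drop = FALSE]
  sexes <- g2$sex[match(rownames(G), g2$id)]
  M <- matrix(NA_integer_, nrow(G), ncol(G), dimnames = dimnames(G))
  for (j in seq_len(ncol(G))) {
    cfg <- pat$config[pat$snp_id == colnames(G)[j]]
    M[, j] <- .x_maternal_allele(G[, j], sexes, cfg)
  }
  keep <- colSums(!is.na(M)) >= min_informative
  M <- M[, keep, drop = FALSE]
  if (ncol(M) < 2) {
    return(structure(list(
      map = tibble::tibble(snp_id = colnames(M),
                           pos = rep(0, ncol(M))),
      maternal_allele = M, diagnostic = diag_ids, loglik = NA_real_
    ), class = "x_map"))
  }

  # two-state pairwise rf: mismatch fraction, flipped if > 0.5
  m <- ncol(M)
  theta <- matrix(NA_real_, m, m); lod <- matrix(NA_real_, m, m)
  phase <- matrix(1L, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    ok <- !is.na(M[, i]) & !is.na(M[, j])
    n <- sum(ok)
    if (n < 10) next
    mism <- sum(M[ok, i] != M[ok, j])
    ph <- 1L
    if (mism > n / 2) { mism <- n - mism; ph <- -1L }
    th <- max(min(mism / n, 0.4999), 1e-6)
    ll <- mism * log(th) + (n - mism) * log(1 - th) - n * log(0.5)
    theta[i, j] <- theta[j, i] <- th
    lod[i, j] <- lod[j, i] <- ll / log(10)
    phase[i, j] <- phase[j, i] <- ph
  }
  dimnames(theta) <- dimnames(lod) <- dimnames(phase) <-
    list(colnames(M), colnames(M))

  lodm <- lod; lodm[is.na(lodm)] <- 0
  set.seed(seed)
  ord <- .ripple(.chain_order(lodm, which.max(colSums(lodm))),
                 lodm, ripple_window)
  if (ord[1] > ord[length(ord)]) ord <- rev(ord)
  th <- theta[cbind(ord[-m], ord[-1])]
  th[is.na(th)] <- 0.25
  pos <- c(0, cumsum(haldane_d(th)))
  structure(
    list(
      map = tibble::tibble(snp_id = colnames(M)[ord], pos = pos),
      maternal_allele = M[, ord, drop = FALSE],
      diagnostic = diag_ids,
      loglik = .adj_score(ord, lodm)
    ),
    class = "x_map"
  )
}
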
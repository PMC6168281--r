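# Marker ordering within a linkage group: phase orientation, greedy
# seriation from pairwise linkage, window-permutation ripple refinement,
# seeded restarts scored by the multipoint HMM likelihood.

# Orient markers to a consistent linkage phase along a maximum-LOD
# spanning tree; returns the flip indicator per marker.
.orient_flags <- function(lod, phase) {
  m <- ncol(lod)
  flip <- rep(NA, m)
  lod[is.na(lod)] <- -Inf
  for (root in seq_len(m)) {
    if (!is.na(flip[root])) next
    flip[root] <- FALSE
    repeat {
      done <- !is.na(flip)
      cand <- which(!done)
      if (!length(cand)) break
      sub <- lod[done, cand, drop = FALSE]
      if (all(!is.finite(sub))) break
      w <- arrayInd(which.max(sub), dim(sub))
      from <- which(done)[w[1]]; to <- cand[w[2]]
      ph <- phase[from, to]
      if (is.na(ph)) ph <- 1L
      flip[to] <- xor(flip[from], ph == -1L)
    }
  }
  flip[is.na(flip)] <- FALSE
  flip
}

flip_geno <- function(geno, flip) {
  for (j in which(flip)) {
    geno[, j] <- FLIP_CODES[geno[, j]]
  }
  geno
}

# all permutations of 1..n (n small)
.perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

.chain_order <- function(lodm, start) {
  m <- ncol(lodm)
  lodm[is.na(lodm)] <- 0
  placed <- start
  left <- setdiff(seq_len(m), start)
  while (length(left)) {
    ends <- c(placed[1], placed[length(placed)])
    sub <- lodm[ends, left, drop = FALSE]
    w <- arrayInd(which.max(sub), dim(sub))
    mk <- left[w[2]]
    if (w[1] == 1) placed <- c(mk, placed) else placed <- c(placed, mk)
    left <- setdiff(left, mk)
  }
  placed
}

.adj_score <- function(ord, lodm) {
  sum(lodm[cbind(ord[-length(ord)], ord[-1])], na.rm = TRUE)
}

# Ripple: permute all windows of the given size, keeping the order with
# the best two-point adjacency score, until no window improves it.
.ripple <- function(ord, lodm, window) {
  m <- length(ord)
  w <- min(window, m)
  if (w < 2) return(ord)
  perms <- .perms(w)
  lodm[is.na(lodm)] <- 0
  repeat {
    improved <- FALSE
    for (s in seq_len(m - w + 1)) {
      idx <- s:(s + w - 1)
      block <- ord[idx]
      cand <- matrix(block[perms], nrow(perms))
      # score adjacent pairs inside the window plus its boundary edges
      sc <- rep(0, nrow(perms))
      for (k in seq_len(w - 1)) {
        sc <- sc + lodm[cbind(cand[, k], cand[, k + 1])]
      }
      if (s > 1) sc <- sc + lodm[cbind(ord[s - 1], cand[, 1])]
      if (s + w <= m) sc <- sc + lodm[cbind(cand[, w], ord[s + w])]
      best <- which.max(sc)
      if (sc[best] > sc[1] + 1e-9) {
        ord[idx] <- cand[best, ]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  ord
}

#' Order the markers of one linkage group
#'
#' Greedy seriation from pairwise linkage followed by exhaustive
#' window-permutation ("ripple") refinement of the stated window, repeated
#' over seeded restarts; completed candidate orders are compared by their
#' multipoint HMM likelihood and the best retained. Orientation of the
#' whole group is arbitrary; the returned order is canonicalized so the
#' first marker's column index precedes the last's.
#'
#' @param geno Individuals x markers matrix restricted to one group
#'   (codes 1-5, NA); dominant-coded and phase-ambiguous markers are
#'   handled through the pairwise likelihoods.
#' @param rf Optional precomputed [rf_matrix()] for these markers.
#' @param n_restarts Number of seeded seriation restarts (default 20).
#' @param ripple_window Window size for the permutation search (default 7).
#' @param error_prob Error rate for the multipoint likelihood.
#' @param seed RNG seed for restart starting points.
#' @return A list: `map` (tibble marker/pos in cM), `order`, `flip`
#'   (phase-flip indicator per input column), `loglik`, `geno` (oriented,
#'   reordered matrix).
#' @export
order_markers <- function(geno, rf = NULL, n_restarts = 20,
                          ripple_window = 7, error_prob = 0.01,
                          seed = 1L, orient = TRUE) {
  m <- ncol(geno)
  if (is.null(rf)) rf <- rf_matrix(geno)
  if (m <= 2) {
    flip <- if (m == 2 && orient) {
      .orient_flags(rf$lod, rf$phase)
    } else rep(FALSE, m)
    g2 <- flip_geno(geno, flip)
    pos <- if (m == 2) {
      th <- min(rf$theta[1, 2] %||% 0.25, 0.4999)
      c(0, haldane_d(ifelse(is.na(th), 0.25, th)))
    } else 0
    return(list(
      map = tibble::tibble(marker = colnames(geno), pos = pos),
      order = seq_len(m), flip = flip,
      loglik = NA_real_, geno = g2
    ))
  }
  set.seed(seed)
  flip <- if (orient) .orient_flags(rf$lod, rf$phase) else rep(FALSE, m)
  g2 <- flip_geno(geno, flip)
  lodm <- rf$lod
  starts <- sample.int(m, min(n_restarts, m))
  best <- NULL
  for (s in starts) {
    ord <- .chain_order(lodm, s)
    ord <- .ripple(ord, lodm, ripple_window)
    th <- rf$theta[cbind(ord[-m], ord[-1])]
    th[is.na(th)] <- 0.25
    ll <- as.numeric(hmm_loglik(g2[, ord, drop = FALSE],
                                pmin(th, 0.4999), error_prob))
    if (is.null(best) || ll > best$ll + 1e-9) {
      best <- list(ord = ord, ll = ll)
    }
  }
  ord <- best$ord
  if (ord[1] > ord[length(ord)]) ord <- rev(ord)
  # adjacent distances from refitted pairwise estimates
  th <- numeric(m - 1)
  for (k in seq_len(m - 1)) {
    e <- estimate_rf(g2[, ord[k]], g2[, ord[k + 1]])
    th[k] <- if (is.na(e$theta)) 0.25 else min(e$theta, 0.45)
  }
  pos <- c(0, cumsum(haldane_d(th)))
  list(
    map = tibble::tibble(marker = colnames(geno)[ord], pos = pos),
    order = ord, flip = flip, loglik = best$ll,
    geno = g2[, ord, drop = FALSE]
  )
}
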
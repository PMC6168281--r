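# Family-structured genome scans: Haley-Knott (or logistic) regression of
# the phenotype on expected genotype dosages, run separately within each
# half-sib G2 family and summed, with genome-wide thresholds from
# within-family permutations.

# flatten a genoprob object into a position table plus per-group arrays
.prob_positions <- function(probs) {
  dplyr::bind_rows(lapply(names(probs), function(g) {
    tibble::tibble(group = g, pos = probs[[g]]$pos,
                   idx = seq_along(probs[[g]]$pos))
  }))
}

#' Family-structured QTL scan
#'
#' At every grid position, regresses the trait on the expected additive
#' (`a = P(LL) - P(PP)`) and dominance (`d = P(PL)`) dosages separately
#' within each G2 family and sums the per-family LOD scores. Normal-model
#' LOD is `(n_f/2) log10(RSS0/RSS1)`; the binary model uses logistic
#' regression with LOD = LRT / (2 ln 10). Maternal-effect traits are
#' scanned by attaching the G3 brood mean to the G2 mother, which the
#' phenotype table already encodes (the trait is simply missing for
#' non-mothers).
#'
#' When `n_perm > 0` the same scan is applied to phenotype vectors
#' permuted among individuals within (never across) families, and the
#' genome-wide 95th percentile of the maximum summed LOD becomes the
#' significance threshold.
#'
#' @param phenotypes Tibble with `id`, `family` and the trait column.
#' @param probs A `genoprob` object from [genotype_probs()].
#' @param trait Name of the trait column.
#' @param model `"normal"` or `"binary"`.
#' @param n_perm Number of structured permutations (0 = no threshold).
#' @param alpha Genome-wide significance level for the threshold.
#' @param seed Seed for the permutation streams.
#' @param min_family Families with fewer phenotyped individuals are
#'   excluded with a warning.
#' @return Object of class `scan_result`: list with `scan` (tibble:
#'   group, pos, lod), `family_lod` (positions x families matrix),
#'   `threshold`, `perm_max`, `trait`, `model`, `n_perm`, `families`.
#' @export
scan_structured <- function(phenotypes, probs, trait,
                            model = c("normal", "binary"),
                            n_perm = 0, alpha = 0.05, seed = 1L,
                            min_family = 5) {
  model <- match.arg(model)
  ptab <- .prob_positions(probs)
  ids_prob <- rownames(probs[[1]]$prob)
  ph <- phenotypes[!is.na(phenotypes[[trait]]) &
                     phenotypes$id %in% ids_prob, ]
  fams <- sort(unique(ph$family))
  keep <- vapply(fams, function(f) sum(ph$family == f) >= min_family,
                 logical(1))
  if (any(!keep)) {
    warning("excluding families with < ", min_family,
            " phenotyped individuals: ",
            paste(fams[!keep], collapse = ", "))
  }
  fams <- fams[keep]
  if (!length(fams)) stop("no family has enough phenotyped individuals")

  set.seed(seed)
  npos <- nrow(ptab)
  ncol_y <- n_perm + 1L
  fam_lod_obs <- matrix(0, npos, length(fams),
                        dimnames = list(NULL, fams))
  sum_lod <- matrix(0, npos, ncol_y)

  for (fi in seq_along(fams)) {
    f <- fams[fi]
    ids <- ph$id[ph$family == f]
    y <- ph[[trait]][ph$family == f]
    n_f <- length(ids)
    Y <- matrix(y, n_f, ncol_y)
    if (n_perm > 0) {
      for (p in 2:ncol_y) Y[, p] <- y[sample.int(n_f)]
    }
    rows <- match(ids, ids_prob)
    if (model == "normal") {
      ySS <- colSums(Y^2)
      css <- ySS - colSums(Y)^2 / n_f # RSS under the null
      for (g in names(probs)) {
        sel <- which(ptab$group == g)
        A <- probs[[g]]$a[rows, , drop = FALSE]
        D <- probs[[g]]$d[rows, , drop = FALSE]
        for (k in seq_along(sel)) {
          X <- cbind(1, A[, k], D[, k])
          qr_x <- qr(X)
          Qy <- qr.qty(qr_x, Y)[seq_len(qr_x$rank), , drop = FALSE]
          rss <- pmax(ySS - colSums(Qy^2), 1e-12)
          lod <- (n_f / 2) * log10(pmax(css, 1e-12) / rss)
          sum_lod[sel[k], ] <- sum_lod[sel[k], ] + lod
          fam_lod_obs[sel[k], fi] <- lod[1]
        }
      }
    } else {
      for (g in names(probs)) {
        sel <- which(ptab$group == g)
        A <- probs[[g]]$a[rows, , drop = FALSE]
        D <- probs[[g]]$d[rows, , drop = FALSE]
        for (k in seq_along(sel)) {
          X <- cbind(1, A[, k], D[, k])
          for (p in seq_len(ncol_y)) {
            lod <- .logistic_lod(X, Y[, p])
            sum_lod[sel[k], p] <- sum_lod[sel[k], p] + lod
            if (p == 1) fam_lod_obs[sel[k], fi] <- lod
          }
        }
      }
    }
  }

  perm_max <- if (n_perm > 0) {
    apply(sum_lod[, -1, drop = FALSE], 2, max)
  } else numeric(0)
  threshold <- if (n_perm > 0) {
    if (n_perm < 100) {
      warning("threshold from fewer than 100 permutations is unstable")
    }
    as.numeric(stats::quantile(perm_max, 1 - alpha))
  } else NA_real_

  structure(
    list(
      scan = tibble::tibble(group = ptab$group, pos = ptab$pos,
                            lod = sum_lod[, 1]),
      family_lod = fam_lod_obs,
      threshold = threshold, perm_max = perm_max,
      trait = trait, model = model, n_perm = n_perm, alpha = alpha,
      families = fams
    ),
    class = "scan_result"
  )
}

# logistic-regression LOD at one position: LRT/(2 ln 10), ridge-stabilized
# if the fit separates.
.logistic_lod <- function(X, y) {
  if (length(unique(y)) < 2) return(0)
  dev0 <- .binom_dev(rep(mean(y), length(y)), y)
  fit <- suppressWarnings(stats::glm.fit(X, y,
                                         family = stats::binomial()))
  dev1 <- fit$deviance
  if (!fit$converged || any(abs(fit$coefficients) > 15, na.rm = TRUE)) {
    # near-separation: data-augmentation ridge keeps the LRT finite
    fit <- suppressWarnings(stats::glm.fit(
      rbind(X, 0.1 * diag(ncol(X))),
      c(y, rep(0.5, ncol(X))),
      family = stats::binomial()
    ))
    dev1 <- .binom_dev(fit$fitted.values[seq_along(y)], y)
  }
  max((dev0 - dev1) / (2 * log(10)), 0)
}

.binom_dev <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Genome-wide threshold from structured permutations
#'
#' Convenience wrapper around [scan_structured()] that returns the
#' threshold alone: phenotypes are permuted among individuals within (but
#' not among) G2 families, and the `1 - alpha` quantile of the
#' genome-wide maximum summed LOD is reported.
#'
#' @inheritParams scan_structured
#' @param n Number of permutations (default 1000).
#' @return A list: `threshold`, `perm_max`.
#' @export
permute_structured <- function(phenotypes, probs, trait,
                               model = c("normal", "binary"),
                               n = 1000, alpha = 0.05, seed = 1L) {
  sc <- scan_structured(phenotypes, probs, trait, model = model,
                        n_perm = n, alpha = alpha, seed = seed)
  list(threshold = sc$threshold, perm_max = sc$perm_max)
}

#' @export
print.scan_result <- function(x, ...) {
  cat("<scan_result>", x$trait, "(", x$model, "model ),",
      nrow(x$scan), "positions,", length(x$families), "families\n")
  pk <- x$scan[which.max(x$scan$lod), ]
  cat("  peak: group", pk$group, "at", round(pk$pos, 1), "cM, LOD",
      round(pk$lod, 2), "\n")
  if (!is.na(x$threshold)) {
    cat("  genome-wide threshold (alpha =", x$alpha, "):",
        round(x$threshold, 2), "from", x$n_perm, "permutations\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.scan_result <- function(x, ...) x$scan

#' @importFrom generics glance
#' @export
glance.scan_result <- function(x, ...) {
  pk <- x$scan[which.max(x$scan$lod), ]
  tibble::tibble(
    trait = x$trait, model = x$model,
    peak_group = pk$group, peak_pos = pk$pos, peak_lod = pk$lod,
    threshold = x$threshold, n_perm = x$n_perm,
    significant = if (is.na(x$threshold)) NA else pk$lod > x$threshold
  )
}

#' Peaks of a scan exceeding the threshold
#'
#' @param x A `scan_result`.
#' @param threshold Override the stored permutation threshold.
#' @return Tibble of per-group maxima above the threshold.
#' @export
scan_peaks <- function(x, threshold = NULL) {
  thr <- threshold %||% x$threshold
  x$scan |>
    dplyr::group_by(.data$group) |>
    dplyr::slice_max(.data$lod, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::filter(is.na(thr) | .data$lod > thr)
}
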
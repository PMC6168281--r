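# End-to-end autosomal map construction from recoded intercross markers.

#' Build an autosomal linkage map
#'
#' Runs the full map-construction sequence on an intercross marker set:
#' pairwise recombination fractions, linkage grouping, per-group phase
#' orientation and marker ordering, removal of individuals with excess
#' crossovers, error-LOD cleaning of probable bad calls, and
#' maximum-likelihood re-estimation of the genotyping error rate (with
#' re-ordering after cleaning).
#'
#' @param markers An `intercross_markers` object (or a genotype matrix).
#' @param lod_limit,join_limit,lod_difference Grouping thresholds, as
#'   [group_markers()].
#' @param n_restarts,ripple_window Ordering search controls.
#' @param error_lod_threshold Calls above this error LOD become missing.
#' @param error_prob Initial error rate for ordering likelihoods.
#' @param xo_outlier_sd Individuals whose crossover count exceeds the mean
#'   by more than this many SDs are dropped before final ordering.
#' @param max_missing Markers missing in more than this fraction of
#'   individuals are excluded before mapping.
#' @param seed Seed for the ordering restarts.
#' @return An object of class `genetic_map`: list with `map` (tibble:
#'   marker, group, pos), `geno` (cleaned, oriented genotype matrix),
#'   `flipped` (named logical: marker orientation flipped relative to
#'   input), `error_rate`, `n_cleaned`, `dropped_individuals`,
#'   `unassigned` (markers without a group).
#' @export
build_linkage_map <- function(markers,
                              lod_limit = 15, join_limit = 10,
                              lod_difference = 5,
                              n_restarts = 20, ripple_window = 7,
                              error_lod_threshold = 6,
                              error_prob = 0.01,
                              xo_outlier_sd = 4,
                              max_missing = 0.10,
                              seed = 1L) {
  geno <- if (inherits(markers, "intercross_markers")) markers$geno
          else as.matrix(markers)
  geno <- geno[, colMeans(is.na(geno)) <= max_missing, drop = FALSE]
  rf <- rf_matrix(geno)
  grp <- group_markers(rf, lod_limit, join_limit, lod_difference)
  unassigned <- grp$marker[is.na(grp$group)]

  # orient each group's markers to a consistent linkage phase once;
  # ordering passes below never re-orient
  flips <- stats::setNames(rep(FALSE, ncol(geno)), colnames(geno))
  for (g in sort(unique(stats::na.omit(grp$group)))) {
    mk <- grp$marker[!is.na(grp$group) & grp$group == g]
    fl <- .orient_flags(rf$lod[mk, mk, drop = FALSE],
                        rf$phase[mk, mk, drop = FALSE])
    flips[mk] <- fl
    geno[, mk] <- flip_geno(geno[, mk, drop = FALSE], fl)
  }

  order_all <- function(geno) {
    maps <- list()
    for (g in sort(unique(stats::na.omit(grp$group)))) {
      mk <- intersect(grp$marker[!is.na(grp$group) & grp$group == g],
                      colnames(geno))
      sub_rf <- lapply(rf[c("theta", "lod", "phase")],
                       function(x) x[mk, mk, drop = FALSE])
      og <- order_markers(geno[, mk, drop = FALSE], rf = sub_rf,
                          n_restarts = n_restarts,
                          ripple_window = ripple_window,
                          error_prob = error_prob, seed = seed + g,
                          orient = FALSE)
      maps[[as.character(g)]] <- dplyr::mutate(og$map, group = g,
                                               .after = "marker")
      geno[, og$map$marker] <- og$geno
    }
    list(map = dplyr::bind_rows(maps), geno = geno)
  }

  built <- order_all(geno)

  # drop crossover outliers (excess apparent recombination = bad calls)
  xo <- count_crossovers(built$geno, built$map)
  bound <- mean(xo$n_crossovers) + xo_outlier_sd * stats::sd(xo$n_crossovers)
  dropped <- xo$id[xo$n_crossovers > bound]
  if (length(dropped)) {
    geno <- geno[setdiff(rownames(geno), dropped), , drop = FALSE]
    built <- order_all(geno)
  }

  eps1 <- estimate_error_rate(built$geno, built$map)
  el <- error_lod(built$geno, built$map, error_prob = eps1)
  cl <- clean_genotypes(built$geno, el, threshold = error_lod_threshold)
  eps2 <- estimate_error_rate(cl$geno, built$map)
  built2 <- order_all(cl$geno)

  structure(
    list(
      map = built2$map,
      geno = built2$geno,
      flipped = flips,
      error_rate = eps2,
      error_rate_pre_clean = eps1,
      n_cleaned = cl$n_converted,
      dropped_individuals = dropped,
      unassigned = unassigned
    ),
    class = "genetic_map"
  )
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("<genetic_map>", nrow(x$map), "markers in",
      length(unique(x$map$group)), "linkage groups\n")
  s <- x$map |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), length_cM = max(.data$pos),
                     .groups = "drop")
  print(as.data.frame(s), row.names = FALSE)
  cat("error rate:", signif(x$error_rate, 3),
      "| calls cleaned:", x$n_cleaned,
      "| individuals dropped:", length(x$dropped_individuals), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.genetic_map <- function(x, ...) x$map
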
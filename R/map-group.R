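# Linkage-group formation: single-linkage clustering at a LOD threshold,
# then singleton adoption with a runner-up margin.

#' Assign markers to linkage groups
#'
#' Single-linkage clustering of markers whose pairwise LOD reaches
#' `lod_limit`; markers left single are then joined to the group holding
#' their best LOD if it reaches `join_limit` and exceeds the best LOD to
#' any other group by at least `lod_difference`. Remaining markers stay
#' unassigned (`NA` group).
#'
#' @param rf Result of [rf_matrix()] (or any list with a `lod` matrix).
#' @param lod_limit LOD threshold for the initial clustering.
#' @param join_limit Minimum LOD for singleton adoption.
#' @param lod_difference Required margin over the runner-up group.
#' @return A tibble: `marker`, `group` (integer, ordered by group size,
#'   `NA` = unassigned).
#' @export
group_markers <- function(rf, lod_limit = 15, join_limit = 10,
                          lod_difference = 5) {
  lod <- rf$lod
  m <- ncol(lod)
  markers <- colnames(lod) %||% as.character(seq_len(m))
  adj <- !is.na(lod) & lod >= lod_limit
  # connected components by BFS
  comp <- rep(NA_integer_, m)
  cur <- 0L
  for (s in seq_len(m)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  sizes <- table(comp)
  group <- comp
  singles <- which(comp %in% as.integer(names(sizes)[sizes == 1]))
  group[singles] <- NA_integer_

  if (length(singles) && any(!is.na(group))) {
    gids <- sort(unique(stats::na.omit(group)))
    for (s in singles) {
      best <- vapply(gids, function(g) {
        suppressWarnings(max(lod[s, which(group == g)], na.rm = TRUE))
      }, numeric(1))
      best[!is.finite(best)] <- -Inf
      o <- order(best, decreasing = TRUE)
      top <- best[o[1]]
      second <- if (length(best) > 1) best[o[2]] else -Inf
      if (top >= join_limit && (top - second) >= lod_difference) {
        group[s] <- gids[o[1]]
      }
    }
  }

  # renumber by decreasing size
  tab <- sort(table(group), decreasing = TRUE)
  renum <- stats::setNames(seq_along(tab), names(tab))
  group <- unname(renum[as.character(group)])
  tibble::tibble(marker = markers, group = as.integer(group))
}
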
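# Recoding multi-SNP contigs (and single intercross SNPs) into
# founder-origin intercross markers. Marker pseudo-alleles are the two P0
# founders' contributions: a G2 genotype is 11/12/22 by the founder origin
# of its two contig haplotypes. In families where one F1 parent's two
# haplotypes are identical in state, the transmitted haplotype's origin is
# ambiguous and only dominant codes (not-11 / not-22) can be assigned.

# Enumerate haplotype-pair phasings of a multi-SNP genotype vector
# (codes 1-3). The first heterozygous site is fixed to break the
# hap1/hap2 labelling symmetry.
.enumerate_phases <- function(g, max_het = 6) {
  het <- which(g == 2L)
  base <- ifelse(g == 1L, 1L, ifelse(g == 3L, 2L, 0L))
  if (!length(het)) return(list(rbind(base, base)))
  if (length(het) > max_het) return(NULL)
  free <- het[-1]
  combos <- if (length(free)) {
    as.matrix(expand.grid(rep(list(0:1), length(free))))
  } else matrix(0L, 1, 0)
  lapply(seq_len(nrow(combos)), function(r) {
    h1 <- base; h2 <- base
    h1[het[1]] <- 1L; h2[het[1]] <- 2L
    if (length(free)) {
      h1[free] <- 1L + combos[r, ]
      h2[free] <- 2L - combos[r, ]
    }
    rbind(h1, h2)
  })
}

# Count individuals whose non-missing calls match hap-pair (a, b) exactly.
.consistent_with <- function(G, a, b) {
  pred <- a + b - 1L
  dif <- sweep(G, 2, pred, `!=`)
  rowSums(dif, na.rm = TRUE) == 0 & rowSums(!is.na(G)) >= 0
}

.hap_key <- function(h) paste(h, collapse = "")

.config_pair_labels <- function(config) {
  parts <- strsplit(sub("x", "_", config), "_")[[1]]
  sort(parts)
}

.geno_label_of_hap <- function(hap_states) {
  # hap_states: character vector of 1-2 distinct single-SNP alleles
  sort(hap_states)
}

# Fit the founder-haplotype model of one contig.
# Gfam: named list of family genotype matrices (G2 rows x S snps).
# parents: named list per family: list(mother = codes, father = codes).
# snp_configs: inferred config per SNP (segregating configs only).
# Returns NULL (rejection) or the model.
.contig_model <- function(Gfam, parents, snp_configs, max_combos = 256) {
  fams <- names(Gfam)
  S <- length(snp_configs)
  phased <- list()
  for (f in fams) {
    gm <- parents[[f]]$mother; gf <- parents[[f]]$father
    if (anyNA(gm) || anyNA(gf) || any(gm == 0) || any(gf == 0)) next
    pm <- .enumerate_phases(gm); pf <- .enumerate_phases(gf)
    if (is.null(pm) || is.null(pf) ||
        length(pm) * length(pf) > max_combos) next
    best <- NULL; best_score <- -1
    for (m in pm) for (p in pf) {
      sc <- 0
      for (i in 1:2) for (j in 1:2) {
        sc <- sc + sum(.consistent_with(Gfam[[f]], m[i, ], p[j, ]))
      }
      if (sc > best_score) { best_score <- sc; best <- list(m = m, p = p) }
    }
    phased[[f]] <- best
  }
  if (!length(phased)) return(NULL)

  # global founder-side assignment: each parent has exactly one haplotype
  # from each founder; each founder contributes at most two distinct
  # haplotype states; per-SNP implied founder genotypes must match the
  # configuration inferred by composite likelihood.
  pf <- names(phased)
  # a parent homozygous across the contig has interchangeable sides
  opts <- unlist(lapply(pf, function(f) {
    ph <- phased[[f]]
    list(if (identical(ph$m[1, ], ph$m[2, ])) 1L else 1:2,
         if (identical(ph$p[1, ], ph$p[2, ])) 1L else 1:2)
  }), recursive = FALSE)
  combos <- as.matrix(expand.grid(opts))
  best <- NULL; best_score <- -1
  for (r in seq_len(nrow(combos))) {
    side1 <- character(0); side2 <- character(0)
    side1_states <- NULL; side2_states <- NULL
    ok <- TRUE
    assign <- list()
    for (k in seq_along(pf)) {
      ph <- phased[[pf[k]]]
      mo_first <- combos[r, 2 * k - 1]
      fa_first <- combos[r, 2 * k]
      m1 <- ph$m[mo_first, ]; m2 <- ph$m[3 - mo_first, ]
      p1 <- ph$p[fa_first, ]; p2 <- ph$p[3 - fa_first, ]
      side1_states <- rbind(side1_states, m1, p1)
      side2_states <- rbind(side2_states, m2, p2)
      assign[[pf[k]]] <- list(m1 = m1, m2 = m2, p1 = p1, p2 = p2)
    }
    u1 <- unique(side1_states); u2 <- unique(side2_states)
    if (nrow(u1) > 2 || nrow(u2) > 2) next
    # per-SNP config consistency
    for (s in seq_len(S)) {
      g1 <- sort(u1[, s]); g2 <- sort(u2[, s])
      lab <- function(a) paste0(c("A", "B")[a], collapse = "")
      f1 <- if (length(g1) == 1) lab(c(g1, g1)) else lab(g1)
      f2 <- if (length(g2) == 1) lab(c(g2, g2)) else lab(g2)
      implied <- sort(c(f1, f2))
      want <- .config_pair_labels(snp_configs[s])
      if (!identical(implied, want)) { ok <- FALSE; break }
    }
    if (!ok) next
    resolvable <- vapply(pf, function(f) {
      a <- assign[[f]]
      !identical(a$m1, a$m2) && !identical(a$p1, a$p2)
    }, logical(1))
    score <- sum(resolvable) * 1000 +
      sum(vapply(pf, function(f) {
        a <- assign[[f]]
        sum(.consistent_with(Gfam[[f]], a$m1, a$p1))
      }, numeric(1)))
    if (score > best_score) {
      best_score <- score
      best <- list(assign = assign, resolvable = resolvable,
                   founder1 = u1, founder2 = u2)
    }
  }
  if (is.null(best)) return(NULL)
  if (!any(best$resolvable)) return(NULL)
  best
}

# Origin-code one family's G2s given the side-assigned parent haplotypes.
.code_family <- function(G, a) {
  n <- nrow(G)
  sets <- vector("list", n)
  for (mi in 1:2) for (pi in 1:2) {
    mh <- if (mi == 1) a$m1 else a$m2
    ph <- if (pi == 1) a$p1 else a$p2
    ok <- .consistent_with(G, mh, ph)
    code <- mi + pi - 1L # 1=both side1, 2=het, 3=both side2
    for (i in which(ok)) sets[[i]] <- union(sets[[i]], code)
  }
  vapply(sets, function(s) {
    if (is.null(s) || !length(s)) return(NA_integer_)
    s <- sort(s)
    if (length(s) == 1) return(s)
    if (identical(s, c(1L, 2L))) return(5L) # not-22
    if (identical(s, c(2L, 3L))) return(4L) # not-11
    NA_integer_
  }, integer(1))
}

#' Recode one contig's SNPs as a founder-origin intercross marker
#'
#' Infers the founder haplotypes spanning the contig's SNPs from the
#' imputed F1 parent genotypes and the G2 segregation within each family,
#' then assigns each G2 a marker genotype only when all of its non-missing
#' SNP calls conform to one intact founder-haplotype pair. Families in
#' which one parent's two haplotypes are identical in state receive
#' dominant codes; the contig is rejected unless at least one family is
#' fully resolvable. Contigs with more than `max_snps` SNPs are split into
#' consecutive blocks recoded separately.
#'
#' @param contig_snps Long SNP tibble for the SNPs of one contig.
#' @param segregation A `segregation` object from [infer_segregation()].
#' @param pedigree Pedigree tibble.
#' @param max_snps Maximum SNPs recoded as a single marker.
#' @return A tibble of markers (possibly several after splitting; zero rows
#'   if rejected): `marker`, `contig_id`, genotype list-column `geno`
#'   (named integer vector over G2 ids, codes 1/2/3/4/5), list-columns
#'   `resolvable` (named logical per family) and `founder_alleles`
#'   (tibble: snp_id, allele1, allele2 for founder-distinct SNPs).
#' @export
recode_contig <- function(contig_snps, segregation, pedigree, max_snps = 8) {
  sid <- unique(contig_snps$snp_id)
  ctg <- contig_snps$contig_id[1]
  if (length(sid) > max_snps) {
    blocks <- split(sid, ceiling(seq_along(sid) / max_snps))
    out <- purrr::imap(blocks, function(b, i) {
      r <- recode_contig(dplyr::filter(contig_snps, .data$snp_id %in% b),
                         segregation, pedigree, max_snps)
      if (nrow(r)) r$marker <- paste0(ctg, "_b", i)
      r
    })
    return(dplyr::bind_rows(out))
  }

  pat <- segregation$patterns[match(sid, segregation$patterns$snp_id), ]
  seg_cfgs <- c("AAxBB", "ABxAB", "AAxAB", "ABxBB")
  if (any(is.na(pat$config)) || !all(pat$config %in% seg_cfgs)) {
    return(.empty_marker_tbl())
  }
  g2 <- pedigree[pedigree$generation == "G2", ]
  fams <- sort(unique(g2$family))
  G <- snp_matrix(contig_snps)
  G <- G[, sid, drop = FALSE]

  if (length(sid) == 1L) {
    # single SNPs are intercross markers only under AAxBB; under the other
    # segregating configurations no family's parental origins are fully
    # resolvable from a lone biallelic site
    if (pat$config != "AAxBB") return(.empty_marker_tbl())
    gg <- G[intersect(rownames(G), g2$id), 1]
    famtab <- segregation$families
    ft <- famtab[famtab$snp_id == sid, ]
    resolvable <- stats::setNames(
      ft$f1_mother == "AB" & ft$f1_father == "AB", ft$family
    )
    return(tibble::tibble(
      marker = ctg, contig_id = ctg, geno = list(gg),
      resolvable = list(resolvable),
      founder_alleles = list(tibble::tibble(
        snp_id = sid, allele1 = 1L, allele2 = 2L
      ))
    ))
  }
  Gfam <- lapply(fams, function(f) {
    G[intersect(g2$id[g2$family == f], rownames(G)), , drop = FALSE]
  })
  names(Gfam) <- fams
  famtab <- segregation$families
  parents <- lapply(fams, function(f) {
    ft <- famtab[famtab$family == f, ]
    ft <- ft[match(sid, ft$snp_id), ]
    list(mother = geno_to_code(ft$f1_mother),
         father = geno_to_code(ft$f1_father))
  })
  names(parents) <- fams

  model <- .contig_model(Gfam, parents, pat$config)
  if (is.null(model)) return(.empty_marker_tbl())

  geno <- integer(0)
  for (f in names(model$assign)) {
    geno <- c(geno, stats::setNames(
      .code_family(Gfam[[f]], model$assign[[f]]), rownames(Gfam[[f]])
    ))
  }
  # families that could not be phased at all: missing
  missing_f <- setdiff(fams, names(model$assign))
  for (f in missing_f) {
    geno <- c(geno, stats::setNames(
      rep(NA_integer_, nrow(Gfam[[f]])), rownames(Gfam[[f]])
    ))
  }
  resolvable <- stats::setNames(rep(FALSE, length(fams)), fams)
  resolvable[names(model$resolvable)] <- model$resolvable

  f1 <- model$founder1; f2 <- model$founder2
  distinct <- vapply(seq_along(sid), function(s) {
    length(unique(f1[, s])) == 1 && length(unique(f2[, s])) == 1 &&
      f1[1, s] != f2[1, s]
  }, logical(1))
  founder_alleles <- tibble::tibble(
    snp_id = sid[distinct],
    allele1 = f1[1, distinct],
    allele2 = f2[1, distinct]
  )

  tibble::tibble(
    marker = ctg, contig_id = ctg,
    geno = list(geno),
    resolvable = list(resolvable),
    founder_alleles = list(founder_alleles)
  )
}

.empty_marker_tbl <- function() {
  tibble::tibble(marker = character(0), contig_id = character(0),
                 geno = list(), resolvable = list(), founder_alleles = list())
}

#' Recode all contigs into an intercross marker set
#'
#' Applies [recode_contig()] to every non-sex-linked contig (multi-SNP
#' contigs and single SNPs with an intercross configuration alike) and
#' assembles the accepted markers into a genotype matrix over G2
#' individuals.
#'
#' @param snps Long SNP tibble after QC.
#' @param segregation A `segregation` object.
#' @param pedigree Pedigree tibble.
#' @param sex_linked_snps SNP ids to exclude (e.g. `meta_p < 0.01` from
#'   [test_sex_linkage()] or X-linked configurations).
#' @param max_snps Contig-size ceiling before splitting.
#' @param max_missing Markers missing in more than this fraction of G2s are
#'   dropped, and markers with strong departures from Mendelian 1:2:1
#'   proportions (chi-squared p below `distortion_p`) are dropped.
#' @param distortion_p Segregation-distortion rejection threshold.
#' @return An object of class `intercross_markers`: list with `geno`
#'   (G2 x markers integer matrix, codes 1-5), `info` (marker tibble) and
#'   `founder_alleles` (tibble: marker, snp_id, allele1, allele2).
#' @export
recode_contigs <- function(snps, segregation, pedigree,
                           sex_linked_snps = character(0),
                           max_snps = 8, max_missing = 0.10,
                           distortion_p = 1e-10) {
  snps <- dplyr::filter(snps, !(.data$snp_id %in% sex_linked_snps))
  g2_ids <- pedigree$id[pedigree$generation == "G2"]
  g2_ids <- intersect(unique(snps$id), g2_ids)
  res <- snps |>
    dplyr::group_split(.data$contig_id) |>
    purrr::map(recode_contig, segregation = segregation,
               pedigree = pedigree, max_snps = max_snps) |>
    dplyr::bind_rows()
  if (!nrow(res)) stop("no contigs could be recoded as intercross markers")

  geno <- matrix(NA_integer_, length(g2_ids), nrow(res),
                 dimnames = list(g2_ids, res$marker))
  for (j in seq_len(nrow(res))) {
    g <- res$geno[[j]]
    geno[intersect(names(g), g2_ids), j] <-
      g[intersect(names(g), g2_ids)]
  }

  miss <- colMeans(is.na(geno))
  codom <- geno; codom[codom > 3] <- NA
  dist_p <- apply(codom, 2, function(g) {
    tab <- tabulate(g, 3)
    if (sum(tab) < 10) return(1)
    stats::chisq.test(tab, p = F2_PRIOR)$p.value
  })
  keep <- miss <= max_missing & dist_p > distortion_p
  geno <- geno[, keep, drop = FALSE]
  res <- res[keep, ]

  fa <- purrr::map2(res$marker, res$founder_alleles, function(m, t) {
    if (nrow(t)) dplyr::mutate(t, marker = m, .before = 1) else NULL
  })
  structure(
    list(
      geno = geno,
      info = tibble::tibble(
        marker = res$marker, contig_id = res$contig_id,
        resolvable = res$resolvable,
        missing_frac = miss[keep], distortion_p = dist_p[keep]
      ),
      founder_alleles = dplyr::bind_rows(fa)
    ),
    class = "intercross_markers"
  )
}

#' @export
print.intercross_markers <- function(x, ...) {
  cat("<intercross_markers>", ncol(x$geno), "markers x", nrow(x$geno),
      "G2 individuals\n")
  invisible(x)
}
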
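# File formats: VCF ingestion, the open cross-CSV layout, pedigree and
# pool-count TSVs. All writers emit deterministic column order and "\n"
# line endings; missing genotypes are ".".

#' Read biallelic SNP calls from a VCF
#'
#' Ingests GT fields into the long SNP table used throughout the package.
#' Contig grouping comes from the CHROM column. Multiallelic records are
#' retained but flagged (`n_alleles`) so [filter_snps()] can remove them;
#' phased separators are accepted and phase discarded.
#'
#' @param path VCF file (plain text or gzipped).
#' @return A tibble: `snp_id`, `contig_id`, `id`, `call` (AA/AB/BB or
#'   NA), `n_alleles`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  alt <- fix[, "ALT"]
  n_alt <- ifelse(is.na(alt) | alt == ".", 0L,
                  1L + stringr::str_count(alt, ","))
  n_alleles <- 1L + n_alt
  snp_id <- if (all(is.na(fix[, "ID"]))) {
    paste0(fix[, "CHROM"], "_", fix[, "POS"])
  } else fix[, "ID"]
  call_of <- function(g) {
    g <- sub("\\|", "/", g)
    dplyr::case_when(
      g %in% c("0/0") ~ "AA",
      g %in% c("0/1", "1/0") ~ "AB",
      g %in% c("1/1") ~ "BB",
      TRUE ~ NA_character_
    )
  }
  tibble::tibble(
    snp_id = rep(snp_id, ncol(gt)),
    contig_id = rep(fix[, "CHROM"], ncol(gt)),
    id = rep(colnames(gt), each = nrow(gt)),
    call = call_of(as.vector(gt)),
    n_alleles = rep(n_alleles, ncol(gt))
  )
}

#' Write simulated SNP calls as a VCF
#'
#' @param cross A `true_cross`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cross, path) {
  sm <- cross$snp_map
  G <- cross$obs_geno
  gt <- matrix(".", nrow(sm), nrow(G))
  codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(sm))) {
    g <- G[, sm$snp_id[j]]
    gt[j, ] <- ifelse(is.na(g), "./.", codes[g])
  }
  pos_in_contig <- stats::ave(seq_len(nrow(sm)), sm$contig_id,
                              FUN = seq_along)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", rownames(G)), collapse = "\t"),
    vapply(seq_len(nrow(sm)), function(j) {
      paste(c(sm$contig_id[j], pos_in_contig[j] * 100, sm$snp_id[j],
              "A", "T", ".", "PASS", ".", "GT", gt[j, ]),
            collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write and read the cross CSV format
#'
#' A single CSV holding the genotype matrix, map and phenotypes: the
#' first row names the id column, the phenotype columns and the markers;
#' the second and third rows carry each marker's linkage group and cM
#' position; data rows follow with genotype codes
#' `PP/PL/LL/not-PP/not-LL` and `.` for missing. The round trip
#' read -> write -> read is lossless.
#'
#' @param map Tibble: `marker`, `group`, `pos`.
#' @param geno Individuals x markers matrix (codes 1-5, NA).
#' @param phenotypes Tibble with `id` first.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cross_csv <- function(map, geno, phenotypes, path) {
  ids <- rownames(geno)
  ph <- phenotypes[match(ids, phenotypes$id), , drop = FALSE]
  pnames <- setdiff(names(ph), "id")
  gl <- matrix(MARKER_LABELS[geno], nrow(geno))
  gl[is.na(gl)] <- "."
  header <- c("id", pnames, map$marker)
  row_g <- c("", rep("", length(pnames)), as.character(map$group))
  row_p <- c("", rep("", length(pnames)), as.character(map$pos))
  fmt_ph <- vapply(pnames, function(p) {
    v <- ph[[p]]
    ifelse(is.na(v), ".", as.character(v))
  }, character(length(ids)))
  body <- cbind(ids, fmt_ph, gl)
  lines <- c(
    paste(header, collapse = ","),
    paste(row_g, collapse = ","),
    paste(row_p, collapse = ","),
    apply(body, 1, paste, collapse = ",")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_cross_csv
#' @return `read_cross_csv()` returns a list: `map`, `geno`,
#'   `phenotypes`.
#' @export
read_cross_csv <- function(path) {
  lines <- readLines(path)
  split1 <- strsplit(lines, ",", fixed = TRUE)
  header <- split1[[1]]
  row_g <- split1[[2]]
  row_p <- split1[[3]]
  is_marker <- row_g != ""
  is_marker[1] <- FALSE
  pnames <- header[-1][!is_marker[-1]]
  markers <- header[is_marker]
  map <- tibble::tibble(
    marker = markers,
    group = as.integer(row_g[is_marker]),
    pos = as.numeric(row_p[is_marker])
  )
  body <- do.call(rbind, split1[-(1:3)])
  ids <- body[, 1]
  ph <- tibble::as_tibble(body[, !is_marker, drop = FALSE][, -1,
                                                          drop = FALSE],
                          .name_repair = "minimal")
  names(ph) <- pnames
  ph <- dplyr::mutate(ph, dplyr::across(
    dplyr::everything(),
    function(x) suppressWarnings(as.numeric(ifelse(x == ".", NA, x)))
  ))
  ph <- dplyr::bind_cols(tibble::tibble(id = ids), ph)
  gl <- body[, is_marker, drop = FALSE]
  geno <- matrix(match(gl, MARKER_LABELS), nrow(gl),
                 dimnames = list(ids, markers))
  list(map = map, geno = geno, phenotypes = ph)
}

#' Write / read pooled allele counts as TSV
#'
#' Columns: `snp_id`, `population`, `replicate`, `ref_count`,
#' `alt_count`.
#'
#' @param counts Pool-count tibble.
#' @param path File path.
#' @export
write_pool_counts <- function(counts, path) {
  utils::write.table(
    counts[, c("snp_id", "population", "replicate",
               "ref_count", "alt_count")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n"
  )
  invisible(path)
}

#' @rdname write_pool_counts
#' @export
read_pool_counts <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Write / read a pedigree TSV
#'
#' @param pedigree Pedigree tibble.
#' @param path File path.
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.table(pedigree, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", na = ".")
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE,
                                      na.strings = "."))
}
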
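# The pipeline driver: QC -> sex linkage -> segregation inference ->
# contig recoding -> pedigree screen -> linkage map -> founder assignment
# -> structured QTL scans -> multi-QTL fits, with staged TSV outputs and
# JSON provenance records.

#' Pipeline configuration
#'
#' Collects every stage's thresholds and inputs. Unknown keys are
#' rejected so configuration typos fail loudly.
#'
#' @param out_dir Output directory for staged results.
#' @param seed Master seed for all stochastic stages.
#' @param vcf,pedigree,pool_counts Input paths (alternatively pass a
#'   simulated cross directly to [run_pipeline()]).
#' @param min_occurrence,min_called SNP / individual QC thresholds.
#' @param sex_p Sex-linkage meta-analysis flag threshold.
#' @param lod_limit,join_limit,lod_difference Grouping thresholds.
#' @param n_restarts,ripple_window Ordering search controls.
#' @param error_lod_threshold Error-LOD cleaning threshold.
#' @param step_cM Scan grid step.
#' @param n_perm Structured permutations per scanned trait.
#' @param traits Named character vector mapping trait columns to scan
#'   models (`"normal"`/`"binary"`).
#' @param resume Reuse stage outputs already present in `out_dir`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       vcf = NULL, pedigree = NULL, pool_counts = NULL,
                       min_occurrence = 0.10, min_called = 1000,
                       sex_p = 0.01,
                       lod_limit = 15, join_limit = 10, lod_difference = 5,
                       n_restarts = 20, ripple_window = 7,
                       error_lod_threshold = 6,
                       step_cM = 1, n_perm = 200,
                       traits = c(chaetae_count = "normal",
                                  chaetae_length = "normal",
                                  anal_cirri = "binary",
                                  g3_area = "normal"),
                       resume = FALSE) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(y$traits)) y$traits <- unlist(y$traits)
  do.call(run_config, y)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", na = ".")
}

.provenance <- function(dir, stage, config, extra = list()) {
  rec <- c(list(
    stage = stage, seed = config$seed,
    package_version = as.character(utils::packageVersion("larvaqtl")),
    r_version = as.character(getRversion()),
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  ), extra)
  jsonlite::write_json(rec, file.path(dir, paste0(stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

.stage <- function(name, config, compute) {
  rds <- file.path(config$out_dir, paste0(name, ".rds"))
  if (isTRUE(config$resume) && file.exists(rds)) {
    message("[", name, "] resumed from ", rds)
    return(readRDS(rds))
  }
  message("[", name, "] running")
  out <- tryCatch(compute(), error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  saveRDS(out, rds)
  out
}

#' Run the full mapping pipeline
#'
#' Executes QC, sex-linkage testing, segregation inference, contig
#' recoding, pedigree screening, map construction, founder assignment
#' (when pool counts are available), structured QTL scans with
#' permutation thresholds, and multi-QTL fits at the significant peaks.
#' Every stage writes a TSV and a JSON provenance record into
#' `config$out_dir`; with `resume = TRUE`, stages whose cached output
#' exists are skipped and only downstream stages recompute.
#'
#' @param config A [run_config()].
#' @param cross Optional `true_cross` to analyze directly (otherwise the
#'   `vcf`/`pedigree`/`pool_counts` paths in `config` are read).
#' @return A list with the main stage results (invisibly also written to
#'   `config$out_dir`).
#' @export
run_pipeline <- function(config, cross = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  inputs <- .stage("inputs", config, function() {
    if (!is.null(cross)) {
      list(snps = cross$observed_snps, pedigree = cross$pedigree,
           phenotypes = cross$phenotypes,
           pool = if (!is.null(config$pool_counts)) {
             read_pool_counts(config$pool_counts)
           } else NULL)
    } else {
      list(snps = read_vcf(config$vcf),
           pedigree = read_pedigree(config$pedigree),
           phenotypes = NULL,
           pool = if (!is.null(config$pool_counts)) {
             read_pool_counts(config$pool_counts)
           } else NULL)
    }
  })

  qc <- .stage("qc", config, function() {
    s <- filter_snps(inputs$snps, config$min_occurrence)
    s <- filter_individuals(s, min_called = min(
      config$min_called, floor(0.7 * dplyr::n_distinct(s$snp_id))
    ))
    message("  SNPs retained: ", dplyr::n_distinct(s$snp_id),
            "; individuals: ", dplyr::n_distinct(s$id))
    s
  })

  sexlink <- .stage("sexlink", config, function() {
    sl <- test_sex_linkage(qc, inputs$pedigree)
    .write_tsv(dplyr::select(sl, -"family_p"),
               file.path(config$out_dir, "sexlink.tsv"))
    .provenance(config$out_dir, "sexlink", config,
                list(n_flagged = sum(sl$meta_p < config$sex_p)))
    sl
  })

  seg <- .stage("segregation", config, function() {
    s <- infer_segregation(qc, inputs$pedigree)
    .write_tsv(s$patterns, file.path(config$out_dir, "segregation.tsv"))
    .provenance(config$out_dir, "segregation", config,
                list(configs = as.list(table(s$patterns$config))))
    s
  })

  sex_linked_ids <- union(
    sexlink$snp_id[sexlink$meta_p < config$sex_p],
    seg$patterns$snp_id[seg$patterns$config %in%
                          c(X_SEG_CONFIGS) & !is.na(seg$patterns$config)]
  )

  screen <- .stage("pedigree_screen", config, function() {
    sc <- screen_pedigree(qc, seg, inputs$pedigree)
    .write_tsv(sc, file.path(config$out_dir, "pedigree_screen.tsv"))
    sc
  })
  ok_ids <- screen$id[screen$flag == "ok"]
  qc_ok <- dplyr::filter(
    qc, .data$id %in% c(ok_ids,
                        inputs$pedigree$id[inputs$pedigree$generation !=
                                             "G2"])
  )

  markers <- .stage("recode", config, function() {
    m <- recode_contigs(qc_ok, seg, inputs$pedigree,
                        sex_linked_snps = sex_linked_ids)
    message("  intercross markers: ", ncol(m$geno))
    m
  })

  gmap <- .stage("map", config, function() {
    gm <- build_linkage_map(
      markers, lod_limit = config$lod_limit,
      join_limit = config$join_limit,
      lod_difference = config$lod_difference,
      n_restarts = config$n_restarts,
      ripple_window = config$ripple_window,
      error_lod_threshold = config$error_lod_threshold,
      seed = config$seed
    )
    .write_tsv(gm$map, file.path(config$out_dir, "map.tsv"))
    .provenance(config$out_dir, "map", config, list(
      n_groups = length(unique(gm$map$group)),
      error_rate = gm$error_rate, n_cleaned = gm$n_cleaned
    ))
    gm
  })

  xmap <- .stage("sex_map", config, function() {
    assemble_sex_linked(qc_ok, seg, inputs$pedigree, seed = config$seed)
  })

  founders <- NULL
  if (!is.null(inputs$pool)) {
    founders <- .stage("founders", config, function() {
      fa <- markers$founder_alleles
      # orientation flips applied during mapping propagate to the founder
      # allele sides
      fl <- gmap$flipped
      flip_these <- fa$marker %in% names(fl)[fl]
      tmp <- fa$allele1[flip_these]
      fa$allele1[flip_these] <- fa$allele2[flip_these]
      fa$allele2[flip_these] <- tmp
      fa$group <- gmap$map$group[match(fa$marker, gmap$map$marker)]
      fa <- dplyr::filter(fa, !is.na(.data$group))
      freqs <- pool_allele_freqs(inputs$pool)
      asg <- assign_founders(fa, freqs)
      .write_tsv(dplyr::select(asg, -"per_snp"),
                 file.path(config$out_dir, "founders.tsv"))
      asg
    })
  }

  polarized <- if (!is.null(founders)) {
    polarize_map(gmap, founders)
  } else gmap

  probs <- .stage("genotype_probs", config, function() {
    genotype_probs(polarized$geno, polarized$map,
                   step_cM = config$step_cM,
                   error_prob = polarized$error_rate)
  })

  phen <- inputs$phenotypes
  scans <- fits <- NULL
  if (!is.null(phen)) {
    scans <- .stage("scans", config, function() {
      out <- list()
      for (tr in names(config$traits)) {
        if (!tr %in% names(phen)) next
        out[[tr]] <- scan_structured(
          phen, probs, tr, model = config$traits[[tr]],
          n_perm = config$n_perm, seed = config$seed
        )
        .write_tsv(out[[tr]]$scan,
                   file.path(config$out_dir, paste0("scan_", tr, ".tsv")))
      }
      out
    })
    fits <- .stage("fits", config, function() {
      out <- list()
      for (tr in names(scans)) {
        pk <- scan_peaks(scans[[tr]])
        if (!nrow(pk)) next
        out[[tr]] <- fit_qtl_model(
          phen, probs, tr,
          qtl = dplyr::select(pk, "group", "pos"),
          model = config$traits[[tr]]
        )
        .write_tsv(out[[tr]]$coefficients,
                   file.path(config$out_dir, paste0("fit_", tr, ".tsv")))
      }
      out
    })
  }
  .provenance(config$out_dir, "pipeline", config, list(done = TRUE))
  invisible(list(
    qc = qc, sexlink = sexlink, segregation = seg, screen = screen,
    markers = markers, map = gmap, x_map = xmap, founders = founders,
    polarized_map = polarized, probs = probs, scans = scans, fits = fits
  ))
}
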
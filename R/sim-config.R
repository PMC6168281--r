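#' Default QTL architecture for the simulated cross
#'
#' One row per locus effect: the two chaetae-number loci (LG3, LG8), the two
#' chaetae-length loci (LG3, LG9), the two maternal offspring-size loci
#' (LG6, LG7) with their four pairwise epistatic terms, and the anal-cirri
#' locus (LG5, logistic scale). Additive effects are in units of the trait
#' per lecithotroph (L) allele under the coding a = (#L alleles - 1); the
#' dominance deviation applies to heterozygotes (d = 1).
#'
#' @return A tibble with columns `trait`, `chrom`, `pos`, `add`, `dom`.
#' @export
default_qtl_spec <- function() {
  tibble::tribble(
    ~trait,           ~chrom, ~pos,  ~add,     ~dom,
    "chaetae_count",  3L,     2.5,   -2.53,    -0.58,
    "chaetae_count",  8L,     1.7,   -2.30,     0.31,
    "chaetae_length", 3L,     3.6,   -29.59,   -20.26,
    "chaetae_length", 9L,     1.5,   -25.07,    4.11,
    "g3_area",        6L,     17.9,  3356.14,  -908.67,
    "g3_area",        7L,     2.1,   4020.69,  -228.43,
    "anal_cirri",     5L,     5.1,   -3.52,     1.86
  )
}

#' Default trait models for the simulated cross
#'
#' Intercepts, residual standard deviations, family effects and epistatic
#' terms for the five larval phenotypes. `g3_area` (mean area of a G2
#' female's G3 brood, in square micrometres) is the maternal-effect trait:
#' it is computed from the G2 mother's genotype, including the LG6 x LG7
#' interaction (AxA, DxA, AxD, DxD coefficients). `larval_area` is the G2's
#' own larval size, which carries no QTL signal in this design (all G2s
#' share heterozygous F1 mothers) but has an environmental family effect.
#' Residual SDs are calibrated so each locus' drop-one variance share
#' approximates the observed shares (roughly 18-26% per major locus).
#'
#' @return A named list of per-trait model descriptions.
#' @export
default_trait_models <- function() {
  list(
    chaetae_count = list(
      type = "count", intercept = 4.29, residual_sd = 3.0,
      family_effects = c(A = 0, C = 0, F = 0, H = 0)
    ),
    chaetae_length = list(
      type = "normal", intercept = 140.02, residual_sd = 34,
      family_effects = c(A = 2.60, C = 0.01, F = 0, H = -19.72)
    ),
    g3_area = list(
      type = "normal", intercept = 29516.79, residual_sd = 3700,
      maternal = TRUE,
      family_effects = c(A = 0, C = 0, F = 0, H = 0),
      epistasis = list(list(
        chroms = c(6L, 7L),
        axa = 1254.06, dxa = 232.10, axd = -3297.03, dxd = 62.26
      ))
    ),
    anal_cirri = list(
      type = "binary", intercept = 1.08,
      family_effects = c(A = 0, C = 0, F = 0, H = 0)
    ),
    larval_area = list(
      type = "normal", intercept = 50000, residual_sd = 8000,
      family_effects = c(A = 2500, C = -1000, F = 3000, H = -4500)
    )
  )
}

#' Configuration for the synthetic-cross simulator
#'
#' Defines the genome, marker panel, pedigree sizes, genotyping-error and
#' missing-data model, and trait architecture used by [simulate_cross()].
#' The defaults emulate the mapping cross the package targets: ten
#' autosomes plus an XY pair, four half-sib G2 families of 51/78/37/79
#' individuals sharing a single F1 sire, a 47-animal F1 panel, and about
#' 1,400 SNPs spread over about 940 contigs (most with 1-3 SNPs, a rare
#' contig with many more).
#'
#' @param n_autosomes Number of autosomes.
#' @param chrom_length_cM Genetic length of each autosome, in cM.
#' @param x_length_cM Genetic length of the X chromosome, in cM.
#' @param n_contigs Number of SNP-bearing contigs.
#' @param snps_per_contig Either a single count applied to every contig or a
#'   named list `list(sizes =, prob =)` sampled per contig.
#' @param frac_x Fraction of contigs on the X chromosome.
#' @param config_weights Sampling weights for per-SNP founder configurations
#'   `AAxBB`, `ABxAB`, `AAxAB`, `ABxBB`, `AAxAA`, `BBxBB` (autosomes).
#' @param n_G2_per_family Named integer vector of G2 family sizes.
#' @param n_F1_panel Number of genotyped F1 animals (panel; roughly half
#'   male).
#' @param error_rate One-step genotyping error probability, in `[0, 0.1]`.
#' @param missing_rate Fraction of genotype calls dropped at random.
#' @param qtl_spec QTL effect table, as [default_qtl_spec()].
#' @param trait_models Trait model list, as [default_trait_models()].
#' @param seed Integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_autosomes = 10,
                       chrom_length_cM = 50,
                       x_length_cM = 40,
                       n_contigs = 939,
                       snps_per_contig = list(
                         sizes = c(1L, 2L, 3L, 4L, 5L, 16L),
                         prob = c(0.72, 0.17, 0.08, 0.02, 0.008, 0.002)
                       ),
                       frac_x = 0.03,
                       config_weights = c(
                         AAxBB = 0.35, ABxAB = 0.15, AAxAB = 0.14,
                         ABxBB = 0.14, AAxAA = 0.11, BBxBB = 0.11
                       ),
                       n_G2_per_family = c(A = 51L, C = 78L, F = 37L, H = 79L),
                       n_F1_panel = 47,
                       error_rate = 0.01,
                       missing_rate = 0.10,
                       qtl_spec = default_qtl_spec(),
                       trait_models = default_trait_models(),
                       seed = 1L) {
  stopifnot(
    n_autosomes >= 1, chrom_length_cM > 0, n_contigs >= 1,
    length(n_G2_per_family) >= 1, !is.null(names(n_G2_per_family))
  )
  if (error_rate < 0 || error_rate > 0.1) {
    stop("error_rate must lie in [0, 0.1]")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  if (any(qtl_spec$pos < 0) ||
      any(qtl_spec$pos > chrom_length_cM)) {
    stop("QTL positions must lie within the chromosome length")
  }
  if (any(qtl_spec$chrom > n_autosomes)) {
    stop("QTL chromosomes must be autosomes present in the genome")
  }
  rsd <- unlist(lapply(trait_models, function(m) m$residual_sd %||% 1))
  if (any(rsd < 0)) stop("residual SDs must be non-negative")
  maternal <- vapply(trait_models, function(m) isTRUE(m$maternal), logical(1))
  if (sum(maternal) != 1) {
    stop("exactly one trait must be flagged maternal")
  }
  structure(
    list(
      n_autosomes = as.integer(n_autosomes),
      chrom_length_cM = chrom_length_cM,
      x_length_cM = x_length_cM,
      n_contigs = as.integer(n_contigs),
      snps_per_contig = snps_per_contig,
      frac_x = frac_x,
      config_weights = config_weights,
      n_G2_per_family = n_G2_per_family,
      n_F1_panel = as.integer(n_F1_panel),
      error_rate = error_rate,
      missing_rate = missing_rate,
      qtl_spec = qtl_spec,
      trait_models = trait_models,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  genome: ", x$n_autosomes, " autosomes x ", x$chrom_length_cM,
      " cM + X (", x$x_length_cM, " cM)\n", sep = "")
  cat("  markers: ", x$n_contigs, " contigs\n", sep = "")
  cat("  G2 families:",
      paste(names(x$n_G2_per_family), x$n_G2_per_family,
            sep = "=", collapse = ", "), "\n")
  cat("  error_rate:", x$error_rate,
      " missing_rate:", x$missing_rate, "\n")
  invisible(x)
}
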
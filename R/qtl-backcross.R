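# Penetrance of zygotic loci in a shifted maternal background: mixed-model
# analysis of backcross broods with a brood random intercept.

#' Test QTL effects in backcross broods
#'
#' Fits a linear mixed-effect model of an offspring trait on the sires'
#' L-allele dosages at the declared loci, with a random intercept per
#' brood to account for the relatedness of larvae within a brood, and
#' compares it to the brood-only null by likelihood-ratio test (models
#' fitted by maximum likelihood). Loci with a single sire genotype class
#' are dropped with a warning, as are unbalanced loci warnings when a
#' genotype class is absent.
#'
#' @param offspring Tibble with `brood`, the trait column, and nothing
#'   else required.
#' @param sires Tibble with `sire_id` and one dosage column (0/1/2 L
#'   alleles) per locus; `offspring` must carry `sire_id` or `brood` must
#'   map 1:1 to sires via `sires$brood`.
#' @param trait Offspring trait column.
#' @param loci Names of the dosage columns in `sires` to test.
#' @return A list of class `backcross_fit`: `test` (tibble: trait,
#'   statistic, df, p_value), `effects` (fixed-effect estimates), `fit`,
#'   `dropped_loci`.
#' @export
backcross_test <- function(offspring, sires, trait, loci) {
  if (!"sire_id" %in% names(offspring)) {
    stop("offspring must carry a sire_id column")
  }
  if (dplyr::n_distinct(offspring$brood) < 2) {
    stop("at least two broods are required")
  }
  dat <- offspring[, c("brood", "sire_id", trait)] |>
    dplyr::left_join(sires[, c("sire_id", loci)], by = "sire_id") |>
    dplyr::filter(!is.na(.data[[trait]]))

  usable <- character(0)
  for (l in loci) {
    cls <- unique(dat[[l]])
    if (length(cls) < 2) {
      warning("locus ", l, " has a single sire genotype class; dropped")
    } else {
      usable <- c(usable, l)
      if (length(unique(sires[[l]])) < 3) {
        warning("locus ", l, " has unbalanced sire genotype classes (",
                paste(sort(unique(sires[[l]])), collapse = "/"),
                " only)")
      }
    }
  }
  dat$.y <- dat[[trait]]
  null_f <- .y ~ 1 + (1 | brood)
  m0 <- lme4::lmer(null_f, data = dat, REML = FALSE)
  if (!length(usable)) {
    return(structure(list(
      test = tibble::tibble(trait = trait, statistic = NA_real_,
                            df = 0L, p_value = NA_real_),
      effects = tibble::tibble(), fit = m0, dropped_loci = loci
    ), class = "backcross_fit"))
  }
  full_f <- stats::as.formula(
    paste(".y ~", paste(usable, collapse = " + "), "+ (1 | brood)")
  )
  m1 <- lme4::lmer(full_f, data = dat, REML = FALSE)
  a <- stats::anova(m0, m1)
  cf <- summary(m1)$coefficients
  structure(
    list(
      test = tibble::tibble(
        trait = trait, statistic = a$Chisq[2], df = a$Df[2],
        p_value = a$`Pr(>Chisq)`[2]
      ),
      effects = tibble::tibble(
        term = rownames(cf), estimate = cf[, 1], std_error = cf[, 2]
      ),
      fit = m1, dropped_loci = setdiff(loci, usable)
    ),
    class = "backcross_fit"
  )
}

#' @export
print.backcross_fit <- function(x, ...) {
  cat("<backcross_fit>", x$test$trait, ": LRT chisq =",
      round(x$test$statistic, 2), "df", x$test$df,
      ", p =", signif(x$test$p_value, 3), "\n")
  print(as.data.frame(x$effects), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.backcross_fit <- function(x, ...) x$effects

#' @importFrom generics glance
#' @export
glance.backcross_fit <- function(x, ...) x$test
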
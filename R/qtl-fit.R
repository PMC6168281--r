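# Multi-QTL model fitting with epistasis and family effects, drop-one
# variance decomposition, and related single-trait tests.

# expected a/d dosages at the grid position nearest to (group, pos)
.qtl_design <- function(probs, qtl, ids) {
  stopifnot(all(c("group", "pos") %in% names(qtl)))
  ids_prob <- rownames(probs[[1]]$prob)
  rows <- match(ids, ids_prob)
  out <- list()
  for (q in seq_len(nrow(qtl))) {
    g <- as.character(qtl$group[q])
    k <- which.min(abs(probs[[g]]$pos - qtl$pos[q]))
    nm <- qtl$name[q] %||% paste0("LG", g, "_", round(qtl$pos[q], 1))
    out[[paste0("a_", nm)]] <- probs[[g]]$a[rows, k]
    out[[paste0("d_", nm)]] <- probs[[g]]$d[rows, k]
  }
  tibble::as_tibble(out)
}

.qtl_names <- function(qtl) {
  if ("name" %in% names(qtl)) qtl[["name"]]
  else paste0("LG", qtl$group, "_", round(qtl$pos, 1))
}

#' Fit a multi-QTL model
#'
#' Linear (or logistic, for binary traits) model of a trait on the
#' additive and dominance dosages of the declared QTL, optional pairwise
#' epistatic terms (AxA, AxD, DxA, DxD) and optional G2-family effects.
#' Reports coefficients with standard errors, likelihood-ratio tests, and
#' the drop-one percentage of phenotypic variance (or deviance) explained
#' by each locus and interaction, where dropping a locus also drops its
#' interactions.
#'
#' @param phenotypes Tibble with `id`, `family`, and the trait.
#' @param probs A `genoprob` object.
#' @param trait Trait column name.
#' @param qtl Tibble of QTL: `group`, `pos` (cM), optional `name`.
#' @param interactions Optional list of 2-vectors of QTL names (or row
#'   indices into `qtl`) to model as interacting pairs.
#' @param family_effect Include family fixed effects.
#' @param model `"normal"` or `"binary"`.
#' @return Object of class `qtl_fit`: list with the underlying `fit`,
#'   `coefficients` tibble, `drop_one` tibble, `trait`, `model`,
#'   `formula`, and `data`.
#' @export
fit_qtl_model <- function(phenotypes, probs, trait, qtl,
                          interactions = NULL, family_effect = FALSE,
                          model = c("normal", "binary")) {
  model <- match.arg(model)
  ph <- phenotypes[!is.na(phenotypes[[trait]]), ]
  ph <- ph[ph$id %in% rownames(probs[[1]]$prob), ]
  qtl <- dplyr::mutate(qtl, name = .qtl_names(qtl))
  X <- .qtl_design(probs, qtl, ph$id)
  dat <- dplyr::bind_cols(
    tibble::tibble(.y = ph[[trait]], family = factor(ph$family)), X
  )

  main_terms <- unlist(lapply(qtl$name, function(nm) {
    paste0(c("a_", "d_"), nm)
  }))
  int_terms <- list()
  if (!is.null(interactions)) {
    for (pair in interactions) {
      if (is.numeric(pair)) pair <- qtl$name[pair]
      for (t1 in c("a", "d")) for (t2 in c("a", "d")) {
        cn <- paste0(t1, t2, "_", pair[1], "_x_", pair[2])
        dat[[cn]] <- dat[[paste0(t1, "_", pair[1])]] *
          dat[[paste0(t2, "_", pair[2])]]
        int_terms[[paste(pair, collapse = ":")]] <-
          c(int_terms[[paste(pair, collapse = ":")]], cn)
      }
    }
  }
  rhs <- c(if (family_effect) "family", main_terms,
           unlist(int_terms))
  fml <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + ")))

  fit_fun <- function(formula) {
    if (model == "normal") stats::lm(formula, data = dat)
    else stats::glm(formula, data = dat, family = stats::binomial())
  }
  fit <- fit_fun(fml)
  if (model == "normal" && any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; inestimable terms: ",
         paste(bad, collapse = ", "))
  }

  total <- if (model == "normal") {
    sum((dat$.y - mean(dat$.y))^2)
  } else .binom_dev(rep(mean(dat$.y), nrow(dat)), dat$.y)
  fitstat <- function(f) {
    if (model == "normal") sum(stats::residuals(f)^2) else f$deviance
  }
  full_rss <- fitstat(fit)

  drop_sets <- list()
  for (q in qtl$name) {
    inv <- unlist(int_terms[grepl(q, names(int_terms), fixed = TRUE)])
    drop_sets[[q]] <- c(paste0(c("a_", "d_"), q), inv)
  }
  for (nm in names(int_terms)) {
    drop_sets[[paste0("int_", nm)]] <- int_terms[[nm]]
  }
  if (family_effect) drop_sets[["family"]] <- "family"

  drop_one <- purrr::imap(drop_sets, function(cols, nm) {
    keep <- setdiff(rhs, cols)
    f_red <- fit_fun(stats::as.formula(
      paste(".y ~", if (length(keep)) paste(keep, collapse = " + ")
            else "1")
    ))
    rss_red <- fitstat(f_red)
    lrt <- if (model == "normal") {
      nrow(dat) * log(rss_red / full_rss)
    } else rss_red - full_rss
    df <- length(stats::coef(fit)) - length(stats::coef(f_red))
    tibble::tibble(
      term = nm,
      pct_explained = 100 * (rss_red - full_rss) / total,
      lrt = lrt, df = df,
      p_value = stats::pchisq(lrt, df, lower.tail = FALSE)
    )
  }) |> dplyr::bind_rows()

  cf <- summary(fit)$coefficients
  coefficients <- tibble::tibble(
    term = rownames(cf), estimate = cf[, 1], std_error = cf[, 2],
    statistic = cf[, 3], p_value = cf[, 4]
  )

  structure(
    list(fit = fit, coefficients = coefficients, drop_one = drop_one,
         trait = trait, model = model, formula = fml, data = dat,
         qtl = qtl,
         pct_model = 100 * (total - full_rss) / total),
    class = "qtl_fit"
  )
}

#' @export
print.qtl_fit <- function(x, ...) {
  cat("<qtl_fit>", x$trait, "(", x$model, ")\n")
  cat("  model explains", round(x$pct_model, 1), "% of",
      if (x$model == "normal") "variance" else "deviance", "\n")
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 4)
  cat("drop-one:\n")
  print(as.data.frame(x$drop_one), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.qtl_fit <- function(x, ...) x$coefficients

#' @importFrom generics glance
#' @export
glance.qtl_fit <- function(x, ...) {
  tibble::tibble(
    trait = x$trait, model = x$model, n = nrow(x$data),
    pct_explained = x$pct_model,
    df_residual = stats::df.residual(x$fit)
  )
}

#' Test for G2 family effects on a trait
#'
#' Likelihood-ratio (normal: F-test; binary: deviance chi-squared) test of
#' adding family to the trait's QTL model. Loci heterozygous in the P0
#' founders would surface as family effects, since the four G2 families
#' differ in their F1 mothers.
#'
#' @inheritParams fit_qtl_model
#' @param qtl Optional QTL to include as covariates (may be `NULL` for a
#'   trait-only test).
#' @return A tibble: `trait`, `statistic`, `df`, `p_value`.
#' @export
family_effect_test <- function(phenotypes, probs = NULL, trait,
                               qtl = NULL, model = c("normal", "binary")) {
  model <- match.arg(model)
  ph <- phenotypes[!is.na(phenotypes[[trait]]), ]
  if (length(unique(ph$family)) < 2) {
    stop("family effect test requires at least two families")
  }
  if (!is.null(qtl) && !is.null(probs)) {
    ph <- ph[ph$id %in% rownames(probs[[1]]$prob), ]
    qtl <- dplyr::mutate(qtl, name = .qtl_names(qtl))
    X <- .qtl_design(probs, qtl, ph$id)
    dat <- dplyr::bind_cols(
      tibble::tibble(.y = ph[[trait]], family = factor(ph$family)), X
    )
    base <- paste(setdiff(names(X), character(0)), collapse = " + ")
  } else {
    dat <- tibble::tibble(.y = ph[[trait]], family = factor(ph$family))
    base <- "1"
  }
  f0 <- stats::as.formula(paste(".y ~", base))
  f1 <- stats::as.formula(paste(".y ~", base, "+ family"))
  if (model == "normal") {
    m0 <- stats::lm(f0, data = dat); m1 <- stats::lm(f1, data = dat)
    a <- stats::anova(m0, m1)
    tibble::tibble(trait = trait, statistic = a$F[2], df = a$Df[2],
                   p_value = a$`Pr(>F)`[2])
  } else {
    m0 <- stats::glm(f0, data = dat, family = stats::binomial())
    m1 <- stats::glm(f1, data = dat, family = stats::binomial())
    lrt <- m0$deviance - m1$deviance
    df <- m0$df.residual - m1$df.residual
    tibble::tibble(trait = trait, statistic = lrt, df = df,
                   p_value = stats::pchisq(lrt, df, lower.tail = FALSE))
  }
}

#' Trait correlation before and after removing a shared QTL
#'
#' Squared correlation of two traits, and of their residuals after
#' regressing each on the additive and dominance dosages of a shared QTL:
#' distinguishes pleiotropy at the shared locus from correlation of the
#' residual (background) variation.
#'
#' @inheritParams fit_qtl_model
#' @param trait1,trait2 Trait column names.
#' @param qtl Single-row tibble (`group`, `pos`) of the shared QTL.
#' @return A tibble: `r2_raw`, `r2_residual`, `n`.
#' @export
residual_correlation <- function(phenotypes, probs, trait1, trait2, qtl) {
  ph <- phenotypes[!is.na(phenotypes[[trait1]]) &
                     !is.na(phenotypes[[trait2]]) &
                     phenotypes$id %in% rownames(probs[[1]]$prob), ]
  if (nrow(ph) < 10) stop("fewer than 10 complete cases")
  X <- .qtl_design(probs, dplyr::mutate(qtl, name = "q"), ph$id)
  r1 <- stats::residuals(stats::lm(ph[[trait1]] ~ X$a_q + X$d_q))
  r2 <- stats::residuals(stats::lm(ph[[trait2]] ~ X$a_q + X$d_q))
  tibble::tibble(
    r2_raw = stats::cor(ph[[trait1]], ph[[trait2]])^2,
    r2_residual = stats::cor(r1, r2)^2,
    n = nrow(ph)
  )
}
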
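# Internal genotype encodings and map-function helpers.
#
# Integer genotype codes used throughout:
#   1 = AA (or PP after founder polarization)
#   2 = AB (PL)
#   3 = BB (LL)
#   4 = "not-AA" dominant code (AB or BB; "not-PP")
#   5 = "not-BB" dominant code (AA or AB; "not-LL")
#   NA = missing

GENO_LABELS <- c("AA", "AB", "BB", "not-AA", "not-BB")
MARKER_LABELS <- c("PP", "PL", "LL", "not-PP", "not-LL")

geno_to_code <- function(x, labels = GENO_LABELS) {
  if (is.numeric(x)) return(as.integer(x))
  match(as.character(x), labels)
}

code_to_geno <- function(x, labels = GENO_LABELS) labels[x]

#' Haldane map functions
#'
#' Convert between genetic distance in centimorgans and recombination
#' fraction under Haldane's no-interference model.
#'
#' @param d Distance in cM.
#' @param r Recombination fraction in `[0, 0.5)`.
#' @return `haldane_r()` returns a recombination fraction; `haldane_d()`
#'   returns a distance in cM.
#' @examples
#' haldane_r(10)
#' haldane_d(haldane_r(10))
#' @export
haldane_r <- function(d) 0.5 * (1 - exp(-2 * d / 100))

#' @rdname haldane_r
#' @export
haldane_d <- function(r) -50 * log(1 - 2 * pmin(r, 0.4999))

# Kosambi equivalents, available behind the map_function flag in mapbuild.
kosambi_r <- function(d) 0.5 * tanh(2 * d / 100)
kosambi_d <- function(r) 25 * log((1 + 2 * r) / (1 - 2 * r))

map_fun <- function(map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (map_function == "haldane") list(r = haldane_r, d = haldane_d)
  else list(r = kosambi_r, d = kosambi_d)
}

#' One-step genotyping error matrix
#'
#' Row-stochastic matrix of observation probabilities under the one-step
#' error model: rows are true genotypes (AA, AB, BB), columns observed
#' calls. A call one mutational step away (AA <-> AB <-> BB) has relative
#' weight `eps`, two steps away `eps^2`; rows are renormalized.
#'
#' @param eps One-step error probability.
#' @return A 3 x 3 numeric matrix.
#' @examples
#' error_matrix(0.01)
#' @export
error_matrix <- function(eps) {
  m <- rbind(
    c(1, eps, eps^2),
    c(eps, 1, eps),
    c(eps^2, eps, 1)
  )
  m / rowSums(m)
}

# Emission matrix over the five observable classes (+ implicit missing).
# Dominant classes are unions: not-AA = AB|BB, not-BB = AA|AB.
emission_matrix <- function(eps) {
  e <- error_matrix(eps)
  cbind(e, e[, 2] + e[, 3], e[, 1] + e[, 2])
}

# F2 intercross genotype transition matrix between two loci at
# recombination fraction r (two independent meioses).
f2_transition <- function(r) {
  s <- 1 - r
  rbind(
    c(s^2, 2 * r * s, r^2),
    c(r * s, s^2 + r^2, r * s),
    c(r^2, 2 * r * s, s^2)
  )
}

F2_PRIOR <- c(0.25, 0.5, 0.25)

`%||%` <- function(a, b) if (is.null(a)) b else a
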
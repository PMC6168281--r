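---
title: "Models and methods: mapping maternal and zygotic larval-trait QTL in a structured outbred cross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the models fitted, the assumptions they rest on, the tunable constants
and why their defaults are what they are, what the synthetic-cross
generator does and does not emulate, and the places where the design was
genuinely open and a choice had to be made.

## 1. The cross and its genetic model

The target design is an outbred intercross between a planktotrophic (P)
dam and a lecithotrophic (L) sire: their F1s are crossed among
themselves — four F1 females to a single F1 male — giving four half-sib
G2 families, plus a panel of genotyped F1 siblings. Because each founder
is outbred, a biallelic SNP can segregate in any of four configurations
(AAxBB, ABxAB, AAxAB, ABxBB); monomorphic sites erroneously called as
SNPs add AAxAA and BBxBB; X-linked sites segregate as AAxBY or BBxAY
(informative) or as fixed X/Y differences (sex-diagnostic only, since
every female is one homozygote and every male the heterozygote call).

Intercross markers are *founder-origin coded*: the two marker
pseudo-alleles are "derived from founder 1" and "derived from founder
2", so genotypes `PP`/`PL`/`LL` count lecithotroph alleles once the
founders have been matched to their source populations. A trait is
modelled as

y = mu + sum_q ( a_q alpha_q + d_q delta_q ) + interactions + family + e

with alpha = (#L alleles − 1) in {−1, 0, +1} and delta = 1 for
heterozygotes. This coding is stated explicitly because nothing pins it
down externally: an "additive effect" here is half the distance between
the homozygote class means. Pairwise epistasis uses the four products
alpha*alpha, delta*alpha, alpha*delta, delta*delta.

Maternal-effect traits (offspring size) are attached to the *mother*:
the phenotype of a G2 female is her G3 brood's mean, and her own
genotype probabilities enter the scan. Brood means are unweighted by
brood size — brood sizes are not modelled, and weighting would import an
assumption about the within-brood variance structure we cannot check.

## 2. Segregation inference without parents

For every SNP we evaluate each configuration by a composite likelihood:

* the F1 panel contributes a multinomial likelihood under the F1
  genotype distribution implied by the configuration;
* each G2 family contributes the maximum, over the F1 parent pairs
  consistent with the configuration, of the pair's Mendelian prior times
  the multinomial likelihood of the family's genotype counts under the
  pair's transmission probabilities.

Genotype observations are convolved with a **one-step error model**: a
call one mutational step from the truth (AA &harr; AB &harr; BB) has
relative weight eps, two steps eps^2, rows renormalized. The error rate
is profiled per family (and for the panel) on a grid from 0 to 0.10 in
steps of 0.001, ties broken toward smaller eps; the 10% cap keeps the
error channel from absorbing genuine segregation. Ties between
configurations are broken toward the one implying fewer error calls
(smaller summed eps-hat).

Two points here were genuinely open. First, the per-family F1 pairs are
maximized independently: the single shared sire is *not* constrained to
have the same genotype in every family. This is exactly what makes the
likelihood composite rather than joint; it is simpler, robust to a
family with aberrant counts, and on simulated data (1,000 SNPs, default
family sizes, eps = 0.01) recovers the generating configuration for
more than 99% of SNPs, so the joint version would have little to add.
Second, the Mendelian prior P(F1 pair | configuration) is included as a
factor; profiling without the prior would let implausible parent pairs
(e.g. both parents the rare homozygote) fit small families too well.

## 3. Recoding multi-SNP contigs

Contigs carrying several SNPs are recoded into single intercross
markers by reconstructing the four founder haplotypes. Per family, the
imputed F1 parent genotype vectors are phased by choosing the haplotype
pair that makes the most G2 individuals fully consistent; globally, a
side assignment gives every parent one haplotype from each founder,
with at most two distinct haplotype states per founder, and with the
per-SNP implied founder genotypes required to match the configuration
inferred by composite likelihood. A G2 receives a marker genotype only
when *all* of its non-missing SNP calls match one intact
(maternal, paternal) haplotype pair — a deliberate layer of stringency
against single erroneous calls. When a parent's two haplotypes are
identical in state, transmitted origin is ambiguous and the family gets
dominant codes (`not-PP` / `not-LL`); a contig is kept only if at least
one family is fully resolvable. Contigs with more than 8 SNPs are split
into consecutive blocks first (haplotype intactness across many SNPs is
too stringent under realistic missingness). Single SNPs qualify as
intercross markers only under AAxBB — under AAxAB a lone site never
yields a fully resolvable family, which the haplotype algebra shows
directly.

The per-family phases are chosen greedily before the global side
assignment; a contig whose greedy phases cannot be reconciled globally
is rejected rather than searched exhaustively. This loses a small
number of recodable contigs and never miscodes one.

Pedigree screening counts, for each G2 and each candidate F1 mother,
genotype calls that are Mendelian-impossible under the family's imputed
parent pair, restricted to SNPs where the family has a zero-probability
class. The recorded-mother rejection threshold is 5%. The
"incompatible with every mother" threshold is 10%: uniform-random calls
land in an impossible class at only about one-third of informative
sites, so a badly contaminated sample shows 10–15% incompatibility
while one-step genotyping error at realistic rates (&le; 1.3%) stays
under about 2% — 10% separates the two regimes cleanly, which a larger
threshold would not.

## 4. Map construction

Two-point recombination fractions are estimated by direct numerical
maximum likelihood of the two-locus intercross transmission model
(dominant codes summed over their compatible classes; both linkage
phases evaluated because founder orientation is arbitrary per marker
until the pool-seq stage). An EM iteration would find the same maximum;
`optimize()` on the closed-form log-likelihood is simpler and its
convergence is unconditional. Pairs sharing fewer than 10 informative
individuals are undefined and excluded from grouping.

Grouping is single-linkage clustering at LOD &ge; 15, followed by
singleton adoption at LOD &ge; 10 with a &ge; 5 LOD margin over the
runner-up group — thresholds kept as configuration values. Markers are
then phase-oriented once per group along a maximum-LOD spanning tree;
subsequent ordering passes never re-orient (re-deriving orientation
from stale phase matrices after cleaning is a subtle way to scramble
founder sides, found and eliminated during development).

Ordering is greedy seriation from pairwise linkage, refined by an
exhaustive permutation "ripple" with window 7, restarted from 20 seeded
starting points; completed orders are compared by the full multipoint
HMM likelihood and the best kept. The ripple itself scores candidate
windows by the two-point composite log-likelihood: a full-HMM
evaluation of 5,040 permutations per window position would cost orders
of magnitude more for the same accepted moves in practice. Orientation
of a completed group is arbitrary; orders are canonicalized so the
first marker's input index precedes the last's.

The intercross HMM has states PP/PL/LL with the standard two-meiosis
transition matrix and the one-step emission model. It supplies: the
multipoint likelihood for ordering; `genotype_probs()` (forward–
backward posteriors at markers and on a 1 cM grid, the substrate of
Haley–Knott scanning); `estimate_error_rate()` (likelihood maximized
over eps on [0, 0.1] by golden-section search); and `error_lod()` — the
log10 posterior odds that a call is erroneous versus correct given the
two nearest informative flanking markers. Error-LOD scores above 6 are
converted to missing. Note the arithmetic of that statistic: it only
exceeds 6 when the flanks are genetically very close (effectively
co-segregating), so cleaning bites on dense, clustered maps and is a
no-op on sparse ones — the invariant that map lengths shrink or hold
under cleaning follows. Individuals whose minimal crossover count
exceeds the mean by 4 SD are dropped before re-ordering, mirroring the
excess-crossover signature of a high-error sample. Haldane's map
function (no interference) is used throughout; Kosambi is available via
`map_function = "kosambi"`.

## 5. Founder assignment from pool-seq

Population allele frequencies are estimated from pooled read counts
with one read added to every allele count
(`p = (n_ref + 1) / (n_ref + n_alt + 2)`), which bounds every per-SNP
likelihood factor away from 0 and 1 and keeps the statistic finite at
zero coverage. Replicate libraries of a population are summed before
the pseudocount — they are draws from the same pool, and summation
maximizes effective depth. For each linkage group the two labellings of
the inferred homozygous-alternate founder genotypes are compared under
Hardy–Weinberg equilibrium (each homozygote contributes p^2; no
inbreeding correction), and log10 L(H1)/L(H2) is reported; its sign
orients the group and `polarize_map()` flips genotype codes so L alleles
derive from the lecithotroph founder genome-wide. Only SNPs inferred
homozygous-alternate in the founders enter; the only additional filter
is presence in both pools.

## 6. Scans, thresholds, and model fits

Scans are Haley–Knott regressions of the trait on expected dosages
within each family, summed across families; binary traits use logistic
regression with LOD = LRT/(2 ln 10), falling back to a light
data-augmentation ridge when a position separates. Families with fewer
than 5 phenotyped individuals are excluded with a warning. The scan
grid is 1 cM by default.

Genome-wide thresholds come from permuting phenotypes among individuals
within (never across) G2 families — preserving family means and
variances under the null — and taking the 95th percentile of the
genome-wide maximum summed statistic over 1,000 permutations by
default. The same statistic is used for binary traits. One master seed
drives the permutation streams, so thresholds are exactly reproducible.
No multiplicity control is applied across traits beyond the per-trait
genome-wide threshold. Under within-family exchangeability the
procedure is essentially exact: its genome-wide type-I error measured
over 1,500 independent null crosses is 0.049 (and the acceptance suite
re-measures it over 500 crosses at 200 permutations each — a reduced
permutation count whose discreteness costs a fraction of a percentage
point at most).

`fit_qtl_model()` fits all declared loci jointly with optional
epistasis and family effects and reports drop-one percentages of
variance (deviance for binary traits): dropping a locus also drops its
interactions, dropping an interaction drops only the interaction, and
the percentage is the RSS increase over the corrected total sum of
squares. The multivariate scan fits Y = XB + e at each position with
intercept, family, and the marker's two dosage columns, tests the
marker by the Pillai–Bartlett trace with the standard F approximation
(reducing exactly to the univariate F test when one trait is supplied),
and derives thresholds from within-family permutation of phenotype
*row vectors* so the traits' correlation structure is preserved.
`reduce_multivariate_model()` backward-prunes dosage columns at
p &ge; 0.01 and reports coefficients on unit-variance traits — effect
vectors in phenotypic-SD units whose angles separate maternal from
zygotic axes. Backcross broods are analysed with a brood random
intercept (`lme4`, ML fits) and a likelihood-ratio test of the sire
L-dosage terms; loci with a single sire genotype class are dropped with
a warning.

## 7. The synthetic-data generator

`simulate_cross()` is first-class, tested code, and its defaults *are*
the study conditions the rest of the package assumes: four half-sib G2
families of 51/78/37/79 sharing one F1 sire, a 47-animal F1 panel, ten
50 cM autosomes plus a 40 cM X with male hemizygosity and a
distinguishable Y, ~940 contigs / ~1,400 SNPs with mostly 1–3 SNPs per
contig and a rare 16-SNP contig, a 35% share of AAxBB sites among a
realistic mixture of configurations, one-step genotyping error
(default eps = 0.01, inside the 0.004–0.013 range the map-construction
stage estimates), and 10% missing calls. Meioses follow Haldane's model
(no crossover interference — the standard assumption, and the one the
downstream HMM machinery makes; simulating interference would test the
machinery against data it does not claim to model). Founder haplotypes
are tracked explicitly, so origin truth exists at every position.

The trait architecture defaults: chaetae number
(intercept 4.29; additive −2.53 and −2.30 on LG3/LG8, dominance −0.58
and 0.31; rounded and floored at zero, generated as a rounded Gaussian
rather than a Poisson because the analysis models it with a normal QTL
model), chaetae length in um (intercept 140.02; additive −29.59 /
−25.07 on LG3/LG9 with a dominant shortening allele; family effects
2.60/0.01/0/−19.72 for A/C/F/H), G3 mean offspring area in um^2 as the
maternal trait (intercept 29,516.79; additive 3,356.14 / 4,020.69 on
LG6/LG7 with the four-term LG6xLG7 epistasis, AxD = −3,297.03
dominating), and anal cirri as a logistic trait on LG5. Residual SDs
(3.0 chaetae, 34 um, 3,700 um^2) are calibrated so each locus' drop-one
variance share lands in the observed 13–26% band; with those values
about 17% of simulated G2s lack chaetae entirely — zero-truncation
emerges from the architecture rather than being imposed — close to the
15% observed in real G2 panels.

One deliberate departure: fitted logistic coefficients for anal cirri
in data of this kind are unstable (standard errors an order of
magnitude above the estimates, a separation artefact), and taken at
face value they would imply ~69% of larvae lacking cirri when ~25% is
observed. The generator therefore uses a calibrated logistic
(intercept 1.08, additive −3.52, dominance 1.86, i.e. presence
probabilities 0.99/0.95/0.08 for PP/PL/LL) that reproduces the 25%
absence and the direction of the L-allele effect. `larval_area` (the
G2's own size) carries *no* QTL — all G2s share heterozygous F1
mothers — only an environmental family effect plus noise, so scans of
it are a built-in negative control.

`simulate_backcross()` mates G2 males to all-P dams; offspring dosages
at the chaetae loci segregate from the sire with recombination between
linked loci, and phenotypes add a brood random intercept with SD equal
to half the residual SD (a value the design leaves open; it is needed
for the mixed model to have something to estimate). Default scale is 30
sires by 45 offspring. `simulate_poolseq()` gives the P founder's
allele frequency 0.5 + d/2 in its own population and 0.5 − d/2 in the
other (default divergence d = 0.2), resamples a pool of 25 diploid
females once per population, and draws reads binomially at
Poisson(20) depth, independently per replicate library.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: read-level variation (depth,
allele-specific bias, genotype-likelihood uncertainty; calls are taken
as given), linkage disequilibrium or relatedness inside the source
populations beyond the two-frequency model, crossover interference,
segregation distortion from viability selection, batch or plate
effects, and informative missingness (dropout here is uniform at
random). Conclusions about those failure modes need real data.

## 8. Numerical conventions and degenerate inputs

Probabilities are floored at 1e-300 before logs; forward–backward is
rescaled per step; an individual with no informative markers on a
chromosome sits at the 1/4, 1/2, 1/4 prior; probability triples sum to
one within 1e-9. The error grid step is 0.001 with ties toward smaller
eps. Recombination fractions are confined to [1e-6, 0.4999]; map
distances use the Haldane inverse. All writers emit fixed column
orders, `\n` line endings and `.` for missing, so staged outputs are
hash-stable; `run_pipeline()` records seed, package version and a
configuration hash in JSON per stage and can resume from cached stage
outputs. Test and acceptance problem sizes are scaled-down versions of
the same conditions (e.g. 70–300 contigs instead of 940, 200
permutations instead of 1,000, 500 null crosses for calibration);
sizes are stated where used.

## 9. Known limitations

The composite likelihood ignores the shared-sire constraint (above);
contig recoding is greedy-then-global rather than exhaustive; the
X chromosome is mapped (2-state, sex-aware) but not scanned for QTL —
the traits of interest map to autosomes, and a hemizygous scan model
would need its own dosage conventions; binary-trait permutation scans
are exact but slow at 1,000 permutations; and `error_lod()` uses the
two nearest informative flanks rather than the full chromosome, the
standard fast approximation with a closed form that tests can verify.
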